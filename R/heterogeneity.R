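# Treatment-effect heterogeneity: per-observation blip estimates
# b(W) = Q(1,W) - Q(0,W), regression-tree subgroup discovery, and predicted
# program impact in conventional-care clinics.

#' Fit an outcome model usable for counterfactual prediction
#'
#' @param data Analysis table (complete cases).
#' @param adjustment_set Covariate column names.
#' @param engine `"superlearner"` (default), `"logistic"` (main effects), or
#'   `"logistic_interactions"` (main effects plus exposure-by-covariate
#'   interaction terms — the natural parametric model when the treatment
#'   effect itself may vary with covariates).
#' @param ... Super Learner controls (learners, V, seed).
#' @return Object of class `outcome_model` with a
#'   `predict_counterfactual(newdata)` contract returning `p1` and `p0`.
#' @export
fit_outcome_model <- function(data, adjustment_set,
                              engine = c("superlearner", "logistic",
                                         "logistic_interactions"), ...) {
  engine <- match.arg(engine)
  X <- as_features(data, adjustment_set)
  y <- data$outcome
  a <- data$exposed
  if (engine == "logistic") {
    dd <- cbind(.y = y, .a = a, X)
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dd,
                                       family = stats::binomial()))
  } else if (engine == "logistic_interactions") {
    dd <- cbind(.y = y, .a = a, X)
    f <- stats::as.formula(paste(
      ".y ~ . +", paste0(".a:", names(X), collapse = " + ")))
    fit <- suppressWarnings(stats::glm(f, data = dd,
                                       family = stats::binomial()))
  } else {
    cl <- if ("patient_id" %in% names(data)) data$patient_id else NULL
    fit <- fit_super_learner(cbind(.a = a, X), y, cluster_ids = cl, ...)
  }
  structure(list(fit = fit, engine = engine,
                 adjustment_set = adjustment_set),
            class = "outcome_model")
}

#' Counterfactual outcome probabilities at both exposure levels
#'
#' @param model An `outcome_model`.
#' @param newdata Rows with the model's adjustment covariates.
#' @return List with numeric vectors `p1` and `p0`.
#' @export
predict_counterfactual <- function(model, newdata) {
  X <- as_features(newdata, model$adjustment_set)
  if (model$engine %in% c("logistic", "logistic_interactions")) {
    p1 <- stats::predict(model$fit, newdata = cbind(.a = 1, X),
                         type = "response")
    p0 <- stats::predict(model$fit, newdata = cbind(.a = 0, X),
                         type = "response")
  } else {
    p1 <- predict(model$fit, cbind(.a = 1, X))
    p0 <- predict(model$fit, cbind(.a = 0, X))
  }
  list(p1 = unname(p1), p0 = unname(p0))
}

#' Estimate per-observation treatment effects (blips)
#'
#' Differences the outcome-model predictions at exposure 1 and 0 for every
#' covariate row.  Blips come from the initial (machine-learning) fit, not
#' the targeted fit: targeting is a marginal correction and is ill-suited to
#' per-row prediction.
#'
#' @param data Analysis table (typically program-clinic observations).
#' @param adjustment_set Covariate column names.
#' @param engine,... Passed to [fit_outcome_model()]; alternatively supply a
#'   pre-fitted model via `model`.
#' @param model Optional existing `outcome_model`.
#' @return Object of class `blip_estimate`: data.frame-like list with
#'   per-row `blip`, the `model`, and the source tag.
#' @export
estimate_blips <- function(data, adjustment_set,
                           engine = c("superlearner", "logistic",
                                      "logistic_interactions"),
                           model = NULL, ...) {
  if (is.null(model)) {
    model <- fit_outcome_model(data, adjustment_set, engine = engine, ...)
  }
  cf <- predict_counterfactual(model, data)
  blip <- cf$p1 - cf$p0
  stopifnot(all(blip >= -1 & blip <= 1))
  structure(list(blip = blip, model = model, source = model$engine,
                 data = data), class = "blip_estimate")
}

#' Regression tree on estimated blips
#'
#' CART-style recursive partitioning (via rpart, squared-error splitting) of
#' the estimated individual treatment effects on covariates: terminal nodes
#' are subgroups with homogeneous predicted program benefit.  A split is
#' kept only if it reduces the total sum of squares by at least
#' `complexity` times the root sum of squares; leaves contain at least
#' `min_leaf` observations.  With fewer than `2 * min_leaf` rows the tree is
#' a single root node.
#'
#' @param blips A `blip_estimate` or a numeric vector of blips.
#' @param covariates data.frame of splitting covariates (defaults to the
#'   blip estimate's adjustment covariates).
#' @param max_depth,min_leaf,complexity Tree controls (defaults 5, 20, 0.01).
#' @param cv_prune Logical; cost-complexity pruning by 10-fold CV (off by
#'   default).
#' @return Object of class `blip_tree`: the rpart fit, a leaf summary
#'   (id, size, mean blip), and the overall mean blip.
#' @export
fit_blip_tree <- function(blips, covariates = NULL, max_depth = 5,
                          min_leaf = 20, complexity = 0.01,
                          cv_prune = FALSE) {
  if (inherits(blips, "blip_estimate")) {
    if (is.null(covariates)) {
      covariates <- blips$data[blips$model$adjustment_set]
    }
    b <- blips$blip
  } else {
    b <- as.numeric(blips)
  }
  stopifnot(!is.null(covariates), nrow(covariates) == length(b))
  d <- cbind(.blip = b, as.data.frame(covariates))
  fit <- rpart::rpart(.blip ~ ., data = d, method = "anova",
                      control = rpart::rpart.control(
                        maxdepth = max_depth, minbucket = min_leaf,
                        cp = complexity,
                        xval = if (cv_prune) 10 else 0))
  if (stats::var(b) == 0 && nrow(fit$frame) > 1) {
    # constant blips: a degenerate zero-SSE surface, collapse to the root
    fit <- rpart::prune(fit, cp = 1e9)
  }
  if (cv_prune && !is.null(fit$cptable) && nrow(fit$cptable) > 1) {
    cpt <- fit$cptable
    best <- cpt[which.min(cpt[, "xerror"]), "CP"]
    fit <- rpart::prune(fit, cp = best)
  }
  leaf_rows <- fit$frame$var == "<leaf>"
  leaves <- data.frame(
    node = as.integer(rownames(fit$frame))[leaf_rows],
    n = fit$frame$n[leaf_rows],
    mean_blip = fit$frame$yval[leaf_rows])
  structure(list(rpart = fit, leaves = leaves, mean_blip = mean(b),
                 n = length(b)), class = "blip_tree")
}

#' @export
print.blip_tree <- function(x, ...) {
  cat("Blip regression tree:", nrow(x$leaves), "terminal subgroup(s),",
      "overall mean effect", sprintf("%.4f", x$mean_blip), "\n")
  print(x$rpart)
  invisible(x)
}

#' Export a blip tree as indented text or nested JSON
#'
#' @param tree A `blip_tree`.
#' @param path Output path.
#' @export
export_blip_tree_text <- function(tree, path) {
  txt <- utils::capture.output(print(tree$rpart))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname export_blip_tree_text
#' @export
export_blip_tree_json <- function(tree, path) {
  fr <- tree$rpart$frame
  nodes <- as.integer(rownames(fr))
  labs <- labels(tree$rpart)
  build <- function(node) {
    i <- match(node, nodes)
    out <- list(node = node, label = labs[i],
                variable = as.character(fr$var[i]),
                n = fr$n[i], mean_blip = fr$yval[i])
    kids <- c(2 * node, 2 * node + 1)
    kids <- kids[kids %in% nodes]
    if (length(kids)) out$children <- lapply(kids, build)
    out
  }
  jsonlite::write_json(build(1L), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Predicted program impact in conventional-care clinics
#'
#' Routes each conventional-care observation through the blip tree (or
#' differences the outcome model) to predict the improvement in glycemic
#' control the program would deliver, and summarizes the per-clinic
#' distributions for a boxplot-style display.
#'
#' @param object A `blip_tree` or `blip_estimate`/`outcome_model`.
#' @param control_data Conventional-care clinic rows with the model's
#'   covariates (and `clinic_id`).
#' @return List: `per_obs` (clinic_id, impact) and `by_clinic`
#'   (clinic_id, n, min, q1, median, q3, max, mean).  Empty input gives
#'   empty tables.
#' @export
predict_control_clinic_impact <- function(object, control_data) {
  if (nrow(control_data) == 0) {
    empty <- data.frame(clinic_id = character(), impact = numeric())
    return(list(per_obs = empty,
                by_clinic = data.frame(clinic_id = character(), n = integer(),
                                       min = numeric(), q1 = numeric(),
                                       median = numeric(), q3 = numeric(),
                                       max = numeric(), mean = numeric())))
  }
  impact <- if (inherits(object, "blip_tree")) {
    unname(stats::predict(object$rpart, newdata = control_data))
  } else if (inherits(object, "blip_estimate")) {
    cf <- predict_counterfactual(object$model, control_data)
    cf$p1 - cf$p0
  } else if (inherits(object, "outcome_model")) {
    cf <- predict_counterfactual(object, control_data)
    cf$p1 - cf$p0
  } else {
    stop("unsupported object for impact prediction", call. = FALSE)
  }
  per_obs <- data.frame(clinic_id = control_data$clinic_id, impact = impact,
                        stringsAsFactors = FALSE)
  by_clinic <- do.call(rbind, lapply(split(per_obs$impact, per_obs$clinic_id),
    function(v) {
      fv <- stats::fivenum(v)
      data.frame(n = length(v), min = fv[1], q1 = fv[2], median = fv[3],
                 q3 = fv[4], max = fv[5], mean = mean(v))
    }))
  by_clinic <- cbind(clinic_id = rownames(by_clinic), by_clinic)
  rownames(by_clinic) <- NULL
  list(per_obs = per_obs, by_clinic = by_clinic)
}
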
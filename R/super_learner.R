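# Super Learner: V-fold cross-validated convex stacking of candidate
# binary-outcome learners under negative log-likelihood loss.

PRED_FLOOR <- 1e-6

clip_prob <- function(p, floor = PRED_FLOOR) pmin(pmax(p, floor), 1 - floor)

#' Negative log-likelihood (log-loss) for probability predictions
#'
#' @param y Binary labels.
#' @param p Predicted probabilities (clipped to `[1e-6, 1 - 1e-6]`).
#' @return Mean negative Bernoulli log-likelihood.
#' @export
log_loss <- function(y, p) {
  p <- clip_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Candidate learner constructors
#'
#' Each returns a `learner_spec`: a name plus fit/predict closures mapping a
#' numeric feature data.frame and binary labels to a probability predictor.
#' Predictions are clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param maxdepth,cp,minbucket rpart controls for the tree learner.
#' @param nrounds,max_depth,eta Boosting controls for the xgboost learner.
#' @param k Neighbourhood size for the k-nearest-neighbour learner.
#' @return A `learner_spec` object.
#' @name learners
NULL

new_learner <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "learner_spec")
}

#' @rdname learners
#' @export
sl_lrn_mean <- function() {
  new_learner("mean",
    fit = function(X, y, weights = NULL) {
      if (is.null(weights)) weights <- rep(1, length(y))
      list(p = sum(y * weights) / sum(weights))
    },
    predict = function(model, X) rep(model$p, nrow(X)))
}

#' @rdname learners
#' @export
sl_lrn_glm <- function() {
  new_learner("glm_main",
    fit = function(X, y, weights = NULL) {
      d <- cbind(.y = y, X)
      suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial(),
                                  weights = weights))
    },
    predict = function(model, X) {
      suppressWarnings(stats::predict(model, newdata = X,
                                      type = "response"))
    })
}

#' @rdname learners
#' @export
sl_lrn_glm_interactions <- function() {
  new_learner("glm_interactions",
    fit = function(X, y, weights = NULL) {
      d <- cbind(.y = y, X)
      suppressWarnings(stats::glm(.y ~ .^2, data = d,
                                  family = stats::binomial(),
                                  weights = weights))
    },
    predict = function(model, X) {
      suppressWarnings(stats::predict(model, newdata = X,
                                      type = "response"))
    })
}

#' @rdname learners
#' @export
sl_lrn_rpart <- function(maxdepth = 5, cp = 0.003, minbucket = 20) {
  new_learner("rpart",
    fit = function(X, y, weights = NULL) {
      d <- cbind(.y = y, X)
      rpart::rpart(.y ~ ., data = d, method = "anova", weights = weights,
                   control = rpart::rpart.control(maxdepth = maxdepth,
                                                  cp = cp,
                                                  minbucket = minbucket,
                                                  xval = 0))
    },
    predict = function(model, X) {
      clip_prob(stats::predict(model, newdata = X))
    })
}

#' @rdname learners
#' @export
sl_lrn_xgboost <- function(nrounds = 50, max_depth = 3, eta = 0.3) {
  new_learner("xgboost",
    fit = function(X, y, weights = NULL) {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        stop("xgboost not available", call. = FALSE)
      }
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y,
                                     weight = weights, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, nthread = 1),
        data = dtrain, nrounds = nrounds, verbose = 0)
    },
    predict = function(model, X) {
      stats::predict(model, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1))
    })
}

#' @rdname learners
#' @export
sl_lrn_knn <- function(k = 25) {
  new_learner("knn",
    fit = function(X, y, weights = NULL) {
      list(X = as.matrix(X), y = y, k = k)
    },
    predict = function(model, X) {
      if (!requireNamespace("class", quietly = TRUE)) {
        stop("class not available", call. = FALSE)
      }
      pred <- class::knn(model$X, as.matrix(X), factor(model$y),
                         k = model$k, prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    })
}

#' Default candidate library
#'
#' Mean, main-effects logistic, pairwise-interaction logistic, depth-limited
#' regression tree and shallow gradient boosting: a spread of smooth and
#' non-smooth learners so the ensemble does well whether the true regression
#' is simple or complex.
#'
#' @return List of `learner_spec` objects.
#' @export
default_learner_library <- function() {
  lib <- list(sl_lrn_mean(), sl_lrn_glm(), sl_lrn_glm_interactions(),
              sl_lrn_rpart())
  if (requireNamespace("xgboost", quietly = TRUE)) {
    lib <- c(lib, list(sl_lrn_xgboost()))
  }
  lib
}

#' Cross-validation fold assignment
#'
#' Balanced fold sizes (differing by at most one unit); when `cluster_ids`
#' are supplied, all observations of a cluster share a fold (e.g. repeated
#' patient-years never straddle a training/validation split).
#'
#' @param n Number of observations.
#' @param V Number of folds.
#' @param cluster_ids Optional cluster labels of length `n`.
#' @param seed Integer seed for the shuffle.
#' @return Integer fold labels in `1:V` of length `n`.
#' @export
make_folds <- function(n, V, cluster_ids = NULL, seed = 1) {
  if (V < 2 || V > n) stop("need 2 <= V <= n", call. = FALSE)
  if (is.null(cluster_ids)) {
    with_seed(seed, sample(rep_len(seq_len(V), n)))
  } else {
    stopifnot(length(cluster_ids) == n)
    cl <- unique(cluster_ids)
    if (V > length(cl)) {
      stop("V exceeds the number of clusters", call. = FALSE)
    }
    cl_fold <- with_seed(seed, sample(rep_len(seq_len(V), length(cl))))
    cl_fold[match(cluster_ids, cl)]
  }
}

# Convex weight solve: minimize NLL of Z %*% w over the simplex via a
# permutation-equivariant softmax parametrization, with every vertex and the
# uniform point as fall-back candidates.
solve_simplex_weights <- function(Z, y) {
  K <- ncol(Z)
  if (K == 1) return(1)
  risk <- function(w) log_loss(y, drop(Z %*% w))
  obj <- function(theta) {
    w <- exp(theta - max(theta)); w <- w / sum(w)
    risk(w)
  }
  opt <- stats::optim(rep(0, K), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  w <- exp(opt$par - max(opt$par)); w <- w / sum(w)
  # sparsify: drop negligible weights, prefer a vertex on ties
  w[w < 1e-6] <- 0
  w <- w / sum(w)
  cand <- c(list(w), lapply(seq_len(K), function(k) {
    v <- rep(0, K); v[k] <- 1; v
  }))
  risks <- vapply(cand, risk, numeric(1))
  best <- min(risks)
  sparsity <- vapply(cand, function(v) sum(v > 0), numeric(1))
  pick <- which(risks <= best + 1e-10)
  cand[[pick[which.min(sparsity[pick])]]]
}

#' Fit a Super Learner ensemble
#'
#' V-fold cross-validation of each candidate learner, followed by a convex
#' combination of the candidates' cross-validated predictions minimizing the
#' negative Bernoulli log-likelihood over the simplex, and a refit of each
#' candidate on the full data.  A learner that fails on any fold is dropped
#' with a warning; the ensemble aborts only if every learner fails.
#'
#' @param X Numeric feature data.frame (no missing values).
#' @param y Binary labels.
#' @param learners List of `learner_spec`s (default
#'   [default_learner_library()]).
#' @param V Number of folds (default 10).
#' @param cluster_ids Optional cluster labels for clustered folds.
#' @param seed Integer seed for fold assignment.
#' @return Object of class `super_learner`: `weights` (simplex vector, named
#'   by learner), `cv_risks`, `cv_risk_ensemble`, fitted candidates, fold
#'   assignment.
#' @export
fit_super_learner <- function(X, y, learners = default_learner_library(),
                              V = 10, cluster_ids = NULL, seed = 1) {
  stopifnot(length(learners) >= 1, nrow(X) == length(y))
  if (anyNA(X)) stop("missing values in features", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  X <- as.data.frame(X)
  n <- length(y)
  folds <- make_folds(n, V, cluster_ids = cluster_ids, seed = seed)

  Z <- matrix(NA_real_, n, length(learners))
  ok <- rep(TRUE, length(learners))
  for (k in seq_along(learners)) {
    lrn <- learners[[k]]
    for (v in seq_len(V)) {
      tr <- folds != v
      pk <- tryCatch({
        m <- lrn$fit(X[tr, , drop = FALSE], y[tr])
        clip_prob(lrn$predict(m, X[!tr, , drop = FALSE]))
      }, error = function(e) e)
      if (inherits(pk, "error")) {
        warning("learner '", lrn$name, "' failed in fold ", v,
                " and was dropped: ", conditionMessage(pk), call. = FALSE)
        ok[k] <- FALSE
        break
      }
      Z[!tr, k] <- pk
    }
  }
  if (!any(ok)) stop("all learners failed", call. = FALSE)
  learners <- learners[ok]
  Z <- Z[, ok, drop = FALSE]

  w <- solve_simplex_weights(Z, y)
  cv_risks <- apply(Z, 2, function(p) log_loss(y, p))
  names(cv_risks) <- vapply(learners, `[[`, character(1), "name")
  names(w) <- names(cv_risks)

  fits <- lapply(learners, function(l) l$fit(X, y))
  structure(list(
    learners = learners, fits = fits, weights = w, cv_risks = cv_risks,
    cv_risk_ensemble = log_loss(y, drop(Z %*% w)),
    folds = folds, feature_names = names(X), V = V, seed = seed
  ), class = "super_learner")
}

#' Predict ensemble probabilities
#'
#' @param object A fitted `super_learner`.
#' @param newdata Feature data.frame with the training columns.
#' @param ... Unused.
#' @return Probabilities in `[1e-6, 1 - 1e-6]`.
#' @export
predict.super_learner <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss)) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  newdata <- newdata[object$feature_names]
  p <- rep(0, nrow(newdata))
  for (k in seq_along(object$learners)) {
    if (object$weights[k] == 0) next
    p <- p + object$weights[k] *
      clip_prob(object$learners[[k]]$predict(object$fits[[k]], newdata))
  }
  clip_prob(p)
}

#' @export
print.super_learner <- function(x, ...) {
  cat("Super Learner (", x$V, "-fold CV, n = ", length(x$folds), ")\n",
      sep = "")
  tab <- data.frame(weight = round(x$weights, 4),
                    cv_risk = round(x$cv_risks, 5))
  print(tab)
  cat("ensemble CV risk:", format(x$cv_risk_ensemble, digits = 6), "\n")
  invisible(x)
}

#' Serialize ensemble metadata to JSON
#'
#' Writes weights, cross-validated risks, fold count and learner names to a
#' sidecar file; learners are re-fit from data on load rather than stored.
#'
#' @param fit A `super_learner`.
#' @param path Output JSON path.
#' @export
export_super_learner <- function(fit, path) {
  jsonlite::write_json(list(
    learners = names(fit$weights),
    weights = unname(fit$weights),
    cv_risks = unname(fit$cv_risks),
    cv_risk_ensemble = fit$cv_risk_ensemble,
    V = fit$V, seed = fit$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
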
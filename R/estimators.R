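# ATE estimators on binary outcomes: unadjusted difference in proportions,
# logistic g-computation (marginal standardization), and TMLE with
# influence-curve inference; clinic-stratified and pooled variants.

as_features <- function(data, cols) {
  X <- data[cols]
  bad <- names(X)[!vapply(X, is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  X
}

# Cluster-robust SE of a mean-zero influence curve: sum contributions within
# each independent unit, variance over units.  With unique ids this is the
# usual sd(ic)/sqrt(n) up to the n vs n-1 factor.
clustered_se <- function(ic, cluster_ids = NULL) {
  n <- length(ic)
  if (is.null(cluster_ids)) cluster_ids <- seq_len(n)
  sums <- tapply(ic, cluster_ids, sum)
  sqrt(sum(sums^2)) / n
}

estimate_row <- function(clinic_id, method, n0, n1, p0, p0_ci, p1, p1_ci,
                         rd, rd_ci) {
  data.frame(clinic_id = clinic_id, method = method, n0 = n0, n1 = n1,
             p0 = p0, p0_lo = p0_ci[1], p0_hi = p0_ci[2],
             p1 = p1, p1_lo = p1_ci[1], p1_hi = p1_ci[2],
             rd = rd, rd_lo = rd_ci[1], rd_hi = rd_ci[2],
             stringsAsFactors = FALSE)
}

#' Unadjusted difference in control proportions
#'
#' Raw proportions of glycemic control among exposed and unexposed
#' observations and their risk difference, with Wald intervals from the
#' binomial variance; an optional patient-cluster correction sums each
#' patient's influence-curve contributions before taking the variance.
#'
#' @param data Analysis table with complete `exposed` and `outcome`.
#' @param cluster_ids Optional patient identifiers for clustered variance.
#' @param clinic_id Label for the output row (default `"All"`).
#' @return A one-row estimate data.frame (group means, RD, 95% CIs).
#' @export
unadjusted_estimate <- function(data, cluster_ids = NULL,
                                clinic_id = "All") {
  a <- data$exposed
  y <- data$outcome
  if (!all(a %in% c(0, 1)) || anyNA(y)) {
    stop("exposure must be binary and outcome complete", call. = FALSE)
  }
  n0 <- sum(a == 0); n1 <- sum(a == 1)
  if (n0 == 0 || n1 == 0) stop("an exposure group is empty", call. = FALSE)
  p0 <- mean(y[a == 0]); p1 <- mean(y[a == 1])
  rd <- p1 - p0
  if (is.null(cluster_ids)) {
    se0 <- sqrt(p0 * (1 - p0) / n0)
    se1 <- sqrt(p1 * (1 - p1) / n1)
    se_rd <- sqrt(se0^2 + se1^2)
  } else {
    pi1 <- n1 / length(a)
    ic <- a / pi1 * (y - p1) - (1 - a) / (1 - pi1) * (y - p0)
    se_rd <- clustered_se(ic, cluster_ids)
    ic0 <- (1 - a) / (1 - pi1) * (y - p0)
    ic1 <- a / pi1 * (y - p1)
    se0 <- clustered_se(ic0, cluster_ids)
    se1 <- clustered_se(ic1, cluster_ids)
  }
  z <- stats::qnorm(0.975)
  estimate_row(clinic_id, "unadjusted", n0, n1,
               p0, p0 + c(-z, z) * se0, p1, p1 + c(-z, z) * se1,
               rd, rd + c(-z, z) * se_rd)
}

#' Logistic g-computation (marginal standardization)
#'
#' Fits one logistic regression of the outcome on exposure and covariates,
#' then averages the predicted control probability over all observed
#' covariate rows with exposure forced to 1 and to 0; the risk difference is
#' the difference of these standardized means.  Confidence intervals by
#' nonparametric bootstrap resampling patients.
#'
#' With an empty adjustment set the model is saturated in exposure and the
#' estimate reduces exactly to the unadjusted proportions.
#'
#' @param data Analysis table.
#' @param adjustment_set Covariate column names.
#' @param boot Bootstrap replicates for the CI (default 500; 0 skips the CI).
#' @param cluster_ids Patient identifiers resampled as units (default
#'   `data$patient_id` when present, else rows).
#' @param seed Seed for the bootstrap.
#' @param clinic_id Label for the output row.
#' @return A one-row estimate data.frame.
#' @export
gcomp_logistic_estimate <- function(data, adjustment_set = character(),
                                    boot = 500, cluster_ids = NULL,
                                    seed = 1, clinic_id = "All") {
  point <- function(d) {
    X <- as_features(d, adjustment_set)
    dd <- cbind(.y = d$outcome, .a = d$exposed, X)
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dd,
                                       family = stats::binomial()))
    cf <- stats::coef(fit)
    if (anyNA(cf)) stop("singular design in g-computation", call. = FALSE)
    if (any(abs(cf[-1]) > 15)) {
      warning("possible separation in g-computation fit", call. = FALSE)
    }
    d1 <- dd; d1$.a <- 1
    d0 <- dd; d0$.a <- 0
    c(p1 = mean(stats::predict(fit, newdata = d1, type = "response")),
      p0 = mean(stats::predict(fit, newdata = d0, type = "response")))
  }
  est <- point(data)
  rd <- est[["p1"]] - est[["p0"]]
  ci <- matrix(NA_real_, 3, 2)
  if (boot > 0) {
    if (is.null(cluster_ids)) {
      cluster_ids <- if ("patient_id" %in% names(data)) data$patient_id
                     else seq_len(nrow(data))
    }
    ids <- unique(cluster_ids)
    idx_by_id <- split(seq_len(nrow(data)), factor(cluster_ids, levels = ids))
    bs <- with_seed(seed, {
      vapply(seq_len(boot), function(b) {
        take <- sample(length(ids), replace = TRUE)
        rows <- unlist(idx_by_id[take], use.names = FALSE)
        e <- tryCatch(point(data[rows, , drop = FALSE]),
                      error = function(err) c(p1 = NA_real_, p0 = NA_real_))
        c(e, rd = e[["p1"]] - e[["p0"]])
      }, numeric(3))
    })
    qs <- apply(bs, 1, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    ci <- t(qs[, c("p0", "p1", "rd")])
  }
  estimate_row(clinic_id, "gcomp", sum(data$exposed == 0),
               sum(data$exposed == 1),
               est[["p0"]], ci[1, ], est[["p1"]], ci[2, ], rd, ci[3, ])
}

#' Fit the propensity (program-intervention) model
#'
#' Estimates g(W) = P(exposed | W) with a logistic regression or a Super
#' Learner ensemble, truncates the fitted values to `bounds`, and logs
#' distribution diagnostics.  The model is fit on exposure only, never on
#' the outcome.
#'
#' @param data Analysis table with both exposure levels present.
#' @param adjustment_set Covariate column names.
#' @param engine `"logistic"` or `"superlearner"`.
#' @param bounds Truncation bounds (default `c(0.025, 0.975)`).
#' @param learners,V,seed Super Learner controls (used when
#'   `engine = "superlearner"`).
#' @return Object of class `propensity_fit`: truncated fitted values `g`,
#'   raw values, the model, bounds and diagnostics.
#' @export
fit_propensity <- function(data, adjustment_set,
                           engine = c("logistic", "superlearner"),
                           bounds = c(0.025, 0.975),
                           learners = default_learner_library(),
                           V = 10, seed = 1) {
  engine <- match.arg(engine)
  a <- data$exposed
  if (length(unique(a)) < 2) {
    stop("both exposure levels must be present", call. = FALSE)
  }
  X <- as_features(data, adjustment_set)
  if (engine == "logistic") {
    dd <- cbind(.a = a, X)
    form <- if (ncol(X) == 0) .a ~ 1 else .a ~ .
    model <- suppressWarnings(stats::glm(form, data = dd,
                                         family = stats::binomial()))
    raw <- stats::predict(model, type = "response")
  } else {
    cl <- if ("patient_id" %in% names(data)) data$patient_id else NULL
    model <- fit_super_learner(X, a, learners = learners, V = V,
                               cluster_ids = cl, seed = seed)
    raw <- predict(model, X)
  }
  g <- pmin(pmax(raw, bounds[1]), bounds[2])
  structure(list(
    g = unname(g), raw = unname(raw), model = model, engine = engine,
    bounds = bounds, adjustment_set = adjustment_set,
    diagnostics = list(
      min = min(raw), max = max(raw),
      quantiles = stats::quantile(raw, c(0.01, 0.05, 0.25, 0.5, 0.75,
                                         0.95, 0.99)),
      frac_below_lower = mean(raw < bounds[1]),
      frac_above_upper = mean(raw > bounds[2]))
  ), class = "propensity_fit")
}

#' Targeted maximum likelihood estimation of the ATE
#'
#' Canonical TMLE for a binary outcome and binary exposure: (1) initial
#' outcome regression Q(A,W) by logistic regression or Super Learner;
#' (2) propensity g(W) via [fit_propensity()]; (3) clever covariate
#' H(A,W) = A/g - (1-A)/(1-g); (4) one-dimensional logistic fluctuation of
#' the initial fit with offset logit Q and covariate H, solved to machine
#' precision so the efficient influence curve has mean ~0; (5) targeted
#' predictions at A=1 and A=0; (6) ATE = mean difference; (7) Wald interval
#' from the influence curve, with patient-clustered aggregation when
#' repeated observations share a patient id.
#'
#' @param data Analysis table (complete cases).
#' @param adjustment_set Covariate column names.
#' @param outcome_engine,propensity_engine `"logistic"` or `"superlearner"`.
#' @param bounds Propensity truncation bounds.
#' @param learners,V,seed Super Learner controls.
#' @param cluster_ids Patient identifiers for clustered inference (default
#'   `data$patient_id` when present).
#' @param fluctuate Set `FALSE` to force the fluctuation coefficient to 0,
#'   reducing the estimate to the g-computation plug-in of the initial fit.
#' @return Object of class `tmle_fit` with components `psi`, `se`, `ci95`,
#'   `epsilon`, `ic`, `Q0`, `Qstar`, `g` (the `propensity_fit`), and group
#'   means `p1`, `p0`.
#' @export
tmle_estimate <- function(data, adjustment_set,
                          outcome_engine = c("logistic", "superlearner"),
                          propensity_engine = c("logistic", "superlearner"),
                          bounds = c(0.025, 0.975),
                          learners = default_learner_library(),
                          V = 10, seed = 1, cluster_ids = NULL,
                          fluctuate = TRUE) {
  outcome_engine <- match.arg(outcome_engine)
  propensity_engine <- match.arg(propensity_engine)
  y <- data$outcome
  a <- data$exposed
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome must be complete and binary", call. = FALSE)
  }
  if (is.null(cluster_ids) && "patient_id" %in% names(data)) {
    cluster_ids <- data$patient_id
  }
  X <- as_features(data, adjustment_set)

  # (1) initial outcome fit on (A, W)
  if (outcome_engine == "logistic") {
    dd <- cbind(.y = y, .a = a, X)
    qfit <- suppressWarnings(stats::glm(.y ~ ., data = dd,
                                        family = stats::binomial()))
    qpred <- function(aval) {
      nd <- dd; nd$.a <- aval
      stats::predict(qfit, newdata = nd, type = "response")
    }
    Q0_1 <- qpred(1); Q0_0 <- qpred(0)
  } else {
    XA <- cbind(.a = a, X)
    qfit <- fit_super_learner(XA, y, learners = learners, V = V,
                              cluster_ids = cluster_ids, seed = seed)
    Q0_1 <- predict(qfit, cbind(.a = 1, X))
    Q0_0 <- predict(qfit, cbind(.a = 0, X))
  }
  Q0_1 <- clip_prob(Q0_1); Q0_0 <- clip_prob(Q0_0)
  Q0_obs <- ifelse(a == 1, Q0_1, Q0_0)

  # (2) propensity
  gfit <- fit_propensity(data, adjustment_set, engine = propensity_engine,
                         bounds = bounds, learners = learners, V = V,
                         seed = seed)
  g <- gfit$g
  at_bounds <- mean(g <= bounds[1] | g >= bounds[2])
  if (at_bounds > 0.20) {
    warning(sprintf(
      "positivity: %.0f%% of propensity scores at the truncation bounds",
      100 * at_bounds), call. = FALSE)
  }

  # (3) clever covariate
  H <- a / g - (1 - a) / (1 - g)
  H1 <- 1 / g
  H0 <- -1 / (1 - g)

  # (4) fluctuation: logistic MLE in epsilon, polished by Newton steps so the
  # score mean(H (Y - Qstar)) vanishes to machine precision
  off <- stats::qlogis(Q0_obs)
  if (fluctuate) {
    eps <- tryCatch(
      stats::coef(suppressWarnings(stats::glm(
        y ~ -1 + H + offset(off), family = stats::binomial())))[["H"]],
      error = function(e) 0)
    score <- function(e) mean(H * (y - stats::plogis(off + e * H)))
    for (i in 1:100) {
      p <- stats::plogis(off + eps * H)
      s <- mean(H * (y - p))
      if (abs(s) < 1e-13) break
      d <- -mean(H^2 * p * (1 - p))
      eps <- eps - s / d
    }
  } else {
    eps <- 0
  }

  # (5)-(6) targeted predictions and estimate
  Qs_1 <- stats::plogis(stats::qlogis(Q0_1) + eps * H1)
  Qs_0 <- stats::plogis(stats::qlogis(Q0_0) + eps * H0)
  Qs_obs <- ifelse(a == 1, Qs_1, Qs_0)
  p1 <- mean(Qs_1); p0 <- mean(Qs_0)
  psi <- p1 - p0

  # (7) influence curve and inference
  ic <- H * (y - Qs_obs) + Qs_1 - Qs_0 - psi
  se <- clustered_se(ic, cluster_ids)
  ic1 <- a / g * (y - Qs_obs) + Qs_1 - p1
  ic0 <- (1 - a) / (1 - g) * (y - Qs_obs) + Qs_0 - p0
  se1 <- clustered_se(ic1, cluster_ids)
  se0 <- clustered_se(ic0, cluster_ids)
  z <- stats::qnorm(0.975)

  structure(list(
    psi = psi, se = se, ci95 = psi + c(-z, z) * se,
    epsilon = eps, ic = ic,
    p1 = p1, p0 = p0, se1 = se1, se0 = se0,
    Q0 = list(obs = Q0_obs, a1 = Q0_1, a0 = Q0_0),
    Qstar = list(obs = Qs_obs, a1 = Qs_1, a0 = Qs_0),
    g = gfit, H = H, n = length(y),
    outcome_engine = outcome_engine, propensity_engine = propensity_engine
  ), class = "tmle_fit")
}

#' @export
print.tmle_fit <- function(x, ...) {
  cat(sprintf(
    "TMLE ATE (risk difference): %.4f (95%% CI %.4f, %.4f), n = %d\n",
    x$psi, x$ci95[1], x$ci95[2], x$n))
  cat(sprintf("  epsilon = %.5g, |mean IC|/sd(IC) = %.2e\n",
              x$epsilon, abs(mean(x$ic)) / stats::sd(x$ic)))
  invisible(x)
}

as_estimate_row <- function(fit, clinic_id = "All") {
  z <- stats::qnorm(0.975)
  n <- fit$n
  estimate_row(clinic_id, "tmle",
               NA_integer_, NA_integer_,
               fit$p0, fit$p0 + c(-z, z) * fit$se0,
               fit$p1, fit$p1 + c(-z, z) * fit$se1,
               fit$psi, fit$ci95)
}

#' Clinic-stratified and pooled ATE estimates
#'
#' One estimate row per program clinic per method, plus an `"All"` row per
#' method computed on the stacked program-clinic data with clinic indicator
#' covariates added to the adjustment set.  Years are pooled within clinic.
#' A clinic with a single exposure level is skipped with a warning.
#'
#' @param data Analysis table (complete cases) containing `clinic_id`; rows
#'   from conventional-care clinics (all unexposed) are ignored unless a
#'   clinic has both exposure levels.
#' @param methods Subset of `c("unadjusted", "gcomp", "tmle")`.
#' @param adjustment_set Covariate column names.
#' @param boot Bootstrap replicates for g-computation CIs.
#' @param ... Passed to [tmle_estimate()] (engines, learners, seed, ...).
#' @return data.frame of estimate rows.
#' @export
estimate_by_clinic_and_pooled <- function(data,
                                          methods = c("unadjusted", "gcomp",
                                                      "tmle"),
                                          adjustment_set = character(),
                                          boot = 500, ...) {
  stopifnot("clinic_id" %in% names(data))
  methods <- match.arg(methods, several.ok = TRUE)
  clinics <- unique(data$clinic_id)
  usable <- clinics[vapply(clinics, function(cl) {
    length(unique(data$exposed[data$clinic_id == cl])) == 2
  }, logical(1))]
  skipped <- setdiff(clinics, usable)
  if (length(skipped)) {
    warning("clinic(s) with a single exposure level skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (!length(usable)) stop("no clinic with both exposure levels",
                            call. = FALSE)

  one <- function(d, adj, label) {
    out <- list()
    cl_ids <- if ("patient_id" %in% names(d)) d$patient_id else NULL
    if ("unadjusted" %in% methods) {
      out$unadjusted <- unadjusted_estimate(d, cluster_ids = cl_ids,
                                            clinic_id = label)
    }
    if ("gcomp" %in% methods) {
      out$gcomp <- gcomp_logistic_estimate(d, adj, boot = boot,
                                           clinic_id = label)
    }
    if ("tmle" %in% methods) {
      fit <- tmle_estimate(d, adj, ...)
      row <- as_estimate_row(fit, clinic_id = label)
      row$n0 <- sum(d$exposed == 0); row$n1 <- sum(d$exposed == 1)
      out$tmle <- row
    }
    do.call(rbind, out)
  }

  rows <- lapply(usable, function(cl) {
    one(data[data$clinic_id == cl, , drop = FALSE], adjustment_set, cl)
  })

  pooled_data <- data[data$clinic_id %in% usable, , drop = FALSE]
  pooled_adj <- adjustment_set
  if (length(usable) > 1) {
    for (cl in usable[-1]) {
      colname <- paste0("clinic_", cl)
      pooled_data[[colname]] <- as.numeric(pooled_data$clinic_id == cl)
      pooled_adj <- c(pooled_adj, colname)
    }
  }
  rows <- c(rows, list(one(pooled_data, pooled_adj, "All")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
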
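# Diagnostics: covariate PCA across clinics and by outcome-missingness,
# propensity-score distribution comparison, and the process-of-care
# sensitivity analysis.

#' Principal component analysis of covariates
#'
#' Centers and scales the covariates to unit variance, decomposes the
#' correlation structure, and labels each observation's component scores by
#' clinic or by outcome-missingness status — the check that clinics (or
#' complete vs missing-outcome patients) share a covariate distribution.
#' Zero-variance covariates are dropped with a warning.
#'
#' @param data Observation records.
#' @param covariates Covariate column names (numeric-encoded; one-hot encode
#'   categoricals first).
#' @param grouping `"clinic"` or `"outcome-missingness"`.
#' @return Object of class `pca_result`: `scores`, `loadings`,
#'   `explained_var` (fractions, non-increasing, summing to 1), `group`.
#' @export
pca_covariates <- function(data, covariates,
                           grouping = c("clinic", "outcome-missingness")) {
  grouping <- match.arg(grouping)
  if (length(covariates) < 2) stop("need at least 2 covariates",
                                   call. = FALSE)
  X <- as_features(data, covariates)
  if (anyNA(X)) stop("covariates must be complete for PCA", call. = FALSE)
  vars <- vapply(X, stats::var, numeric(1))
  if (any(vars == 0)) {
    warning("dropping zero-variance covariate(s): ",
            paste(names(X)[vars == 0], collapse = ", "), call. = FALSE)
    X <- X[vars > 0]
    if (ncol(X) < 2) stop("fewer than 2 informative covariates",
                          call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  group <- if (grouping == "clinic") as.character(data$clinic_id)
           else ifelse(is.na(data$outcome), "missing", "observed")
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_var = ev, group = group, grouping = grouping),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of", ncol(x$loadings), "covariates, grouped by", x$grouping, "\n")
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained_var, 5)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Per-group centroids of the first two component scores
#'
#' @param x A `pca_result`.
#' @return data.frame: group, n, PC1, PC2 centroid coordinates.
#' @export
pca_group_centroids <- function(x) {
  out <- do.call(rbind, lapply(split(seq_along(x$group), x$group),
    function(i) data.frame(n = length(i),
                           PC1 = mean(x$scores[i, 1]),
                           PC2 = mean(x$scores[i, 2]))))
  cbind(group = rownames(out), out, row.names = NULL)
}

#' Compare propensity-score distributions across adjustment sets
#'
#' Summarizes the raw (untruncated) fitted propensity scores of a base and
#' an extended adjustment set on the same observations: quantiles, the
#' fraction of near-zero scores (below `near_zero`) and near-one scores, and
#' a positivity flag raised when the extended set increases the near-zero
#' fraction by at least `flag_margin` — the signature of adjustment
#' variables that predict program exposure strongly but the outcome weakly.
#'
#' @param fit_base,fit_extended `propensity_fit` objects on the same rows.
#' @param near_zero,near_one Tail thresholds (defaults 0.05, 0.95).
#' @param flag_margin Near-zero fraction increase that raises the flag
#'   (default 0.05).
#' @return Object of class `propensity_report` with per-fit summaries, the
#'   near-zero fraction increase, and `flag`.
#' @export
propensity_distribution_report <- function(fit_base, fit_extended,
                                           near_zero = 0.05,
                                           near_one = 0.95,
                                           flag_margin = 0.05) {
  stopifnot(inherits(fit_base, "propensity_fit"),
            inherits(fit_extended, "propensity_fit"))
  if (length(fit_base$raw) != length(fit_extended$raw)) {
    stop("propensity fits cover different observations", call. = FALSE)
  }
  summarize <- function(f) {
    list(quantiles = stats::quantile(f$raw, c(0.01, 0.05, 0.1, 0.25, 0.5,
                                              0.75, 0.9, 0.95, 0.99)),
         frac_near_zero = mean(f$raw < near_zero),
         frac_near_one = mean(f$raw > near_one),
         adjustment_set = f$adjustment_set)
  }
  base <- summarize(fit_base)
  ext <- summarize(fit_extended)
  increase <- ext$frac_near_zero - base$frac_near_zero
  structure(list(base = base, extended = ext,
                 near_zero_increase = increase,
                 flag = increase >= flag_margin,
                 thresholds = c(near_zero = near_zero, near_one = near_one,
                                flag_margin = flag_margin)),
            class = "propensity_report")
}

#' @export
print.propensity_report <- function(x, ...) {
  cat(sprintf("near-zero propensity mass: base %.3f -> extended %.3f (%+.3f)\n",
              x$base$frac_near_zero, x$extended$frac_near_zero,
              x$near_zero_increase))
  if (x$flag) cat("POSITIVITY FLAG: extended adjustment set inflates the",
                  "near-zero tail\n")
  invisible(x)
}

#' Sensitivity analysis with process-of-care indicators
#'
#' Re-runs the clinic-stratified and pooled estimators with the
#' process-of-care indicators added to the adjustment set and reports the
#' per-clinic and pooled risk-difference deltas against the base analysis.
#'
#' @param data Analysis table containing the indicator columns.
#' @param base_adjustment_set Covariate column names of the main analysis.
#' @param indicators Indicator column names (default
#'   [process_indicator_columns()]).
#' @param methods,boot,... Passed to [estimate_by_clinic_and_pooled()].
#' @return List: `base` and `extended` estimate tables plus `deltas`
#'   (clinic_id, method, rd_base, rd_extended, delta).
#' @export
sensitivity_with_process_indicators <- function(data, base_adjustment_set,
                                                indicators =
                                                  process_indicator_columns(),
                                                methods = c("unadjusted",
                                                            "gcomp", "tmle"),
                                                boot = 0, ...) {
  miss <- setdiff(indicators, names(data))
  if (length(miss)) {
    stop("process indicator column(s) absent: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  base <- estimate_by_clinic_and_pooled(data, methods = methods,
                                        adjustment_set = base_adjustment_set,
                                        boot = boot, ...)
  ext <- estimate_by_clinic_and_pooled(
    data, methods = methods,
    adjustment_set = c(base_adjustment_set, indicators), boot = boot, ...)
  key <- c("clinic_id", "method")
  deltas <- merge(base[c(key, "rd")], ext[c(key, "rd")], by = key,
                  suffixes = c("_base", "_extended"))
  deltas$delta <- deltas$rd_extended - deltas$rd_base
  list(base = base, extended = ext, deltas = deltas)
}
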
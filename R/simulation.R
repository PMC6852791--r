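# Estimator-comparison simulation study: bias, variance, RMSE and CI
# coverage of the unadjusted, g-computation and TMLE estimators across
# seeded replicates of the built-in scenarios.

#' Default adjustment set for the synthetic study
#'
#' @return Character vector of covariate names.
#' @export
default_adjustment_set <- function() {
  c("sex", "age", "bmi", "previous_control", "risk_factors", "smoking",
    "insurance_type", "n_complications", "obesity")
}

# Stack the program clinics and add clinic indicator covariates, mirroring
# the pooled estimation path.
pooled_treated_data <- function(records, adjustment_set) {
  d <- records[records$diabetimss_clinic, , drop = FALSE]
  clinics <- sort(unique(d$clinic_id))
  adj <- adjustment_set
  for (cl in clinics[-1]) {
    nm <- paste0("clinic_", cl)
    d[[nm]] <- as.numeric(d$clinic_id == cl)
    adj <- c(adj, nm)
  }
  list(data = d, adjustment_set = adj)
}

#' Run the estimator-comparison simulation
#'
#' Per replicate: generate a dataset from the scenario, apply every
#' requested estimator to the same pooled program-clinic data (paired
#' comparison), record point estimate and 95% CI, and compare against that
#' replicate's ground-truth pooled ATE.  Fully reproducible from
#' `master_seed`.  An estimator failing on a replicate is recorded as
#' missing; the replicate is kept for the others.
#'
#' @param config A [synthetic_config()] (scenario).
#' @param estimators Subset of `c("unadjusted", "gcomp", "tmle")`.
#' @param n Approximate total records per replicate (distributed over
#'   clinics and years).
#' @param replicates Number of seeded replicates (default 200).
#' @param master_seed Integer master seed.
#' @param adjustment_set Covariates given to the adjusted estimators.
#' @param with_missingness Impose MAR outcome missingness and analyze
#'   complete cases (default FALSE: estimator properties are isolated from
#'   the missingness mechanism, which is tested separately).
#' @param tmle_args List of extra arguments to [tmle_estimate()].
#' @param scenario_name Label stored in the report.
#' @return Object of class `simulation_report`: `summary` (per-estimator
#'   mean estimate, bias, empirical SD, mean SE, RMSE, coverage), `raw`
#'   (long table of replicate estimates), dims and seeds.
#' @export
run_simulation <- function(config, estimators = c("unadjusted", "gcomp",
                                                  "tmle"),
                           n = 2000, replicates = 200, master_seed = 1,
                           adjustment_set = default_adjustment_set(),
                           with_missingness = FALSE,
                           tmle_args = list(), scenario_name = "scenario") {
  stopifnot(inherits(config, "synthetic_config"), replicates >= 2)
  estimators <- match.arg(estimators, several.ok = TRUE)
  n_clinics <- config$n_clinics_treated + config$n_clinics_control
  ppc <- max(2L, ceiling(n / (n_clinics * config$years)))

  seeds <- vapply(seq_len(replicates), function(r) {
    substream_seed(master_seed, r, 0, 6L)
  }, integer(1))

  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- seeds[r]
    cfg$n_patients_per_clinic <- rep_len(ppc, n_clinics)
    study <- generate_study(cfg)
    recs <- study$records
    if (with_missingness) {
      recs <- impose_missingness(recs, cfg)
      recs <- recs[!is.na(recs$outcome), , drop = FALSE]
    }
    pooled <- pooled_treated_data(recs, adjustment_set)
    truth <- study$truth$pooled_ate

    res <- lapply(estimators, function(m) {
      est <- tryCatch(switch(m,
        unadjusted = unadjusted_estimate(pooled$data,
                                         cluster_ids = pooled$data$patient_id),
        gcomp = gcomp_logistic_estimate(pooled$data, pooled$adjustment_set,
                                        boot = 0),
        tmle = {
          fit <- do.call(tmle_estimate,
                         c(list(data = pooled$data,
                                adjustment_set = pooled$adjustment_set,
                                seed = seeds[r]),
                           tmle_args))
          as_estimate_row(fit)
        }), error = function(e) NULL)
      if (is.null(est)) {
        data.frame(estimator = m, replicate = r, estimate = NA_real_,
                   ci_lo = NA_real_, ci_hi = NA_real_, truth = truth)
      } else {
        data.frame(estimator = m, replicate = r, estimate = est$rd,
                   ci_lo = est$rd_lo, ci_hi = est$rd_hi, truth = truth)
      }
    })
    rows[[r]] <- do.call(rbind, res)
  }
  raw <- do.call(rbind, rows)
  rownames(raw) <- NULL

  summary <- do.call(rbind, lapply(estimators, function(m) {
    d <- raw[raw$estimator == m & !is.na(raw$estimate), , drop = FALSE]
    err <- d$estimate - d$truth
    bias <- mean(err)
    variance <- mean((err - bias)^2)
    mean_se <- mean((d$ci_hi - d$ci_lo) / (2 * stats::qnorm(0.975)))
    cover <- mean(d$ci_lo <= d$truth & d$truth <= d$ci_hi)
    data.frame(estimator = m, n_ok = nrow(d),
               mean_estimate = mean(d$estimate), bias = bias,
               empirical_sd = stats::sd(d$estimate), variance = variance,
               mean_se = mean_se,
               rmse = sqrt(mean(err^2)), coverage = cover)
  }))
  rownames(summary) <- NULL

  structure(list(scenario = scenario_name, n = n, n_per_clinic = ppc,
                 replicates = replicates, seeds = seeds,
                 summary = summary, raw = raw),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf("Simulation '%s': %d replicates, ~%d records each\n",
              x$scenario, x$replicates, x$n))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Long-format plotting table of replicate estimates
#'
#' @param report A `simulation_report`.
#' @return data.frame: scenario, estimator, replicate, estimate, truth.
#' @export
summarize_distributions <- function(report) {
  stopifnot(inherits(report, "simulation_report"))
  data.frame(scenario = report$scenario,
             estimator = report$raw$estimator,
             replicate = report$raw$replicate,
             estimate = report$raw$estimate,
             truth = report$raw$truth,
             stringsAsFactors = FALSE)
}
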
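# Synthetic multi-clinic serial cross-sectional generator with known
# ground-truth treatment effects, confounding, clinic heterogeneity and
# missing-at-random outcome missingness.

#' Configuration for the synthetic study generator
#'
#' Emulates the structure of the evaluated program data: six clinics
#' delivering the program and five conventional-care clinics, five calendar
#' years, ~25-30% exposure prevalence inside program clinics, confounding of
#' exposure by prior control / complications / age, clinic-level
#' heterogeneity of baseline control, and (optionally) ~62% outcome
#' missingness under a MAR logistic model.
#'
#' @param n_clinics_treated,n_clinics_control Clinic counts (defaults 6, 5).
#' @param n_patients_per_clinic Patients per clinic (scalar or per-clinic
#'   vector, treated clinics first).
#' @param years Number of calendar years (default 5).
#' @param baseline_control_by_clinic Year-one probability of glycemic
#'   control among unexposed patients, per clinic (treated clinics first).
#'   Defaults anchor the treated clinics at the observed unexposed-group
#'   control proportions 0.36, 0.40, 0.34, 0.31, 0.16, 0.20.
#' @param blip Treatment-effect specification on the risk-difference scale:
#'   either `list(type = "constant", value = ...)` or
#'   `list(type = "by_complications", values = c(ate0, ate1, ate2))` giving
#'   the effect at 0, 1 and >1 diabetes complications.
#' @param confounding_strength Scalar multiplying the covariate coefficients
#'   of the exposure model; 0 gives a randomized exposure.
#' @param outcome_model `"main"` (main-effects logistic risk surface) or
#'   `"interactions"` (adds a quadratic age term and
#'   prior-control-by-complications and age-by-risk-factor interactions so a
#'   main-effects logistic fit is misspecified).
#' @param exposure_prevalence Target marginal exposure prevalence within
#'   treated clinics (default 0.28).
#' @param missingness_rate Target fraction of missing outcomes under
#'   [impose_missingness()] (default 0.62; 0 disables).
#' @param missingness_coefs Named coefficients of the MAR logistic model on
#'   standardized age, previous control and exposure (never on the outcome).
#' @param seed Master seed; all randomness flows through per-clinic-year
#'   substreams derived from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clinics_treated = 6,
                             n_clinics_control = 5,
                             n_patients_per_clinic = 500,
                             years = 5,
                             baseline_control_by_clinic = NULL,
                             blip = list(type = "constant", value = 0.05),
                             confounding_strength = 1,
                             outcome_model = c("main", "interactions"),
                             exposure_prevalence = 0.28,
                             missingness_rate = 0.62,
                             missingness_coefs = c(age_std = -0.35,
                                                   previous_control = -0.25,
                                                   exposed = -0.7),
                             seed = 1) {
  outcome_model <- match.arg(outcome_model)
  n_clinics <- n_clinics_treated + n_clinics_control
  if (n_clinics_treated < 1 || n_clinics_control < 0 || years < 1) {
    stop("invalid clinic/year counts", call. = FALSE)
  }
  if (any(n_patients_per_clinic < 1)) {
    stop("n_patients_per_clinic must be positive", call. = FALSE)
  }
  if (is.null(baseline_control_by_clinic)) {
    treated <- c(0.36, 0.40, 0.34, 0.31, 0.16, 0.20)
    control <- c(0.33, 0.30, 0.27, 0.24, 0.21)
    baseline_control_by_clinic <- c(
      rep_len(treated, n_clinics_treated),
      rep_len(control, max(n_clinics_control, 1))[seq_len(n_clinics_control)]
    )
  }
  baseline_control_by_clinic <- rep_len(baseline_control_by_clinic, n_clinics)
  if (any(baseline_control_by_clinic <= 0 | baseline_control_by_clinic >= 1)) {
    stop("baseline control probabilities must lie in (0,1)", call. = FALSE)
  }
  if (exposure_prevalence <= 0 || exposure_prevalence >= 1 ||
      missingness_rate < 0 || missingness_rate >= 1) {
    stop("invalid probability in config", call. = FALSE)
  }
  if (!blip$type %in% c("constant", "by_complications")) {
    stop("unknown blip type: ", blip$type, call. = FALSE)
  }
  structure(list(
    n_clinics_treated = n_clinics_treated,
    n_clinics_control = n_clinics_control,
    n_patients_per_clinic = rep_len(n_patients_per_clinic, n_clinics),
    years = years,
    baseline_control_by_clinic = baseline_control_by_clinic,
    blip = blip,
    confounding_strength = confounding_strength,
    outcome_model = outcome_model,
    exposure_prevalence = exposure_prevalence,
    missingness_rate = missingness_rate,
    missingness_coefs = missingness_coefs,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Deterministic substream seed for (clinic, year, stage): clinic substreams
# mean adding clinics never perturbs earlier ones.
substream_seed <- function(master, clinic, year, stage = 0L) {
  as.integer((abs(as.numeric(master)) * 48271 + clinic * 10007 +
                year * 101 + stage * 7) %% 2147483587) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Baseline (year-one) patient covariates for one clinic.
draw_patient_covariates <- function(n, seed) {
  with_seed(seed, {
    sex <- stats::rbinom(n, 1, 0.58)
    age <- pmin(pmax(stats::rnorm(n, 60, 11), 25), 95)
    height_cm <- pmin(pmax(stats::rnorm(n, 160 - 8 * (sex == 1) + 12, 7),
                           131), 209)
    bmi <- pmin(pmax(stats::rnorm(n, 29.5, 5), 16), 60)
    weight_kg <- pmin(pmax(bmi * (height_cm / 100)^2, 31), 199)
    smoking <- stats::rbinom(n, 1, 0.04)
    risk_factors <- pmax(smoking, stats::rbinom(n, 1, 0.77))
    insurance_type <- stats::rbinom(n, 1, 0.48)
    n_complications <- sample(0:2, n, replace = TRUE,
                              prob = c(0.52, 0.33, 0.15))
    data.frame(sex = sex, age = age, height_cm = height_cm,
               weight_kg = weight_kg, bmi = bmi,
               nutrition_status = cut(bmi, c(-Inf, 18.5, 25, 30, Inf),
                                      labels = FALSE, right = FALSE) - 1,
               smoking = smoking, risk_factors = risk_factors,
               insurance_type = insurance_type,
               n_complications = n_complications,
               obesity = as.numeric(bmi >= 30))
  })
}

# Confounder linear predictors -----------------------------------------------

outcome_lp <- function(W, model = "main") {
  age_std <- (W$age - 60) / 10
  bmi_std <- (W$bmi - 29.5) / 5
  lp <- 1.9 * W$previous_control + 0.25 * age_std -
    0.175 * W$n_complications + 0.10 * W$risk_factors + 0.05 * bmi_std
  if (model == "interactions") {
    lp <- lp - 0.40 * age_std^2 +
      0.90 * W$previous_control * (W$n_complications >= 1) +
      0.60 * age_std * W$risk_factors
  }
  lp
}

exposure_lp <- function(W, strength = 1) {
  age_std <- (W$age - 60) / 10
  strength * (0.8 * W$previous_control - 0.4 * age_std -
                0.4 * W$n_complications + 0.2 * W$risk_factors)
}

# Target risk difference per observation from the blip specification.
blip_target <- function(W, blip) {
  if (blip$type == "constant") {
    rep(blip$value, nrow(W))
  } else {
    blip$values[pmin(W$n_complications, 2) + 1]
  }
}

# Logit-scale treatment coefficient solving
# mean(clip(plogis(lp + beta)) - clip(plogis(lp))) = target
# within the given subset, so realized mean blips match the configured
# risk differences exactly.
calibrate_treatment_beta <- function(lp, target) {
  if (target == 0) return(0)
  p0 <- pmin(pmax(stats::plogis(lp), 0.01), 0.99)
  f <- function(b) {
    mean(pmin(pmax(stats::plogis(lp + b), 0.01), 0.99) - p0) - target
  }
  stats::uniroot(f, c(-8, 8), tol = 1e-12)$root
}

# Solve an intercept so that mean(plogis(a + lp)) hits a target probability.
calibrate_intercept <- function(lp, target) {
  f <- function(a) mean(stats::plogis(a + lp)) - target
  stats::uniroot(f, c(-15, 15), tol = 1e-10)$root
}

#' Generate a synthetic multi-clinic serial cross-sectional study
#'
#' Per clinic and year: stable patient covariates (age advances yearly),
#' exposure assigned by a logistic model on covariates inside treated clinics
#' only (conventional-care clinics have exposure exactly 0), potential
#' outcome probabilities `p0 = plogis(a_clinic + f(W))` and
#' `p1 = clip(p0 + b(W), 0.01, 0.99)`, coupled potential-outcome draws, and
#' previous-year control carried forward as next year's `previous_control`.
#' Clinic intercepts are calibrated so the year-one unexposed control
#' probability matches `baseline_control_by_clinic`; the exposure intercept
#' is calibrated to the target prevalence.  Seven process-of-care indicators
#' are generated as strongly exposure-associated, weakly outcome-associated
#' flags.  Outcomes are fully observed; apply [impose_missingness()]
#' afterwards.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_study`: `records` (one row per
#'   patient-year, canonical columns plus `diabetimss_clinic`) and `truth`
#'   (list: per-observation `table` with p0/p1/y0/y1/blip, `clinic_ate`,
#'   `pooled_ate` over treated clinics, `pooled_ate_all`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_clinics <- config$n_clinics_treated + config$n_clinics_control
  clinic_ids <- sprintf("C%02d", seq_len(n_clinics))
  treated_clinic <- seq_len(n_clinics) <= config$n_clinics_treated
  rec_list <- truth_list <- vector("list", n_clinics)

  for (ci in seq_len(n_clinics)) {
    n <- config$n_patients_per_clinic[ci]
    W <- draw_patient_covariates(n, substream_seed(config$seed, ci, 0, 1L))
    W$previous_control <- with_seed(
      substream_seed(config$seed, ci, 0, 2L),
      stats::rbinom(n, 1, config$baseline_control_by_clinic[ci]))
    patient_id <- sprintf("%s_P%05d", clinic_ids[ci], seq_len(n))

    # clinic intercept: year-one unexposed control probability = baseline
    alpha <- calibrate_intercept(outcome_lp(W, config$outcome_model),
                                 config$baseline_control_by_clinic[ci])
    # exposure intercept fixed at year one so the propensity model is a
    # stable main-effects logistic surface across years
    a0 <- if (treated_clinic[ci]) {
      calibrate_intercept(exposure_lp(W, config$confounding_strength),
                          config$exposure_prevalence)
    } else NA_real_

    yrs <- vector("list", config$years)
    tys <- vector("list", config$years)
    for (t in seq_len(config$years)) {
      lpy <- alpha + outcome_lp(W, config$outcome_model)
      p0 <- pmin(pmax(stats::plogis(lpy), 0.01), 0.99)
      target <- blip_target(W, config$blip)
      if (config$blip$type == "constant") {
        # treatment acts on the logit scale, its coefficient calibrated so
        # the mean risk difference equals the configured effect: the world
        # stays a (correctly-specifiable) logistic model in (A, W)
        beta <- calibrate_treatment_beta(lpy, target[1])
        p1 <- pmin(pmax(stats::plogis(lpy + beta), 0.01), 0.99)
      } else {
        # subgroup-varying effects are additive on the risk scale, so the
        # true blip is exactly the configured value within each subgroup
        # (up to rare clipping) and varies only across subgroups
        p1 <- pmin(pmax(p0 + target, 0.01), 0.99)
      }

      if (treated_clinic[ci]) {
        lpa <- exposure_lp(W, config$confounding_strength)
        A <- with_seed(substream_seed(config$seed, ci, t, 3L),
                       stats::rbinom(n, 1, stats::plogis(a0 + lpa)))
      } else {
        A <- rep(0L, n)
      }

      draws <- with_seed(substream_seed(config$seed, ci, t, 4L),
                         cbind(stats::runif(n),
                               matrix(stats::runif(n * 7), n, 7)))
      u <- draws[, 1]
      y0 <- as.integer(u < p0)
      y1 <- as.integer(u < p1)
      y <- ifelse(A == 1, y1, y0)

      # process indicators: strongly driven by exposure, weakly by covariates
      pi_base <- c(-0.8, -1.2, -1.6, -1.4, -0.5, -0.7, -1.0)
      pi_mat <- matrix(0L, n, 7)
      for (j in 1:7) {
        pp <- stats::plogis(pi_base[j] + 1.0 * A +
                              0.15 * W$risk_factors +
                              0.05 * (W$age - 60) / 10)
        pi_mat[, j] <- as.integer(draws[, j + 1] < pp)
      }
      colnames(pi_mat) <- process_indicator_columns()

      yrs[[t]] <- data.frame(
        patient_id = patient_id, clinic_id = clinic_ids[ci],
        year = 2011 + t, exposed = A, outcome = as.numeric(y),
        W[c("sex", "age", "height_cm", "weight_kg", "bmi",
            "nutrition_status")],
        previous_control = W$previous_control,
        W[c("risk_factors", "smoking", "insurance_type", "n_complications",
            "obesity")],
        pi_mat,
        diabetimss_clinic = treated_clinic[ci],
        stringsAsFactors = FALSE)
      tys[[t]] <- data.frame(
        patient_id = patient_id, clinic_id = clinic_ids[ci], year = 2011 + t,
        p0 = p0, p1 = p1, y0 = y0, y1 = y1, blip = p1 - p0,
        stringsAsFactors = FALSE)

      W$previous_control <- y       # realized control feeds next year
      W$age <- W$age + 1
    }
    rec_list[[ci]] <- do.call(rbind, yrs)
    truth_list[[ci]] <- do.call(rbind, tys)
  }

  records <- do.call(rbind, rec_list)
  truth_tab <- do.call(rbind, truth_list)
  rownames(records) <- rownames(truth_tab) <- NULL

  clinic_ate <- tapply(truth_tab$blip, truth_tab$clinic_id, mean)
  treated_ids <- clinic_ids[treated_clinic]
  wts <- table(truth_tab$clinic_id)[treated_ids]
  pooled_ate <- sum(clinic_ate[treated_ids] * as.numeric(wts)) / sum(wts)

  structure(list(
    records = records,
    truth = list(table = truth_tab,
                 clinic_ate = clinic_ate,
                 pooled_ate = unname(pooled_ate),
                 pooled_ate_all = mean(truth_tab$blip)),
    config = config
  ), class = "synthetic_study")
}

#' Impose missing-at-random outcome missingness
#'
#' Deletes outcomes with probability `plogis(d0 + coefs' (W, A))`, where the
#' intercept `d0` is calibrated so the realized missingness fraction matches
#' the configured target.  The model never involves the outcome, so within
#' strata of covariates and exposure the missingness indicator is independent
#' of Y (MAR by construction).
#'
#' @param records Observation records with fully observed outcomes.
#' @param config The [synthetic_config()] used to generate them.
#' @return `records` with `outcome` set to NA for the selected rows.
#' @export
impose_missingness <- function(records, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (anyNA(records$outcome)) {
    stop("outcomes must be fully observed on input", call. = FALSE)
  }
  if (config$missingness_rate == 0) return(records)
  cf <- config$missingness_coefs
  lp <- cf[["age_std"]] * (records$age - 60) / 10 +
    cf[["previous_control"]] * records$previous_control +
    cf[["exposed"]] * records$exposed
  d0 <- calibrate_intercept(lp, config$missingness_rate)
  miss <- with_seed(substream_seed(config$seed, 0, 0, 5L),
                    stats::rbinom(nrow(records), 1,
                                  stats::plogis(d0 + lp)) == 1)
  records$outcome[miss] <- NA
  records
}

#' Built-in simulation scenarios
#'
#' Four named worlds used throughout the tests and the estimator-comparison
#' study:
#' \describe{
#'   \item{original-like}{main-effects logistic exposure and outcome models
#'     (a correctly-specifiable world), constant 5-point effect;}
#'   \item{variant}{outcome risk surface with a quadratic age term and
#'     interactions so a main-effects logistic outcome fit is misspecified
#'     (the exposure model stays main-effects);}
#'   \item{null}{zero treatment effect and randomized (unconfounded)
#'     exposure, so every estimator should center on zero;}
#'   \item{hte}{effect declining with diabetes complications (6.4 points at
#'     none, 4.5 at one, 2.6 above one).}
#' }
#'
#' @param n_patients_per_clinic,seed Passed through to [synthetic_config()].
#' @return Named list of `synthetic_config` objects.
#' @export
builtin_scenarios <- function(n_patients_per_clinic = 500, seed = 1) {
  list(
    "original-like" = synthetic_config(
      n_patients_per_clinic = n_patients_per_clinic, seed = seed),
    "variant" = synthetic_config(
      n_patients_per_clinic = n_patients_per_clinic,
      outcome_model = "interactions", confounding_strength = 1.5,
      seed = seed),
    "null" = synthetic_config(
      n_patients_per_clinic = n_patients_per_clinic,
      blip = list(type = "constant", value = 0),
      confounding_strength = 0, seed = seed),
    "hte" = synthetic_config(
      n_patients_per_clinic = n_patients_per_clinic,
      blip = list(type = "by_complications",
                  values = c(0.064, 0.045, 0.026)),
      seed = seed)
  )
}
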
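# Data model: patient-year records, plausibility filtering, outcome
# construction, complete-case analysis sets, descriptive cross-tabs.

#' Canonical patient-year column names
#'
#' One row per patient-year: identifiers, program exposure, the binary
#' glycemic-control outcome (NA when undetermined), covariates and the seven
#' binary process-of-care indicators.
#'
#' @return Character vector of canonical column names.
#' @export
observation_columns <- function() {
  c("patient_id", "clinic_id", "year", "exposed", "outcome",
    covariate_columns(), process_indicator_columns())
}

#' @rdname observation_columns
#' @export
covariate_columns <- function() {
  c("sex", "age", "height_cm", "weight_kg", "bmi", "nutrition_status",
    "previous_control", "risk_factors", "smoking", "insurance_type",
    "n_complications", "obesity")
}

#' @rdname observation_columns
#' @export
process_indicator_columns <- function() {
  # P1 HbA1c measured, P2 foot exam, P3 ophthalmology referral,
  # P4 nutritional counseling, P5 metformin if overweight/obese,
  # P6 ACE-i/ARB if hypertensive, P7 aspirin if >40 with risk factors
  paste0("p", 1:7)
}

required_observation_columns <- function() {
  c("patient_id", "clinic_id", "year", "exposed", "outcome")
}

#' Plausibility cut-offs for clinical measurements
#'
#' Predefined non-plausible value ranges: systolic blood pressure outside
#' (50, 250) mmHg, diastolic outside (40, 200) mmHg, height outside
#' (130, 250) cm, weight outside (30, 200) kg, HbA1c below 3.0%, fasting
#' plasma glucose below 37 mg/dl.  Values strictly outside a range are
#' excluded; the bounds themselves are retained.
#'
#' @param sbp_range,dbp_range,height_range,weight_range Numeric length-2
#'   (low, high) retention bounds.
#' @param hba1c_min,fpg_min Lower retention bounds; no upper cut-off.
#' @return An object of class `plausibility_rules`.
#' @export
plausibility_rules <- function(sbp_range = c(50, 250),
                               dbp_range = c(40, 200),
                               height_range = c(130, 250),
                               weight_range = c(30, 200),
                               hba1c_min = 3.0,
                               fpg_min = 37) {
  rules <- list(
    SBP = c(sbp_range[1], sbp_range[2]),
    DBP = c(dbp_range[1], dbp_range[2]),
    HEIGHT = c(height_range[1], height_range[2]),
    WEIGHT = c(weight_range[1], weight_range[2]),
    HBA1C = c(hba1c_min, Inf),
    FPG = c(fpg_min, Inf)
  )
  for (nm in names(rules)) {
    if (!is.numeric(rules[[nm]]) || length(rules[[nm]]) != 2 ||
        rules[[nm]][1] >= rules[[nm]][2]) {
      stop("invalid plausibility range for ", nm, call. = FALSE)
    }
  }
  structure(rules, class = "plausibility_rules")
}

#' Load patient-year observation records from CSV
#'
#' Reads one row per patient-year.  Empty cells and the string "NA" become
#' missing values; missingness in the outcome or covariates is preserved,
#' never coerced to 0.
#'
#' @param path CSV file path (comma-separated, UTF-8, header row).
#' @param schema Optional named character vector mapping canonical column
#'   names (see [observation_columns()]) to the file's column names.
#' @return A data.frame of observation records with canonical column names.
#' @export
load_observations <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!is.null(schema)) {
    hit <- match(unname(schema), names(raw))
    if (anyNA(hit)) {
      stop("schema names absent from file: ",
           paste(unname(schema)[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    names(raw)[hit] <- names(schema)
  }
  miss <- setdiff(required_observation_columns(), names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  numeric_cols <- intersect(
    setdiff(observation_columns(), c("patient_id", "clinic_id")), names(raw))
  for (cl in numeric_cols) {
    v <- raw[[cl]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad)) {
        stop("non-numeric value in column '", cl, "' at row ", bad[1],
             call. = FALSE)
      }
      raw[[cl]] <- conv
    }
  }
  dup <- duplicated(raw[c("patient_id", "year")])
  if (any(dup)) {
    stop("duplicate (patient_id, year) at row ", which(dup)[1], call. = FALSE)
  }
  raw
}

#' Load a long-format laboratory/anthropometry series from CSV
#'
#' Expected columns: patient_id, year, date, analyte (one of HBA1C, FPG,
#' SBP, DBP, HEIGHT, WEIGHT), value.
#'
#' @param path CSV file path.
#' @return A data.frame with the five columns above, `date` as `Date`.
#' @export
load_lab_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ser <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("patient_id", "year", "date", "analyte", "value")
  miss <- setdiff(need, names(ser))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ser$date <- as.Date(ser$date)
  ser$analyte <- toupper(ser$analyte)
  bad <- !ser$analyte %in% c("HBA1C", "FPG", "SBP", "DBP", "HEIGHT", "WEIGHT")
  if (any(bad)) {
    stop("unknown analyte at row ", which(bad)[1], call. = FALSE)
  }
  ser
}

#' Remove non-plausible measurement values
#'
#' Exclusion is per-value, not per-record: a record keeps its remaining
#' in-range measurements.  Returns the filtered series plus an exclusion log
#' naming each dropped value and the violated bound.  Idempotent.
#'
#' @param series Long-format series as from [load_lab_series()].
#' @param rules A [plausibility_rules()] object.
#' @return A list with elements `series` (retained rows) and `exclusions`
#'   (data.frame: patient_id, year, analyte, value, reason).
#' @export
apply_plausibility_filters <- function(series, rules = plausibility_rules()) {
  stopifnot(inherits(rules, "plausibility_rules"))
  if (nrow(series) == 0) {
    return(list(series = series,
                exclusions = data.frame(patient_id = character(),
                                        year = integer(),
                                        analyte = character(),
                                        value = numeric(),
                                        reason = character())))
  }
  lo <- vapply(series$analyte, function(a) rules[[a]][1], numeric(1))
  hi <- vapply(series$analyte, function(a) rules[[a]][2], numeric(1))
  drop <- !is.na(series$value) & (series$value < lo | series$value > hi)
  reason <- ifelse(series$value < lo,
                   paste0(series$analyte, " < ", lo),
                   paste0(series$analyte, " > ", hi))
  list(
    series = series[!drop, , drop = FALSE],
    exclusions = data.frame(
      patient_id = series$patient_id[drop],
      year = series$year[drop],
      analyte = series$analyte[drop],
      value = series$value[drop],
      reason = reason[drop],
      stringsAsFactors = FALSE
    )
  )
}

#' Derive the binary glycemic-control outcome for one patient-year
#'
#' Control is determined directly from the latest HbA1c of the year
#' (< 7% means controlled) or, when no HbA1c is available, inferred from the
#' last three fasting-glucose measurements of the year (controlled when all
#' three are <= 130 mg/dl).  With fewer than three fasting-glucose values and
#' no HbA1c the outcome is undetermined (NA).  When both rules are decidable
#' the HbA1c verdict is authoritative; a disagreement is flagged via the
#' `"conflict"` attribute.
#'
#' @param series Long-format rows for a single patient-year, already
#'   plausibility-filtered.  Unsorted input is sorted by date internally.
#' @param hba1c_threshold HbA1c control threshold in percent (default 7).
#' @param fpg_threshold Fasting-glucose control threshold in mg/dl
#'   (default 130).
#' @param n_fpg Number of trailing fasting-glucose values required
#'   (default 3).
#' @return 1, 0 or NA, with attribute `conflict` (TRUE/FALSE).
#' @export
derive_glycemic_control <- function(series, hba1c_threshold = 7,
                                    fpg_threshold = 130, n_fpg = 3) {
  series <- series[!is.na(series$value), , drop = FALSE]
  series <- series[order(series$date), , drop = FALSE]
  a1c <- series$value[series$analyte == "HBA1C"]
  fpg <- series$value[series$analyte == "FPG"]
  fpg_verdict <- if (length(fpg) >= n_fpg) {
    as.numeric(all(utils::tail(fpg, n_fpg) <= fpg_threshold))
  } else NA_real_
  if (length(a1c) > 0) {
    out <- as.numeric(a1c[length(a1c)] < hba1c_threshold)
    conflict <- !is.na(fpg_verdict) && fpg_verdict != out
  } else {
    out <- fpg_verdict
    conflict <- FALSE
  }
  structure(out, conflict = conflict)
}

#' Derive outcomes for every patient-year in a series table
#'
#' @param series Long-format filtered series covering many patient-years.
#' @param ... Passed to [derive_glycemic_control()].
#' @return data.frame: patient_id, year, outcome, conflict.
#' @export
derive_outcomes <- function(series, ...) {
  if (nrow(series) == 0) {
    return(data.frame(patient_id = character(), year = integer(),
                      outcome = numeric(), conflict = logical()))
  }
  key <- interaction(series$patient_id, series$year, drop = TRUE)
  parts <- split(series, key)
  res <- lapply(parts, function(p) {
    o <- derive_glycemic_control(p, ...)
    data.frame(patient_id = p$patient_id[1], year = p$year[1],
               outcome = as.numeric(o), conflict = attr(o, "conflict"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$patient_id, out$year), , drop = FALSE]
}

#' Build the complete-case analysis set
#'
#' Drops rows with a missing outcome, then rows with missing values in any
#' adjustment covariate (complete-case analysis under a missing-at-random
#' assumption).  Drop counts by reason are attached as the `"drop_log"`
#' attribute; output size plus total drops always equals input size.
#'
#' @param records Observation records (data.frame).
#' @param adjustment_set Character vector of covariate names that must be
#'   complete.
#' @return The retained rows, with attribute `drop_log`.
#' @export
build_analysis_set <- function(records, adjustment_set = character()) {
  unknown <- setdiff(adjustment_set, names(records))
  if (length(unknown)) {
    stop("unknown adjustment covariate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n0 <- nrow(records)
  miss_y <- is.na(records$outcome)
  kept <- records[!miss_y, , drop = FALSE]
  drop_log <- c(missing_outcome = sum(miss_y))
  for (cv in adjustment_set) {
    m <- is.na(kept[[cv]])
    drop_log[paste0("missing_", cv)] <- sum(m)
    kept <- kept[!m, , drop = FALSE]
  }
  if (nrow(kept) == 0) {
    stop("empty analysis set after complete-case filtering", call. = FALSE)
  }
  stopifnot(nrow(kept) + sum(drop_log) == n0)
  attr(kept, "drop_log") <- drop_log
  kept
}

#' Cross-tabulate the glycemic-control outcome against a covariate
#'
#' Counts and row proportions of {uncontrolled, controlled, missing} per
#' covariate level, pooled over years and clinics.  Continuous covariates can
#' be binned at empirical quartiles or at supplied breaks.
#'
#' @param records Observation records (outcome may be missing).
#' @param covariate Covariate column name.
#' @param binning `"none"` (default), `"quartile"`, or a numeric vector of
#'   cut points.
#' @return data.frame: level, n_uncontrolled, n_controlled, n_missing,
#'   p_uncontrolled, p_controlled, p_missing, p_controlled_nonmissing.
#' @export
crosstab_outcome <- function(records, covariate, binning = "none") {
  if (!covariate %in% names(records)) {
    stop("unknown covariate: ", covariate, call. = FALSE)
  }
  x <- records[[covariate]]
  if (is.numeric(binning)) {
    x <- cut(x, breaks = binning, include.lowest = TRUE, right = FALSE)
  } else if (identical(binning, "quartile")) {
    qs <- stats::quantile(x, probs = seq(0, 1, 0.25), na.rm = TRUE)
    x <- cut(x, breaks = unique(qs), include.lowest = TRUE, right = FALSE)
  }
  lev <- if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
  ycat <- ifelse(is.na(records$outcome), "missing",
                 ifelse(records$outcome == 1, "controlled", "uncontrolled"))
  rows <- lapply(lev, function(l) {
    sel <- !is.na(x) & x == l
    n_un <- sum(sel & ycat == "uncontrolled")
    n_co <- sum(sel & ycat == "controlled")
    n_mi <- sum(sel & ycat == "missing")
    n <- n_un + n_co + n_mi
    data.frame(level = as.character(l), n_uncontrolled = n_un,
               n_controlled = n_co, n_missing = n_mi,
               p_uncontrolled = n_un / n, p_controlled = n_co / n,
               p_missing = n_mi / n,
               p_controlled_nonmissing = n_co / (n_un + n_co),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(x)) {
    sel <- is.na(x)
    n_un <- sum(sel & ycat == "uncontrolled")
    n_co <- sum(sel & ycat == "controlled")
    n_mi <- sum(sel & ycat == "missing")
    n <- n_un + n_co + n_mi
    out <- rbind(out, data.frame(
      level = "Missing", n_uncontrolled = n_un, n_controlled = n_co,
      n_missing = n_mi, p_uncontrolled = n_un / n, p_controlled = n_co / n,
      p_missing = n_mi / n,
      p_controlled_nonmissing = n_co / (n_un + n_co)))
  }
  rownames(out) <- NULL
  out
}
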
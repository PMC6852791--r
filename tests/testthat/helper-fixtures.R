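# Fixture builders shared across the suite.  Everything is generated in
# code; no stored data.

# A tiny well-formed patient-year table.
tiny_records <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    clinic_id = rep(c("C01", "C02"), length.out = n),
    year = 2012,
    exposed = rep(c(0, 1), length.out = n),
    outcome = rbinom(n, 1, 0.4),
    sex = rbinom(n, 1, 0.5),
    age = round(runif(n, 40, 80)),
    previous_control = rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE)
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  write.csv(records, path, row.names = FALSE, na = "")
  path
}

# Long-format lab series for one patient-year.
lab_series <- function(analytes, values, dates = NULL,
                       patient_id = "P1", year = 2013) {
  if (is.null(dates)) {
    dates <- as.Date("2013-01-01") + seq_along(values) * 10
  }
  data.frame(patient_id = patient_id, year = year, date = dates,
             analyte = analytes, value = values, stringsAsFactors = FALSE)
}

# A generated study restricted to the program clinics, stacked with clinic
# indicator covariates (the pooled estimation frame).
pooled_scenario_data <- function(scenario = "original-like",
                                 n_patients_per_clinic = 100, seed = 1,
                                 adjustment_set = default_adjustment_set(),
                                 ...) {
  cfg <- builtin_scenarios(n_patients_per_clinic = n_patients_per_clinic,
                           seed = seed)[[scenario]]
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  study <- generate_study(cfg)
  pool <- diabtmle:::pooled_treated_data(study$records, adjustment_set)
  list(study = study, data = pool$data, adjustment_set = pool$adjustment_set)
}

# Treated-clinics-only config: identical treated records (per-clinic RNG
# substreams) at a fraction of the generation cost.
treated_only_config <- function(scenario, n_patients_per_clinic, seed) {
  cfg <- builtin_scenarios(seed = seed)[[scenario]]
  nt <- cfg$n_clinics_treated
  cfg$n_clinics_control <- 0L
  cfg$n_patients_per_clinic <- rep(n_patients_per_clinic, nt)
  cfg$baseline_control_by_clinic <- cfg$baseline_control_by_clinic[seq_len(nt)]
  cfg
}
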
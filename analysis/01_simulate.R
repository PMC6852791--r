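#!/usr/bin/env Rscript
# Generate the working synthetic cohort: 11 clinics (6 program, 5
# conventional care), 5 years, confounded program exposure, 5-point true
# effect, and 62% MAR outcome missingness.  Writes the observed data, the
# ground truth and the configuration under results/cohort/.

library(diabtmle)

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- builtin_scenarios(n_patients_per_clinic = 500, seed = 20240501)[["original-like"]]
study <- generate_study(cfg)
observed <- impose_missingness(study$records, cfg)

write.csv(observed, file.path(out, "observed_records.csv"), row.names = FALSE)
write.csv(study$truth$table, file.path(out, "ground_truth.csv"),
          row.names = FALSE)
yaml::write_yaml(unclass(cfg), file.path(out, "config.yaml"))

cat(sprintf("cohort: %d patient-years, %d clinics, exposure prevalence %.3f in program clinics\n",
            nrow(observed), length(unique(observed$clinic_id)),
            mean(observed$exposed[observed$diabetimss_clinic])))
cat(sprintf("outcome missingness: %.3f; true pooled ATE: %.4f\n",
            mean(is.na(observed$outcome)), study$truth$pooled_ate))
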
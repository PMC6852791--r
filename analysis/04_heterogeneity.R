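#!/usr/bin/env Rscript
# Treatment-effect heterogeneity: per-observation blips from the outcome
# model on program-clinic data, a regression-tree partition of the blips,
# and predicted program impact for the conventional-care clinics.

library(diabtmle)

out <- "results/heterogeneity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

observed <- read.csv("results/cohort/observed_records.csv")
adj <- default_adjustment_set()
analysis <- build_analysis_set(observed, adj)
treated <- analysis[analysis$diabetimss_clinic, ]

blips <- estimate_blips(treated, adj, engine = "superlearner", seed = 21)
cat(sprintf("blips: mean %.4f, IQR [%.4f, %.4f]\n", mean(blips$blip),
            quantile(blips$blip, 0.25), quantile(blips$blip, 0.75)))
write.csv(data.frame(clinic_id = treated$clinic_id, blip = blips$blip),
          file.path(out, "blips.csv"), row.names = FALSE)

tree <- fit_blip_tree(blips)
export_blip_tree_text(tree, file.path(out, "blip_tree.txt"))
export_blip_tree_json(tree, file.path(out, "blip_tree.json"))
cat(sprintf("tree: %d leaves, leaf means %s\n", nrow(tree$leaves),
            paste(sprintf("%.3f", sort(tree$leaves$mean_blip)),
                  collapse = ", ")))

control <- observed[!observed$diabetimss_clinic &
                      complete.cases(observed[adj]), ]
impact <- predict_control_clinic_impact(tree, control)
write.csv(impact$by_clinic, file.path(out, "control_clinic_impact.csv"),
          row.names = FALSE)
cat(sprintf("predicted impact in conventional-care clinics: mean %.4f across %d clinics\n",
            mean(impact$per_obs$impact), nrow(impact$by_clinic)))
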
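test_that("generation is deterministic in the seed and stable under added clinics", {
  cfg <- builtin_scenarios(n_patients_per_clinic = 40, seed = 3)[["original-like"]]
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$table, s2$truth$table)

  cfg2 <- cfg
  cfg2$seed <- 4L
  expect_false(identical(generate_study(cfg2)$records$outcome,
                         s1$records$outcome))

  # per-clinic substreams: dropping the conventional-care clinics leaves the
  # program clinics' records byte-identical
  cfg3 <- treated_only_config("original-like", 40, 3)
  s3 <- generate_study(cfg3)
  treated <- s1$records[s1$records$diabetimss_clinic, ]
  rownames(treated) <- NULL
  expect_identical(treated, s3$records)
})

test_that("study dimensions, exposure assignment and prevalence match the design", {
  cfg <- builtin_scenarios(n_patients_per_clinic = 334, seed = 5)[["original-like"]]
  st <- generate_study(cfg)
  recs <- st$records
  expect_equal(nrow(recs), 334 * 11 * 5)
  expect_equal(length(unique(recs$clinic_id)), 11)
  expect_equal(sort(unique(recs$year)), 2012:2016)
  # conventional-care clinics have exposure exactly zero
  expect_equal(sum(recs$exposed[!recs$diabetimss_clinic]), 0)
  # treated-clinic prevalence within 2pp of the target at n >= 10,000
  expect_equal(mean(recs$exposed[recs$diabetimss_clinic]), 0.28,
               tolerance = 0.02 / 0.28)
  # previous control equals last year's realized outcome
  one <- recs[recs$patient_id == recs$patient_id[1], ]
  one <- one[order(one$year), ]
  expect_equal(one$previous_control[-1], one$outcome[-nrow(one)])
})

test_that("ground truth matches the configured effects", {
  # constant effect: potential-outcome draws reproduce the target ATE
  cfg <- builtin_scenarios(n_patients_per_clinic = 334, seed = 7)[["original-like"]]
  st <- generate_study(cfg)
  tb <- st$truth$table
  expect_equal(st$truth$pooled_ate, 0.05, tolerance = 1e-6)
  mc <- mean(tb$y1) - mean(tb$y0)
  se <- sqrt(2 * 0.25 / nrow(tb))
  expect_lt(abs(mc - 0.05), 3 * se + 1e-12)
  # pooled ATE is the clinic-size-weighted mean of clinic ATEs
  treated_ids <- unique(tb$clinic_id[tb$clinic_id %in%
                                       st$records$clinic_id[st$records$diabetimss_clinic]])
  w <- table(tb$clinic_id)[treated_ids]
  expect_equal(st$truth$pooled_ate,
               sum(st$truth$clinic_ate[treated_ids] * as.numeric(w)) / sum(w),
               tolerance = 1e-12)
  # potential-outcome probabilities live inside the clip bounds
  expect_true(all(tb$p0 >= 0.01 & tb$p0 <= 0.99))
  expect_true(all(tb$p1 >= 0.01 & tb$p1 <= 0.99))

  # null world: exactly zero everywhere
  st0 <- generate_study(builtin_scenarios(n_patients_per_clinic = 60,
                                          seed = 7)[["null"]])
  expect_equal(st0$truth$pooled_ate, 0)
  expect_true(all(st0$truth$table$blip == 0))

  # unconfounded null: empirical RD near zero
  pool <- diabtmle:::pooled_treated_data(st0$records,
                                         default_adjustment_set())
  rd <- unadjusted_estimate(pool$data)
  expect_lt(abs(rd$rd), 3 * (rd$rd_hi - rd$rd) / stats::qnorm(0.975))

  # heterogeneous effects ordered by complication count
  sth <- generate_study(builtin_scenarios(n_patients_per_clinic = 60,
                                          seed = 7)[["hte"]])
  bl <- tapply(sth$truth$table$blip, sth$records$n_complications, mean)
  expect_gt(bl[["0"]], bl[["2"]])
  expect_equal(unname(bl[["0"]]), 0.064, tolerance = 1e-6)
  expect_equal(unname(bl[["2"]]), 0.026, tolerance = 1e-6)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(baseline_control_by_clinic = c(0, 0.5)),
               "baseline")
  expect_error(synthetic_config(missingness_rate = 1.2), "probability")
  expect_error(synthetic_config(n_patients_per_clinic = 0), "positive")
  expect_error(synthetic_config(blip = list(type = "spline")), "blip")
})

test_that("imposed missingness hits its target and is MAR", {
  cfg <- builtin_scenarios(n_patients_per_clinic = 909, seed = 21)[["original-like"]]
  st <- generate_study(cfg)
  m <- impose_missingness(st$records, cfg)
  frac <- mean(is.na(m$outcome))
  expect_gte(frac, 0.60)
  expect_lte(frac, 0.64)

  # rate 0 is the identity
  cfg0 <- cfg
  cfg0$missingness_rate <- 0
  expect_identical(impose_missingness(st$records, cfg0), st$records)

  # refuses partially observed input
  expect_error(impose_missingness(m, cfg), "fully observed")

  # MAR: given (W, A), the missingness indicator carries no information
  # about the outcome (likelihood-ratio test on an added Y term)
  d <- m
  d$miss <- as.numeric(is.na(d$outcome))
  d$y_true <- st$records$outcome
  base <- glm(miss ~ age + previous_control + exposed, data = d,
              family = binomial())
  ext <- glm(miss ~ age + previous_control + exposed + y_true, data = d,
             family = binomial())
  p <- anova(base, ext, test = "LRT")[2, "Pr(>Chi)"]
  expect_gt(p, 0.01)
})

test_that("missingness driven only by age is monotone in age", {
  cfg <- builtin_scenarios(n_patients_per_clinic = 400, seed = 22)[["original-like"]]
  cfg$missingness_coefs <- c(age_std = -0.8, previous_control = 0,
                             exposed = 0)
  st <- generate_study(cfg)
  m <- impose_missingness(st$records, cfg)
  q <- cut(m$age, quantile(m$age, seq(0, 1, 0.25)), include.lowest = TRUE)
  rates <- tapply(is.na(m$outcome), q, mean)
  expect_gt(rates[[1]], rates[[4]])
  expect_true(all(diff(rates) < 0.02))  # non-increasing up to noise
})
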
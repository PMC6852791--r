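test_that("CSV ingestion preserves rows and missingness, validates schema", {
  recs <- tiny_records(10)
  path <- write_records_csv(recs)
  got <- load_observations(path)
  expect_equal(nrow(got), 10)

  # empty outcome cells become NA, never 0
  recs2 <- recs
  recs2$outcome[c(2, 5)] <- NA
  got2 <- load_observations(write_records_csv(recs2))
  expect_true(all(is.na(got2$outcome[c(2, 5)])))
  expect_equal(sum(is.na(got2$outcome)), 2)

  # missing required column named in the error
  expect_error(load_observations(write_records_csv(recs[setdiff(names(recs),
                                                                "exposed")])),
               "exposed")
  # non-numeric value reported with its row
  recs3 <- recs
  recs3$age <- as.character(recs3$age)
  recs3$age[4] <- "forty"
  expect_error(load_observations(write_records_csv(recs3)), "row 4")
  # duplicate patient-year rejected
  recs4 <- rbind(recs, recs[1, ])
  expect_error(load_observations(write_records_csv(recs4)), "duplicate")
  # schema mapping renames file columns to canonical names
  recs5 <- recs
  names(recs5)[names(recs5) == "exposed"] <- "in_program"
  got5 <- load_observations(write_records_csv(recs5),
                            schema = c(exposed = "in_program"))
  expect_true("exposed" %in% names(got5))
})

test_that("plausibility filtering is per-value, logged, and idempotent", {
  ser <- lab_series(c("SBP", "HEIGHT", "WEIGHT", "HBA1C", "FPG", "DBP"),
                    c(40, 120, 70, 6.8, 36, 100))
  out <- apply_plausibility_filters(ser)
  # SBP 40 and height 120 and FPG 36 excluded; weight/HbA1c/DBP retained
  expect_setequal(out$exclusions$analyte, c("SBP", "HEIGHT", "FPG"))
  expect_setequal(out$series$analyte, c("WEIGHT", "HBA1C", "DBP"))
  expect_match(out$exclusions$reason[out$exclusions$analyte == "SBP"],
               "SBP < 50")
  # exclusion is per-value: the patient-year keeps its in-range values
  expect_equal(nrow(out$series) + nrow(out$exclusions), nrow(ser))

  again <- apply_plausibility_filters(out$series)
  expect_identical(again$series, out$series)
  expect_equal(nrow(again$exclusions), 0)

  empty <- apply_plausibility_filters(ser[0, , drop = FALSE])
  expect_equal(nrow(empty$series), 0)

  expect_error(plausibility_rules(sbp_range = c(250, 50)), "invalid")
})

test_that("glycemic control follows the HbA1c-first, FPG-triplet rule", {
  cases <- list(
    list(a = c(HBA1C = 6.5), want = 1),
    list(a = c(HBA1C = 7.2), want = 0),
    list(a = c(FPG = 120, FPG = 125, FPG = 130), want = 1),
    list(a = c(FPG = 120, FPG = 140, FPG = 125), want = 0),
    list(a = c(FPG = 120), want = NA_real_),
    # four FPG values: only the last three decide
    list(a = c(FPG = 180, FPG = 120, FPG = 125, FPG = 128), want = 1)
  )
  for (cs in cases) {
    ser <- lab_series(names(cs$a), unname(cs$a))
    got <- derive_glycemic_control(ser)
    expect_equal(as.numeric(got), cs$want, info = paste(names(cs$a),
                                                        collapse = ","))
  }

  # latest HbA1c of the year decides, and input order does not matter
  ser <- lab_series(c("HBA1C", "HBA1C"), c(7.5, 6.6),
                    dates = as.Date(c("2013-02-01", "2013-11-01")))
  expect_equal(as.numeric(derive_glycemic_control(ser)), 1)
  shuffled <- ser[2:1, ]
  expect_equal(as.numeric(derive_glycemic_control(shuffled)), 1)

  # HbA1c authoritative over a conflicting FPG triplet, conflict flagged
  ser2 <- rbind(lab_series("HBA1C", 7.5,
                           dates = as.Date("2013-12-01")),
                lab_series(rep("FPG", 3), c(110, 115, 120)))
  got2 <- derive_glycemic_control(ser2)
  expect_equal(as.numeric(got2), 0)
  expect_true(attr(got2, "conflict"))

  # grouped derivation covers each patient-year once
  many <- rbind(lab_series("HBA1C", 6.5, patient_id = "A", year = 2012),
                lab_series(rep("FPG", 3), c(120, 125, 128),
                           patient_id = "B", year = 2012),
                lab_series("FPG", 150, patient_id = "B", year = 2013))
  tab <- derive_outcomes(many)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$outcome[tab$patient_id == "A"], 1)
  expect_true(is.na(tab$outcome[tab$patient_id == "B" & tab$year == 2013]))
})

test_that("complete-case analysis set accounts for every dropped row", {
  recs <- tiny_records(100)
  recs$outcome[1:62] <- NA
  out <- build_analysis_set(recs)
  expect_equal(nrow(out), 38)
  expect_equal(unname(attr(out, "drop_log")["missing_outcome"]), 62)

  # no missingness: identity
  full <- tiny_records(100)
  expect_equal(nrow(build_analysis_set(full, "previous_control")), 100)

  # covariate missingness drops after outcome missingness, sizes add up
  recs2 <- tiny_records(100)
  recs2$outcome[1:30] <- NA
  recs2$previous_control[25:40] <- NA
  out2 <- build_analysis_set(recs2, "previous_control")
  dl <- attr(out2, "drop_log")
  expect_equal(nrow(out2) + sum(dl), 100)

  recs3 <- tiny_records(10)
  recs3$previous_control <- NA
  expect_error(build_analysis_set(recs3, "previous_control"), "empty")
  expect_error(build_analysis_set(recs3, "nonexistent"), "nonexistent")
})

test_that("outcome cross-tabs reproduce printed-count arithmetic", {
  # the previous-control row of the published descriptive table:
  # 12707 uncontrolled, 19724 controlled, 15628 missing
  recs <- data.frame(
    patient_id = sprintf("P%d", 1:(12707 + 19724 + 15628)),
    year = 2013,
    outcome = c(rep(0, 12707), rep(1, 19724), rep(NA, 15628)),
    previous_control = 1)
  tab <- crosstab_outcome(recs, "previous_control")
  expect_equal(tab$n_uncontrolled, 12707)
  expect_equal(tab$n_controlled, 19724)
  expect_equal(tab$p_controlled_nonmissing, 0.608, tolerance = 5e-4)
  # row proportions sum to one
  expect_equal(tab$p_uncontrolled + tab$p_controlled + tab$p_missing, 1,
               tolerance = 1e-12)
  # counts add to input size
  expect_equal(tab$n_uncontrolled + tab$n_controlled + tab$n_missing,
               nrow(recs))

  # single-level covariate: one row equal to the full dataset
  recs$flat <- 1
  tab2 <- crosstab_outcome(recs, "flat")
  expect_equal(nrow(tab2), 1)

  # hand-computed proportions on known cells
  small <- data.frame(outcome = c(1, 1, 0, NA, 0, 1), g = c(1, 1, 1, 2, 2, 2))
  t3 <- crosstab_outcome(small, "g")
  expect_equal(t3$p_controlled, c(2 / 3, 1 / 3))
  expect_equal(t3$p_missing, c(0, 1 / 3))

  # quartile binning yields at most four levels plus missing
  recsq <- tiny_records(80)
  tq <- crosstab_outcome(recsq, "age", binning = "quartile")
  expect_lte(nrow(tq), 5)
  expect_equal(sum(tq$n_uncontrolled + tq$n_controlled + tq$n_missing), 80)

  expect_error(crosstab_outcome(small, "nope"), "unknown covariate")
})
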
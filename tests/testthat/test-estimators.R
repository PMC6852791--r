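test_that("unadjusted estimator reproduces binomial arithmetic", {
  d <- data.frame(exposed = rep(c(0, 1), each = 100),
                  outcome = c(rep(1, 30), rep(0, 70), rep(1, 45), rep(0, 55)))
  est <- unadjusted_estimate(d)
  expect_equal(est$rd, 0.15)
  se <- sqrt(0.3 * 0.7 / 100 + 0.45 * 0.55 / 100)
  expect_equal(est$rd_hi - est$rd, qnorm(0.975) * se, tolerance = 1e-12)
  expect_true(est$rd_lo <= est$rd && est$rd <= est$rd_hi)

  d2 <- data.frame(exposed = rep(c(0, 1), each = 10),
                   outcome = rep(c(1, 0), 10))
  expect_equal(unadjusted_estimate(d2)$rd, 0)

  expect_error(unadjusted_estimate(data.frame(exposed = rep(1, 5),
                                              outcome = rep(0, 5))),
               "empty")
})

test_that("g-computation with no covariates reduces to the unadjusted estimate", {
  d <- tiny_records(200, seed = 4)
  ua <- unadjusted_estimate(d)
  gc <- gcomp_logistic_estimate(d, character(), boot = 0)
  expect_equal(gc$rd, ua$rd, tolerance = 1e-10)
  expect_equal(gc$p1, ua$p1, tolerance = 1e-10)
  expect_equal(gc$p0, ua$p0, tolerance = 1e-10)
})

test_that("g-computation recovers the truth in the correctly-specified world", {
  sc <- pooled_scenario_data("original-like", 667, seed = 31)
  gc <- gcomp_logistic_estimate(sc$data, sc$adjustment_set, boot = 0)
  expect_equal(gc$rd, sc$study$truth$pooled_ate, tolerance = 0.01 / 0.05)
  # bootstrap CI brackets the point estimate (single clinic, no dummies)
  one_clinic <- sc$data[sc$data$clinic_id == "C01", ]
  gcb <- gcomp_logistic_estimate(one_clinic, default_adjustment_set(),
                                 boot = 60, seed = 2)
  expect_true(gcb$rd_lo <= gcb$rd && gcb$rd <= gcb$rd_hi)
})

test_that("propensity fitting truncates, diagnoses and validates", {
  # exposure independent of covariates: fitted g concentrates at the
  # marginal rate
  set.seed(8)
  n <- 10000
  d <- data.frame(exposed = rbinom(n, 1, 0.3), x = rnorm(n))
  g <- fit_propensity(d, "x")
  expect_lt(sd(g$g), 0.05)
  expect_equal(mean(g$g), 0.3, tolerance = 0.05)

  # strong separation pushes raw values through the bounds; storage honors
  # the truncation contract
  d2 <- data.frame(exposed = rep(c(0, 1), each = 200),
                   x = c(rnorm(200, -2), rnorm(200, 2)))
  g2 <- fit_propensity(d2, "x")
  expect_lt(min(g2$raw), 0.025)
  expect_equal(min(g2$g), 0.025)
  expect_equal(max(g2$g), 0.975)
  # bounds [0,1] are the identity
  g3 <- fit_propensity(d2, "x", bounds = c(0, 1))
  expect_equal(g3$g, g3$raw)

  expect_error(fit_propensity(data.frame(exposed = rep(1, 10), x = 1:10),
                              "x"), "both exposure levels")
})

test_that("the clever covariate follows A/g - (1-A)/(1-g)", {
  # with no adjustment covariates the fitted g is exactly the exposed share
  d <- data.frame(exposed = rep(c(1, 0), each = 5), outcome = rep(c(1, 0), 5),
                  patient_id = sprintf("P%d", 1:10))
  fit <- tmle_estimate(d, character(), bounds = c(0, 1))
  expect_equal(fit$H[d$exposed == 1], rep(2, 5))
  expect_equal(fit$H[d$exposed == 0], rep(-2, 5))

  d2 <- data.frame(exposed = c(rep(1, 2), rep(0, 8)),
                   outcome = rep(c(1, 0), 5), patient_id = sprintf("P%d", 1:10))
  fit2 <- tmle_estimate(d2, character(), bounds = c(0, 1))
  expect_equal(fit2$H[d2$exposed == 1], rep(5, 2))
})

test_that("zero fluctuation reproduces the plug-in of the initial fit", {
  sc <- pooled_scenario_data("original-like", 60, seed = 33)
  fit0 <- tmle_estimate(sc$data, sc$adjustment_set, fluctuate = FALSE)
  expect_equal(fit0$epsilon, 0)
  plugin <- mean(fit0$Q0$a1) - mean(fit0$Q0$a0)
  expect_equal(fit0$psi, plugin, tolerance = 1e-12)
  # and the targeted estimate equals the mean difference of Qstar exactly
  fit <- tmle_estimate(sc$data, sc$adjustment_set)
  expect_equal(fit$psi, mean(fit$Qstar$a1) - mean(fit$Qstar$a0),
               tolerance = 1e-12)
  expect_equal(fit$ci95, fit$psi + c(-1, 1) * qnorm(0.975) * fit$se)
})

test_that("targeting solves the efficient influence-curve equation", {
  for (s in c(41, 42)) {
    sc <- pooled_scenario_data("variant", 100, seed = s)
    fit <- tmle_estimate(sc$data, sc$adjustment_set)
    expect_lt(abs(mean(fit$ic)), 1e-8 * sd(fit$ic))
  }
})

test_that("under randomized exposure TMLE agrees with the unadjusted contrast", {
  sc <- pooled_scenario_data("original-like", 667, seed = 35,
                             confounding_strength = 0)
  ua <- unadjusted_estimate(sc$data)
  tm <- tmle_estimate(sc$data, sc$adjustment_set)
  expect_equal(tm$psi, ua$rd, tolerance = 0.01 / max(abs(ua$rd), 0.01))
  expect_lt(abs(tm$psi - ua$rd), 0.01)
})

test_that("TMLE recovers the true effect in the correctly-specified world", {
  sc <- pooled_scenario_data("original-like", 667, seed = 36)
  fit <- tmle_estimate(sc$data, sc$adjustment_set)
  # single realization: allow ~2.5 standard errors around the truth
  expect_lt(abs(fit$psi - sc$study$truth$pooled_ate), 2.5 * fit$se)
})

test_that("positivity trouble raises a warning", {
  sc <- pooled_scenario_data("original-like", 150, seed = 38)
  d <- sc$data
  d$instr <- d$exposed + rnorm(nrow(d), 0, 0.1)  # near-deterministic of A
  expect_warning(tmle_estimate(d, c(sc$adjustment_set, "instr")),
                 "positivity")
})

test_that("clinic-stratified and pooled estimation has the published shape", {
  sc <- pooled_scenario_data("original-like", 120, seed = 39)
  d <- sc$study$records
  analysis <- d[d$diabetimss_clinic, ]
  rows <- estimate_by_clinic_and_pooled(analysis,
                                        methods = c("unadjusted", "tmle"),
                                        adjustment_set = default_adjustment_set(),
                                        boot = 0)
  # six clinics plus the pooled row, per method
  expect_equal(nrow(rows), 7 * 2)
  expect_setequal(unique(rows$clinic_id), c(sprintf("C%02d", 1:6), "All"))
  # risk difference consistent with the group means
  expect_equal(rows$rd, rows$p1 - rows$p0, tolerance = 1e-10)

  # a single usable clinic: pooled equals that clinic
  one <- analysis[analysis$clinic_id == "C01", ]
  rows1 <- estimate_by_clinic_and_pooled(one, methods = "unadjusted")
  expect_equal(rows1$rd[rows1$clinic_id == "C01"],
               rows1$rd[rows1$clinic_id == "All"])

  # a clinic with one exposure level is skipped with a warning
  broken <- analysis
  broken$exposed[broken$clinic_id == "C02"] <- 0
  expect_warning(r2 <- estimate_by_clinic_and_pooled(broken,
                                                     methods = "unadjusted"),
                 "C02")
  expect_false("C02" %in% r2$clinic_id)
})
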
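test_that("fold assignment is balanced, clustered and deterministic", {
  f <- make_folds(10, 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))

  # clustered folds never split a patient across folds
  ids <- rep(sprintf("P%d", 1:4), each = 3)
  fc <- make_folds(12, 2, cluster_ids = ids, seed = 2)
  expect_true(all(tapply(fc, ids, function(v) length(unique(v))) == 1))

  expect_identical(make_folds(100, 10, seed = 9), make_folds(100, 10, seed = 9))
  expect_error(make_folds(12, 5, cluster_ids = rep(c("a", "b"), 6)),
               "clusters")
  expect_error(make_folds(5, 1), "V")
})

test_that("a single learner receives weight one", {
  set.seed(1)
  X <- data.frame(x = rnorm(60))
  y <- rbinom(60, 1, plogis(X$x))
  fit <- fit_super_learner(X, y, learners = list(sl_lrn_mean()), V = 5)
  expect_equal(unname(fit$weights), 1)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
})

test_that("ensemble prediction is the convex combination of candidates", {
  const_learner <- function(p, name) {
    diabtmle:::new_learner(name,
      fit = function(X, y, weights = NULL) p,
      predict = function(model, X) rep(model, nrow(X)))
  }
  fit <- structure(list(
    learners = list(const_learner(0.2, "a"), const_learner(0.4, "b")),
    fits = list(0.2, 0.4), weights = c(a = 0.5, b = 0.5),
    feature_names = "x"), class = "super_learner")
  expect_equal(predict(fit, data.frame(x = 1:3)), rep(0.3, 3))
  expect_error(predict(fit, data.frame(z = 1)), "x")
})

test_that("cross-validated weights find the true model", {
  set.seed(42)
  n <- 5000
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * X$x1 - 0.8 * X$x2))
  fit <- fit_super_learner(X, y, learners = list(sl_lrn_glm(),
                                                 sl_lrn_mean()), V = 10)
  expect_gt(fit$weights[["glm_main"]], 0.9)
  # the ensemble CV risk never exceeds the best single candidate's
  expect_lte(fit$cv_risk_ensemble, min(fit$cv_risks) + 1e-8)
})

test_that("pure-noise labels drive the ensemble to the marginal mean", {
  set.seed(7)
  n <- 3000
  X <- data.frame(x = rnorm(n))
  y <- rbinom(n, 1, 0.3)
  fit <- fit_super_learner(X, y, learners = list(sl_lrn_mean(),
                                                 sl_lrn_glm()), V = 10)
  # Bernoulli(0.3) entropy is the analytic floor for the log-loss
  floor_ <- -(0.3 * log(0.3) + 0.7 * log(0.7))
  expect_lt(fit$cv_risk_ensemble, floor_ + 0.02)
  expect_lte(fit$cv_risk_ensemble, fit$cv_risks[["mean"]] + 1e-8)
})

test_that("weights are invariant to learner ordering and degenerate labels clip", {
  set.seed(11)
  n <- 800
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(X$x1))
  lib <- list(sl_lrn_mean(), sl_lrn_glm(), sl_lrn_rpart())
  f1 <- fit_super_learner(X, y, learners = lib, V = 5, seed = 3)
  f2 <- fit_super_learner(X, y, learners = rev(lib), V = 5, seed = 3)
  expect_equal(f1$weights[names(f2$weights)], f2$weights, tolerance = 1e-5)

  # all-one labels: predictions respect the probability ceiling
  fit1 <- fit_super_learner(data.frame(x = rnorm(40)), rep(1, 40),
                            learners = list(sl_lrn_mean()), V = 4)
  expect_true(all(predict(fit1, data.frame(x = 0)) <= 1 - 1e-6))
})

test_that("zero-weight learners do not influence predictions", {
  set.seed(5)
  n <- 2000
  X <- data.frame(x = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X$x))
  fit <- fit_super_learner(X, y, learners = list(sl_lrn_glm(),
                                                 sl_lrn_mean()), V = 10)
  drop <- which(fit$weights == 0)
  skip_if(length(drop) == 0, "no zero-weight learner in this fit")
  pruned <- fit
  pruned$learners <- fit$learners[-drop]
  pruned$fits <- fit$fits[-drop]
  pruned$weights <- fit$weights[-drop]
  nd <- data.frame(x = seq(-2, 2, length.out = 50))
  expect_lt(max(abs(predict(fit, nd) - predict(pruned, nd))), 1e-8)
})

test_that("a failing learner is dropped with a warning, not fatal", {
  bad <- diabtmle:::new_learner("boom",
    fit = function(X, y, weights = NULL) stop("no fit"),
    predict = function(model, X) rep(0.5, nrow(X)))
  set.seed(2)
  X <- data.frame(x = rnorm(100))
  y <- rbinom(100, 1, 0.5)
  expect_warning(fit <- fit_super_learner(X, y,
                                          learners = list(sl_lrn_mean(), bad),
                                          V = 4),
                 "boom")
  expect_equal(names(fit$weights), "mean")
  expect_error(suppressWarnings(
    fit_super_learner(X, y, learners = list(bad), V = 4)), "all learners")
})

test_that("the ensemble tracks the best candidate on held-out data", {
  # scaled-down oracle property: under the misspecified-logistic world the
  # ensemble's independent test-set log-loss stays within 0.005 of the best
  # single candidate in nearly every replicate
  adj <- default_adjustment_set()
  wins <- 0
  reps <- 10
  for (s in seq_len(reps)) {
    cfg <- treated_only_config("variant", 67, 6000 + s)
    tr <- generate_study(cfg)$records
    cfg_te <- treated_only_config("variant", 134, 60000 + s)
    te <- generate_study(cfg_te)$records
    Xtr <- cbind(.a = tr$exposed, tr[adj])
    Xte <- cbind(.a = te$exposed, te[adj])
    sl <- fit_super_learner(Xtr, tr$outcome, cluster_ids = tr$patient_id,
                            seed = s)
    ens <- log_loss(te$outcome, predict(sl, Xte))
    singles <- vapply(seq_along(sl$learners), function(k) {
      log_loss(te$outcome,
               diabtmle:::clip_prob(sl$learners[[k]]$predict(sl$fits[[k]],
                                                             Xte)))
    }, numeric(1))
    if (ens <= min(singles) + 0.005) wins <- wins + 1
  }
  expect_gte(wins, reps - 1)
})

test_that("fit metadata serializes to JSON", {
  set.seed(3)
  X <- data.frame(x = rnorm(80))
  y <- rbinom(80, 1, 0.4)
  fit <- fit_super_learner(X, y, learners = list(sl_lrn_mean(),
                                                 sl_lrn_glm()), V = 4)
  path <- tempfile(fileext = ".json")
  export_super_learner(fit, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$weights, unname(fit$weights))
  expect_equal(sum(got$weights), 1, tolerance = 1e-10)
})
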
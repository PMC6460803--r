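test_that("scenario_config validates prevalences, covariance, dimensions", {
  expect_error(scenario_config("conditional_gaussian", K = 3,
                               prevalences = c(0.5, 0.5),
                               level_means = matrix(0, 3, 2),
                               covariance = diag(2)),
               "prevalences")
  expect_error(scenario_config("conditional_gaussian", K = 3,
                               prevalences = c(0.2, 0.3, 0.5),
                               level_means = matrix(0, 2, 2),
                               covariance = diag(2)),
               "level_means")
  bad <- matrix(c(1, 2, 2, 1), 2)        # not positive-definite
  expect_error(scenario_config("cumulative_logit", K = 3,
                               prevalences = c(0.2, 0.3, 0.5),
                               covariance = bad, slopes = c(1, 1)),
               "positive-definite")
})

test_that("conditional-Gaussian generator hits target prevalences and
           level means", {
  cfg <- construction_scenario(K = 3, mu = 1, p1 = 0.1, pK = 0.05)
  set.seed(71)
  d <- gen_conditional_gaussian(cfg, n = 1e5)
  freq <- level_counts(d) / d$n
  tol <- 3 * sqrt(cfg$prevalences * (1 - cfg$prevalences) / d$n)
  expect_true(all(abs(freq - cfg$prevalences) < tol))
  for (k in 1:3) {
    nk <- sum(d$D == k)
    mhat <- colMeans(d$X[d$D == k, ])
    expect_true(all(abs(mhat - cfg$level_means[k, ]) <
                      3 * sqrt(2 / nk)))
  }
})

test_that("intercept calibration: closed form at beta = 0, accuracy and
           stability otherwise", {
  cfg0 <- scenario_config("cumulative_logit", K = 3,
                          prevalences = c(0.6, 0.3, 0.1),
                          covariance = diag(2), slopes = c(0, 0))
  cal0 <- calibrate_intercepts(cfg0, calibration_n = 1e3)
  expect_equal(cal0$alphas, qlogis(c(0.6, 0.9)), tolerance = 1e-8)

  cfg <- construction_po_scenario(K = 3, beta = c(1, 2), p1 = 0.6, pK = 0.1)
  set.seed(73)
  cal <- calibrate_intercepts(cfg, calibration_n = 5e5)
  expect_true(all(diff(cal$alphas) > 0))
  expect_true(all(abs(cal$achieved_prevalences - cfg$prevalences) < 0.005))
  # doubling the calibration sample barely moves the solution
  set.seed(73)
  cal2 <- calibrate_intercepts(cfg, calibration_n = 1e6)
  expect_equal(cal$alphas, cal2$alphas, tolerance = 0.02)
  # fresh draw achieves the targets
  d <- gen_cumulative_logit(cfg, n = 2e5, intercepts = cal)
  expect_true(all(abs(level_counts(d) / d$n - cfg$prevalences) < 0.01))
})

test_that("cumulative-logit generator is calibrated conditionally on the
           linear predictor", {
  cfg <- construction_po_scenario(K = 3, beta = c(1, 2))
  set.seed(79)
  cal <- calibrate_intercepts(cfg, calibration_n = 2e5)
  d <- gen_cumulative_logit(cfg, n = 2e5, intercepts = cal)
  pr <- cumlogit_level_probs(cfg, d$X, cal$alphas)
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, d$n), tolerance = 1e-12)
  # empirical P(D <= 1 | eta in a narrow bin) ~ expit(alpha_1 - t)
  eta <- drop(d$X %*% cfg$slopes)
  t0 <- median(eta)
  bin <- abs(eta - t0) < 0.05
  expect_lt(abs(mean(d$D[bin] <= 1) - plogis(cal$alphas[1] - t0)), 0.02)
})

test_that("selection example presets encode the published designs", {
  ex1 <- selection_example_config(1)
  expect_equal(ex1$family, "cumulative_logit")
  expect_equal(ex1$slopes, c(1, 2, rep(0.5, 14), rep(0.1, 14)))
  expect_equal(ex1$prevalences, c(0.6, 0.3, 0.1))
  expect_equal(ex1$marker_mean, rep(1, 30))
  expect_equal(diag(ex1$covariance), rep(2, 30))
  expect_equal(ex1$covariance[1, 2], 0.6)      # 2 * 0.3 off-diagonal
  ex2 <- selection_example_config(2)
  expect_equal(ex2$prevalences, c(0.6, 0.335, 0.065))
  expect_equal(ex2$slopes, ex1$slopes)

  ex3 <- selection_example_config(3)
  ex4 <- selection_example_config(4)
  ex5 <- selection_example_config(5)
  # Example 4 differs from 3 only in beta2_1 and beta3_17..30
  dif <- which(ex3$level_means != ex4$level_means, arr.ind = TRUE)
  expect_equal(unname(dif[dif[, 1] == 2, 2]), 1)
  expect_equal(unname(dif[dif[, 1] == 3, 2]), 17:30)
  expect_equal(ex4$level_means[3, 17:30], rep(0.2, 14))
  # Example 5: markers 17-30 null for level 2
  expect_equal(ex5$level_means[2, 17:30], rep(0, 14))
  expect_equal(ex5$level_means[3, 17:30], rep(0.2, 14))
  for (ex in list(ex3, ex4, ex5)) {
    expect_equal(ex$p, 30L)
    expect_equal(ex$K, 3L)
    expect_equal(ex$level_means[1, ], rep(0, 30))
  }
})

test_that("generators are deterministic given a seed and refuse missing
           levels", {
  d1 <- gen_selection_example(1, 200, seed = 5)
  d2 <- gen_selection_example(1, 200, seed = 5)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$D, d2$D)
  d3 <- gen_selection_example(1, 200, seed = 6)
  expect_false(identical(d1$D, d3$D))
  expect_true(has_all_levels(d1))

  # rare top level at tiny n forces redraws, but all levels always appear
  cfg <- construction_scenario(K = 3, mu = 1, p1 = 0.5, pK = 0.05)
  set.seed(7)
  for (i in 1:20) {
    d <- gen_conditional_gaussian(cfg, n = 15)
    expect_true(has_all_levels(d))
  }
})

test_that("fixtures have their designed shapes", {
  aki <- gen_fixture("aki_like", seed = 2)
  expect_equal(aki$n, 465L)
  expect_equal(aki$p, 14L)
  expect_equal(level_counts(aki), c(374L, 61L, 30L))

  sep <- gen_fixture("separated", n = 80, seed = 3)
  f <- fit_combination(sep, "simple")   # flagged, but scores still separate
  expect_equal(auc(predict_risk(f, sep$X), sep$D == 3), 1.0)

  ties <- gen_fixture("ties", n = 60, seed = 4)
  expect_true(any(duplicated(ties$X[, 1])))

  # null fixture: outcome carries no marker information by construction
  nul <- gen_fixture("null", n = 3000, p = 2, seed = 5)
  expect_lt(abs(cor(nul$X[, 1], nul$D)), 0.06)
})

test_that("preset registry resolves every advertised name", {
  for (nm in preset_scenario()) {
    expect_s3_class(preset_scenario(nm), "scenario_config")
  }
  expect_error(preset_scenario("nope"), "unknown")
})
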
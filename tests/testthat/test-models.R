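test_that("simple fit matches a derivative-free likelihood oracle", {
  set.seed(42)
  d <- make_ordered_data(n = 20, K = 3, seed = 42)
  fit <- fit_combination(d, "simple")
  oracle <- logistic_ml_oracle(d$X, as.numeric(d$D <= 2))
  expect_equal(unname(c(fit$intercepts, fit$slopes)), oracle,
               tolerance = 1e-4)
})

test_that("null markers give near-zero slopes and test AUC near 0.5", {
  d <- gen_fixture("null", n = 2000, p = 2, seed = 7)
  fit <- fit_combination(d, "simple")
  se <- sqrt(diag(vcov(glm(I(d$D <= 2) ~ d$X, family = binomial()))))[-1]
  expect_true(all(abs(fit$slopes) < 3 * se))
  test <- gen_fixture("null", n = 5000, p = 2, seed = 8)
  a <- conditional_auc(predict_risk(fit, test$X), test$D,
                       level_contrast(3, 1:2))
  expect_equal(a, 0.5, tolerance = 0.05)
})

test_that("sequential submodels equal independent per-subset refits", {
  d <- make_ordered_data(n = 250, K = 4, seed = 5)
  fit <- fit_combination(d, "sequential")
  for (k in 1:3) {
    sub <- d$D >= k
    ref <- glm(I(d$D[sub] == k) ~ d$X[sub, ], family = binomial())
    expect_equal(unname(c(fit$intercepts[k], fit$slopes[, k])),
                 unname(coef(ref)), tolerance = 1e-8)
  }
  # risk score is the telescoped product of the submodels
  manual <- rep(1, d$n)
  for (k in 1:3) {
    manual <- manual *
      (1 - plogis(fit$intercepts[k] + drop(d$X %*% fit$slopes[, k])))
  }
  expect_equal(predict_risk(fit, d$X), manual, tolerance = 1e-12)
})

test_that("constraint-release: a free-slope continuation-ratio fit is the
           sequential fit, submodel by submodel", {
  d <- make_ordered_data(n = 300, K = 3, seed = 6)
  seq_fit <- fit_combination(d, "sequential")
  # free the common-slope restriction by refitting each conditional logit
  for (k in 1:2) {
    sub <- d$D >= k
    free <- glm(I(d$D[sub] == k) ~ d$X[sub, ], family = binomial())
    expect_equal(unname(coef(free)),
                 unname(c(seq_fit$intercepts[k], seq_fit$slopes[, k])),
                 tolerance = 1e-8)
  }
  # and the constrained fit has common slopes with loglik <= sequential's
  cr <- fit_combination(d, "contratio_logit")
  expect_lt(cr$loglik, seq_fit$loglik + 1e-8)
  expect_length(cr$slopes, 2L)
})

test_that("cumulative logit: ordered intercepts, no crossing, monotone score", {
  d <- make_ordered_data(n = 400, K = 4, seed = 11)
  fit <- fit_combination(d, "cum_logit")
  expect_true(all(diff(fit$intercepts) > 0))
  # fitted cumulative probabilities nondecreasing in k for every x
  pr <- category_probs(fit, d$X)
  cum <- t(apply(pr, 1, cumsum))
  expect_true(all(diff(t(cum)) >= -1e-12))
  # risk score is a monotone transformation of -(beta' x)
  eta <- drop(d$X %*% fit$slopes)
  expect_equal(cor(predict_risk(fit, d$X), -eta, method = "spearman"), 1)
})

test_that("proportional-odds parameter recovery at large n", {
  cfg <- construction_po_scenario(K = 3, beta = c(1, 2))
  set.seed(99)
  cal <- calibrate_intercepts(cfg, calibration_n = 2e5)
  d <- gen_cumulative_logit(cfg, n = 1e5, intercepts = cal)
  fit <- fit_combination(d, "cum_logit")
  # generator: logit P(D<=k) = alpha_k - beta'x; fitted: alpha_k + bhat'x
  ratio <- fit$slopes[2] / fit$slopes[1]
  expect_equal(ratio, 2, tolerance = 0.05)
  expect_lt(fit$slopes[1], 0)        # sign per fitted parameterization
})

test_that("baseline-category probabilities normalize and match multinom", {
  d <- make_ordered_data(n = 300, K = 3, seed = 13)
  fit <- fit_combination(d, "baseline_cat")
  pr <- category_probs(fit, d$X)
  expect_equal(rowSums(pr), rep(1, d$n), tolerance = 1e-10)
  df <- data.frame(D = factor(d$D), d$X)
  ref <- nnet::multinom(D ~ ., data = df, trace = FALSE, maxit = 1000,
                        reltol = 1e-13)
  expect_equal(unname(pr),
               unname(predict(ref, newdata = df, type = "probs")),
               tolerance = 1e-5)
  expect_equal(dim(fit$slopes), c(2L, 2L))
})

test_that("stereotype model honors its constraints and nesting sandwich", {
  for (seed in c(2, 21, 33)) {
    d <- make_ordered_data(n = 250, K = 4, seed = seed)
    st <- fit_combination(d, "stereotype")
    expect_identical(st$phi[1], 0)
    expect_identical(st$phi[d$K], 1)
    adj <- fit_combination(d, "adjcat_logit")
    base <- fit_combination(d, "baseline_cat")
    expect_lte(adj$loglik, st$loglik + 1e-6)
    expect_lte(st$loglik, base$loglik + 1e-6)
    pr <- category_probs(st, d$X)
    expect_equal(rowSums(pr), rep(1, d$n), tolerance = 1e-10)
  }
})

test_that("all seven strategies collapse to binary logistic when K = 2", {
  d <- make_ordered_data(n = 300, K = 2, seed = 17)
  ref <- implied_binary_coefs(fit_combination(d, "simple"))
  for (s in setdiff(combo_strategies(), "simple")) {
    fit <- fit_combination(d, s)
    expect_equal(implied_binary_coefs(fit), ref, tolerance = 1e-5,
                 label = s)
  }
})

test_that("predict_risk stays in [0,1], validates dimensions, handles
           zero slopes", {
  d <- make_ordered_data(n = 200, K = 3, seed = 19)
  for (s in combo_strategies()) {
    fit <- fit_combination(d, s)
    r <- predict_risk(fit, d$X)
    expect_true(all(r >= 0 & r <= 1), label = s)
    expect_error(predict_risk(fit, d$X[, 1, drop = FALSE]), "column")
  }
  # zero slopes: constant score implied by the intercepts alone
  fit <- fit_combination(d, "simple")
  fit$slopes[] <- 0
  r <- predict_risk(fit, d$X)
  expect_equal(r, rep(r[1], d$n))
})

test_that("perfect separation is flagged as non-convergence", {
  d <- gen_fixture("separated", n = 120, p = 2, seed = 23)
  fit <- fit_combination(d, "simple")
  expect_false(fit$converged)
})
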
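test_that("candidate sets are sorted, unique, validated", {
  cs <- candidate_set(list(c(2, 1), c(1, 2), c(3, 1)), p = 3)
  expect_equal(nrow(cs$combos), 2L)
  expect_equal(cs$combos[1, ], c(1L, 2L))
  expect_error(candidate_set(list(c(1, 4)), p = 3), "1\\.\\.p")
  expect_error(candidate_set(list(c(2, 2)), p = 3), "repeat")
  ap <- all_pairs(30)
  expect_equal(nrow(ap$combos), 435L)
  expect_equal(ap$combos[1, ], c(1L, 2L))
})

test_that("fit_candidates equals standalone logistic fits and the
           likelihood oracle", {
  d <- make_ordered_data(n = 120, K = 3, p = 3, seed = 51)
  cs <- all_pairs(3)
  fit <- fit_candidates(d, cs)
  expect_equal(ncol(fit$coefs), 3L)
  y <- as.numeric(d$D == 3)
  for (c in 1:3) {
    cols <- cs$combos[c, ]
    ref <- glm(y ~ d$X[, cols], family = binomial())
    expect_equal(unname(fit$coefs[, c]), unname(coef(ref)),
                 tolerance = 1e-6)
  }
  # brute-force oracle on a 30-row fixture
  d30 <- make_ordered_data(n = 30, K = 3, p = 3, seed = 52)
  f30 <- fit_candidates(d30, cs)
  for (c in 1:3) {
    oracle <- logistic_ml_oracle(d30$X[, cs$combos[c, ]],
                                 as.numeric(d30$D == 3))
    expect_equal(unname(f30$coefs[, c]), oracle, tolerance = 1e-4)
  }
})

test_that("apparent AUCs delegate to conditional_auc and reuse one score", {
  d <- make_ordered_data(n = 200, K = 3, p = 4, seed = 53)
  cs <- all_pairs(4)
  fit <- fit_candidates(d, cs)
  app <- apparent_aucs(d, cs, fit$coefs)
  for (c in seq_len(nrow(cs$combos))) {
    cols <- cs$combos[c, ]
    eta <- fit$coefs[1, c] + drop(d$X[, cols] %*% fit$coefs[-1, c])
    sc <- plogis(eta)
    expect_equal(app[c, 1], conditional_auc(sc, d$D, level_contrast(3, 1:2)),
                 tolerance = 1e-12)
    expect_equal(app[c, 2], conditional_auc(sc, d$D, level_contrast(2, 1)),
                 tolerance = 1e-12)
  }
  # strong ordered signal: both AUCs above one half
  expect_true(all(app > 0.5))
})

test_that("identity resampling yields exactly zero bias", {
  d <- make_ordered_data(n = 150, K = 3, p = 4, seed = 54)
  cs <- all_pairs(4)
  fit <- fit_candidates(d, cs)
  bb <- bootstrap_bias(d, cs, fit$coefs, B = 5,
                       resample = function(n) seq_len(n))
  expect_true(all(bb$bias == 0))
  expect_equal(bb$redraws, 0L)
})

test_that("bootstrap optimism is positive when noise markers overfit", {
  set.seed(55)
  mean_bias <- replicate(100, {
    d <- gen_fixture("null", n = 50, p = 10, seed = sample.int(1e6, 1))
    cs <- all_pairs(10)
    fit <- fit_candidates(d, cs)
    bb <- bootstrap_bias(d, cs, fit$coefs, B = 10)
    mean(bb$bias[fit$converged, 1], na.rm = TRUE)
  })
  expect_gt(mean(mean_bias), 0)
})

test_that("bias estimates stabilize as B grows (Monte Carlo SE shrinks)", {
  d <- make_ordered_data(n = 100, K = 3, p = 3, seed = 56)
  cs <- all_pairs(3)
  fit <- fit_candidates(d, cs)
  set.seed(561)
  sd_small <- sd(replicate(24, bootstrap_bias(d, cs, fit$coefs,
                                              B = 5)$bias[1, 1]))
  sd_large <- sd(replicate(24, bootstrap_bias(d, cs, fit$coefs,
                                              B = 45)$bias[1, 1]))
  # SE of the B-mean scales as 1/sqrt(B): expect roughly a 3x reduction
  expect_lt(sd_large, sd_small / 1.5)
})

test_that("selection generalizes to K = 4 with one contrast per level drop", {
  d <- make_ordered_data(n = 250, K = 4, p = 4, seed = 62)
  rep <- select_combination(d, B = 10, seed = 2)
  expect_length(rep$contrasts, 3L)
  expect_equal(rep$contrasts[[2]]$positive, 3L)
  expect_equal(rep$contrasts[[2]]$negative, 1:2)
  expect_equal(ncol(rep$corrected), 3L)
  expect_equal(rep$rank_sum, rowSums(rep$ranks))
  ev <- evaluate_on_test(rep, make_ordered_data(n = 400, K = 4, p = 4,
                                                seed = 63))
  expect_equal(nrow(ev), 2L)
  expect_true(all(ev$test_auc_top > 0.5))
})

test_that("rank_and_select reproduces the hand-enumerated example and its
           tie behavior", {
  corrected <- rbind(c(0.90, 0.60), c(0.88, 0.70), c(0.85, 0.65))
  sel <- rank_and_select(corrected)
  expect_equal(sel$ranks, rbind(c(3, 1), c(2, 3), c(1, 2)))
  expect_equal(sel$rank_sum, c(4, 5, 3))
  expect_equal(sel$chosen_standard, 1L)
  expect_equal(sel$chosen_new, 2L)

  # constant second contrast collapses the new pick onto the standard pick
  corrected2 <- cbind(c(0.7, 0.9, 0.8), 0.5)
  sel2 <- rank_and_select(corrected2)
  expect_equal(sel2$chosen_new, sel2$chosen_standard)
  expect_equal(sel2$chosen_standard, 2L)

  # midranks on ties; non-converged candidates rank 0 and are never picked
  sel3 <- rank_and_select(rbind(c(0.9, 0.5), c(0.8, 0.5), c(0.99, 0.99)),
                          converged = c(TRUE, TRUE, FALSE))
  expect_equal(sel3$ranks[3, ], c(0, 0))
  expect_equal(sel3$ranks[, 2], c(1.5, 1.5, 0))
  expect_equal(sel3$chosen_standard, 1L)
  expect_error(rank_and_select(matrix(0.5, 1, 2), converged = FALSE),
               "no converged")
})

test_that("selection reports are internally consistent and reproducible", {
  d <- make_ordered_data(n = 150, K = 3, p = 5, seed = 57)
  rep1 <- select_combination(d, B = 20, seed = 99)
  rep2 <- select_combination(d, B = 20, seed = 99)
  expect_identical(rep1, rep2)                       # bit reproducibility
  rep3 <- select_combination(d, B = 20, seed = 100)
  expect_false(identical(rep1$bias, rep3$bias))

  # corrected = apparent - bias; standard pick maximizes corrected top AUC
  expect_equal(rep1$corrected, rep1$apparent - rep1$bias, tolerance = 0)
  conv <- rep1$candidates$converged
  expect_equal(rep1$corrected[rep1$chosen_standard, 1],
               max(rep1$corrected[conv, 1]))
  # ranks are a permutation (midranks aside) of 1..n_converged per contrast
  expect_equal(sort(rep1$ranks[conv, 1]), seq_len(sum(conv)))
})

test_that("a candidate dominating all contrasts is chosen by both
           approaches", {
  set.seed(58)
  n <- 400
  D <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  X <- cbind(matrix(rnorm(n * 2) + 2 * (D - 1), n, 2),
             matrix(rnorm(n * 3), n, 3))
  d <- ordinal_data(X, D)
  rep <- select_combination(d, B = 20, seed = 1)
  expect_equal(rep$chosen_standard, 1L)   # pair (1,2) is candidate 1
  expect_equal(rep$chosen_new, 1L)
})

test_that("evaluate_on_test: self-test bias equals the resubstitution
           correction", {
  d <- make_ordered_data(n = 200, K = 3, p = 4, seed = 59)
  rep <- select_combination(d, B = 20, seed = 3)
  ev <- evaluate_on_test(rep, d)
  for (i in 1:2) {
    ci <- ev$candidate[i]
    # test AUC on the training data is the apparent AUC, so the measured
    # bias is apparent - corrected = the bootstrap bias estimate
    expect_equal(ev$model_selection_bias[i],
                 rep$corrected[ci, 1] - rep$apparent[ci, 1],
                 tolerance = 1e-12)
  }
  test_missing <- ordinal_data(d$X[d$D < 3, ], d$D[d$D < 3], K = 3)
  expect_error(evaluate_on_test(rep, test_missing), "top level")
})

test_that("report_table orders candidates by corrected top AUC", {
  d <- make_ordered_data(n = 150, K = 3, p = 4, seed = 61)
  rep <- select_combination(d, B = 10, seed = 5)
  tab <- report_table(rep, top_n = 3)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$corrected_3vs12,
               sort(rep$corrected[, 1], decreasing = TRUE)[1:3])
  f <- tempfile(fileext = ".csv")
  report_table(rep, path = f)
  expect_true(file.exists(f))
  expect_equal(nrow(read.csv(f)), nrow(rep$combos))
})
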
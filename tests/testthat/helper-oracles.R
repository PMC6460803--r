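# Independent oracles used across the suite.

# O(n^2) pair-counting AUC: every case/control pair contributes 1 if the
# case scores higher, 1/2 on a tie.
auc_paircount <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) tot <- tot + sum(a > controls) + 0.5 * sum(a == controls)
  tot / (length(cases) * length(controls))
}

# Derivative-free maximization of the binary logistic log-likelihood,
# independent of glm's IRLS path.
logistic_ml_oracle <- function(X, y) {
  Z <- cbind(1, X)
  negll <- function(b) {
    eta <- drop(Z %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  out <- stats::optim(rep(0, ncol(Z)), negll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  out <- stats::optim(out$par, negll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  out$par
}

# For K = 2 every strategy implies logit P(D = 2 | x) = a + b'x; extract
# (a, b) on that common orientation so fits can be compared directly.
implied_binary_coefs <- function(fit) {
  stopifnot(fit$K == 2L)
  sl <- if (is.matrix(fit$slopes)) fit$slopes[, 1L] else fit$slopes
  sl <- unname(sl)
  a <- unname(fit$intercepts[1L])
  switch(fit$strategy,
    # these model logit P(D = 1 | x) (or P(D <= 1)) = a + b'x
    simple = ,
    sequential = ,
    cum_logit = ,
    contratio_logit = ,
    adjcat_logit = ,
    baseline_cat = c(-a, -sl),
    # stereotype: log P(1)/P(2) = a - b'x
    stereotype = c(-a, sl)
  )
}

# A small conditional-Gaussian dataset with mildly ordered level means.
make_ordered_data <- function(n = 150, K = 3, p = 2, seed = 1) {
  set.seed(seed)
  repeat {
    D <- sample.int(K, n, replace = TRUE)
    if (all(tabulate(D, K) > 0L)) break
  }
  X <- matrix(rnorm(n * p), n, p) + 0.8 * (D - 1)
  ordinal_data(X, D, K = K)
}
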
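# Shared numerical helpers (internal).

# Row-wise log-sum-exp of a matrix of category log-weights.
row_logsumexp <- function(eta) {
  m <- apply(eta, 1L, max)
  m + log(rowSums(exp(eta - m)))
}

# Row-wise softmax.
row_softmax <- function(eta) {
  m <- apply(eta, 1L, max)
  w <- exp(eta - m)
  w / rowSums(w)
}

# Multinomial log-likelihood for an n x K matrix of category log-weights.
multinomial_loglik <- function(eta, D) {
  sum(eta[cbind(seq_along(D), D)]) - sum(row_logsumexp(eta))
}

# Coefficient blow-up used as a separation diagnostic: quasi-complete
# separation drives logistic estimates to +/- infinity.
coef_diverged <- function(coefs, limit = 1e4) {
  any(!is.finite(coefs)) || max(abs(coefs)) > limit
}

# Binary logistic ML fit via IRLS (stats::glm.fit), returning intercept,
# slopes, convergence flag and log-likelihood.
binary_logistic <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial())
  )
  cf <- fit$coefficients
  ok <- isTRUE(fit$converged) && !isTRUE(fit$boundary) && !coef_diverged(cf)
  list(alpha = unname(cf[1L]), beta = unname(cf[-1L]),
       converged = ok, loglik = -fit$deviance / 2)
}
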
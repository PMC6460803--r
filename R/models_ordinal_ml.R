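# Direct maximum-likelihood fitters for the adjacent-category logit and the
# one-dimensional stereotype model. Both are constrained multinomial models
# with category log-weights eta_k(x); probabilities are softmax(eta). Fitting
# is BFGS with analytic gradients followed by Newton polishing (numerical
# Hessian via optimHess), so the gradient sup-norm at the reported optimum is
# driven well below the convergence threshold.

GRAD_TOL <- 1e-6

# Generic maximizer: fn/gr are the NEGATIVE log-likelihood and its gradient.
# Tries each start, keeps the best, Newton-polishes, and deterministically
# jitters the best start on failure (no RNG use).
ml_maximize <- function(starts, fn, gr, restarts = 5L) {
  best <- NULL
  run_one <- function(par) {
    out <- tryCatch(
      stats::optim(par, fn, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(out) || !all(is.finite(out$par))) return(NULL)
    # Newton polish: quadratic convergence near the optimum.
    for (i in 1:20) {
      g <- gr(out$par)
      if (max(abs(g)) < GRAD_TOL / 10) break
      H <- tryCatch(stats::optimHess(out$par, fn, gr), error = function(e) NULL)
      if (is.null(H)) break
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- out$par - step
      fcand <- fn(cand)
      if (!is.finite(fcand) || fcand > out$value + 1e-9) break
      out$par <- cand
      out$value <- fcand
    }
    out$gmax <- max(abs(gr(out$par)))
    out
  }
  for (par in starts) {
    out <- run_one(par)
    if (!is.null(out) && (is.null(best) || out$value < best$value)) best <- out
  }
  if (is.null(best)) return(NULL)
  r <- 0L
  while (best$gmax >= GRAD_TOL && r < restarts) {
    r <- r + 1L
    jit <- 0.3 * sin(seq_along(best$par) * (r + 1) * 1.7)
    out <- run_one(best$par + jit)
    if (!is.null(out) && out$value <= best$value) best <- out
  }
  best$converged <- best$gmax < GRAD_TOL && max(abs(best$par)) < 1e4
  best
}

# --- adjacent-category logit ------------------------------------------------
# log[P(D=k)/P(D=k+1)] = alpha_k + beta' x, common beta. In reference-K form
# the category log-weights are eta_k = A_k + (K - k) * beta' x with A_K = 0
# and A_k = sum_{j>=k} alpha_j.
fit_adjcat_ <- function(data) {
  K <- data$K
  if (K == 2L) {
    b <- binary_logistic(data$X, as.numeric(data$D == 1L))
    return(list(intercepts = b$alpha, slopes = b$beta, phi = NULL,
                converged = b$converged, loglik = b$loglik))
  }
  X <- data$X
  D <- data$D
  n <- data$n
  p <- data$p
  cwt <- K - seq_len(K)                 # per-category multiplier on beta'x
  idxA <- seq_len(K - 1L)
  eta_of <- function(par) {
    u <- drop(X %*% par[-idxA])
    outer(rep(1, n), c(par[idxA], 0)) + outer(u, cwt)
  }
  negll <- function(par) -multinomial_loglik(eta_of(par), D)
  grad <- function(par) {
    P <- row_softmax(eta_of(par))
    Yk <- P
    Yk[cbind(seq_len(n), D)] <- P[cbind(seq_len(n), D)] - 1  # P - indicator
    gA <- colSums(Yk[, idxA, drop = FALSE])
    gb <- drop(crossprod(X, drop(Yk %*% cwt)))
    c(gA, gb)
  }
  freq <- pmax(level_counts(data), 0.5)
  A0 <- log(freq[idxA] / freq[K])
  simple <- binary_logistic(X, as.numeric(D <= K - 1L))
  starts <- list(c(A0, rep(0, p)),
                 c(A0, -simple$beta / (K - 1)))
  best <- ml_maximize(starts, negll, grad)
  if (is.null(best)) {
    return(list(intercepts = rep(NA_real_, K - 1L),
                slopes = rep(NA_real_, p), phi = NULL,
                converged = FALSE, loglik = NA_real_))
  }
  A <- c(best$par[idxA], 0)
  list(intercepts = A[idxA] - A[idxA + 1L],   # adjacent-logit intercepts
       slopes = unname(best$par[-idxA]), phi = NULL,
       converged = best$converged, loglik = -best$value,
       ref_intercepts = A[idxA])
}

# --- one-dimensional stereotype model ---------------------------------------
# Category log-weights eta_k = alpha_k + phi_k * beta' x with alpha_K = 0,
# phi_1 = 0, phi_K = 1; free parameters alpha_1..alpha_{K-1},
# phi_2..phi_{K-1}, beta. No ordering constraint is placed on the phi_k.
# The adjacent-category model is the special case phi_k = (k-1)/(K-1)
# (after rescaling beta), so one start maps the fitted adjacent-category
# solution into this parameterization; the optimizer can then only improve
# on its likelihood.
fit_stereotype_ <- function(data) {
  K <- data$K
  if (K == 2L) {
    # eta_1 = alpha_1, eta_2 = beta'x: binary logistic on I(D == 1) with
    # slope -beta.
    b <- binary_logistic(data$X, as.numeric(data$D == 1L))
    return(list(intercepts = b$alpha, slopes = -b$beta, phi = c(0, 1),
                converged = b$converged, loglik = b$loglik))
  }
  X <- data$X
  D <- data$D
  n <- data$n
  p <- data$p
  nA <- K - 1L
  nF <- K - 2L
  idxA <- seq_len(nA)
  idxF <- if (nF > 0L) nA + seq_len(nF) else integer(0)
  idxB <- nA + nF + seq_len(p)
  phi_of <- function(par) c(0, par[idxF], 1)
  eta_of <- function(par) {
    u <- drop(X %*% par[idxB])
    outer(rep(1, n), c(par[idxA], 0)) + outer(u, phi_of(par))
  }
  negll <- function(par) -multinomial_loglik(eta_of(par), D)
  grad <- function(par) {
    phi <- phi_of(par)
    u <- drop(X %*% par[idxB])
    eta <- outer(rep(1, n), c(par[idxA], 0)) + outer(u, phi)
    P <- row_softmax(eta)
    Yk <- P
    Yk[cbind(seq_len(n), D)] <- P[cbind(seq_len(n), D)] - 1  # P - indicator
    gA <- colSums(Yk[, idxA, drop = FALSE])
    gF <- if (nF > 0L) colSums(u * Yk[, 1L + seq_len(nF), drop = FALSE])
          else numeric(0)
    gb <- drop(crossprod(X, drop(Yk %*% phi)))
    c(gA, gF, gb)
  }
  freq <- pmax(level_counts(data), 0.5)
  alpha0 <- log(freq[idxA] / freq[K])
  phi_lin <- (seq_len(K) - 1) / (K - 1)
  simple <- binary_logistic(X, as.numeric(D <= K - 1L))
  starts <- list(c(alpha0, phi_lin[1L + seq_len(nF)], -simple$beta))
  adj <- fit_adjcat_(data)
  if (!is.null(adj$ref_intercepts) && all(is.finite(adj$ref_intercepts))) {
    starts <- c(starts, list(c(adj$ref_intercepts,
                               phi_lin[1L + seq_len(nF)],
                               -(K - 1) * adj$slopes)))
  }
  best <- ml_maximize(starts, negll, grad)
  if (is.null(best)) {
    return(list(intercepts = rep(NA_real_, nA), slopes = rep(NA_real_, p),
                phi = rep(NA_real_, K), converged = FALSE,
                loglik = NA_real_))
  }
  list(intercepts = unname(best$par[idxA]),
       slopes = unname(best$par[idxB]),
       phi = phi_of(best$par),
       converged = best$converged, loglik = -best$value)
}
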
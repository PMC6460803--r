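#' Fit a biomarker-combination strategy to an ordinal dataset
#'
#' Fits one of seven regression strategies for combining biomarkers when the
#' outcome is ordinal with \code{K} levels and interest lies in predicting the
#' top level \code{D = K}:
#' \describe{
#'   \item{\code{"simple"}}{one binary logistic model after dichotomizing the
#'     outcome at \code{K - 1}: \eqn{logit P(D \le K-1 | x) = \alpha +
#'     \beta'x}.}
#'   \item{\code{"sequential"}}{\code{K - 1} binary logistic models, model
#'     \code{k} fit to the subset \code{D >= k} with outcome indicator
#'     \code{D == k}; each has its own slope vector.}
#'   \item{\code{"cum_logit"}}{the proportional-odds cumulative logit model
#'     \eqn{logit P(D \le k | x) = \alpha_k + \beta'x} with a common slope and
#'     ordered intercepts.}
#'   \item{\code{"adjcat_logit"}}{the adjacent-category logit model
#'     \eqn{log[P(D=k)/P(D=k+1)] = \alpha_k + \beta'x} with a common slope.}
#'   \item{\code{"contratio_logit"}}{the continuation-ratio logit model
#'     \eqn{logit P(D = k | D \ge k, x) = \alpha_k + \beta'x} with a common
#'     slope.}
#'   \item{\code{"stereotype"}}{the one-dimensional stereotype model with
#'     level-specific slopes restricted to \eqn{\beta_k = \phi_k \beta},
#'     \eqn{\phi_1 = 0}, \eqn{\phi_K = 1} and no a-priori ordering of the
#'     remaining \eqn{\phi_k}.}
#'   \item{\code{"baseline_cat"}}{the baseline-category (multinomial) logit
#'     model with reference level \code{K} and a free slope vector per level.}
#' }
#' All strategies share the scoring contract of \code{\link{predict_risk}}:
#' the fitted object produces the predicted probability of \code{D = K}.
#'
#' @param data an \code{\link{ordinal_data}} object; every level \code{1..K}
#'   must be present.
#' @param strategy one of the strategy names above.
#' @return An object of class \code{"combo_fit"} with elements
#'   \code{strategy}, \code{intercepts}, \code{slopes} (a vector for
#'   common-slope strategies, a \code{p x (K-1)} matrix for
#'   \code{sequential}/\code{baseline_cat}), \code{phi} (stereotype only),
#'   \code{converged}, \code{loglik}, \code{K}, \code{p},
#'   \code{marker_names}.
#' @examples
#' d <- gen_fixture("ordered", n = 200, seed = 1)
#' fit <- fit_combination(d, "cum_logit")
#' head(predict_risk(fit, d$X))
#' @seealso \code{\link{predict_risk}}, \code{\link{category_probs}}
#' @export
fit_combination <- function(data,
                            strategy = c("simple", "sequential", "cum_logit",
                                         "adjcat_logit", "contratio_logit",
                                         "stereotype", "baseline_cat")) {
  stopifnot(inherits(data, "ordinal_data"))
  strategy <- match.arg(strategy)
  if (!has_all_levels(data)) {
    stop("every outcome level 1..K must appear in the training data")
  }
  fit <- switch(strategy,
    simple          = fit_simple_(data),
    sequential      = fit_sequential_(data),
    cum_logit       = fit_cum_logit_(data),
    adjcat_logit    = fit_adjcat_(data),
    contratio_logit = fit_contratio_(data),
    stereotype      = fit_stereotype_(data),
    baseline_cat    = fit_baseline_cat_(data)
  )
  fit$strategy <- strategy
  fit$K <- data$K
  fit$p <- data$p
  fit$marker_names <- data$marker_names
  class(fit) <- "combo_fit"
  fit
}

#' Names of the seven combination-construction strategies
#' @return character vector of strategy identifiers accepted by
#'   \code{\link{fit_combination}}.
#' @export
combo_strategies <- function() {
  c("simple", "sequential", "cum_logit", "adjcat_logit", "contratio_logit",
    "stereotype", "baseline_cat")
}

#' @export
print.combo_fit <- function(x, ...) {
  cat(sprintf("<combo_fit> strategy = %s, K = %d, p = %d, converged = %s\n",
              x$strategy, x$K, x$p, x$converged))
  cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

# (i) Simple: binary logistic on the indicator D <= K-1.
fit_simple_ <- function(data) {
  y <- as.numeric(data$D <= data$K - 1L)
  if (all(y == 0) || all(y == 1)) {
    stop("dichotomized outcome is constant: need both D = K and D < K")
  }
  b <- binary_logistic(data$X, y)
  list(intercepts = b$alpha, slopes = b$beta, phi = NULL,
       converged = b$converged, loglik = b$loglik)
}

# (iv) Sequential: K-1 binary logistic models on nested subsets D >= k,
# each comparing level k to the pooled levels above it.
fit_sequential_ <- function(data) {
  K <- data$K
  alphas <- numeric(K - 1L)
  slopes <- matrix(NA_real_, data$p, K - 1L,
                   dimnames = list(data$marker_names, NULL))
  ok <- TRUE
  ll <- 0
  for (k in seq_len(K - 1L)) {
    sub <- data$D >= k
    y <- as.numeric(data$D[sub] == k)
    if (all(y == 0) || all(y == 1)) {
      stop(sprintf("subset D >= %d lacks one of the compared groups", k))
    }
    b <- binary_logistic(data$X[sub, , drop = FALSE], y)
    alphas[k] <- b$alpha
    slopes[, k] <- b$beta
    ok <- ok && b$converged
    ll <- ll + b$loglik
  }
  list(intercepts = alphas, slopes = slopes, phi = NULL,
       converged = ok, loglik = ll)
}

# Cumulative (proportional-odds) logit, parameterized as
# logit P(D <= k | x) = alpha_k + beta' x. MASS::polr fits
# zeta_k - eta' x, so alpha_k = zeta_k and beta = -eta.
fit_cum_logit_ <- function(data) {
  if (data$K == 2L) return(fit_collapsed_binary_(data))
  df <- data.frame(.D = factor(data$D, levels = seq_len(data$K),
                               ordered = TRUE),
                   data$X, check.names = FALSE)
  fit <- tryCatch(
    suppressWarnings(MASS::polr(.D ~ ., data = df, method = "logistic",
                                Hess = FALSE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(intercepts = rep(NA_real_, data$K - 1L),
                slopes = rep(NA_real_, data$p), phi = NULL,
                converged = FALSE, loglik = NA_real_))
  }
  alpha <- unname(fit$zeta)
  beta <- -unname(stats::coef(fit))
  ok <- isTRUE(fit$convergence == 0) && !coef_diverged(c(alpha, beta))
  list(intercepts = alpha, slopes = beta, phi = NULL,
       converged = ok, loglik = as.numeric(stats::logLik(fit)))
}

# For K = 2, cumulative logit is exactly binary logistic on I(D <= 1).
fit_collapsed_binary_ <- function(data) {
  y <- as.numeric(data$D <= 1L)
  b <- binary_logistic(data$X, y)
  list(intercepts = b$alpha, slopes = b$beta, phi = NULL,
       converged = b$converged, loglik = b$loglik)
}

# Continuation-ratio logit with a common slope, fit as one binary GLM on the
# expanded conditional-Bernoulli representation: each subject with D = d
# contributes records for k = 1..min(d, K-1) restricted to D >= k, outcome
# I(D == k), with level-specific intercepts and shared marker effects. The
# binomial log-likelihood of the expanded fit equals the ordinal model's.
fit_contratio_ <- function(data) {
  K <- data$K
  if (K == 2L) return(fit_collapsed_binary_(data))
  rows <- NULL
  ks <- NULL
  y <- NULL
  for (k in seq_len(K - 1L)) {
    sub <- which(data$D >= k)
    rows <- c(rows, sub)
    ks <- c(ks, rep.int(k, length(sub)))
    y <- c(y, as.numeric(data$D[sub] == k))
  }
  Z <- cbind(stats::model.matrix(~ 0 + factor(ks, levels = seq_len(K - 1L))),
             data$X[rows, , drop = FALSE])
  fit <- suppressWarnings(stats::glm.fit(Z, y, family = stats::binomial()))
  cf <- unname(fit$coefficients)
  ok <- isTRUE(fit$converged) && !coef_diverged(cf)
  list(intercepts = cf[seq_len(K - 1L)], slopes = cf[-seq_len(K - 1L)],
       phi = NULL, converged = ok, loglik = -fit$deviance / 2)
}

# Baseline-category (multinomial) logit with reference level K, via
# nnet::multinom (which uses level 1 as its reference; coefficients are
# re-expressed relative to level K).
fit_baseline_cat_ <- function(data) {
  K <- data$K
  if (K == 2L) {
    # log P(D=1)/P(D=2) = alpha_1 + beta_1' x: binary logistic on I(D == 1).
    b <- binary_logistic(data$X, as.numeric(data$D == 1L))
    return(list(intercepts = b$alpha,
                slopes = matrix(b$beta, data$p, 1L,
                                dimnames = list(data$marker_names, NULL)),
                phi = NULL, converged = b$converged, loglik = b$loglik))
  }
  df <- data.frame(.D = factor(data$D, levels = seq_len(K)),
                   data$X, check.names = FALSE)
  fit <- tryCatch(
    nnet::multinom(.D ~ ., data = df, trace = FALSE,
                   maxit = 1000, reltol = 1e-13),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(intercepts = rep(NA_real_, K - 1L),
                slopes = matrix(NA_real_, data$p, K - 1L),
                phi = NULL, converged = FALSE, loglik = NA_real_))
  }
  # nnet rows: levels 2..K relative to level 1; columns: intercept, markers.
  cf <- stats::coef(fit)
  cf1 <- rbind(0, unname(cf))                      # K x (p+1), level-1 row 0
  rel <- cf1 - matrix(cf1[K, ], K, ncol(cf1), byrow = TRUE)  # vs level K
  ok <- isTRUE(fit$convergence == 0) && !coef_diverged(rel)
  list(intercepts = rel[seq_len(K - 1L), 1L],
       slopes = matrix(t(rel[seq_len(K - 1L), -1L, drop = FALSE]),
                       data$p, K - 1L,
                       dimnames = list(data$marker_names, NULL)),
       phi = NULL, converged = ok,
       loglik = -fit$deviance / 2)
}
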
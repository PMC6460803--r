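# Synthetic ordinal-outcome biomarker generators. Two families are
# supported:
#   * conditional_gaussian -- draw D from fixed prevalences, then markers
#     X | D = k from a level-specific multivariate normal;
#   * cumulative_logit -- draw Gaussian markers, then D from the
#     proportional-odds mechanism logit P(D <= k | x) = alpha_k - beta'x.
# Both refuse to emit a dataset missing an outcome level: the whole dataset
# is redrawn (keeping draws i.i.d. conditional on validity) and the redraw
# count is attached as attribute "redraws".

#' Scenario configuration for a data-generating mechanism
#'
#' @param family \code{"conditional_gaussian"} or \code{"cumulative_logit"}.
#' @param K number of outcome levels.
#' @param prevalences length-K level probabilities (strictly positive,
#'   summing to 1).
#' @param level_means K x p matrix of marker means per level
#'   (conditional-Gaussian family).
#' @param covariance p x p marker covariance matrix (both families).
#' @param slopes length-p slope vector beta (cumulative-logit family).
#' @param marker_mean length-p marker mean vector (cumulative-logit family).
#' @param marker_names optional labels.
#' @return an object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(family = c("conditional_gaussian",
                                       "cumulative_logit"),
                            K, prevalences, level_means = NULL,
                            covariance, slopes = NULL, marker_mean = NULL,
                            marker_names = NULL) {
  family <- match.arg(family)
  K <- as.integer(K)
  prevalences <- as.numeric(prevalences)
  if (length(prevalences) != K || any(prevalences <= 0) ||
      abs(sum(prevalences) - 1) > 1e-8) {
    stop("prevalences must be K strictly positive probabilities summing to 1")
  }
  covariance <- as.matrix(covariance)
  if (!isSymmetric(unname(covariance)) ||
      any(eigen(covariance, symmetric = TRUE,
                only.values = TRUE)$values <= 0)) {
    stop("covariance must be symmetric positive-definite")
  }
  p <- ncol(covariance)
  if (family == "conditional_gaussian") {
    level_means <- as.matrix(level_means)
    if (nrow(level_means) != K || ncol(level_means) != p) {
      stop("level_means must be a K x p matrix")
    }
  } else {
    if (length(slopes) != p) stop("slopes must have length p")
    if (is.null(marker_mean)) marker_mean <- rep(0, p)
    if (length(marker_mean) != p) stop("marker_mean must have length p")
  }
  if (is.null(marker_names)) marker_names <- paste0("X", seq_len(p))
  structure(list(family = family, K = K, prevalences = prevalences,
                 level_means = level_means, covariance = covariance,
                 slopes = if (is.null(slopes)) NULL else as.numeric(slopes),
                 marker_mean = if (is.null(marker_mean)) NULL
                               else as.numeric(marker_mean),
                 p = p, marker_names = marker_names),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> family = %s, K = %d, p = %d\n",
              x$family, x$K, x$p))
  cat("prevalences:", paste(signif(x$prevalences, 4), collapse = ", "), "\n")
  invisible(x)
}

# Multivariate normal draws via Cholesky (deterministic given the RNG state).
rmvn <- function(n, mean, Sigma) {
  p <- length(mean)
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% chol(Sigma), 2L, mean, `+`)
}

#' Generate data from a conditional-Gaussian scenario
#'
#' Draws \code{D} multinomially with the configured prevalences, then
#' \code{X | D = k} from N(level_means[k, ], covariance).
#'
#' @param cfg a \code{\link{scenario_config}} with family
#'   \code{"conditional_gaussian"}.
#' @param n number of observations.
#' @param require_all_levels redraw the whole dataset until every level
#'   appears (default TRUE; the redraw count is attached as attribute
#'   \code{"redraws"}).
#' @return an \code{\link{ordinal_data}} object.
#' @export
gen_conditional_gaussian <- function(cfg, n, require_all_levels = TRUE) {
  stopifnot(inherits(cfg, "scenario_config"),
            cfg$family == "conditional_gaussian")
  redraws <- 0L
  repeat {
    D <- sample.int(cfg$K, n, replace = TRUE, prob = cfg$prevalences)
    if (!require_all_levels || all(tabulate(D, cfg$K) > 0L)) break
    redraws <- redraws + 1L
    if (redraws > 10000L) stop("could not draw a dataset with all levels")
  }
  X <- matrix(0, n, cfg$p)
  R <- chol(cfg$covariance)
  Z <- matrix(stats::rnorm(n * cfg$p), n, cfg$p)
  X <- Z %*% R + cfg$level_means[D, , drop = FALSE]
  out <- ordinal_data(X, D, K = cfg$K, marker_names = cfg$marker_names)
  attr(out, "redraws") <- redraws
  out
}

#' Calibrate cumulative-logit generator intercepts to target prevalences
#'
#' Under the generator \eqn{logit P(D \le k | x) = \alpha_k - \beta'x}, the
#' marginal prevalences depend on the distribution of \eqn{\eta = \beta'x}.
#' For each k this solves (by monotone bisection) for the \eqn{\alpha_k}
#' whose mean of \eqn{expit(\alpha_k - \eta)} over a large calibration sample
#' equals the target cumulative prevalence. Since the markers are Gaussian,
#' \eqn{\eta} is drawn directly from its exact normal law
#' N(\code{marker_mean}'beta, beta' covariance beta), which is equivalent to
#' (and far cheaper than) materialising the marker matrix.
#'
#' @param cfg a \code{\link{scenario_config}} with family
#'   \code{"cumulative_logit"}.
#' @param calibration_n calibration sample size (default \code{1e6}).
#' @return an object of class \code{"calibrated_intercepts"}: list with
#'   \code{alphas} (strictly increasing, length K-1),
#'   \code{achieved_prevalences} and \code{calibration_n}.
#' @export
calibrate_intercepts <- function(cfg, calibration_n = 1e6) {
  stopifnot(inherits(cfg, "scenario_config"),
            cfg$family == "cumulative_logit")
  cum <- cumsum(cfg$prevalences)[seq_len(cfg$K - 1L)]
  if (any(diff(c(0, cum)) <= 0) || any(cum >= 1)) {
    stop("target cumulative probabilities must be strictly increasing in (0,1)")
  }
  m <- sum(cfg$marker_mean * cfg$slopes)
  s2 <- drop(crossprod(cfg$slopes, cfg$covariance %*% cfg$slopes))
  eta <- if (s2 > 0) stats::rnorm(calibration_n, m, sqrt(s2))
         else rep(m, calibration_n)
  alphas <- vapply(cum, function(target) {
    f <- function(a) mean(stats::plogis(a - eta)) - target
    lo <- m - 50; hi <- m + 50
    while (f(lo) > 0) lo <- lo - 50
    while (f(hi) < 0) hi <- hi + 50
    for (i in 1:200) {            # bisection: f is monotone increasing in a
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-10) break
    }
    (lo + hi) / 2
  }, numeric(1))
  achieved <- vapply(alphas, function(a) mean(stats::plogis(a - eta)),
                     numeric(1))
  structure(list(alphas = alphas,
                 achieved_prevalences = diff(c(0, achieved, 1)),
                 calibration_n = calibration_n),
            class = "calibrated_intercepts")
}

#' Generate data from a cumulative-logit (proportional-odds) scenario
#'
#' Draws markers from the configured Gaussian, computes
#' \eqn{P(D \le k | x) = expit(\alpha_k - \beta'x)}, and draws the level of
#' each observation from the implied category probabilities.
#'
#' @param cfg a \code{\link{scenario_config}} with family
#'   \code{"cumulative_logit"}.
#' @param n number of observations.
#' @param intercepts a \code{\link{calibrate_intercepts}} result (or a
#'   numeric vector of K-1 increasing alphas). If missing, calibration is
#'   run first.
#' @param require_all_levels redraw until every level appears (default TRUE).
#' @return an \code{\link{ordinal_data}} object.
#' @export
gen_cumulative_logit <- function(cfg, n, intercepts = NULL,
                                 require_all_levels = TRUE) {
  stopifnot(inherits(cfg, "scenario_config"),
            cfg$family == "cumulative_logit")
  if (is.null(intercepts)) intercepts <- calibrate_intercepts(cfg)
  alphas <- if (inherits(intercepts, "calibrated_intercepts")) {
    intercepts$alphas
  } else as.numeric(intercepts)
  if (length(alphas) != cfg$K - 1L || any(diff(alphas) <= 0)) {
    stop("intercepts must be K-1 strictly increasing values")
  }
  redraws <- 0L
  repeat {
    X <- rmvn(n, cfg$marker_mean, cfg$covariance)
    eta <- drop(X %*% cfg$slopes)
    cum <- stats::plogis(outer(-eta, alphas, `+`))      # P(D <= k | x)
    D <- 1L + rowSums(stats::runif(n) > cum)
    if (!require_all_levels || all(tabulate(D, cfg$K) > 0L)) break
    redraws <- redraws + 1L
    if (redraws > 10000L) stop("could not draw a dataset with all levels")
  }
  out <- ordinal_data(X, D, K = cfg$K, marker_names = cfg$marker_names)
  attr(out, "redraws") <- redraws
  out
}

#' Per-row category probabilities of a cumulative-logit scenario
#'
#' @inheritParams gen_cumulative_logit
#' @param X marker matrix.
#' @param alphas numeric vector of K-1 increasing intercepts.
#' @return n x K matrix of probabilities (rows sum to 1).
#' @export
cumlogit_level_probs <- function(cfg, X, alphas) {
  eta <- drop(X %*% cfg$slopes)
  cum <- stats::plogis(outer(-eta, alphas, `+`))
  cbind(cum[, 1L],
        if (cfg$K > 2L) cum[, -1L, drop = FALSE] -
          cum[, -(cfg$K - 1L), drop = FALSE],
        1 - cum[, cfg$K - 1L])
}

#' Generate data for a scenario (either family)
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @param n number of observations.
#' @param intercepts optional calibrated intercepts (cumulative-logit only).
#' @param require_all_levels redraw until every level appears.
#' @return an \code{\link{ordinal_data}} object.
#' @export
gen_scenario <- function(cfg, n, intercepts = NULL,
                         require_all_levels = TRUE) {
  if (cfg$family == "conditional_gaussian") {
    gen_conditional_gaussian(cfg, n, require_all_levels)
  } else {
    gen_cumulative_logit(cfg, n, intercepts, require_all_levels)
  }
}
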
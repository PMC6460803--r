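# Shipped scenario presets: the construction-study grid (conditional-Gaussian
# and proportional-odds families) and the five selection examples.

# Compound-symmetric correlation matrix: 1 on the diagonal, rho off it.
compound_symmetric <- function(p, rho = 0.3) {
  G <- matrix(rho, p, p)
  diag(G) <- 1
  G
}

#' Construction-study scenario (conditional-Gaussian family)
#'
#' Two biomarkers whose conditional distributions are bivariate normal with
#' covariance \code{2 I2} and level means (for K = 3) \code{0, mu, 2} and
#' (for K = 5) \code{0, 0.5, 1, mu, 2} in both coordinates. \code{mu}
#' controls whether the level means are ordered by the outcome; the
#' proportional-odds assumption does not hold in this family.
#'
#' @param K 3 or 5.
#' @param mu scalar mean (applied to both markers) of level 2 (K = 3) or
#'   level 4 (K = 5).
#' @param p1 prevalence of level 1.
#' @param pK prevalence of the top level; the remaining mass is split over
#'   the middle levels (equally, for K = 5).
#' @return a \code{\link{scenario_config}}.
#' @export
construction_scenario <- function(K = 3, mu = 1, p1 = 0.1, pK = 0.05) {
  K <- as.integer(K)
  stopifnot(K %in% c(3L, 5L))
  if (K == 3L) {
    means <- rbind(0, mu, 2)
    prev <- c(p1, 1 - p1 - pK, pK)
  } else {
    means <- rbind(0, 0.5, 1, mu, 2)
    prev <- c(p1, rep((1 - p1 - pK) / 3, 3), pK)
  }
  scenario_config("conditional_gaussian", K = K, prevalences = prev,
                  level_means = cbind(means, means),
                  covariance = 2 * diag(2))
}

#' Construction-study scenario (proportional-odds family)
#'
#' Two independent normal biomarkers, both with mean 1 and variance 0.25;
#' the outcome follows the cumulative-logit mechanism
#' \eqn{logit P(D \le k | x) = \alpha_k - \beta'x} with intercepts
#' calibrated to the target prevalences.
#'
#' @param K 3 or 5.
#' @param beta length-2 slope vector; shipped choices are \code{c(1, 2)},
#'   \code{c(1, 1.5)} and \code{c(-1, 1)}.
#' @inheritParams construction_scenario
#' @return a \code{\link{scenario_config}}.
#' @export
construction_po_scenario <- function(K = 3, beta = c(1, 2), p1 = 0.1,
                                     pK = 0.05) {
  K <- as.integer(K)
  stopifnot(K %in% c(3L, 5L), length(beta) == 2L)
  prev <- if (K == 3L) c(p1, 1 - p1 - pK, pK)
          else c(p1, rep((1 - p1 - pK) / 3, 3), pK)
  scenario_config("cumulative_logit", K = K, prevalences = prev,
                  covariance = 0.25 * diag(2), slopes = beta,
                  marker_mean = c(1, 1))
}

#' Configuration of a selection example (1-5)
#'
#' Thirty moderately correlated biomarkers (compound-symmetric correlation
#' 0.3, variance scale 2), K = 3. Examples 1-2 use the cumulative-logit
#' mechanism with slopes \code{(1, 2, 0.5 x14, 0.1 x14)} and differ in
#' prevalence of the upper levels; Examples 3-5 are conditional-Gaussian
#' with level-2/level-3 mean vectors that make markers 1-2 the strongest
#' pair throughout.
#'
#' @param example integer 1..5.
#' @return a \code{\link{scenario_config}}.
#' @export
selection_example_config <- function(example) {
  example <- as.integer(example)
  stopifnot(example %in% 1:5)
  p <- 30L
  Sigma <- 2 * compound_symmetric(p, 0.3)
  if (example %in% 1:2) {
    beta <- c(1, 2, rep(0.5, 14), rep(0.1, 14))
    prev <- if (example == 1L) c(0.6, 0.3, 0.1) else c(0.6, 0.335, 0.065)
    return(scenario_config("cumulative_logit", K = 3, prevalences = prev,
                           covariance = Sigma, slopes = beta,
                           marker_mean = rep(1, p)))
  }
  b2 <- switch(example - 2L,
    c(1.5, 1, rep(0.5, 14), rep(0.1, 14)),          # Example 3
    c(1,   1, rep(0.5, 14), rep(0.1, 14)),          # Example 4
    c(1,   1, rep(0.5, 14), rep(0,   14)))          # Example 5
  b3 <- switch(example - 2L,
    c(2, 2, rep(0.8, 14), rep(0.1, 14)),            # Example 3
    c(2, 2, rep(0.8, 14), rep(0.2, 14)),            # Example 4
    c(2, 2, rep(0.8, 14), rep(0.2, 14)))            # Example 5
  scenario_config("conditional_gaussian", K = 3,
                  prevalences = c(0.6, 0.335, 0.065),
                  level_means = rbind(rep(0, p), b2, b3),
                  covariance = Sigma)
}

# Calibrated generator intercepts for Examples 1-2, computed once per session
# under a fixed internal calibration seed (part of the generator definition,
# so the result does not depend on, or disturb, the caller's RNG stream).
preset_env <- new.env(parent = emptyenv())

example_alphas <- function(example) {
  key <- paste0("alphas_ex", example)
  if (!is.null(preset_env[[key]])) return(preset_env[[key]])
  cfg <- selection_example_config(example)
  cal <- with_preserved_rng(20180521L,
                            calibrate_intercepts(cfg, calibration_n = 1e6))
  preset_env[[key]] <- cal$alphas
  cal$alphas
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate data for a selection example
#'
#' Dispatches to the cumulative-logit generator (Examples 1-2, with shipped
#' calibrated intercepts) or the conditional-Gaussian generator (Examples
#' 3-5).
#'
#' @param example integer 1..5.
#' @param n number of observations.
#' @param seed optional seed set before drawing.
#' @param require_all_levels redraw until every level appears (default TRUE).
#' @return an \code{\link{ordinal_data}} object.
#' @export
gen_selection_example <- function(example, n, seed = NULL,
                                  require_all_levels = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- selection_example_config(example)
  if (cfg$family == "cumulative_logit") {
    gen_cumulative_logit(cfg, n, intercepts = example_alphas(example),
                         require_all_levels = require_all_levels)
  } else {
    gen_conditional_gaussian(cfg, n, require_all_levels)
  }
}

#' Small deterministic datasets for tests and demonstrations
#'
#' @param type one of:
#'   \describe{
#'     \item{\code{"null"}}{markers independent of the outcome;}
#'     \item{\code{"ordered"}}{level means increasing with the outcome
#'       (a well-ordered conditional-Gaussian signal);}
#'     \item{\code{"separated"}}{marker 1 perfectly separates the top level
#'       from the rest;}
#'     \item{\code{"ties"}}{markers rounded to a coarse integer grid, so
#'       scores are tie-heavy;}
#'     \item{\code{"aki_like"}}{emulates the shape of a post-surgery kidney
#'       injury cohort: exactly 465 observations with 374/61/30 at levels
#'       1/2/3 and 14 markers.}
#'   }
#' @param n observations (ignored for \code{"aki_like"}).
#' @param p markers (ignored for \code{"aki_like"}).
#' @param seed RNG seed (set before drawing).
#' @param K outcome levels for the generic types (default 3).
#' @return an \code{\link{ordinal_data}} object.
#' @export
gen_fixture <- function(type = c("null", "ordered", "separated", "ties",
                                 "aki_like"),
                        n = 100, p = 2, seed = 1, K = 3) {
  type <- match.arg(type)
  set.seed(seed)
  K <- as.integer(K)
  if (type == "aki_like") {
    n <- 465L
    p <- 14L
    D <- sample(rep.int(1:3, c(374L, 61L, 30L)))
    shift <- c(0, 0.4, 0.9)[D]
    X <- matrix(stats::rnorm(n * p), n, p) + shift
    return(ordinal_data(X, D, K = 3L))
  }
  repeat {
    D <- sample.int(K, n, replace = TRUE)
    if (all(tabulate(D, K) > 0L)) break
  }
  X <- matrix(stats::rnorm(n * p), n, p)
  if (type == "ordered") X <- X + (D - 1)
  if (type == "separated") X[, 1L] <- X[, 1L] + 100 * (D == K)
  if (type == "ties") X <- round(X)
  ordinal_data(X, D, K = K)
}

#' Named scenario presets
#'
#' The shipped data-generating presets are kept in a JSON registry
#' (\code{inst/extdata/scenarios.json}), keyed by short names such as
#' \code{"example1"} or \code{"np_K3_mu2"}; each entry names a constructor
#' and its arguments and resolves to a \code{\link{scenario_config}}.
#'
#' @param name optional preset name; if omitted, the available names are
#'   returned.
#' @return a \code{scenario_config}, or a character vector of names.
#' @export
preset_scenario <- function(name = NULL) {
  reg <- scenario_registry()
  if (is.null(name)) return(names(reg))
  entry <- reg[[name]]
  if (is.null(entry)) stop("unknown preset: ", name)
  args <- lapply(entry$args, function(a) if (is.list(a)) unlist(a) else a)
  do.call(entry$constructor, args)
}

#' @rdname preset_scenario
#' @export
scenario_registry <- function() {
  path <- system.file("extdata", "scenarios.json", package = "ordcombo")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
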
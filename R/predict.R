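#' Risk score for the top outcome level
#'
#' Applies a fitted combination to new biomarker data and returns the
#' predicted probability of the top outcome level, \eqn{\hat P(D = K | x)},
#' for every row. This is the single scoring contract shared by all seven
#' strategies; for common-slope strategies the score is a fixed monotone
#' transformation of \eqn{\hat\beta' x}, with the orientation determined by
#' the fitted model itself (never by post-hoc flipping of an AUC below 0.5).
#'
#' @param fit a \code{combo_fit} from \code{\link{fit_combination}}.
#' @param X numeric matrix of biomarker values with \code{fit$p} columns
#'   (or an \code{\link{ordinal_data}} object, whose \code{X} is used).
#' @return numeric vector of scores in \code{[0, 1]}, one per row of
#'   \code{X}.
#' @export
predict_risk <- function(fit, X) {
  stopifnot(inherits(fit, "combo_fit"))
  if (inherits(X, "ordinal_data")) X <- X$X
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = fit$p)
  if (ncol(X) != fit$p) {
    stop(sprintf("X has %d columns but the fit expects %d", ncol(X), fit$p))
  }
  K <- fit$K
  a <- fit$intercepts
  switch(fit$strategy,
    simple = 1 - stats::plogis(a + drop(X %*% fit$slopes)),
    cum_logit = {
      if (K == 2L) 1 - stats::plogis(a + drop(X %*% fit$slopes))
      else 1 - stats::plogis(a[K - 1L] + drop(X %*% fit$slopes))
    },
    sequential = {
      if (K == 2L) return(1 - stats::plogis(a + drop(X %*% fit$slopes)))
      risk <- rep(1, nrow(X))
      for (k in seq_len(K - 1L)) {
        risk <- risk * (1 - stats::plogis(a[k] + drop(X %*% fit$slopes[, k])))
      }
      risk
    },
    contratio_logit = {
      if (K == 2L) return(1 - stats::plogis(a + drop(X %*% fit$slopes)))
      eta <- drop(X %*% fit$slopes)
      risk <- rep(1, nrow(X))
      for (k in seq_len(K - 1L)) risk <- risk * (1 - stats::plogis(a[k] + eta))
      risk
    },
    adjcat_logit = ,
    stereotype = ,
    baseline_cat = category_probs(fit, X)[, K]
  )
}

#' Fitted category probabilities
#'
#' Returns the full fitted outcome distribution \eqn{\hat P(D = k | x)} for
#' each row of \code{X}. For the full-likelihood models this is the softmax
#' of the category log-weights; for the conditional/cumulative strategies the
#' probabilities are assembled by telescoping or differencing. The
#' dichotomized \code{simple} strategy identifies only the top level, so its
#' remainder \eqn{1 - \hat P(D = K | x)} is placed on level 1 and the middle
#' columns are \code{NA}.
#'
#' @inheritParams predict_risk
#' @return numeric matrix with \code{nrow(X)} rows and \code{K} columns; rows
#'   sum to 1 for every strategy except \code{simple}.
#' @export
category_probs <- function(fit, X) {
  stopifnot(inherits(fit, "combo_fit"))
  if (inherits(X, "ordinal_data")) X <- X$X
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = fit$p)
  if (ncol(X) != fit$p) stop("column count does not match the fit")
  K <- fit$K
  n <- nrow(X)
  a <- fit$intercepts
  if (K == 2L) {
    top <- predict_risk(fit, X)
    return(cbind(1 - top, top))
  }
  switch(fit$strategy,
    simple = {
      top <- predict_risk(fit, X)
      out <- matrix(NA_real_, n, K)
      out[, 1L] <- 1 - top
      out[, K] <- top
      out
    },
    cum_logit = {
      cum <- stats::plogis(outer(drop(X %*% fit$slopes), a, `+`))
      cbind(cum[, 1L], cum[, -1L, drop = FALSE] -
              cum[, -(K - 1L), drop = FALSE], 1 - cum[, K - 1L])
    },
    sequential = ,
    contratio_logit = {
      cond <- sapply(seq_len(K - 1L), function(k) {
        b <- if (is.matrix(fit$slopes)) fit$slopes[, k] else fit$slopes
        stats::plogis(a[k] + drop(X %*% b))
      })
      cond <- matrix(cond, n, K - 1L)
      out <- matrix(0, n, K)
      surv <- rep(1, n)
      for (k in seq_len(K - 1L)) {
        out[, k] <- surv * cond[, k]
        surv <- surv * (1 - cond[, k])
      }
      out[, K] <- surv
      out
    },
    adjcat_logit = {
      A <- rev(cumsum(rev(a)))                   # reference-K intercepts
      eta <- cbind(outer(rep(1, n), c(A, 0)) +
                     outer(drop(X %*% fit$slopes), K - seq_len(K)))
      row_softmax(eta)
    },
    stereotype = {
      eta <- outer(rep(1, n), c(a, 0)) +
        outer(drop(X %*% fit$slopes), fit$phi)
      row_softmax(eta)
    },
    baseline_cat = {
      eta <- cbind(outer(rep(1, n), c(a, 0)))
      eta[, seq_len(K - 1L)] <- eta[, seq_len(K - 1L)] + X %*% fit$slopes
      row_softmax(eta)
    }
  )
}

#' Serialize a fitted combination to JSON
#'
#' @param fit a \code{combo_fit}.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, if written to \code{path}).
#' @export
combo_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "combo_fit"))
  obj <- list(strategy = fit$strategy, K = fit$K, p = fit$p,
              marker_names = fit$marker_names,
              intercepts = fit$intercepts,
              slopes = if (is.matrix(fit$slopes)) {
                lapply(seq_len(ncol(fit$slopes)),
                       function(k) unname(fit$slopes[, k]))
              } else unname(fit$slopes),
              phi = fit$phi, converged = fit$converged, loglik = fit$loglik)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a fitted combination from JSON
#'
#' @param json JSON string or path to a file written by
#'   \code{\link{combo_to_json}}.
#' @return a \code{combo_fit}.
#' @export
combo_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyMatrix = FALSE)
  slopes <- obj$slopes
  if (is.list(slopes)) slopes <- do.call(cbind, slopes)
  if (is.matrix(slopes)) rownames(slopes) <- obj$marker_names
  structure(
    list(strategy = obj$strategy, intercepts = obj$intercepts,
         slopes = slopes, phi = obj$phi, converged = obj$converged,
         loglik = obj$loglik, K = obj$K, p = obj$p,
         marker_names = obj$marker_names),
    class = "combo_fit"
  )
}
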
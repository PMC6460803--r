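#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Estimates the AUC of a scalar score for discriminating cases
#' (\code{labels == 1}) from controls (\code{labels == 0}) using the
#' Mann-Whitney U statistic with midrank handling of ties:
#' \deqn{AUC = [\#(case > control) + \tfrac12\,\#(case = control)] /
#'   (n_{case} n_{control}).}
#'
#' @param scores numeric vector of risk scores (higher = more case-like).
#' @param labels binary vector (0/1 or logical) of the same length.
#' @return AUC in \code{[0, 1]}.
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  if (anyNA(scores) || anyNA(labels)) stop("missing values in scores/labels")
  if (!any(labels == 1L)) stop("no cases (labels == 1) present")
  if (!any(labels == 0L)) stop("no controls (labels == 0) present")
  cpp_auc(as.numeric(scores), labels)
}

#' Outcome-level contrast
#'
#' Defines which outcome levels are treated as cases and which as controls
#' when estimating a level-specific AUC, e.g. \code{D = K} vs. \code{D < K}
#' or \code{D = 2} vs. \code{D = 1}.
#'
#' @param positive integer vector of case levels.
#' @param negative integer vector of control levels (disjoint from
#'   \code{positive}).
#' @return an object of class \code{"level_contrast"}.
#' @export
level_contrast <- function(positive, negative) {
  positive <- sort(unique(as.integer(positive)))
  negative <- sort(unique(as.integer(negative)))
  if (!length(positive) || !length(negative)) {
    stop("both contrast groups must be nonempty")
  }
  if (length(intersect(positive, negative))) {
    stop("contrast groups must be disjoint")
  }
  structure(list(positive = positive, negative = negative),
            class = "level_contrast")
}

#' @export
print.level_contrast <- function(x, ...) {
  cat(sprintf("<level_contrast> {%s} vs {%s}\n",
              paste(x$positive, collapse = ","),
              paste(x$negative, collapse = ",")))
  invisible(x)
}

#' Default selection contrasts for a K-level outcome
#'
#' The contrasts the rank-sum selection algorithm scores: \code{\{K\}} vs.
#' \code{\{<K\}}, then \code{\{K-1\}} vs. \code{\{<K-1\}}, and so on down to
#' \code{\{2\}} vs. \code{\{1\}}.
#'
#' @param K number of outcome levels.
#' @return list of \code{\link{level_contrast}} objects, top contrast first.
#' @export
default_contrasts <- function(K) {
  K <- as.integer(K)
  stopifnot(K >= 2L)
  lapply(seq(K, 2L), function(k) level_contrast(k, seq_len(k - 1L)))
}

#' AUC between two outcome-level groups
#'
#' Restricts to observations whose level belongs to the contrast and computes
#' the midrank AUC of the score for the positive vs. the negative group.
#'
#' @param scores numeric score vector.
#' @param D integer outcome-level vector of the same length.
#' @param contrast a \code{\link{level_contrast}}.
#' @return AUC in \code{[0, 1]}.
#' @export
conditional_auc <- function(scores, D, contrast) {
  stopifnot(inherits(contrast, "level_contrast"))
  pos <- D %in% contrast$positive
  neg <- D %in% contrast$negative
  if (!any(pos)) stop("no observations in the positive contrast group")
  if (!any(neg)) stop("no observations in the negative contrast group")
  keep <- pos | neg
  auc(scores[keep], as.integer(pos[keep]))
}
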
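#' Ordinal biomarker dataset
#'
#' Bundles a numeric biomarker matrix with an ordinal outcome taking integer
#' levels \code{1..K}. This is the common input container for every fitting,
#' selection and simulation function in the package.
#'
#' @param X numeric matrix (or data frame of numerics), one row per
#'   observation, one column per biomarker.
#' @param D integer vector of outcome levels in \code{1..K}; length must equal
#'   \code{nrow(X)}.
#' @param K number of outcome levels (>= 2). Defaults to \code{max(D)}.
#' @param marker_names optional character vector of biomarker labels; defaults
#'   to the column names of \code{X} or \code{X1..Xp}.
#'
#' @return An object of class \code{"ordinal_data"}: a list with elements
#'   \code{X}, \code{D}, \code{K}, \code{n}, \code{p}, \code{marker_names}.
#' @examples
#' d <- ordinal_data(matrix(rnorm(40), 20, 2), rep(1:2, 10))
#' level_counts(d)
#' @export
ordinal_data <- function(X, D, K = max(D), marker_names = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("'X' must be a numeric matrix or data frame")
  }
  if (anyNA(X) || anyNA(D)) stop("missing values are not supported")
  D <- as.integer(round(D))
  if (length(D) != nrow(X)) stop("length(D) must equal nrow(X)")
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  if (any(D < 1L | D > K)) stop("all outcome levels must lie in 1..K")
  if (is.null(marker_names)) {
    marker_names <- colnames(X)
    if (is.null(marker_names)) marker_names <- paste0("X", seq_len(ncol(X)))
  }
  if (length(marker_names) != ncol(X)) {
    stop("marker_names length must equal ncol(X)")
  }
  colnames(X) <- marker_names
  structure(
    list(X = X, D = D, K = K, n = nrow(X), p = ncol(X),
         marker_names = marker_names),
    class = "ordinal_data"
  )
}

#' @export
print.ordinal_data <- function(x, ...) {
  cat(sprintf("<ordinal_data> %d observations, %d biomarkers, K = %d levels\n",
              x$n, x$p, x$K))
  cnt <- level_counts(x)
  cat("level counts:", paste(sprintf("%d:%d", seq_along(cnt), cnt),
                             collapse = "  "), "\n")
  invisible(x)
}

#' Outcome level counts
#'
#' @param data an \code{ordinal_data} object.
#' @return integer vector of length \code{K}; element \code{k} counts
#'   observations with \code{D == k} (zeros kept).
#' @export
level_counts <- function(data) {
  stopifnot(inherits(data, "ordinal_data"))
  tabulate(data$D, nbins = data$K)
}

#' Check that every outcome level is represented
#'
#' @param data an \code{ordinal_data} object.
#' @return logical scalar.
#' @export
has_all_levels <- function(data) all(level_counts(data) > 0L)

#' Read an ordinal biomarker dataset from CSV
#'
#' The file must have a header row. One column holds the outcome as integers
#' \code{1..K}; the marker columns must be numeric. Markers may optionally be
#' log-transformed on read, the usual pre-processing for skewed biomarker
#' concentrations.
#'
#' @param path path to a CSV file with header.
#' @param outcome name of the outcome column.
#' @param markers character vector of marker column names; default: all
#'   columns except the outcome.
#' @param log_transform if \code{TRUE}, apply \code{log} to every marker
#'   column before constructing the dataset (values must be positive).
#' @param K number of outcome levels; defaults to the maximum observed level.
#' @return an \code{\link{ordinal_data}} object.
#' @export
read_ordinal_csv <- function(path, outcome, markers = NULL,
                             log_transform = FALSE, K = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!outcome %in% names(df)) {
    stop(sprintf("outcome column '%s' not found", outcome))
  }
  if (is.null(markers)) markers <- setdiff(names(df), outcome)
  missing_cols <- setdiff(markers, names(df))
  if (length(missing_cols)) {
    stop("marker columns not found: ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(df[markers])
  storage.mode(X) <- "double"
  if (log_transform) {
    if (any(X <= 0)) stop("log_transform requires strictly positive markers")
    X <- log(X)
  }
  D <- df[[outcome]]
  if (is.null(K)) K <- max(D)
  ordinal_data(X, D, K = K, marker_names = markers)
}

#' Write an ordinal biomarker dataset to CSV
#'
#' @param data an \code{ordinal_data} object.
#' @param path output file path.
#' @param outcome name for the outcome column (default \code{"D"}).
#' @return \code{path}, invisibly.
#' @export
write_ordinal_csv <- function(data, path, outcome = "D") {
  stopifnot(inherits(data, "ordinal_data"))
  df <- data.frame(data$X, check.names = FALSE)
  df[[outcome]] <- data$D
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
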
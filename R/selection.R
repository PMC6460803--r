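#' Candidate biomarker combinations
#'
#' A candidate set is a collection of marker-index tuples; each tuple names
#' the biomarkers entering one candidate combination. Tuples are stored
#' sorted ascending and deduplicated, in lexicographic order.
#'
#' @param combos list of integer vectors, or an integer matrix with one row
#'   per candidate.
#' @param p total number of available markers.
#' @return an object of class \code{"candidate_set"} with elements
#'   \code{combos} (integer matrix, one row per candidate) and \code{p}.
#' @seealso \code{\link{all_pairs}}
#' @export
candidate_set <- function(combos, p) {
  if (is.list(combos)) {
    sizes <- lengths(combos)
    if (length(unique(sizes)) != 1L) stop("all tuples must have equal size")
    combos <- do.call(rbind, combos)
  }
  combos <- matrix(as.integer(combos), nrow = nrow(combos))
  if (any(combos < 1L) || any(combos > p)) {
    stop("marker indices must lie in 1..p")
  }
  combos <- t(apply(combos, 1L, sort))
  if (any(apply(combos, 1L, anyDuplicated) > 0L)) {
    stop("a tuple may not repeat a marker")
  }
  combos <- unique(combos)
  ord <- do.call(order, lapply(seq_len(ncol(combos)), function(j) combos[, j]))
  structure(list(combos = combos[ord, , drop = FALSE], p = as.integer(p)),
            class = "candidate_set")
}

#' All marker pairs as candidates
#'
#' @param p number of markers; \code{choose(p, 2)} candidates result.
#' @param size tuple size (default 2, the all-pairs setting).
#' @return a \code{\link{candidate_set}}.
#' @export
all_pairs <- function(p, size = 2L) {
  candidate_set(t(utils::combn(p, size)), p)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d candidates of size %d from %d markers\n",
              nrow(x$combos), ncol(x$combos), x$p))
  invisible(x)
}

#' Fit every candidate combination by binary logistic regression
#'
#' Step (1) of the selection algorithm: dichotomize the outcome at
#' \code{D = K} vs. \code{D < K} and fit
#' \eqn{logit P(D = K | x) = \theta_0 + \theta'x} for each candidate tuple.
#' The fitted score is the predicted probability of \code{D = K}.
#'
#' @param data an \code{\link{ordinal_data}} object.
#' @param cands a \code{\link{candidate_set}}.
#' @return list with \code{coefs} (\code{(m+1) x n_cand} matrix, intercept
#'   first) and \code{converged} (logical vector; separation or IRLS failure
#'   flags a candidate).
#' @export
fit_candidates <- function(data, cands) {
  stopifnot(inherits(data, "ordinal_data"), inherits(cands, "candidate_set"))
  if (cands$p != data$p) stop("candidate set was built for a different p")
  y <- as.integer(data$D == data$K)
  if (!any(y == 1L) || !any(y == 0L)) {
    stop("need observations both at and below the top level")
  }
  fit <- cpp_fit_candidates(data$X, y, cands$combos)
  fit$converged <- as.logical(fit$converged)
  fit
}

#' Apparent AUCs of fitted candidates
#'
#' Step (2): for each candidate, the training-data AUC at every contrast,
#' always computed from the single score fit for \code{D = K} vs.
#' \code{D < K} (lower contrasts reuse that score; nothing is refit).
#'
#' @param data the training \code{\link{ordinal_data}}.
#' @param cands a \code{\link{candidate_set}}.
#' @param coefs coefficient matrix from \code{\link{fit_candidates}}.
#' @param contrasts list of \code{\link{level_contrast}} objects (default
#'   \code{\link{default_contrasts}(data$K)}).
#' @return numeric matrix, candidates x contrasts.
#' @export
apparent_aucs <- function(data, cands, coefs,
                          contrasts = default_contrasts(data$K)) {
  scores <- cpp_score_candidates(data$X, cands$combos, coefs)
  contrast_auc_cols(scores, data$D, contrasts)
}

# Columnwise conditional AUCs for a score matrix at each contrast.
# Rows outside a contrast are flagged -1 rather than subset away.
contrast_auc_cols <- function(scores, D, contrasts) {
  out <- sapply(contrasts, function(ct) {
    group <- rep(-1L, length(D))
    group[D %in% ct$negative] <- 0L
    group[D %in% ct$positive] <- 1L
    cpp_auc_cols(scores, group)
  })
  matrix(out, ncol = length(contrasts))
}

# TRUE if every contrast has both groups represented in D.
contrasts_supported <- function(D, contrasts) {
  all(vapply(contrasts, function(ct) {
    any(D %in% ct$positive) && any(D %in% ct$negative)
  }, logical(1)))
}

#' Bootstrap estimate of resubstitution bias per candidate and contrast
#'
#' Steps (3a)-(3c): draw \code{B} bootstrap resamples of the training rows,
#' refit every candidate in each resample, and estimate the resubstitution
#' bias of each AUC as the average over resamples of (AUC in the resample)
#' minus (AUC of the resample-fitted score in the original training data).
#' Resamples missing a level needed by any contrast are redrawn (the redraw
#' count is returned); the same \code{B} resamples are shared by all
#' candidates.
#'
#' @inheritParams apparent_aucs
#' @param B number of bootstrap resamples (>= 1).
#' @param resample resampling function taking \code{n} and returning \code{n}
#'   row indices; default is the nonparametric bootstrap
#'   \code{sample.int(n, n, replace = TRUE)}. (An identity stub reproduces
#'   the training data and yields bias exactly 0.)
#' @return list with \code{bias} (candidates x contrasts matrix),
#'   \code{n_boot_used} (per-candidate count of resamples in which the
#'   candidate refit converged) and \code{redraws}.
#' @export
bootstrap_bias <- function(data, cands, coefs,
                           contrasts = default_contrasts(data$K), B = 50L,
                           resample = NULL) {
  stopifnot(B >= 1L)
  if (is.null(resample)) {
    resample <- function(n) sample.int(n, n, replace = TRUE)
  }
  n <- data$n
  nc <- nrow(cands$combos)
  y <- as.integer(data$D == data$K)
  diff_sum <- matrix(0, nc, length(contrasts))
  used <- integer(nc)
  redraws <- 0L
  attempts_left <- 100L * B
  for (b in seq_len(B)) {
    repeat {
      if (attempts_left <= 0L) {
        stop("could not draw a bootstrap resample containing every level ",
             "required by the contrasts")
      }
      attempts_left <- attempts_left - 1L
      idx <- resample(n)
      if (contrasts_supported(data$D[idx], contrasts)) break
      redraws <- redraws + 1L
    }
    fit_b <- cpp_fit_candidates(data$X[idx, , drop = FALSE], y[idx],
                                cands$combos, init = coefs)
    ok <- as.logical(fit_b$converged)
    # Scoring is rowwise, so scoring the full training matrix once gives the
    # resample's scores by row indexing.
    scores_train <- cpp_score_candidates(data$X, cands$combos, fit_b$coefs)
    auc_boot <- contrast_auc_cols(scores_train[idx, , drop = FALSE],
                                  data$D[idx], contrasts)
    auc_train <- contrast_auc_cols(scores_train, data$D, contrasts)
    d <- auc_boot - auc_train
    d[!ok, ] <- 0
    d[is.na(d)] <- 0
    diff_sum <- diff_sum + d
    used <- used + as.integer(ok)
  }
  bias <- diff_sum / pmax(used, 1L)
  bias[used == 0L, ] <- NA_real_
  list(bias = bias, n_boot_used = used, redraws = redraws)
}

#' Rank corrected AUCs and select combinations
#'
#' Steps (4)-(5): given optimism-corrected AUCs per candidate and contrast,
#' assign ranks within each contrast (largest corrected AUC gets the largest
#' rank; midranks on ties). The "standard" selection is the candidate with
#' the highest corrected top-level AUC; the "new" selection is the candidate
#' with the highest rank sum across all contrasts. Ties are broken by the
#' larger corrected top-level AUC, then by lowest lexicographic candidate
#' order. Candidates flagged as non-converged get rank 0 everywhere and are
#' never selected.
#'
#' @param corrected numeric matrix, candidates x contrasts; column 1 must be
#'   the top-level contrast.
#' @param converged logical vector (default: all converged).
#' @return list with \code{ranks} (matrix), \code{rank_sum},
#'   \code{chosen_standard} and \code{chosen_new} (row indices).
#' @export
rank_and_select <- function(corrected, converged = NULL) {
  corrected <- as.matrix(corrected)
  nc <- nrow(corrected)
  if (is.null(converged)) converged <- rep(TRUE, nc)
  converged <- converged & !apply(is.na(corrected), 1L, any)
  if (!any(converged)) stop("no converged candidates to select from")
  ranks <- matrix(0, nc, ncol(corrected))
  for (j in seq_len(ncol(corrected))) {
    ranks[converged, j] <- rank(corrected[converged, j],
                                ties.method = "average")
  }
  rank_sum <- rowSums(ranks)
  pick <- function(key) {
    # lexicographic tie-break: order() is stable, candidates are presorted
    ord <- order(!converged, -key, -corrected[, 1L])
    ord[1L]
  }
  list(ranks = ranks, rank_sum = rank_sum,
       chosen_standard = pick(corrected[, 1L]),
       chosen_new = pick(rank_sum))
}

#' Rank-sum selection of a biomarker combination
#'
#' Runs the full selection algorithm on training data: fit all candidate
#' combinations by binary logistic regression for \code{D = K} vs.
#' \code{D < K} (step 1), estimate the AUC at each level contrast from the
#' single fitted score (step 2), bootstrap-correct each AUC for
#' resubstitution bias (steps 3-4), and select both the "standard"
#' combination (highest corrected top-level AUC) and the "new" combination
#' (highest sum of ranks across contrasts) (step 5). Use
#' \code{\link{evaluate_on_test}} for step 6.
#'
#' @param data training \code{\link{ordinal_data}}.
#' @param cands a \code{\link{candidate_set}}; default all marker pairs.
#' @param B number of bootstrap resamples (default 50).
#' @param contrasts list of \code{\link{level_contrast}}s, top level first;
#'   default \code{\link{default_contrasts}(data$K)}.
#' @param seed optional integer seed; a given seed makes the report
#'   bit-reproducible.
#' @param resample optional resampling function (see
#'   \code{\link{bootstrap_bias}}).
#' @return An object of class \code{"selection_report"}: a list with the
#'   per-candidate table \code{candidates} (indices, convergence, apparent,
#'   bias and corrected AUC per contrast, ranks, rank sum), the coefficient
#'   matrix \code{coefs}, \code{chosen_standard}, \code{chosen_new},
#'   \code{B}, \code{seed}, \code{boot_redraws}, \code{contrasts} and the
#'   marker names.
#' @examples
#' d <- gen_fixture("ordered", n = 150, p = 4, seed = 7)
#' rep <- select_combination(d, B = 10, seed = 1)
#' rep
#' @export
select_combination <- function(data, cands = all_pairs(data$p), B = 50L,
                               contrasts = default_contrasts(data$K),
                               seed = NULL, resample = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_candidates(data, cands)
  apparent <- apparent_aucs(data, cands, fit$coefs, contrasts)
  bb <- bootstrap_bias(data, cands, fit$coefs, contrasts, B = B,
                       resample = resample)
  corrected <- apparent - bb$bias
  sel <- rank_and_select(corrected, fit$converged)
  tab <- data.frame(candidate = seq_len(nrow(cands$combos)))
  for (j in seq_len(ncol(cands$combos))) {
    tab[[paste0("marker", j)]] <- cands$combos[, j]
  }
  tab$converged <- fit$converged
  cn <- contrast_names(contrasts)
  for (j in seq_along(contrasts)) {
    tab[[paste0("apparent_", cn[j])]] <- apparent[, j]
    tab[[paste0("bias_", cn[j])]] <- bb$bias[, j]
    tab[[paste0("corrected_", cn[j])]] <- corrected[, j]
    tab[[paste0("rank_", cn[j])]] <- sel$ranks[, j]
  }
  tab$rank_sum <- sel$rank_sum
  structure(
    list(candidates = tab, combos = cands$combos, coefs = fit$coefs,
         contrasts = contrasts, apparent = apparent, bias = bb$bias,
         corrected = corrected, ranks = sel$ranks, rank_sum = sel$rank_sum,
         chosen_standard = sel$chosen_standard, chosen_new = sel$chosen_new,
         B = as.integer(B), seed = seed, boot_redraws = bb$redraws,
         n_not_converged = sum(!fit$converged),
         marker_names = data$marker_names, K = data$K),
    class = "selection_report"
  )
}

contrast_names <- function(contrasts) {
  vapply(contrasts, function(ct) {
    sprintf("%svs%s", paste(ct$positive, collapse = ""),
            paste(ct$negative, collapse = ""))
  }, character(1))
}

#' @export
print.selection_report <- function(x, ...) {
  nm <- function(i) paste(x$marker_names[x$combos[i, ]], collapse = " + ")
  cat(sprintf("<selection_report> %d candidates, B = %d bootstrap resamples\n",
              nrow(x$combos), x$B))
  cat(sprintf("standard pick (best corrected top-level AUC): %s (%.4f)\n",
              nm(x$chosen_standard), x$corrected[x$chosen_standard, 1L]))
  cat(sprintf("new pick      (best rank sum):                %s (%.4f)\n",
              nm(x$chosen_new), x$corrected[x$chosen_new, 1L]))
  if (x$n_not_converged > 0L) {
    cat(sprintf("%d candidate fit(s) did not converge\n", x$n_not_converged))
  }
  invisible(x)
}

#' Evaluate the selected combinations on independent test data
#'
#' Step (6): apply each chosen combination's training-data fit to test data,
#' estimate the test AUC for \code{D = K} vs. \code{D < K}, and report the
#' estimated model selection bias = (corrected training AUC) - (test AUC),
#' so optimism is positive.
#'
#' @param report a \code{\link{select_combination}} report.
#' @param test an \code{\link{ordinal_data}} test set containing the top
#'   level and at least one lower level.
#' @return data.frame with one row per approach (\code{standard},
#'   \code{new}): chosen candidate index, marker indices, corrected training
#'   AUC, test AUC and model selection bias.
#' @export
evaluate_on_test <- function(report, test) {
  stopifnot(inherits(report, "selection_report"),
            inherits(test, "ordinal_data"))
  top <- report$contrasts[[1L]]
  if (!any(test$D %in% top$positive) || !any(test$D %in% top$negative)) {
    stop("test data must contain the top level and its complement")
  }
  picks <- c(standard = report$chosen_standard, new = report$chosen_new)
  rows <- lapply(seq_along(picks), function(i) {
    ci <- picks[i]
    scores <- drop(cpp_score_candidates(
      test$X, report$combos[ci, , drop = FALSE],
      report$coefs[, ci, drop = FALSE]))
    test_auc <- conditional_auc(scores, test$D, top)
    data.frame(approach = names(picks)[i], candidate = ci,
               markers = paste(report$combos[ci, ], collapse = ","),
               corrected_auc_top = report$corrected[ci, 1L],
               test_auc_top = test_auc,
               model_selection_bias = report$corrected[ci, 1L] - test_auc)
  })
  do.call(rbind, rows)
}

#' Export a selection report as a ranked candidate table
#'
#' Writes (or returns) the per-candidate table sorted by corrected top-level
#' AUC, mirroring the usual presentation of the best pairs with their two
#' optimism-corrected AUCs.
#'
#' @param report a \code{selection_report}.
#' @param path optional CSV path.
#' @param top_n keep only the best \code{top_n} rows (default: all).
#' @return the (sorted) data.frame, invisibly if written to \code{path}.
#' @export
report_table <- function(report, path = NULL, top_n = NULL) {
  stopifnot(inherits(report, "selection_report"))
  tab <- report$candidates
  for (j in seq_len(ncol(report$combos))) {
    tab[[paste0("marker", j)]] <-
      report$marker_names[report$combos[, j]]
  }
  tab <- tab[order(-report$corrected[, 1L]), ]
  if (!is.null(top_n)) tab <- utils::head(tab, top_n)
  if (is.null(path)) return(tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
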
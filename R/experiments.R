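# Monte Carlo drivers reproducing the two simulation studies: combination
# construction (median test AUC of each strategy per scenario cell) and
# combination selection (model selection bias, test AUC and selection
# frequencies of the standard vs. rank-sum approaches).

# Per-replicate seeds derived once from the root seed, so replicate r is
# reproducible regardless of how many replicates run before it.
replicate_seeds <- function(seed, reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, reps)
}

#' Run one construction-study cell
#'
#' Per replicate: draw a training set and a test set from the scenario, fit
#' each strategy on the training data, score the test data, and record the
#' test AUC for \code{D = K} vs. \code{D < K}. Replicates in which a
#' strategy fails to converge are dropped from that strategy's summary and
#' counted.
#'
#' @param cfg a \code{\link{scenario_config}} (e.g. from
#'   \code{\link{construction_scenario}} or \code{\link{preset_scenario}}).
#' @param strategies character vector of strategies (default all seven).
#' @param reps Monte Carlo replicates (default 1000).
#' @param n_train training-set size (default 400).
#' @param n_test test-set size (default \code{1e4}).
#' @param seed root seed; per-replicate seeds are derived from it.
#' @return an object of class \code{"experiment_summary"} whose
#'   \code{summary} element has one row per strategy with the median and
#'   interquartile range of the test AUC, the convergence-failure count and
#'   the replicate count; the replicate-level AUCs are kept in \code{detail}.
#' @export
run_construction_cell <- function(cfg, strategies = combo_strategies(),
                                  reps = 1000L, n_train = 400L,
                                  n_test = 10000L, seed = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  strategies <- match.arg(strategies, combo_strategies(),
                          several.ok = TRUE)
  t0 <- proc.time()[["elapsed"]]
  intercepts <- NULL
  if (cfg$family == "cumulative_logit") {
    intercepts <- with_preserved_rng(seed, calibrate_intercepts(cfg))
  }
  seeds <- replicate_seeds(seed, reps)
  top <- level_contrast(cfg$K, seq_len(cfg$K - 1L))
  aucs <- matrix(NA_real_, reps, length(strategies),
                 dimnames = list(NULL, strategies))
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    train <- gen_scenario(cfg, n_train, intercepts)
    test <- gen_scenario(cfg, n_test, intercepts,
                         require_all_levels = FALSE)
    for (s in strategies) {
      fit <- tryCatch(fit_combination(train, s), error = function(e) NULL)
      if (is.null(fit) || !isTRUE(fit$converged)) next
      sc <- predict_risk(fit, test$X)
      if (anyNA(sc)) next
      aucs[r, s] <- conditional_auc(sc, test$D, top)
    }
  }
  summary <- do.call(rbind, lapply(strategies, function(s) {
    v <- aucs[, s]
    ok <- !is.na(v)
    data.frame(strategy = s,
               median_auc = if (any(ok)) stats::median(v[ok]) else NA_real_,
               q25 = if (any(ok)) unname(stats::quantile(v[ok], 0.25))
                     else NA_real_,
               q75 = if (any(ok)) unname(stats::quantile(v[ok], 0.75))
                     else NA_real_,
               n_failed = sum(!ok), reps = reps,
               degenerate = !any(ok))
  }))
  structure(list(kind = "construction", summary = summary,
                 detail = aucs, seed = seed, reps = reps,
                 n_train = n_train, n_test = n_test,
                 runtime = proc.time()[["elapsed"]] - t0),
            class = "experiment_summary")
}

#' Run one selection example end to end
#'
#' Per replicate: generate training and test data for the example, run the
#' full rank-sum selection pipeline over all marker pairs
#' (\code{\link{select_combination}}), and evaluate both selected
#' combinations on the test data. Summaries report the median and
#' interquartile range of the estimated model selection bias and of the test
#' AUC per approach, plus how often each pair -- notably the strong pair
#' (1, 2) -- was chosen.
#'
#' @param example integer 1..5.
#' @param reps Monte Carlo replicates (default 500).
#' @param B bootstrap resamples per replicate (default 50).
#' @param n_train training-set size (default 400).
#' @param n_test test-set size (default \code{1e4}).
#' @param seed root seed.
#' @return an \code{"experiment_summary"}: \code{summary} has one row per
#'   approach with median (IQR) bias and test AUC; \code{selection_freq}
#'   gives per-approach percentages for every selected pair;
#'   \code{detail} keeps the replicate-level records.
#' @export
run_selection_example <- function(example, reps = 500L, B = 50L,
                                  n_train = 400L, n_test = 10000L,
                                  seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  cfg <- selection_example_config(example)
  seeds <- replicate_seeds(seed, reps)
  cands <- all_pairs(cfg$p)
  rows <- vector("list", reps)
  failed <- 0L
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    res <- tryCatch({
      train <- gen_selection_example(example, n_train)
      test <- gen_selection_example(example, n_test,
                                    require_all_levels = FALSE)
      rep_ <- select_combination(train, cands, B = B)
      ev <- evaluate_on_test(rep_, test)
      ev$replicate <- r
      ev$n_not_converged <- rep_$n_not_converged
      ev
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else rows[[r]] <- res
  }
  detail <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(c("standard", "new"), function(a) {
    d <- detail[detail$approach == a, ]
    data.frame(approach = a,
               median_bias = stats::median(d$model_selection_bias),
               bias_q25 = unname(stats::quantile(d$model_selection_bias, 0.25)),
               bias_q75 = unname(stats::quantile(d$model_selection_bias, 0.75)),
               median_auc = stats::median(d$test_auc_top),
               auc_q25 = unname(stats::quantile(d$test_auc_top, 0.25)),
               auc_q75 = unname(stats::quantile(d$test_auc_top, 0.75)),
               reps = nrow(d))
  }))
  freq <- do.call(rbind, lapply(c("standard", "new"), function(a) {
    d <- detail[detail$approach == a, ]
    tt <- sort(table(d$markers), decreasing = TRUE)
    data.frame(approach = a, markers = names(tt),
               percent = 100 * as.numeric(tt) / nrow(d))
  }))
  structure(list(kind = "selection", example = example, summary = summary,
                 selection_freq = freq, detail = detail,
                 reps = reps, B = B, seed = seed, n_failed = failed,
                 runtime = proc.time()[["elapsed"]] - t0),
            class = "experiment_summary")
}

#' Selection frequency of a given pair
#'
#' @param x an \code{experiment_summary} from
#'   \code{\link{run_selection_example}}.
#' @param markers integer vector naming the pair (default \code{c(1, 2)},
#'   the strong pair in every shipped example).
#' @param approach \code{"new"} or \code{"standard"}.
#' @return percentage of replicates in which the approach chose that pair.
#' @export
selection_frequency <- function(x, markers = c(1, 2), approach = "new") {
  stopifnot(inherits(x, "experiment_summary"), x$kind == "selection")
  key <- paste(sort(as.integer(markers)), collapse = ",")
  f <- x$selection_freq
  hit <- f$approach == approach & f$markers == key
  if (!any(hit)) 0 else f$percent[hit]
}

#' @export
print.experiment_summary <- function(x, ...) {
  if (x$kind == "construction") {
    cat(sprintf("<experiment_summary> construction cell, %d replicates\n",
                x$reps))
    s <- x$summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-16s %.3f (%.3f, %.3f)  [failed: %d]\n",
                  s$strategy[i], s$median_auc[i], s$q25[i], s$q75[i],
                  s$n_failed[i]))
    }
  } else {
    cat(sprintf(
      "<experiment_summary> selection example %d, %d replicates, B = %d\n",
      x$example, x$reps, x$B))
    cat(sprintf("  %-10s %-22s %s\n", "Method", "Bias", "AUC"))
    s <- x$summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-10s %.3f (%.3f, %.3f)  %.3f (%.3f, %.3f)\n",
                  s$approach[i], s$median_bias[i], s$bias_q25[i],
                  s$bias_q75[i], s$median_auc[i], s$auc_q25[i], s$auc_q75[i]))
    }
    cat(sprintf("  pair (1,2) chosen: standard %.1f%%, new %.1f%%\n",
                selection_frequency(x, approach = "standard"),
                selection_frequency(x, approach = "new")))
  }
  invisible(x)
}

#' Combine experiment summaries into tidy tables
#'
#' Binds the summary rows of several runs into one tidy data.frame (one row
#' per scenario x strategy/approach) and optionally writes it to CSV along
#' with a rendered text table.
#'
#' @param summaries list of \code{experiment_summary} objects; names are
#'   used as scenario identifiers.
#' @param csv optional path for the tidy CSV.
#' @param txt optional path for the rendered text table.
#' @return the tidy data.frame, invisibly if written.
#' @export
summarize_experiments <- function(summaries, csv = NULL, txt = NULL) {
  if (inherits(summaries, "experiment_summary")) {
    summaries <- list(summaries)
  }
  ids <- names(summaries)
  if (is.null(ids)) ids <- as.character(seq_along(summaries))
  tidy <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]$summary
    s$scenario <- ids[i]
    s$kind <- summaries[[i]]$kind
    s
  }))
  tidy <- tidy[, c("scenario", "kind",
                   setdiff(names(tidy), c("scenario", "kind")))]
  if (!is.null(csv)) utils::write.csv(tidy, csv, row.names = FALSE)
  if (!is.null(txt)) {
    con <- file(txt, "w")
    on.exit(close(con))
    for (i in seq_along(summaries)) {
      writeLines(paste0("== ", ids[i], " =="), con)
      writeLines(utils::capture.output(print(summaries[[i]])), con)
    }
  }
  if (is.null(csv) && is.null(txt)) tidy else invisible(tidy)
}
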
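#' Aggregate a misconduct grid under an evaluation scheme
#'
#' The three schemes evaluate detection at different granularities:
#' `iteration_site` keeps the (trial, iteration, site) cells;
#' `iteration_aggregated` ORs over sites within each (trial, iteration) — an
#' iteration with any misconducted site is a misconduct iteration;
#' `site_aggregated` ORs over iterations within each (trial, site).
#' Aggregation never crosses trials.
#'
#' @param grid data.frame with columns `trial`, `iteration`, `site` and the
#'   logical column named by `value`.
#' @param scheme one of `"iteration_site"`, `"iteration_aggregated"`,
#'   `"site_aggregated"`.
#' @param value name of the logical column to aggregate.
#' @return data.frame with the scheme's key columns and the aggregated
#'   logical `value` column, sorted by key.
#' @export
aggregate_scheme <- function(grid,
                             scheme = c("iteration_site", "iteration_aggregated",
                                        "site_aggregated"),
                             value = "misconduct") {
  scheme <- match.arg(scheme)
  v <- grid[[value]]
  if (is.null(v)) .stopf("grid lacks column '%s'", value)
  keys <- switch(scheme,
                 iteration_site = c("trial", "iteration", "site"),
                 iteration_aggregated = c("trial", "iteration"),
                 site_aggregated = c("trial", "site"))
  out <- stats::aggregate(v, by = grid[keys], FUN = any)
  names(out)[ncol(out)] <- value
  out[do.call(order, out[keys]), , drop = FALSE]
}

.confusion <- function(truth, pred) {
  c(tp = sum(truth & pred), fp = sum(!truth & pred),
    fn = sum(truth & !pred), tn = sum(!truth & !pred))
}

.metrics_from_counts <- function(counts, scheme) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  # zero-denominator convention: nothing flagged and nothing missed is a
  # perfect score, not an undefined one (honest folds exist)
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(scheme = scheme, tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics [%s]: P = %.3f, R = %.3f, F1 = %.3f (tp %d, fp %d, fn %d, tn %d)>\n",
              x$scheme, x$precision, x$recall, x$f1, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Precision/recall/F1 of detections against ground truth
#'
#' Aggregates both grids under the scheme, aligns them on the scheme's keys
#' and computes the confusion counts and metrics. Zero-denominator
#' convention: a ratio with zero denominator is 1 when the corresponding
#' error count is 0 (nothing to find / nothing wrongly flagged), else 0;
#' F1 is 0 when precision + recall is 0.
#'
#' @param truth data.frame with key columns and logical `truth_col`.
#' @param predicted data.frame with key columns and logical `pred_col`.
#' @param scheme evaluation scheme, see [aggregate_scheme()].
#' @param truth_col,pred_col column names of the logical labels.
#' @return A `"metrics_report"`: scheme, tp/fp/fn/tn, precision, recall, f1.
#' @export
compute_metrics <- function(truth, predicted,
                            scheme = c("iteration_site", "iteration_aggregated",
                                       "site_aggregated"),
                            truth_col = "misconduct", pred_col = "flagged") {
  scheme <- match.arg(scheme)
  cm <- .scheme_confusion(truth, predicted, scheme, truth_col, pred_col)
  .metrics_from_counts(cm, scheme)
}

.scheme_confusion <- function(truth, predicted, scheme, truth_col = "misconduct",
                              pred_col = "flagged") {
  ta <- aggregate_scheme(truth, scheme, value = truth_col)
  pa <- aggregate_scheme(predicted, scheme, value = pred_col)
  keys <- setdiff(names(ta), truth_col)
  mg <- merge(ta, pa, by = keys, all = TRUE)
  if (anyNA(mg[[truth_col]]) || anyNA(mg[[pred_col]]))
    .stopf("truth and predictions do not cover the same (%s) units",
           paste(keys, collapse = ", "))
  .confusion(mg[[truth_col]], mg[[pred_col]])
}

#' Per-trial k-fold cross-validated detection
#'
#' Randomly partitions the trials into `n_folds` folds of near-equal size.
#' For each fold, `(beta, gamma)` are tuned by [greedy_tune()] on the other
#' folds' trials and detection is scored on the held-out trials; held-out
#' confusion counts are pooled across folds (micro-averaging, stable with
#' rare positives) and reported per scheme.
#'
#' @param stats per-cell detector statistics ([detector_stats()]) covering
#'   all trials.
#' @param truth ground-truth grid over the same cells.
#' @param grid a [tuning_grid()].
#' @param n_folds number of folds (default 10; must not exceed the number of
#'   trials).
#' @param seed seed for the fold assignment.
#' @param enabled detector subset, see [detector_params()].
#' @return An object of class `"cv_result"`: `plan` (trial to fold map),
#'   `folds` (per-fold tuned parameters and held-out counts) and `pooled`
#'   (named list of `"metrics_report"`s, one per scheme).
#' @export
cross_validate <- function(stats, truth, grid = tuning_grid(), n_folds = 10L,
                           seed = 1L,
                           enabled = c("auditing", "coefficient", "performance")) {
  trials <- sort(unique(truth$trial))
  if (n_folds > length(trials))
    .stopf("n_folds (%d) exceeds the number of trials (%d)", n_folds, length(trials))
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = length(trials)))
  plan <- data.frame(trial = trials, fold = fold)
  schemes <- c("iteration_site", "iteration_aggregated", "site_aggregated")
  totals <- sapply(schemes, function(s) c(tp = 0, fp = 0, fn = 0, tn = 0),
                   simplify = FALSE)
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_trials <- trials[fold == f]
    train <- truth$trial %in% test_trials
    tuned <- greedy_tune(stats[!train, , drop = FALSE],
                         truth[!train, , drop = FALSE], grid, enabled = enabled)
    params <- detector_params(tuned$beta, tuned$gamma, enabled = enabled)
    det <- detect_cells(stats[train, , drop = FALSE], params)
    counts <- lapply(schemes, function(s)
      .scheme_confusion(truth[train, , drop = FALSE], det, s))
    names(counts) <- schemes
    for (s in schemes) totals[[s]] <- totals[[s]] + counts[[s]]
    folds[[f]] <- list(fold = f, trials = test_trials, beta = tuned$beta,
                       gamma = tuned$gamma, objective = tuned$objective,
                       counts = counts)
  }
  pooled <- lapply(schemes, function(s) .metrics_from_counts(totals[[s]], s))
  names(pooled) <- schemes
  structure(list(plan = plan, folds = folds, pooled = pooled,
                 enabled = enabled),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds, detectors {%s}>\n",
              length(x$folds), paste(x$enabled, collapse = ", ")))
  for (m in x$pooled) print(m)
  invisible(x)
}

#' Detector ablation study
#'
#' Repeats [cross_validate()] with each detector subset (default: all three,
#' then each detector removed in turn) and tabulates the pooled
#' Iteration-Site metrics, quantifying each component's contribution.
#'
#' @inheritParams cross_validate
#' @param subsets named list of detector subsets.
#' @return List with `table` (data.frame of pooled Iteration-Site metrics per
#'   subset) and `results` (the underlying `"cv_result"`s).
#' @export
ablation_run <- function(stats, truth, grid = tuning_grid(), n_folds = 10L,
                         seed = 1L,
                         subsets = list(
                           all = c("auditing", "coefficient", "performance"),
                           minus_auditing = c("coefficient", "performance"),
                           minus_coefficient = c("auditing", "performance"),
                           minus_performance = c("auditing", "coefficient"))) {
  results <- lapply(subsets, function(en)
    cross_validate(stats, truth, grid, n_folds = n_folds, seed = seed,
                   enabled = en))
  table <- do.call(rbind, lapply(names(results), function(nm) {
    m <- results[[nm]]$pooled$iteration_site
    data.frame(subset = nm, detectors = paste(subsets[[nm]], collapse = "+"),
               precision = m$precision, recall = m$recall, f1 = m$f1)
  }))
  list(table = table, results = results)
}
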
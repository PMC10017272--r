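#' Experiment configuration
#'
#' Bundles every experiment-level setting. One master seed deterministically
#' derives the stage seeds (data generation, site split, per-trial training
#' sampling, injection, fold assignment) via [derive_seed()], so a full run
#' is reproducible from the configuration alone.
#'
#' @param preset dataset preset name (`"edin"`, `"ca"`, `"cdiff"`) or a
#'   [dataset_spec()] for custom shapes.
#' @param scale sample-size multiplier for desk-scale runs (preset only).
#' @param n_sites number of participating sites (default 4).
#' @param n_trials number of training trials (default 30).
#' @param max_iter per-trial iteration cap (default 100).
#' @param tol convergence precision (default 1e-6).
#' @param fraction per-trial training fraction per site (default 0.5).
#' @param scenario misconduct scenario, see [injection_config()].
#' @param prob injection probability rho (default 0.25).
#' @param grid a [tuning_grid()].
#' @param n_folds cross-validation folds (default 10).
#' @param detect_site detecting site id (default 1).
#' @param enabled detector subset.
#' @param history history scope for injection and detection, `"stream"`
#'   (histories accumulate over trials in ledger order, the default) or
#'   `"trial"` (histories reset at every trial).
#' @param seed master seed.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(preset = "edin", scale = 1, n_sites = 4L,
                              n_trials = 30L, max_iter = 100L, tol = 1e-6,
                              fraction = 0.5, scenario = "all", prob = 0.25,
                              grid = tuning_grid(), n_folds = 10L,
                              detect_site = 1L,
                              enabled = c("auditing", "coefficient", "performance"),
                              history = c("stream", "trial"), seed = 1L) {
  history <- match.arg(history)
  stopifnot(inherits(grid, "tuning_grid"), n_sites >= 1L, n_trials >= 1L,
            n_folds >= 1L, n_folds <= n_trials,
            detect_site >= 1L, detect_site <= n_sites)
  structure(list(preset = preset, scale = scale, n_sites = as.integer(n_sites),
                 n_trials = as.integer(n_trials), max_iter = as.integer(max_iter),
                 tol = tol, fraction = fraction, scenario = scenario,
                 prob = prob, grid = grid, n_folds = as.integer(n_folds),
                 detect_site = as.integer(detect_site), enabled = enabled,
                 history = history, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run a full misconduct-detection experiment
#'
#' End-to-end pipeline: generate the synthetic dataset, split it into sites,
#' run the federated training trials, inject misconducts, precompute detector
#' statistics, cross-validate detection with per-fold greedy tuning, and tune
#' once more on all trials (the "final parameters"). Optionally runs the
#' detector ablation and writes every intermediate artifact to `out_dir`.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory for artifacts (site CSV, honest and
#'   tampered JSONL traces, labels CSV, detections CSV, report JSON,
#'   manifest).
#' @param ablation if `TRUE`, also run [ablation_run()].
#' @param verbose if `TRUE`, log stages to stderr.
#' @return List (class `"experiment_report"`) with `config`, `dataset`
#'   summary, `trials` summary, `truth`, `stats`, `tuned` (full-data greedy
#'   parameters), `cv` (a `"cv_result"`), and optionally `ablation`.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = NULL,
                           ablation = FALSE, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  log <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  spec <- if (inherits(cfg$preset, "dataset_spec")) cfg$preset
          else dataset_preset(cfg$preset, scale = cfg$scale,
                              seed = derive_seed(cfg$seed, "data"))
  log("stage data: generating '%s' (n = %d, d = %d, seed %d)",
      spec$name, spec$n_samples, spec$n_covariates, spec$seed)
  dataset <- generate_dataset(spec)

  sites <- split_sites(dataset, n_sites = cfg$n_sites,
                       seed = derive_seed(cfg$seed, "split"))
  log("stage split: %d sites of sizes %s", cfg$n_sites,
      paste(vapply(sites, function(s) nrow(s$X), 1L), collapse = "/"))

  traces <- run_trials(sites, n_trials = cfg$n_trials, max_iter = cfg$max_iter,
                       tol = cfg$tol, fraction = cfg$fraction,
                       seed = derive_seed(cfg$seed, "train"))
  n_iter <- vapply(traces, `[[`, 1L, "n_iterations")
  log("stage train: %d trials, %d-%d iterations", cfg$n_trials,
      min(n_iter), max(n_iter))

  inj_cfg <- injection_config(scenario = cfg$scenario, prob = cfg$prob,
                              seed = derive_seed(cfg$seed, "inject"))
  inj <- inject_traces(traces, inj_cfg, history = cfg$history)
  log("stage inject: %d / %d cells tampered (rho = %.2f)",
      sum(inj$truth$misconduct), nrow(inj$truth), cfg$prob)

  stats <- detector_stats(inj$traces, sites[[cfg$detect_site]],
                          history = cfg$history)

  cv <- cross_validate(stats, inj$truth, cfg$grid, n_folds = cfg$n_folds,
                       seed = derive_seed(cfg$seed, "cv"), enabled = cfg$enabled)
  log("stage cv: pooled Iteration-Site P = %.3f, R = %.3f, F1 = %.3f",
      cv$pooled$iteration_site$precision, cv$pooled$iteration_site$recall,
      cv$pooled$iteration_site$f1)

  tuned <- greedy_tune(stats, inj$truth, cfg$grid, enabled = cfg$enabled)
  log("stage tune (all trials): beta = %.2f, gamma = %.2f, F1 = %.3f",
      tuned$beta, tuned$gamma, tuned$objective)

  abl <- NULL
  if (ablation) {
    abl <- ablation_run(stats, inj$truth, cfg$grid, n_folds = cfg$n_folds,
                        seed = derive_seed(cfg$seed, "cv"))
    log("stage ablation: done (%d subsets)", nrow(abl$table))
  }

  report <- structure(list(
    config = cfg,
    dataset = list(name = spec$name, n_samples = spec$n_samples,
                   n_covariates = spec$n_covariates,
                   target_prevalence = spec$prevalence,
                   empirical_prevalence = mean(dataset$y),
                   intercept = dataset$intercept),
    trials = list(n_trials = cfg$n_trials, n_iterations = n_iter,
                  converged = vapply(traces, `[[`, TRUE, "converged")),
    truth = inj$truth, stats = stats, tuned = tuned, cv = cv,
    ablation = abl), class = "experiment_report")

  if (!is.null(out_dir)) {
    .write_artifacts(report, dataset, sites, traces, inj, spec, out_dir)
    log("stage write: artifacts under %s", out_dir)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report: '%s', %d trials, scenario %s, rho %.2f>\n",
              x$dataset$name, x$trials$n_trials,
              as.character(x$config$scenario), x$config$prob))
  cat(sprintf("  tuned (all trials): beta = %.2f, gamma = %.2f, F1 = %.3f\n",
              x$tuned$beta, x$tuned$gamma, x$tuned$objective))
  for (m in x$cv$pooled) print(m)
  invisible(x)
}

.write_artifacts <- function(report, dataset, sites, traces, inj, spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_dataset_spec(spec, p("dataset_spec.json"))
  write_sites_csv(sites, p("sites.csv"))
  write_traces(traces, p("trace_honest.jsonl"))
  write_traces(inj$traces, p("trace_tampered.jsonl"))
  write_labels(inj$truth, p("labels.csv"))
  params <- detector_params(report$tuned$beta, report$tuned$gamma,
                            enabled = report$config$enabled)
  det <- detect_cells(report$stats, params)
  det[c("auditing", "coefficient", "performance", "flagged")] <-
    lapply(det[c("auditing", "coefficient", "performance", "flagged")], as.integer)
  utils::write.csv(det, p("detections.csv"), row.names = FALSE)
  jsonlite::write_json(summarize_report(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- data.frame(
    file = c("dataset_spec.json", "sites.csv", "trace_honest.jsonl",
             "trace_tampered.jsonl", "labels.csv", "detections.csv",
             "report.json"),
    stage = c("data", "split", "train", "inject", "inject", "detect", "report"))
  utils::write.csv(manifest, p("manifest.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Plain-list summary of an experiment report
#'
#' JSON-friendly view of [run_experiment()]'s result: configuration scalars,
#' dataset summary, tuned parameters, pooled per-scheme metrics, per-fold
#' parameters, and the ablation table when present.
#'
#' @param report an `"experiment_report"`.
#' @return A nested plain list.
#' @export
summarize_report <- function(report) {
  cv <- report$cv
  pooled <- lapply(cv$pooled, function(m)
    list(tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
         precision = m$precision, recall = m$recall, f1 = m$f1))
  list(
    config = list(preset = if (inherits(report$config$preset, "dataset_spec"))
                    report$config$preset$name else report$config$preset,
                  scale = report$config$scale,
                  n_sites = report$config$n_sites,
                  n_trials = report$config$n_trials,
                  scenario = as.character(report$config$scenario),
                  prob = report$config$prob,
                  n_folds = report$config$n_folds,
                  enabled = report$config$enabled,
                  history = report$config$history,
                  seed = report$config$seed),
    dataset = report$dataset,
    trials = report$trials,
    injected = sum(report$truth$misconduct),
    cells = nrow(report$truth),
    tuned = report$tuned[c("beta", "gamma", "objective")],
    pooled = pooled,
    folds = lapply(cv$folds, function(f)
      list(fold = f$fold, beta = f$beta, gamma = f$gamma,
           objective = f$objective)),
    ablation = if (!is.null(report$ablation)) report$ablation$table)
}
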
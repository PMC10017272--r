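#' Misconduct type codes
#'
#' The ten threat models, grouped into three categories:
#' plagiarism (a copied model), fabrication (a mocked-up model) and
#' falsification (a tampered model).
#'
#' \describe{
#'   \item{1 self_plagiarism}{resubmit the same site's model from an earlier
#'     iteration (free-riding).}
#'   \item{2 others_plagiarism}{resubmit another site's earlier model.}
#'   \item{3 empty_fabrication}{all-zero gradient and matrix.}
#'   \item{4 random_fabrication}{every entry i.i.d. Uniform(-r, r).}
#'   \item{5 gaussian_fabrication}{every entry i.i.d. N(0, sigma^2).}
#'   \item{6 opposite_falsification}{negate the gradient (reverses the
#'     update direction); matrix unchanged.}
#'   \item{7 cosine_falsification}{replace the gradient by a same-norm vector
#'     with cosine similarity exactly c to the original; matrix unchanged.}
#'   \item{8 random_falsification}{add Uniform(-r, r) noise to the gradient,
#'     r = noise_scale * max|g|; matrix unchanged.}
#'   \item{9 gaussian_falsification}{add N(0, (noise_scale * rms(g))^2) noise
#'     to the gradient; matrix unchanged.}
#'   \item{10 rounded_falsification}{round every entry of gradient and matrix
#'     to `digits` decimals.}
#' }
#'
#' Falsifications tamper only the gradient (the update direction and
#' magnitude) because they tweak an actual result; fabrications corrupt the
#' whole submission.
#'
#' @format Named integer vector of length 10.
#' @export
MISCONDUCT_TYPES <- c(self_plagiarism = 1L, others_plagiarism = 2L,
                      empty_fabrication = 3L, random_fabrication = 4L,
                      gaussian_fabrication = 5L, opposite_falsification = 6L,
                      cosine_falsification = 7L, random_falsification = 8L,
                      gaussian_falsification = 9L, rounded_falsification = 10L)

#' Category of a misconduct type
#'
#' @param type integer code(s) in 1..10.
#' @return `"plagiarism"`, `"fabrication"` or `"falsification"`.
#' @export
misconduct_category <- function(type) {
  out <- rep(NA_character_, length(type))
  out[type %in% 1:2] <- "plagiarism"
  out[type %in% 3:5] <- "fabrication"
  out[type %in% 6:10] <- "falsification"
  out
}

#' Injection configuration
#'
#' @param scenario `"all"` (each injected cell draws one of the 10 types
#'   uniformly), or a single type: an integer 1..10 or a name from
#'   [MISCONDUCT_TYPES].
#' @param prob per-local-model injection probability rho (default 0.25).
#' @param uniform_range r for random fabrication (entries Uniform(-r, r)).
#' @param gaussian_sd sigma for gaussian fabrication.
#' @param cosine_target target cosine similarity c for cosine falsification.
#' @param noise_scale relative scale for random/gaussian falsification noise.
#' @param digits decimals kept by rounded falsification.
#' @param seed integer seed.
#' @return An object of class `"injection_config"`.
#' @export
injection_config <- function(scenario = "all", prob = 0.25, uniform_range = 1,
                             gaussian_sd = 1, cosine_target = 0,
                             noise_scale = 0.5, digits = 2L, seed = 1L) {
  if (!(prob >= 0 && prob <= 1)) .stopf("prob must lie in [0, 1]")
  if (is.character(scenario) && scenario != "all") {
    if (!scenario %in% names(MISCONDUCT_TYPES))
      .stopf("unknown misconduct type '%s'", scenario)
    scenario <- MISCONDUCT_TYPES[[scenario]]
  }
  if (is.numeric(scenario)) {
    scenario <- as.integer(scenario)
    if (!scenario %in% 1:10) .stopf("scenario must be 'all' or a type in 1..10")
  }
  structure(list(scenario = scenario, prob = prob,
                 uniform_range = uniform_range, gaussian_sd = gaussian_sd,
                 cosine_target = cosine_target, noise_scale = noise_scale,
                 digits = as.integer(digits), seed = as.integer(seed)),
            class = "injection_config")
}

# earlier-published models eligible as a plagiarism source for m:
# same/other site, and strictly earlier in the stream (earlier trial, or
# same trial and earlier iteration)
.plagiarism_pool <- function(m, history, same_site) {
  Filter(function(h) {
    site_ok <- if (same_site) h$site == m$site else h$site != m$site
    earlier <- (!is.na(h$trial) && !is.na(m$trial) && h$trial != m$trial) ||
      h$iteration < m$iteration
    site_ok && earlier
  }, history)
}

# types applicable at a cell given the available history: plagiarism needs an
# eligible source model
.applicable_types <- function(m, history) {
  ok <- rep(TRUE, 10L)
  if (length(.plagiarism_pool(m, history, TRUE)) == 0L) ok[1L] <- FALSE
  if (length(.plagiarism_pool(m, history, FALSE)) == 0L) ok[2L] <- FALSE
  which(ok)
}

#' Apply one misconduct type to a local model
#'
#' Transforms a local model according to the type semantics documented in
#' [MISCONDUCT_TYPES]. Plagiarism types copy a complete (gradient, matrix)
#' pair from a uniformly chosen eligible historical model and signal an error
#' when the history contains none (iteration 1).
#'
#' Uses the current R RNG stream; seed it (or go through [inject_trace()])
#' for reproducibility.
#'
#' @param m the honest `"local_model"`.
#' @param type integer code 1..10.
#' @param history list of `"local_model"`s published earlier in the stream
#'   (all sites; earlier iterations of the same trial and, under stream-scoped
#'   injection, all models of earlier trials).
#' @param cfg an [injection_config()] supplying the magnitudes.
#' @return The tampered `"local_model"`.
#' @export
apply_misconduct <- function(m, type, history = list(),
                             cfg = injection_config()) {
  g <- m$gradient; H <- m$info_matrix
  p <- length(g)
  if (type %in% 1:2) {
    keep <- .plagiarism_pool(m, history, same_site = (type == 1L))
    if (length(keep) == 0L)
      .stopf("plagiarism (type %d) inapplicable at iteration %s: no eligible history",
             type, m$iteration)
    pick <- keep[[sample.int(length(keep), 1L)]]
    g <- pick$gradient; H <- pick$info_matrix
  } else if (type == 3L) {
    g <- rep(0, p); H <- matrix(0, p, p)
  } else if (type == 4L) {
    r <- cfg$uniform_range
    g <- stats::runif(p, -r, r)
    H <- matrix(stats::runif(p * p, -r, r), p, p)
  } else if (type == 5L) {
    g <- stats::rnorm(p, 0, cfg$gaussian_sd)
    H <- matrix(stats::rnorm(p * p, 0, cfg$gaussian_sd), p, p)
  } else if (type == 6L) {
    g <- -g
  } else if (type == 7L) {
    g <- .cosine_vector(g, cfg$cosine_target)
  } else if (type == 8L) {
    r <- cfg$noise_scale * max(abs(g))
    g <- g + stats::runif(p, -r, r)
  } else if (type == 9L) {
    g <- g + stats::rnorm(p, 0, cfg$noise_scale * sqrt(mean(g^2)))
  } else if (type == 10L) {
    g <- round(g, cfg$digits)
    H <- round(H, cfg$digits)
  } else .stopf("unknown misconduct type %s", type)
  local_model(g, H, trial = m$trial, iteration = m$iteration, site = m$site)
}

# same-norm vector with cosine similarity exactly `target` to g:
# ||g|| * (target * ghat + sqrt(1 - target^2) * what), what orthonormal to g
.cosine_vector <- function(g, target) {
  nrm <- sqrt(sum(g^2))
  if (nrm == 0) return(g)
  ghat <- g / nrm
  repeat {
    v <- stats::rnorm(length(g))
    w <- v - sum(v * ghat) * ghat
    wn <- sqrt(sum(w^2))
    if (wn > 1e-12) break
  }
  nrm * (target * ghat + sqrt(max(0, 1 - target^2)) * w / wn)
}

#' Inject misconducts into a training trace
#'
#' Walks the trace's local models in (iteration, site) order; each model is
#' independently selected with probability `cfg$prob` and, if selected,
#' replaced via [apply_misconduct()]. Under the `"all"` scenario the type is
#' drawn uniformly from the ten; a draw that is inapplicable at that cell
#' (plagiarism with no eligible source model) is redrawn among the applicable
#' types. Under a single-type scenario an inapplicable cell is skipped and
#' labelled honest. Global models are never tampered (recombining local
#' models exposes that immediately). Plagiarism copies from the trace as
#' already tampered — the adversary sees the published ledger.
#'
#' @param trace a `"training_trace"`.
#' @param cfg an [injection_config()]; `cfg$seed` makes the injection
#'   reproducible.
#' @param history list of `"local_model"`s published before this trace
#'   (earlier trials of the same stream); empty for an isolated trial.
#' @return List with `trace` (tampered copy) and `truth`, a data.frame with
#'   columns `trial`, `iteration`, `site`, `misconduct` (logical) and `type`
#'   (integer, NA on honest cells) — the ground-truth misconduct grid.
#' @export
inject_trace <- function(trace, cfg = injection_config(), history = list()) {
  stopifnot(inherits(trace, "training_trace"))
  set.seed(cfg$seed)
  n_it <- trace$n_iterations; n_sites <- trace$n_sites
  locals <- trace$locals
  rows <- vector("list", n_it * n_sites)
  k <- 0L
  for (it in seq_len(n_it)) {
    for (s in seq_len(n_sites)) {
      k <- k + 1L
      idx <- (it - 1L) * n_sites + s
      hit <- stats::runif(1) < cfg$prob
      type <- NA_integer_
      if (hit) {
        hist <- c(history,
                  if (it > 1L) locals[seq_len((it - 1L) * n_sites)] else list())
        appl <- .applicable_types(locals[[idx]], hist)
        if (identical(cfg$scenario, "all")) {
          type <- sample.int(10L, 1L)
          if (!type %in% appl) type <- appl[sample.int(length(appl), 1L)]
        } else if (cfg$scenario %in% appl) {
          type <- cfg$scenario
        } else {
          hit <- FALSE  # single-type scenario, inapplicable cell: skip
        }
        if (hit) locals[[idx]] <- apply_misconduct(locals[[idx]], type, hist, cfg)
      }
      rows[[k]] <- data.frame(trial = trace$trial, iteration = it, site = s,
                              misconduct = hit, type = if (hit) type else NA_integer_)
    }
  }
  tampered <- trace
  tampered$locals <- locals
  list(trace = tampered, truth = do.call(rbind, rows))
}

#' Inject misconducts into a list of traces
#'
#' Applies [inject_trace()] to each trial with a trial-indexed seed derived
#' from `cfg$seed`. Under the default `"stream"` history scope the plagiarism
#' source pool accumulates over trials in trace order (the adversary sees
#' every model already on the ledger); under `"trial"` scope each trial's
#' history starts empty.
#'
#' @param traces list of `"training_trace"` objects.
#' @param cfg an [injection_config()].
#' @param history history scope, `"stream"` (default) or `"trial"`.
#' @return List with `traces` (tampered) and `truth` (row-bound ground-truth
#'   grid over all trials).
#' @export
inject_traces <- function(traces, cfg = injection_config(),
                          history = c("stream", "trial")) {
  history <- match.arg(history)
  traces <- traces[order(vapply(traces, `[[`, 1L, "trial"))]
  carried <- list()
  out <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    cfg_t <- cfg
    cfg_t$seed <- derive_seed(cfg$seed, "inject", tr$trial)
    out[[i]] <- inject_trace(tr, cfg_t, history = carried)
    if (history == "stream")
      carried <- c(carried, out[[i]]$trace$locals)
  }
  list(traces = lapply(out, `[[`, "trace"),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Write / read ground-truth misconduct labels as CSV
#'
#' Columns: `trial`, `iteration`, `site`, `misconduct` (0/1), `type` (1..10,
#' empty on honest cells).
#'
#' @param truth ground-truth data.frame as produced by [inject_traces()].
#' @param path CSV file path.
#' @return `write_labels` returns `path` invisibly; `read_labels` returns the
#'   data.frame with a logical `misconduct` column.
#' @export
write_labels <- function(truth, path) {
  df <- truth
  df$misconduct <- as.integer(df$misconduct)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  df$misconduct <- df$misconduct == 1L
  df$type <- as.integer(df$type)
  df
}
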
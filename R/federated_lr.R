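#' Construct a local model
#'
#' A site's per-iteration submission in GLORE-style federated logistic
#' regression: the score (gradient) vector and the Fisher information
#' ("variance-covariance") matrix evaluated at the current global
#' coefficients on the site's local training data.
#'
#' @param gradient numeric vector of length d+1.
#' @param info_matrix (d+1) x (d+1) matrix; honest submissions are symmetric
#'   positive semi-definite, tampered ones need not be.
#' @param trial,iteration,site integer bookkeeping ids.
#' @return An object of class `"local_model"`.
#' @export
local_model <- function(gradient, info_matrix, trial = NA_integer_,
                        iteration = NA_integer_, site = NA_integer_) {
  gradient <- unname(as.numeric(gradient))
  info_matrix <- unname(as.matrix(info_matrix))
  dimnames(info_matrix) <- NULL
  if (length(gradient) != nrow(info_matrix) || nrow(info_matrix) != ncol(info_matrix))
    .stopf("gradient length must equal info_matrix dimension")
  structure(list(trial = as.integer(trial), iteration = as.integer(iteration),
                 site = as.integer(site), gradient = gradient,
                 info_matrix = info_matrix),
            class = "local_model")
}

#' Local sufficient statistics at the current global model
#'
#' With probabilities `p_i = sigmoid(x_i' b)` on the site's training rows,
#' computes the gradient `sum_i x_i (y_i - p_i)` and the information matrix
#' `sum_i p_i (1 - p_i) x_i x_i'` — the quantities a GLORE site shares in
#' place of patient-level data.
#'
#' @param site a `"site_dataset"` (training subset).
#' @param global_coefs numeric coefficient vector of length d+1.
#' @param trial,iteration bookkeeping ids stamped on the result.
#' @return A `"local_model"`.
#' @export
local_stats <- function(site, global_coefs, trial = NA_integer_,
                        iteration = NA_integer_) {
  stopifnot(inherits(site, "site_dataset"))
  X <- site$X
  if (ncol(X) != length(global_coefs))
    .stopf("coefficient length %d does not match design width %d",
           length(global_coefs), ncol(X))
  p <- stats::plogis(drop(X %*% global_coefs))
  g <- drop(crossprod(X, site$y - p))
  H <- crossprod(X, X * (p * (1 - p)))
  local_model(g, H, trial = trial, iteration = iteration, site = site$site_id)
}

#' One global Newton-Raphson step from pooled local statistics
#'
#' Combines the sites' local models by summation and takes the Newton step
#' `b_new = b + (sum_k H_k)^{-1} (sum_k g_k)`. Because the statistics are
#' additive over rows, this is algebraically identical to the centralized
#' Newton step on the pooled data.
#'
#' @param prev_coefs numeric coefficient vector of the previous global model.
#' @param locals list of `"local_model"` objects, one per site, same
#'   iteration and dimension.
#' @return Numeric vector of updated global coefficients.
#' @export
global_update <- function(prev_coefs, locals) {
  stopifnot(length(locals) >= 1L)
  d1 <- length(prev_coefs)
  if (any(vapply(locals, function(m) length(m$gradient), 1L) != d1))
    .stopf("local model dimension mismatch with global coefficients")
  it <- locals[[1]]$iteration
  g <- Reduce(`+`, lapply(locals, `[[`, "gradient"))
  H <- Reduce(`+`, lapply(locals, `[[`, "info_matrix"))
  step <- tryCatch(solve(H, g), error = function(e)
    .stopf("singular pooled information matrix at iteration %s: %s",
           ifelse(is.na(it), "?", it), conditionMessage(e)))
  out <- unname(prev_coefs + drop(step))
  if (!all(is.finite(out)))
    .stopf("non-finite global update at iteration %s", ifelse(is.na(it), "?", it))
  out
}

#' Solo update of the previous global model from one local model
#'
#' The coefficient vector a detecting site obtains by applying only one
#' site's local model to the previous global model:
#' `U = G_prev + H^{-1} g`. A singular or otherwise unusable information
#' matrix yields a *sentinel* update (`sentinel = TRUE`, NA coefficients)
#' that downstream detectors treat as maximally anomalous rather than an
#' error (an all-zero fabricated matrix must not crash detection).
#'
#' @param prev_coefs previous global coefficient vector.
#' @param m a `"local_model"`.
#' @return List with `coefficients` (numeric, NA if sentinel) and `sentinel`
#'   (logical), class `"solo_update"`.
#' @export
solo_update <- function(prev_coefs, m) {
  d1 <- length(prev_coefs)
  out <- rep(NA_real_, d1)
  sentinel <- TRUE
  if (length(m$gradient) == d1 && !.is_zero(m$info_matrix)) {
    step <- tryCatch(solve(m$info_matrix, m$gradient), error = function(e) NULL)
    if (!is.null(step) && all(is.finite(step))) {
      out <- prev_coefs + drop(step)
      sentinel <- FALSE
    }
  }
  structure(list(trial = m$trial, iteration = m$iteration, site = m$site,
                 coefficients = out, sentinel = sentinel),
            class = "solo_update")
}

#' Run federated logistic-regression training trials
#'
#' Simulates the decentralized training protocol: per trial, each site draws
#' a fresh 50% training sample ([sample_training()], trial-indexed seed),
#' the global model starts at zero, and iterations alternate local statistics
#' with the pooled Newton step until the maximum absolute coefficient change
#' drops below `tol` or `max_iter` is reached. Every local and global model
#' is recorded.
#'
#' @param sites list of `"site_dataset"` objects (the full site splits).
#' @param n_trials number of independent training trials (default 30).
#' @param max_iter iteration cap per trial (default 100).
#' @param tol convergence precision on the max absolute coefficient change
#'   (default 1e-6).
#' @param fraction training fraction per site per trial (default 0.5).
#' @param seed master seed; per-trial/per-site sampling seeds are derived.
#' @return List of `"training_trace"` objects, one per trial. Each trace has
#'   `global` (an (n_iterations+1) x (d+1) matrix whose first row is the zero
#'   initialization), `locals` (list ordered by iteration then site),
#'   `training` (the per-trial training `site_dataset`s), `n_iterations`,
#'   `n_sites` and `converged`.
#' @export
run_trials <- function(sites, n_trials = 30L, max_iter = 100L, tol = 1e-6,
                       fraction = 0.5, seed = 1L) {
  stopifnot(length(sites) >= 1L)
  n_sites <- length(sites)
  d1 <- ncol(sites[[1]]$X)
  lapply(seq_len(n_trials), function(t) {
    training <- lapply(sites, function(s)
      sample_training(s, fraction = fraction,
                      seed = derive_seed(seed, "training", t * 1000L + s$site_id)))
    G <- matrix(0, 1L, d1)
    locals <- list()
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      prev <- G[nrow(G), ]
      lm_it <- lapply(training, local_stats, global_coefs = prev,
                      trial = t, iteration = it)
      g_new <- tryCatch(global_update(prev, lm_it), error = function(e)
        .stopf("trial %d: %s", t, conditionMessage(e)))
      locals <- c(locals, lm_it)
      G <- rbind(G, g_new)
      if (max(abs(g_new - prev)) < tol) { converged <- TRUE; break }
    }
    rownames(G) <- NULL
    structure(list(trial = t, global = G, locals = locals,
                   n_iterations = nrow(G) - 1L, n_sites = n_sites,
                   converged = converged, training = training),
              class = "training_trace")
  })
}

#' @export
print.training_trace <- function(x, ...) {
  cat(sprintf("<training_trace trial %d: %d sites, %d iterations, %s>\n",
              x$trial, x$n_sites, x$n_iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Look up one local model in a trace
#'
#' @param trace a `"training_trace"`.
#' @param iteration,site indices (1-based).
#' @return The `"local_model"` at that cell.
#' @export
trace_local <- function(trace, iteration, site) {
  trace$locals[[(iteration - 1L) * trace$n_sites + site]]
}

#' Write / read training traces as JSON lines
#'
#' One record per model: local models as
#' `{"type":"local","trial":..,"iteration":..,"site":..,"gradient":[..],"matrix":[[..]]}`
#' and global models (iteration 0 is the initialization) as
#' `{"type":"global","trial":..,"iteration":..,"coefficients":[..]}`.
#' Numbers are serialized at full precision so a write/read round trip is
#' bit-exact.
#'
#' @param traces list of `"training_trace"` objects.
#' @param path file path.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns a
#'   list of `"training_trace"` objects (training data and convergence flag
#'   are not stored on disk and come back as `NULL`/`NA`).
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "training_trace")) traces <- list(traces)
  lines <- character(0)
  for (tr in traces) {
    lines <- c(lines, .json_global(tr$trial, 0L, tr$global[1L, ]))
    for (it in seq_len(tr$n_iterations)) {
      for (s in seq_len(tr$n_sites)) {
        m <- trace_local(tr, it, s)
        lines <- c(lines, as.character(jsonlite::toJSON(
          list(type = "local", trial = tr$trial, iteration = it, site = s,
               gradient = m$gradient,
               matrix = lapply(seq_len(nrow(m$info_matrix)),
                               function(i) unname(m$info_matrix[i, ]))),
          auto_unbox = TRUE, digits = I(17))))
      }
      lines <- c(lines, .json_global(tr$trial, it, tr$global[it + 1L, ]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.json_global <- function(trial, iteration, coefs) {
  as.character(jsonlite::toJSON(
    list(type = "global", trial = trial, iteration = iteration,
         coefficients = as.numeric(coefs)),
    auto_unbox = TRUE, digits = I(17)))
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
  trials <- sort(unique(vapply(recs, function(r) as.integer(r$trial), 1L)))
  lapply(trials, function(t) {
    rt <- Filter(function(r) r$trial == t, recs)
    gl <- Filter(function(r) r$type == "global", rt)
    lo <- Filter(function(r) r$type == "local", rt)
    gl <- gl[order(vapply(gl, function(r) r$iteration, 1))]
    G <- do.call(rbind, lapply(gl, function(r) as.numeric(r$coefficients)))
    n_sites <- max(vapply(lo, function(r) as.integer(r$site), 1L))
    n_it <- nrow(G) - 1L
    ord <- order(vapply(lo, function(r) r$iteration, 1),
                 vapply(lo, function(r) r$site, 1))
    locals <- lapply(lo[ord], function(r)
      local_model(r$gradient,
                  if (is.matrix(r$matrix)) r$matrix else do.call(rbind, r$matrix),
                  trial = t, iteration = r$iteration, site = r$site))
    structure(list(trial = t, global = G, locals = locals,
                   n_iterations = n_it, n_sites = n_sites,
                   converged = NA, training = NULL),
              class = "training_trace")
  })
}
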
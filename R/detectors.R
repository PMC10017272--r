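#' Detector parameters
#'
#' @param beta ModelChange Ratio in `[0, 1]`: the Coefficient detector fires
#'   when the fraction of coefficients whose trend reverses exceeds `beta`
#'   (strictly). `beta = 1` disables it in practice.
#' @param gamma AUC Difference Threshold in `[0, 1]`: the Performance
#'   detector fires when the absolute difference between the current solo
#'   update's AUC and the mean of all previous ones exceeds `gamma`
#'   (strictly). `gamma >= 1` disables it.
#' @param enabled subset of `c("auditing", "coefficient", "performance")`;
#'   disabled detectors contribute `FALSE` (ablation support).
#' @return An object of class `"detector_params"`.
#' @export
detector_params <- function(beta = 0.5, gamma = 0.15,
                            enabled = c("auditing", "coefficient", "performance")) {
  if (!(beta >= 0 && beta <= 1)) .stopf("beta must lie in [0, 1]")
  if (!(gamma >= 0 && gamma <= 1)) .stopf("gamma must lie in [0, 1]")
  bad <- setdiff(enabled, c("auditing", "coefficient", "performance"))
  if (length(bad)) .stopf("unknown detector(s): %s", paste(bad, collapse = ", "))
  structure(list(beta = beta, gamma = gamma, enabled = enabled),
            class = "detector_params")
}

#' Auditing detector: copies and empty submissions
#'
#' Flags a local model iff its (gradient, matrix) pair is entry-wise
#' identical to any historical local model of the same trial (any site,
#' earlier iteration), or its gradient is all zeros, or its matrix is all
#' zeros. Exact equality keeps the false-positive rate on honest
#' continuous-covariate traces at zero.
#'
#' @param m the received `"local_model"`.
#' @param history list of `"local_model"`s with earlier iterations, same
#'   trial, all sites.
#' @return Logical.
#' @export
audit_detect <- function(m, history = list()) {
  if (.is_zero(m$gradient) || .is_zero(m$info_matrix)) return(TRUE)
  key <- .num_key(c(m$gradient, m$info_matrix))
  for (h in history) {
    if (length(h$gradient) == length(m$gradient) &&
        key == .num_key(c(h$gradient, h$info_matrix))) return(TRUE)
  }
  FALSE
}

#' Coefficient detector: trend reversal in solo updates
#'
#' With per-coefficient changes `dcur = U_T - U_(T-1)` and
#' `dprev = U_(T-1) - U_(T-2)`, coefficient j is *reversed* iff
#' `dcur[j] * dprev[j] < 0`. Fires iff the reversed fraction exceeds `beta`
#' (strict). Abstains (returns `FALSE`) with fewer than two usable historical
#' solo updates; a sentinel current update is flagged unconditionally.
#'
#' @param u_current the current `"solo_update"` (or a plain numeric vector).
#' @param u_history matrix whose rows are the earlier solo updates
#'   `U_1..U_(T-1)` (NA rows for sentinels), or a list of `"solo_update"`s.
#' @param beta ModelChange Ratio.
#' @return Logical.
#' @export
coefficient_detect <- function(u_current, u_history, beta) {
  cur <- if (inherits(u_current, "solo_update")) {
    if (u_current$sentinel) return(TRUE)
    u_current$coefficients
  } else as.numeric(u_current)
  if (anyNA(cur)) return(TRUE)
  U <- .solo_history_matrix(u_history, length(cur))
  n_hist <- nrow(U)
  if (n_hist < 2L) return(FALSE)
  last <- U[n_hist, ]; prev <- U[n_hist - 1L, ]
  if (anyNA(last) || anyNA(prev)) return(FALSE)  # sentinel in history: abstain
  frac <- mean((cur - last) * (last - prev) < 0)
  frac > beta
}

.solo_history_matrix <- function(u_history, d1) {
  if (is.matrix(u_history)) return(u_history)
  if (length(u_history) == 0L) return(matrix(numeric(0), 0L, d1))
  do.call(rbind, lapply(u_history, function(u)
    if (inherits(u, "solo_update")) u$coefficients else as.numeric(u)))
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)`, computed
#' from midranks; ties are credited 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    .stopf("roc_auc requires at least one positive and one negative label")
  r <- rank(scores)  # midranks: ties credited 0.5
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Detection context
#'
#' Everything a detecting site K may use at iteration T of one trial: its own
#' local patient-level data, the global-model history, the local-model
#' history of all sites at earlier iterations, and site S's solo-update
#' history with their AUCs on D_K. No other site's patient data is present.
#'
#' @param site_data the detecting site's `"site_dataset"` (D_K).
#' @param global_history matrix of global coefficients `G_0..G_(T-1)`, one
#'   row per iteration starting at the initialization.
#' @param local_history list of `"local_model"`s with iteration < T (all
#'   sites, same trial).
#' @param solo_history matrix of site S's earlier solo updates
#'   `U_S_1..U_S_(T-1)` (NA rows for sentinels).
#' @param auc_history numeric AUCs of those solo updates on `site_data` (NA
#'   for sentinels).
#' @return An object of class `"detection_context"`.
#' @export
detection_context <- function(site_data, global_history,
                              local_history = list(),
                              solo_history = NULL, auc_history = numeric(0)) {
  structure(list(site_data = site_data, global_history = global_history,
                 local_history = local_history, solo_history = solo_history,
                 auc_history = auc_history),
            class = "detection_context")
}

#' Performance detector: AUC drift of the solo update
#'
#' Scores the detecting site's data with the solo update, computes the ROC
#' AUC `a_T`, and fires iff `|a_T - mean(a_1..a_(T-1))| > gamma` (strict,
#' two-sided: a sudden jump is as anomalous as a drop). Abstains with no
#' usable historical AUC; a sentinel current update is flagged
#' unconditionally.
#'
#' @param u_current the current `"solo_update"`.
#' @param ctx a [detection_context()] (uses `site_data` and `auc_history`).
#' @param gamma AUC Difference Threshold.
#' @return Logical.
#' @export
performance_detect <- function(u_current, ctx, gamma) {
  if (inherits(u_current, "solo_update") && u_current$sentinel) return(TRUE)
  cur <- if (inherits(u_current, "solo_update")) u_current$coefficients else u_current
  if (anyNA(cur)) return(TRUE)
  hist <- ctx$auc_history[!is.na(ctx$auc_history)]
  if (length(hist) == 0L) return(FALSE)
  a_t <- roc_auc(stats::plogis(drop(ctx$site_data$X %*% cur)), ctx$site_data$y)
  abs(a_t - mean(hist)) > gamma
}

#' Combined misconduct decision for one local model
#'
#' OR over the enabled detectors: Auditing on the model itself; Coefficient
#' and Performance on the solo update `solo_update(G_(T-1), m)`. A model is
#' honest only if no enabled detector fires.
#'
#' @param m the received `"local_model"`.
#' @param ctx a [detection_context()].
#' @param params a [detector_params()].
#' @return List with `flagged` plus the per-detector booleans and the solo
#'   update used.
#' @export
detect_model <- function(m, ctx, params = detector_params()) {
  g_prev <- ctx$global_history[nrow(ctx$global_history), ]
  u <- solo_update(g_prev, m)
  aud <- "auditing" %in% params$enabled && audit_detect(m, ctx$local_history)
  coefd <- "coefficient" %in% params$enabled &&
    coefficient_detect(u, ctx$solo_history, params$beta)
  perf <- "performance" %in% params$enabled &&
    performance_detect(u, ctx, params$gamma)
  list(flagged = aud || coefd || perf, auditing = aud, coefficient = coefd,
       performance = perf, solo = u)
}

#' Per-cell detector statistics for a set of traces
#'
#' Precomputes, for every (trial, iteration, site) cell, the
#' threshold-independent quantities the three detectors need: the Auditing
#' flag, the sentinel flag of the solo update, the reversed-coefficient
#' fraction (NA when fewer than two usable historical solo updates exist) and
#' the absolute AUC deviation from the historical mean (NA when no usable
#' history exists). Thresholding these with any `(beta, gamma)` via
#' [detect_cells()] reproduces [detect_model()] cell by cell, which makes
#' grid tuning and cross-validation cheap.
#'
#' Under the default `"stream"` history scope the detectors' histories
#' accumulate over trials in trace order: all models ever published on the
#' ledger are historical, so only the very first iterations of the first
#' trial lack history. Under `"trial"` scope histories reset at every trial
#' boundary.
#'
#' @param traces list of `"training_trace"` objects (typically tampered).
#' @param site_data the detecting site's `"site_dataset"` (must contain both
#'   outcome classes).
#' @param history history scope, `"stream"` (default) or `"trial"`.
#' @return data.frame with columns `trial`, `iteration`, `site`, `audit`,
#'   `sentinel`, `rev_frac`, `auc_dev`.
#' @export
detector_stats <- function(traces, site_data, history = c("stream", "trial")) {
  history <- match.arg(history)
  if (inherits(traces, "training_trace")) traces <- list(traces)
  stopifnot(inherits(site_data, "site_dataset"))
  if (all(site_data$y == 1L) || all(site_data$y == 0L))
    .stopf("detecting site's data must contain both outcome classes")
  traces <- traces[order(vapply(traces, `[[`, 1L, "trial"))]
  n_sites <- max(vapply(traces, `[[`, 1L, "n_sites"))
  carry <- .empty_carry(n_sites)
  out <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    res <- .stats_one_trace(traces[[i]], site_data, carry)
    out[[i]] <- res$stats
    if (history == "stream") carry <- res$carry else carry <- .empty_carry(n_sites)
  }
  do.call(rbind, out)
}

.empty_carry <- function(n_sites) {
  list(keys = character(0),
       U = replicate(n_sites, NULL, simplify = FALSE),      # rows: past solo updates
       auc = replicate(n_sites, numeric(0), simplify = FALSE))
}

.stats_one_trace <- function(trace, site_data, carry) {
  n_it <- trace$n_iterations; n_sites <- trace$n_sites
  d1 <- ncol(trace$global)
  X <- site_data$X; y <- site_data$y

  # auditing: full-precision keys, empty checks
  keys <- character(n_it * n_sites)
  empty <- logical(n_it * n_sites)
  for (i in seq_along(trace$locals)) {
    m <- trace$locals[[i]]
    keys[i] <- .num_key(c(m$gradient, m$info_matrix))
    empty[i] <- .is_zero(m$gradient) || .is_zero(m$info_matrix)
  }

  U <- array(NA_real_, c(n_it, n_sites, d1))
  sent <- matrix(FALSE, n_it, n_sites)
  auc <- matrix(NA_real_, n_it, n_sites)
  for (it in seq_len(n_it)) {
    g_prev <- trace$global[it, ]  # row `it` is G_(it-1)
    for (s in seq_len(n_sites)) {
      u <- solo_update(g_prev, trace_local(trace, it, s))
      sent[it, s] <- u$sentinel
      if (!u$sentinel) {
        U[it, s, ] <- u$coefficients
        auc[it, s] <- roc_auc(stats::plogis(drop(X %*% u$coefficients)), y)
      }
    }
  }

  # per-site solo/AUC histories including the carried-in stream prefix
  Uh <- lapply(seq_len(n_sites), function(s)
    rbind(carry$U[[s]], matrix(U[, s, ], n_it, d1)))
  ah <- lapply(seq_len(n_sites), function(s) c(carry$auc[[s]], auc[, s]))
  n0 <- if (is.null(carry$U[[1L]])) 0L else nrow(carry$U[[1L]])

  rows <- vector("list", n_it * n_sites)
  k <- 0L
  for (it in seq_len(n_it)) {
    hist_keys <- c(carry$keys, keys[seq_len((it - 1L) * n_sites)])
    for (s in seq_len(n_sites)) {
      k <- k + 1L
      idx <- (it - 1L) * n_sites + s
      aud <- empty[idx] || keys[idx] %in% hist_keys
      pos <- n0 + it  # row of the current cell in the site's stream history
      rev_frac <- NA_real_
      if (pos >= 3L && !sent[it, s]) {
        last <- Uh[[s]][pos - 1L, ]; prev <- Uh[[s]][pos - 2L, ]
        if (!anyNA(last) && !anyNA(prev)) {
          dcur <- U[it, s, ] - last
          dprev <- last - prev
          rev_frac <- mean(dcur * dprev < 0)
        }
      }
      auc_dev <- NA_real_
      if (!sent[it, s] && pos >= 2L) {
        hist <- ah[[s]][seq_len(pos - 1L)]
        hist <- hist[!is.na(hist)]
        if (length(hist) > 0L) auc_dev <- abs(auc[it, s] - mean(hist))
      }
      rows[[k]] <- data.frame(trial = trace$trial, iteration = it, site = s,
                              audit = aud, sentinel = sent[it, s],
                              rev_frac = rev_frac, auc_dev = auc_dev)
    }
  }
  list(stats = do.call(rbind, rows),
       carry = list(keys = c(carry$keys, keys),
                    U = Uh, auc = ah))
}

#' Threshold precomputed detector statistics
#'
#' Applies detector parameters to the output of [detector_stats()], yielding
#' the per-cell detector decisions and their OR.
#'
#' @param stats data.frame from [detector_stats()].
#' @param params a [detector_params()].
#' @return `stats` with added logical columns `auditing`, `coefficient`,
#'   `performance`, `flagged`.
#' @export
detect_cells <- function(stats, params = detector_params()) {
  en <- params$enabled
  aud <- ("auditing" %in% en) & stats$audit
  coefd <- ("coefficient" %in% en) &
    (stats$sentinel | (!is.na(stats$rev_frac) & stats$rev_frac > params$beta))
  perf <- ("performance" %in% en) &
    (stats$sentinel | (!is.na(stats$auc_dev) & stats$auc_dev > params$gamma))
  out <- stats[, c("trial", "iteration", "site")]
  out$auditing <- aud
  out$coefficient <- coefd
  out$performance <- perf
  out$flagged <- aud | coefd | perf
  out
}

#' Detect misconducts over whole traces
#'
#' Convenience wrapper: [detector_stats()] followed by [detect_cells()].
#'
#' @inheritParams detector_stats
#' @inheritParams detect_cells
#' @return Per-cell decisions (see [detect_cells()]).
#' @export
detect_traces <- function(traces, site_data, params = detector_params()) {
  detect_cells(detector_stats(traces, site_data), params)
}
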
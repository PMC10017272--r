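#' Tuning grid for the detector thresholds
#'
#' Default grids cover beta in 0.1..1.0 (step 0.1) and gamma in 0.05..0.50
#' (step 0.05). The objective is fixed: Iteration-Site F1 of the combined
#' detector against ground truth.
#'
#' @param beta_grid,gamma_grid strictly increasing values within `[0, 1]`.
#' @return An object of class `"tuning_grid"`.
#' @export
tuning_grid <- function(beta_grid = seq(0.1, 1, by = 0.1),
                        gamma_grid = seq(0.05, 0.5, by = 0.05)) {
  check <- function(g, nm) {
    if (length(g) == 0L || any(diff(g) <= 0) || any(g < 0 | g > 1))
      .stopf("%s must be non-empty, strictly increasing and within [0, 1]", nm)
  }
  check(beta_grid, "beta_grid"); check(gamma_grid, "gamma_grid")
  structure(list(beta_grid = beta_grid, gamma_grid = gamma_grid),
            class = "tuning_grid")
}

#' Tuning objective: Iteration-Site F1
#'
#' Runs the combined detector at `(beta, gamma)` over all cells and returns
#' the Iteration-Site F1 against ground truth (zero-denominator convention of
#' [compute_metrics()]).
#'
#' @param stats per-cell detector statistics ([detector_stats()]).
#' @param truth ground-truth grid over the same cells.
#' @param beta,gamma detector thresholds.
#' @param enabled detector subset.
#' @return F1 in `[0, 1]`.
#' @export
objective_f1 <- function(stats, truth, beta, gamma,
                         enabled = c("auditing", "coefficient", "performance")) {
  det <- detect_cells(stats, detector_params(beta, gamma, enabled = enabled))
  compute_metrics(truth, det, "iteration_site")$f1
}

# fast aligned objective: truth$misconduct reordered to stats' row order
.aligned_truth <- function(stats, truth) {
  key_s <- paste(stats$trial, stats$iteration, stats$site)
  key_t <- paste(truth$trial, truth$iteration, truth$site)
  ix <- match(key_s, key_t)
  if (anyNA(ix) || length(key_s) != length(key_t))
    .stopf("detector statistics and ground truth do not cover the same cells")
  truth$misconduct[ix]
}

.make_objective <- function(stats, truth, enabled) {
  tv <- .aligned_truth(stats, truth)
  use_aud <- "auditing" %in% enabled
  use_coef <- "coefficient" %in% enabled
  use_perf <- "performance" %in% enabled
  rev_ok <- !is.na(stats$rev_frac)
  dev_ok <- !is.na(stats$auc_dev)
  function(beta, gamma) {
    fl <- (use_aud & stats$audit) |
      (use_coef & (stats$sentinel | (rev_ok & stats$rev_frac > beta))) |
      (use_perf & (stats$sentinel | (dev_ok & stats$auc_dev > gamma)))
    .metrics_from_counts(.confusion(tv, fl), "iteration_site")$f1
  }
}

#' Greedy (coordinate-ascent) tuning of (beta, gamma)
#'
#' Starting from gamma fixed at the middle grid value, alternately scans one
#' parameter's grid holding the other fixed, keeping the value with the best
#' Iteration-Site F1; stops when a full sweep changes nothing. Ties are
#' broken toward the smaller parameter value. Terminates within
#' `length(beta_grid) * length(gamma_grid)` sweeps for any objective.
#'
#' @inheritParams objective_f1
#' @param grid a [tuning_grid()].
#' @return List with `beta`, `gamma`, `objective` (F1 at the optimum),
#'   `method = "greedy"`.
#' @export
greedy_tune <- function(stats, truth, grid = tuning_grid(),
                        enabled = c("auditing", "coefficient", "performance")) {
  stopifnot(inherits(grid, "tuning_grid"))
  obj <- .make_objective(stats, truth, enabled)
  bg <- grid$beta_grid; gg <- grid$gamma_grid
  gamma <- gg[ceiling(length(gg) / 2)]
  beta <- bg[1L]
  best <- -Inf
  max_sweeps <- length(bg) * length(gg)
  for (sweep in seq_len(max_sweeps)) {
    prev <- c(beta, gamma)
    vals_b <- vapply(bg, obj, numeric(1), gamma = gamma)
    beta <- bg[which.max(vals_b)]  # which.max takes the first (smallest) tie
    vals_g <- vapply(gg, function(g) obj(beta, g), numeric(1))
    gamma <- gg[which.max(vals_g)]
    best <- max(vals_g)
    if (identical(c(beta, gamma), prev)) break
  }
  list(beta = beta, gamma = gamma, objective = best, method = "greedy")
}

#' Exhaustive grid tuning of (beta, gamma)
#'
#' Evaluates the objective at every grid point. Cheap on the default 10 x 10
#' grid; serves as the reference the greedy search is compared against. Ties
#' are broken toward the smaller beta, then the smaller gamma.
#'
#' @inheritParams greedy_tune
#' @return List with `beta`, `gamma`, `objective`, `method = "exhaustive"`
#'   and `surface` (data.frame of F1 at every grid point).
#' @export
exhaustive_tune <- function(stats, truth, grid = tuning_grid(),
                            enabled = c("auditing", "coefficient", "performance")) {
  stopifnot(inherits(grid, "tuning_grid"))
  obj <- .make_objective(stats, truth, enabled)
  surface <- expand.grid(gamma = grid$gamma_grid, beta = grid$beta_grid)
  surface <- surface[, c("beta", "gamma")]
  surface$f1 <- mapply(obj, surface$beta, surface$gamma)
  ord <- order(-surface$f1, surface$beta, surface$gamma)
  top <- surface[ord[1L], ]
  list(beta = top$beta, gamma = top$gamma, objective = top$f1,
       method = "exhaustive", surface = surface)
}
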
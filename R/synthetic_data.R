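#' Specification of a synthetic binary-outcome dataset
#'
#' Describes a logistic-model dataset: covariate count, sample size, outcome
#' prevalence and the true coefficient vector. The packaged presets (see
#' [dataset_preset()]) emulate the shapes of three clinical datasets commonly
#' used for federated logistic regression benchmarking: a myocardial
#' infarction cohort (9 covariates, 1253 samples, 21.9% positive), a small
#' cancer-biomarker cohort (2 covariates, 141 samples, 63.8% positive) and a
#' large C. difficile infection cohort (25 covariates, 157493 samples, 1%
#' positive).
#'
#' When `coefficients` is `NULL`, half of the entries (the first
#' `ceiling(d/2)`) are drawn once from N(0, 1) under the spec seed and the
#' rest are zero, so the outcome carries real signal (AUC-based detection is
#' meaningful) while some covariates are pure noise.
#'
#' @param name identifier for the dataset.
#' @param n_samples number of records (>= 8, so four sites each retain a
#'   mixed-outcome 50% training sample).
#' @param n_covariates number of covariates `d`.
#' @param prevalence target positive fraction, strictly inside (0, 1).
#' @param coefficients true effects, length `d`; `NULL` for the default
#'   half-sparse draw.
#' @param covariate_model `"standard_normal"` (i.i.d. N(0,1) covariates) or
#'   `"bernoulli_mixture"` (binary indicators with per-column rates drawn
#'   uniformly in (0.2, 0.8), emulating clinical flags).
#' @param seed integer seed controlling the default coefficient draw and
#'   dataset generation.
#' @return An object of class `"dataset_spec"`.
#' @seealso [generate_dataset()], [dataset_preset()]
#' @export
dataset_spec <- function(name, n_samples, n_covariates, prevalence,
                         coefficients = NULL,
                         covariate_model = c("standard_normal", "bernoulli_mixture"),
                         seed = 1L) {
  covariate_model <- match.arg(covariate_model)
  n_samples <- as.integer(n_samples)
  n_covariates <- as.integer(n_covariates)
  if (n_samples < 8L) .stopf("n_samples must be >= 8, got %d", n_samples)
  if (n_covariates < 1L) .stopf("n_covariates must be >= 1")
  if (!(prevalence > 0 && prevalence < 1)) .stopf("prevalence must lie in (0, 1)")
  if (is.null(coefficients)) {
    n_active <- ceiling(n_covariates / 2)
    set.seed(derive_seed(seed, "coefficients"))
    coefficients <- c(stats::rnorm(n_active), rep(0, n_covariates - n_active))
  }
  if (length(coefficients) != n_covariates)
    .stopf("coefficients must have length %d", n_covariates)
  structure(list(name = as.character(name), n_samples = n_samples,
                 n_covariates = n_covariates, prevalence = prevalence,
                 coefficients = as.numeric(coefficients),
                 covariate_model = covariate_model, seed = as.integer(seed)),
            class = "dataset_spec")
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat(sprintf("<dataset_spec '%s': n = %d, d = %d, prevalence = %.3f, %s>\n",
              x$name, x$n_samples, x$n_covariates, x$prevalence, x$covariate_model))
  invisible(x)
}

#' Packaged dataset presets
#'
#' Returns the spec of one of the three packaged preset shapes (`"edin"`,
#' `"ca"`, `"cdiff"`; see [dataset_spec()]). The presets are stored as JSON
#' under `inst/extdata/presets/`. `scale` shrinks the sample size for
#' desk-scale runs while preserving the covariate count and prevalence.
#'
#' @param name preset name.
#' @param scale multiplier on the sample size (floored at 16 records).
#' @param seed seed passed to [dataset_spec()].
#' @return A `"dataset_spec"`.
#' @export
dataset_preset <- function(name = c("edin", "ca", "cdiff"), scale = 1, seed = 1L) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "fedaudit", mustWork = TRUE)
  read_dataset_spec(path, scale = scale, seed = seed)
}

#' Read / write a dataset spec as JSON
#'
#' @param path JSON file path.
#' @param scale,seed see [dataset_preset()]; applied on top of the stored
#'   fields. A `null`/absent `coefficients` field triggers the default draw.
#' @return `read_dataset_spec` returns a `"dataset_spec"`;
#'   `write_dataset_spec` returns `path` invisibly.
#' @export
read_dataset_spec <- function(path, scale = 1, seed = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- max(16L, as.integer(round(j$n_samples * scale)))
  dataset_spec(name = j$name, n_samples = n, n_covariates = j$n_covariates,
               prevalence = j$prevalence,
               coefficients = if (!is.null(j$coefficients) && length(j$coefficients)) j$coefficients,
               covariate_model = j$covariate_model %||% "standard_normal",
               seed = if (is.null(seed)) (j$seed %||% 1L) else seed)
}

#' @rdname read_dataset_spec
#' @param spec a `"dataset_spec"`.
#' @export
write_dataset_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bisection for the intercept b0 such that mean(sigmoid(b0 + eta)) = target.
# Monotone in b0, so bisection always converges for finite eta.
calibrate_intercept <- function(eta, target, tol = 1e-4, max_iter = 200L) {
  f <- function(b) mean(stats::plogis(b + eta)) - target
  lo <- -50; hi <- 50
  if (!is.finite(f(lo)) || !is.finite(f(hi)) || f(lo) > 0 || f(hi) < 0)
    .stopf("intercept calibration failed: target prevalence unreachable (pathological coefficients?)")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  .stopf("intercept calibration did not converge within %d bisection steps", max_iter)
}

#' Generate a synthetic logistic-model dataset
#'
#' Draws covariates according to the spec's covariate model, then calibrates
#' the intercept `b0` by bisection so that the mean predicted probability
#' `mean(sigmoid(b0 + X b))` equals the target prevalence within 1e-4, and
#' finally draws outcomes `y_i ~ Bernoulli(sigmoid(b0 + x_i b))`. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [dataset_spec()].
#' @return An object of class `"fed_dataset"`: list with `X` (n x d covariate
#'   matrix, no intercept column), `y` (0/1 vector), `intercept` (calibrated
#'   b0) and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  n <- spec$n_samples; d <- spec$n_covariates
  set.seed(derive_seed(spec$seed, "covariates"))
  X <- switch(spec$covariate_model,
    standard_normal = matrix(stats::rnorm(n * d), n, d),
    bernoulli_mixture = {
      rates <- stats::runif(d, 0.2, 0.8)
      matrix(stats::rbinom(n * d, 1L, rep(rates, each = n)), n, d)
    })
  colnames(X) <- paste0("x", seq_len(d))
  eta <- drop(X %*% spec$coefficients)
  b0 <- calibrate_intercept(eta, spec$prevalence)
  set.seed(derive_seed(spec$seed, "outcome"))
  y <- stats::rbinom(n, 1L, stats::plogis(b0 + eta))
  structure(list(X = X, y = as.integer(y), intercept = b0, spec = spec),
            class = "fed_dataset")
}

#' @export
print.fed_dataset <- function(x, ...) {
  cat(sprintf("<fed_dataset '%s': %d x %d, %.1f%% positive (target %.1f%%)>\n",
              x$spec$name, nrow(x$X), ncol(x$X), 100 * mean(x$y),
              100 * x$spec$prevalence))
  invisible(x)
}

#' Construct a site dataset
#'
#' A site's local design matrix (leading intercept column of ones) and
#' binary outcomes.
#'
#' @param site_id integer site identifier (1..N).
#' @param X n x (d+1) design matrix whose first column is all ones.
#' @param y 0/1 outcome vector of length n.
#' @return An object of class `"site_dataset"`.
#' @export
site_dataset <- function(site_id, X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) .stopf("X and y disagree in length")
  if (!all(X[, 1] == 1)) .stopf("column 1 of X must be the intercept (all ones)")
  if (!all(y %in% c(0L, 1L))) .stopf("y must be binary 0/1")
  structure(list(site_id = as.integer(site_id), X = X, y = as.integer(y)),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("<site_dataset %d: %d records, %d covariates, %d positive>\n",
              x$site_id, nrow(x$X), ncol(x$X) - 1L, sum(x$y)))
  invisible(x)
}

#' Split a dataset uniformly at random into sites
#'
#' Random partition of the records into `n_sites` parts whose sizes differ by
#' at most one (1253 records over 4 sites gives sizes 314/313/313/313). Each
#' part becomes a [site_dataset()] with an intercept column prepended.
#'
#' @param dataset a `"fed_dataset"` from [generate_dataset()].
#' @param n_sites number of participating sites (default 4).
#' @param seed integer seed for the permutation.
#' @return List of `n_sites` `"site_dataset"` objects.
#' @export
split_sites <- function(dataset, n_sites = 4L, seed = 1L) {
  stopifnot(inherits(dataset, "fed_dataset"))
  n <- nrow(dataset$X)
  if (n < n_sites) .stopf("cannot split %d samples into %d sites", n, n_sites)
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% n_sites, n_sites)
  extra <- n %% n_sites
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  offsets <- cumsum(c(0L, sizes))
  lapply(seq_len(n_sites), function(k) {
    ix <- perm[(offsets[k] + 1L):offsets[k + 1L]]
    X <- cbind(`(Intercept)` = 1, dataset$X[ix, , drop = FALSE])
    site_dataset(k, X, dataset$y[ix])
  })
}

#' Sample a training subset from a site
#'
#' Draws `round(fraction * n)` records (round half up) without replacement,
#' resampling until the subset contains at least one positive and one
#' negative outcome; after `max_retries` draws a stratified fallback forces
#' one record of each class. `fraction = 1` returns the site unchanged.
#'
#' @param site a `"site_dataset"` containing both outcome classes.
#' @param fraction training fraction (default 0.5).
#' @param seed integer seed.
#' @param max_retries rejection-sampling budget before the stratified
#'   fallback.
#' @return A `"site_dataset"` holding the sampled records.
#' @export
sample_training <- function(site, fraction = 0.5, seed = 1L, max_retries = 100L) {
  stopifnot(inherits(site, "site_dataset"))
  y <- site$y; n <- length(y)
  if (all(y == 1L) || all(y == 0L))
    .stopf("site %d has single-class outcomes; cannot sample a mixed training set",
           site$site_id)
  size <- floor(fraction * n + 0.5)
  size <- max(2L, min(n, as.integer(size)))
  if (size == n) return(site)
  set.seed(seed)
  for (i in seq_len(max_retries)) {
    ix <- sample.int(n, size)
    if (any(y[ix] == 1L) && any(y[ix] == 0L))
      return(site_dataset(site$site_id, site$X[ix, , drop = FALSE], y[ix]))
  }
  # stratified fallback: guarantee one of each class, fill the rest at random
  pos <- which(y == 1L); neg <- which(y == 0L)
  ix <- c(pos[sample.int(length(pos), 1L)], neg[sample.int(length(neg), 1L)])
  rest <- setdiff(seq_len(n), ix)
  if (size > 2L) ix <- c(ix, rest[sample.int(length(rest), size - 2L)])
  site_dataset(site$site_id, site$X[ix, , drop = FALSE], y[ix])
}

#' Read / write site data as CSV
#'
#' On disk a site is a plain CSV with covariate columns `x1..xd` followed by
#' an `outcome` column (0/1); when several sites share one file a leading
#' `site_id` column distinguishes them. The intercept column is never stored
#' and is added at load.
#'
#' @param sites a single `"site_dataset"` or a list of them.
#' @param path CSV file path.
#' @return `write_sites_csv` returns `path` invisibly; `read_sites_csv`
#'   returns a list of `"site_dataset"` objects (a single one if the file has
#'   no `site_id` column and `site_id` is given).
#' @export
write_sites_csv <- function(sites, path) {
  if (inherits(sites, "site_dataset")) sites <- list(sites)
  rows <- lapply(sites, function(s) {
    df <- as.data.frame(s$X[, -1, drop = FALSE])
    names(df) <- paste0("x", seq_len(ncol(df)))
    cbind(site_id = s$site_id, df, outcome = s$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_csv
#' @param site_id site id to assign when the file has no `site_id` column.
#' @export
read_sites_csv <- function(path, site_id = 1L) {
  df <- utils::read.csv(path)
  if (!"outcome" %in% names(df)) .stopf("site CSV lacks an 'outcome' column")
  has_id <- "site_id" %in% names(df)
  ids <- if (has_id) sort(unique(df$site_id)) else site_id
  lapply(ids, function(k) {
    sub <- if (has_id) df[df$site_id == k, , drop = FALSE] else df
    Xc <- as.matrix(sub[, grep("^x[0-9]+$", names(sub)), drop = FALSE])
    site_dataset(k, cbind(`(Intercept)` = 1, Xc), sub$outcome)
  })
}
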
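# shared fixtures and independent oracles

make_sites <- function(n = 80, d = 3, n_sites = 2, prevalence = 0.4, seed = 42) {
  spec <- dataset_spec("toy", n, d, prevalence, seed = seed)
  ds <- generate_dataset(spec)
  split_sites(ds, n_sites, seed = seed + 1L)
}

pool_sites <- function(sites) {
  list(X = do.call(rbind, lapply(sites, `[[`, "X")),
       y = unlist(lapply(sites, `[[`, "y")))
}

# centralized Newton-Raphson step on pooled rows (independent of the package's
# per-site path)
centralized_newton_step <- function(sites, coefs) {
  p <- pool_sites(sites)
  mu <- stats::plogis(drop(p$X %*% coefs))
  g <- drop(crossprod(p$X, p$y - mu))
  H <- crossprod(p$X, p$X * (mu * (1 - mu)))
  unname(coefs + drop(solve(H, g)))
}

# centralized IRLS fit via stats::glm.fit
centralized_glm <- function(sites) {
  p <- pool_sites(sites)
  fit <- stats::glm.fit(p$X, p$y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  unname(fit$coefficients)
}

# brute-force AUC by pairwise enumeration, ties credited 0.5
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# brute-force confusion counts on logical vectors
confusion_brute <- function(truth, pred) {
  c(tp = sum(truth & pred), fp = sum(!truth & pred),
    fn = sum(truth & !pred), tn = sum(!truth & !pred))
}

# a small honest training run shared by several tests
make_traces <- function(n_trials = 3, n = 160, d = 3, n_sites = 4, seed = 7) {
  sites <- make_sites(n = n, d = d, n_sites = n_sites, seed = seed)
  list(sites = sites,
       traces = run_trials(sites, n_trials = n_trials, seed = seed + 1L))
}

# grid data.frame of all (trial, iteration, site) cells with a logical column
grid_df <- function(values, n_it = 3, n_sites = 4, trial = 1L, col = "misconduct") {
  df <- expand.grid(site = seq_len(n_sites), iteration = seq_len(n_it))
  df <- data.frame(trial = trial, iteration = df$iteration, site = df$site)
  df[[col]] <- as.logical(values)
  df
}

# hand-built detector-stats rows for synthetic detector behavior
stats_df <- function(n, trial = 1L, n_sites = 4L,
                     audit = FALSE, sentinel = FALSE,
                     rev_frac = NA_real_, auc_dev = NA_real_) {
  it <- rep(seq_len(ceiling(n / n_sites)), each = n_sites)[seq_len(n)]
  st <- rep(seq_len(n_sites), length.out = n)
  data.frame(trial = trial, iteration = it, site = st,
             audit = rep_len(audit, n), sentinel = rep_len(sentinel, n),
             rev_frac = rep_len(rev_frac, n), auc_dev = rep_len(auc_dev, n))
}
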
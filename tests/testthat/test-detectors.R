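test_that("auditing flags exact copies and empty submissions, nothing else", {
  fx <- make_traces(n_trials = 1, n = 120, d = 2, n_sites = 4, seed = 61)
  tr <- fx$traces[[1]]
  history <- tr$locals[seq_len(4 * tr$n_sites)]  # iterations 1..4
  copied <- trace_local(tr, 2, 3)                # site 3's iteration-2 model
  copied$site <- 1L; copied$iteration <- 5L
  expect_true(audit_detect(copied, history))
  empty_g <- local_model(c(0, 0, 0), diag(3))
  expect_true(audit_detect(empty_g, history))
  empty_h <- local_model(c(1, 2, 3), matrix(0, 3, 3))
  expect_true(audit_detect(empty_h, history))
  fresh <- local_stats(tr$training[[1]], c(0.1, 0.1, 0.1))
  expect_false(audit_detect(fresh, history))
})

test_that("honest traces never trigger the auditing detector", {
  fx <- make_traces(n_trials = 3, n = 160, d = 3, n_sites = 4, seed = 63)
  st <- detector_stats(fx$traces, fx$sites[[1]])
  expect_equal(sum(st$audit), 0L)
  expect_equal(sum(st$sentinel), 0L)
})

test_that("roc_auc matches direct pairwise enumeration", {
  expect_equal(roc_auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.8, 0.8, 0.2), c(1, 0, 1)), 0.25)
  expect_error(roc_auc(c(0.4, 0.6), c(1, 1)), "positive and one negative")
  set.seed(71)
  for (i in 1:10) {
    scores <- round(runif(20), 1)  # coarse grid forces ties
    labels <- rbinom(20, 1, 0.4)
    if (all(labels == labels[1])) labels[1] <- 1 - labels[1]
    expect_equal(roc_auc(scores, labels), auc_pairwise(scores, labels))
  }
})

test_that("coefficient detector thresholds the reversal fraction strictly", {
  hist <- rbind(c(0.1, 0.1), c(0.2, 0.2))
  cur <- c(0.1, 0.3)  # coordinate 1 reverses, coordinate 2 keeps rising
  expect_true(coefficient_detect(cur, hist, beta = 0.4))
  expect_false(coefficient_detect(cur, hist, beta = 0.6))
  expect_false(coefficient_detect(cur, hist, beta = 0.5))  # tie: not flagged
  # monotone trajectories never fire
  mono <- rbind(c(0, 0), c(0.1, 0.2))
  expect_false(coefficient_detect(c(0.2, 0.4), mono, beta = 0))
  # abstention with insufficient history
  expect_false(coefficient_detect(cur, hist[1, , drop = FALSE], beta = 0))
  expect_false(coefficient_detect(cur, hist[0, , drop = FALSE], beta = 0))
  # a sentinel current update is always anomalous
  sent <- structure(list(coefficients = c(NA_real_, NA_real_), sentinel = TRUE),
                    class = "solo_update")
  expect_true(coefficient_detect(sent, hist, beta = 1))
})

test_that("beta = 1 disables the coefficient detector on any finite trajectory", {
  set.seed(73)
  for (i in 1:20) {
    hist <- matrix(rnorm(6), 3, 2)
    expect_false(coefficient_detect(rnorm(2), hist, beta = 1))
  }
})

test_that("performance detector compares the AUC against the historical mean", {
  sites <- make_sites(n = 100, d = 2, n_sites = 1, seed = 75)
  ctx <- detection_context(sites[[1]], global_history = matrix(0, 1, 3),
                           auc_history = c(0.8, 0.8, 0.8))
  # craft an update whose AUC we can read back
  u <- structure(list(coefficients = c(0, 1, 1), sentinel = FALSE),
                 class = "solo_update")
  a <- roc_auc(stats::plogis(drop(sites[[1]]$X %*% u$coefficients)), sites[[1]]$y)
  dev <- abs(a - 0.8)
  expect_equal(performance_detect(u, ctx, gamma = dev + 1e-9), FALSE)
  expect_equal(performance_detect(u, ctx, gamma = dev - 1e-9), TRUE)
  expect_false(performance_detect(u, ctx, gamma = dev))  # strict inequality
  # no history: abstain; sentinel: flag
  ctx0 <- detection_context(sites[[1]], matrix(0, 1, 3), auc_history = numeric(0))
  expect_false(performance_detect(u, ctx0, gamma = 0))
  sent <- structure(list(coefficients = rep(NA_real_, 3), sentinel = TRUE),
                    class = "solo_update")
  expect_true(performance_detect(sent, ctx, gamma = 1))
})

test_that("gamma >= 1 disables the performance detector", {
  sites <- make_sites(n = 100, d = 2, n_sites = 1, seed = 77)
  ctx <- detection_context(sites[[1]], matrix(0, 1, 3), auc_history = c(1, 1))
  u <- structure(list(coefficients = c(0, -1, -1), sentinel = FALSE),
                 class = "solo_update")
  expect_false(performance_detect(u, ctx, gamma = 1))
})

test_that("detect_model ORs the enabled detectors and honors ablation", {
  fx <- make_traces(n_trials = 1, n = 160, d = 2, n_sites = 4, seed = 79)
  tr <- fx$traces[[1]]
  stopifnot(tr$n_iterations >= 4)
  T_ <- 4L
  history <- tr$locals[seq_len((T_ - 1L) * tr$n_sites)]
  # plagiarized-but-plausible model: copy of the same site's previous model
  copy <- trace_local(tr, T_ - 1L, 2L)
  copy$iteration <- T_
  solo_hist <- do.call(rbind, lapply(seq_len(T_ - 1L), function(it)
    solo_update(tr$global[it, ], trace_local(tr, it, 2L))$coefficients))
  aucs <- apply(solo_hist, 1, function(b)
    roc_auc(stats::plogis(drop(fx$sites[[1]]$X %*% b)), fx$sites[[1]]$y))
  ctx <- detection_context(fx$sites[[1]],
                           global_history = tr$global[seq_len(T_), , drop = FALSE],
                           local_history = history,
                           solo_history = solo_hist, auc_history = aucs)
  full <- detect_model(copy, ctx, detector_params(beta = 1, gamma = 1))
  expect_true(full$auditing)
  expect_true(full$flagged)   # OR semantics: auditing alone suffices
  ablated <- detect_model(copy, ctx,
                          detector_params(beta = 1, gamma = 1,
                                          enabled = c("coefficient", "performance")))
  expect_false(ablated$flagged)  # the copy is plausible without auditing
  none <- detect_model(trace_local(tr, T_, 3L), ctx,
                       detector_params(beta = 1, gamma = 1))
  expect_false(none$flagged)
})

test_that("single-model detection agrees with the vectorized statistics path", {
  fx <- make_traces(n_trials = 1, n = 160, d = 2, n_sites = 4, seed = 81)
  inj <- inject_traces(fx$traces, injection_config("all", prob = 0.4, seed = 5))
  tr <- inj$traces[[1]]
  site1 <- fx$sites[[1]]
  params <- detector_params(beta = 0.3, gamma = 0.1)
  st <- detector_stats(inj$traces, site1)
  cells <- detect_cells(st, params)
  # rebuild per-cell contexts independently and compare decisions
  n_sites <- tr$n_sites
  solos <- lapply(seq_len(n_sites), function(s)
    lapply(seq_len(tr$n_iterations), function(it)
      solo_update(tr$global[it, ], trace_local(tr, it, s))))
  for (T_ in seq_len(tr$n_iterations)) {
    for (s in seq_len(n_sites)) {
      hist <- if (T_ > 1L) tr$locals[seq_len((T_ - 1L) * n_sites)] else list()
      sh <- if (T_ > 1L)
        do.call(rbind, lapply(solos[[s]][seq_len(T_ - 1L)], `[[`, "coefficients"))
      else matrix(numeric(0), 0, 3)
      ah <- vapply(seq_len(T_ - 1L), function(it) {
        u <- solos[[s]][[it]]
        if (u$sentinel) NA_real_
        else roc_auc(stats::plogis(drop(site1$X %*% u$coefficients)), site1$y)
      }, numeric(1))
      ctx <- detection_context(site1, tr$global[seq_len(T_), , drop = FALSE],
                               local_history = hist, solo_history = sh,
                               auc_history = ah)
      one <- detect_model(trace_local(tr, T_, s), ctx, params)
      row <- cells[cells$iteration == T_ & cells$site == s, ]
      expect_equal(one$flagged, row$flagged,
                   info = sprintf("iteration %d site %d", T_, s))
    }
  }
})

test_that("detector histories can span trials in stream scope", {
  fx <- make_traces(n_trials = 2, n = 160, d = 2, n_sites = 4, seed = 83)
  st_stream <- detector_stats(fx$traces, fx$sites[[1]], history = "stream")
  st_trial <- detector_stats(fx$traces, fx$sites[[1]], history = "trial")
  t2 <- st_stream$trial == 2L & st_stream$iteration <= 2L
  # stream scope: trial 2's first iterations have usable histories
  expect_true(all(!is.na(st_stream$auc_dev[t2])))
  expect_true(all(!is.na(st_stream$rev_frac[t2])))
  # trial scope: they abstain
  expect_true(all(is.na(st_trial$auc_dev[st_trial$trial == 2L &
                                           st_trial$iteration == 1L])))
  expect_true(all(is.na(st_trial$rev_frac[st_trial$trial == 2L &
                                            st_trial$iteration <= 2L])))
  # trial 1 rows agree between the scopes
  expect_identical(st_stream[st_stream$trial == 1L, ],
                   st_trial[st_trial$trial == 1L, ])
  # and a plagiarized copy across trials is audit-visible only in stream scope
  tam <- fx$traces
  tam[[2]]$locals[[1]] <- trace_local(fx$traces[[1]], 2, 3)
  tam[[2]]$locals[[1]]$trial <- 2L
  s2 <- detector_stats(tam, fx$sites[[1]], history = "stream")
  expect_true(s2$audit[s2$trial == 2L & s2$iteration == 1L & s2$site == 1L])
  s3 <- detector_stats(tam, fx$sites[[1]], history = "trial")
  expect_false(s3$audit[s3$trial == 2L & s3$iteration == 1L & s3$site == 1L])
})
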
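honest_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- make_traces(n_trials = 3, n = 160, d = 3,
                                        n_sites = 4, seed = 7)
    fx
  }
})

test_that("probability zero leaves the trace untouched with an all-false grid", {
  fx <- honest_fixture()
  inj <- inject_traces(fx$traces, injection_config("all", prob = 0, seed = 1))
  expect_false(any(inj$truth$misconduct))
  expect_identical(lapply(inj$traces, `[[`, "locals"),
                   lapply(fx$traces, `[[`, "locals"))
})

test_that("probability one with empty fabrication zeroes every local model", {
  fx <- honest_fixture()
  inj <- inject_traces(fx$traces,
                       injection_config("empty_fabrication", prob = 1, seed = 2))
  expect_true(all(inj$truth$misconduct))
  for (tr in inj$traces) {
    expect_true(all(vapply(tr$locals, function(m)
      all(m$gradient == 0) && all(m$info_matrix == 0), TRUE)))
  }
})

test_that("injected fraction is within the binomial 99% CI of rho", {
  fx <- make_traces(n_trials = 12, n = 200, d = 3, n_sites = 4, seed = 51)
  inj <- inject_traces(fx$traces, injection_config("all", prob = 0.25, seed = 3))
  n <- nrow(inj$truth)
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.25)
  expect_gte(sum(inj$truth$misconduct), ci[1])
  expect_lte(sum(inj$truth$misconduct), ci[2])
})

test_that("opposite falsification negates the gradient and is an involution", {
  m <- local_model(c(0, 1), diag(2), trial = 1L, iteration = 2L, site = 1L)
  once <- apply_misconduct(m, 6L)
  expect_equal(once$gradient, c(0, -1))
  expect_equal(once$info_matrix, m$info_matrix)
  expect_equal(apply_misconduct(once, 6L)$gradient, m$gradient)
})

test_that("cosine falsification preserves the norm and hits the target cosine", {
  m <- local_model(c(3, 4), diag(2), trial = 1L, iteration = 2L, site = 1L)
  set.seed(9)
  out <- apply_misconduct(m, 7L, cfg = injection_config(cosine_target = 0))
  expect_equal(sqrt(sum(out$gradient^2)), 5, tolerance = 1e-10)
  expect_equal(sum(out$gradient * c(3, 4)), 0, tolerance = 1e-10)
  set.seed(9)
  half <- apply_misconduct(m, 7L, cfg = injection_config(cosine_target = 0.5))
  expect_equal(sum(half$gradient * c(3, 4)) / 25, 0.5, tolerance = 1e-10)
})

test_that("rounded falsification keeps the configured number of decimals", {
  m <- local_model(c(0.1234, -5.6789), matrix(0.98765, 2, 2) + diag(2),
                   trial = 1L, iteration = 2L, site = 1L)
  out <- apply_misconduct(m, 10L, cfg = injection_config(digits = 2))
  expect_equal(out$gradient, c(0.12, -5.68))
  expect_equal(out$info_matrix, round(m$info_matrix, 2))
})

test_that("plagiarism copies a complete eligible historical model bit-for-bit", {
  fx <- honest_fixture()
  tr <- fx$traces[[1]]
  m <- trace_local(tr, 4, 2)
  history <- tr$locals[seq_len(3 * tr$n_sites)]
  set.seed(4)
  self <- apply_misconduct(m, 1L, history)
  src <- Filter(function(h) h$site == 2L, history)
  expect_true(any(vapply(src, function(h)
    identical(h$gradient, self$gradient) &&
      identical(h$info_matrix, self$info_matrix), TRUE)))
  set.seed(4)
  other <- apply_misconduct(m, 2L, history)
  src_o <- Filter(function(h) h$site != 2L, history)
  expect_true(any(vapply(src_o, function(h)
    identical(h$gradient, other$gradient), TRUE)))
  # no eligible source: explicit failure
  m1 <- trace_local(tr, 1, 1)
  expect_error(apply_misconduct(m1, 1L, list()), "inapplicable")
})

test_that("relative falsification noise is bounded by its configured scale", {
  m <- local_model(c(2, -4, 1), diag(3), trial = 1L, iteration = 2L, site = 1L)
  set.seed(5)
  out <- apply_misconduct(m, 8L, cfg = injection_config(noise_scale = 0.5))
  expect_true(all(abs(out$gradient - m$gradient) <= 0.5 * 4))
  expect_equal(out$info_matrix, m$info_matrix)
})

test_that("tampered cells differ from the honest trace exactly where labelled", {
  fx <- honest_fixture()
  inj <- inject_traces(fx$traces, injection_config("all", prob = 0.4, seed = 6))
  for (i in seq_along(fx$traces)) {
    honest <- fx$traces[[i]]; tam <- inj$traces[[i]]
    truth_i <- inj$truth[inj$truth$trial == honest$trial, ]
    for (k in seq_len(nrow(truth_i))) {
      row <- truth_i[k, ]
      a <- trace_local(honest, row$iteration, row$site)
      b <- trace_local(tam, row$iteration, row$site)
      same <- identical(a$gradient, b$gradient) &&
        identical(a$info_matrix, b$info_matrix)
      if (row$misconduct) {
        # self-plagiarism can coincide only if an identical model existed,
        # which continuous training forbids
        expect_false(same)
        expect_true(row$type %in% 1:10)
        expect_false(is.na(misconduct_category(row$type)))
      } else {
        expect_true(same)
        expect_true(is.na(row$type))
      }
    }
  }
})

test_that("single-type plagiarism skips cells with no eligible source", {
  fx <- honest_fixture()
  # trial scope: iteration 1 never has a same-site earlier model
  inj <- inject_traces(fx$traces,
                       injection_config("self_plagiarism", prob = 1, seed = 8),
                       history = "trial")
  t1 <- inj$truth[inj$truth$iteration == 1L, ]
  expect_false(any(t1$misconduct))
  expect_true(all(inj$truth$misconduct[inj$truth$iteration > 1L]))
  # stream scope: only the very first trial's first iteration lacks history
  inj_s <- inject_traces(fx$traces,
                         injection_config("self_plagiarism", prob = 1, seed = 8),
                         history = "stream")
  first <- inj_s$truth$trial == 1L & inj_s$truth$iteration == 1L
  expect_false(any(inj_s$truth$misconduct[first]))
  expect_true(all(inj_s$truth$misconduct[!first]))
})

test_that("all-types scenario never labels plagiarism where it is inapplicable", {
  fx <- honest_fixture()
  inj <- inject_traces(fx$traces, injection_config("all", prob = 1, seed = 10),
                       history = "trial")
  it1 <- inj$truth[inj$truth$iteration == 1L, ]
  expect_true(all(it1$misconduct))
  expect_false(any(it1$type %in% 1:2))
})

test_that("injection is deterministic under the seed", {
  fx <- honest_fixture()
  a <- inject_traces(fx$traces, injection_config("all", prob = 0.3, seed = 11))
  b <- inject_traces(fx$traces, injection_config("all", prob = 0.3, seed = 11))
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$traces, `[[`, "locals"),
                   lapply(b$traces, `[[`, "locals"))
})

test_that("ground-truth labels survive a CSV round trip", {
  fx <- honest_fixture()
  inj <- inject_traces(fx$traces, injection_config("all", prob = 0.3, seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(inj$truth, path)
  back <- read_labels(path)
  expect_equal(back$misconduct, inj$truth$misconduct)
  expect_equal(back$type, inj$truth$type)
})
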
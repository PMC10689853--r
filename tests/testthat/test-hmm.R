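test_that("noiseless alternating trace is fitted exactly", {
  tr <- block_trace(c(1, 2), block_len = 1, n_blocks = 40, sd = 0)
  fit <- fit_hmm(tr, k_max = 2)
  expect_equal(fit$means, c(1, 2), tolerance = 1e-9)
  # strict alternation: off-diagonal transition probabilities near 1
  expect_gt(fit$trans[1, 2], 0.95)
  expect_gt(fit$trans[2, 1], 0.95)
  vp <- viterbi_path(fit, tr)
  expect_equal(vp$state, rep(c(1L, 2L), 20))
})

test_that("single-level noisy trace prunes to one state", {
  set.seed(3)
  tr <- tibble::tibble(time_s = (0:199) / 10,
                       intensity = rnorm(200, 1, 0.15))
  fit <- fit_hmm(tr, k_max = 3)
  expect_equal(fit$n_states, 1L)
  expect_equal(fit$means, 1, tolerance = 0.05)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  for (s in 1:5) {
    set.seed(s)
    y <- c(rnorm(60, 1, 0.15), rnorm(40, 2, 0.15),
           rnorm(50, 1, 0.2), rnorm(30, 3, 0.15))
    tr <- tibble::tibble(time_s = (seq_along(y) - 1) / 10, intensity = y)
    fit <- fit_hmm(tr, k_max = 3, n_restarts = 2, seed = s)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("Viterbi equals brute-force path enumeration on small instances", {
  set.seed(7)
  for (rep in 1:20) {
    K <- sample(2:3, 1)
    T_ <- sample(4:8, 1)
    mu <- sort(runif(K, 0.5, 3))
    sigma <- runif(K, 0.1, 0.4)
    A <- matrix(runif(K * K), K)
    A <- A / rowSums(A)
    init <- runif(K)
    init <- init / sum(init)
    y <- rnorm(T_, sample(mu, T_, replace = TRUE), 0.3)
    fit <- structure(list(means = mu, sds = sigma, trans = A, init = init),
                     class = "tk_hmm")
    tr <- tibble::tibble(time_s = (seq_len(T_) - 1) / 10, intensity = y)
    got <- viterbi_path(fit, tr)
    want <- oracle_viterbi(y, mu, sigma, A, init)
    expect_equal(got$state, want$path)
    expect_equal(attr(got, "logprob"), want$logprob, tolerance = 1e-8)
  }
})

test_that("zero-noise frame-aligned traces are decoded exactly", {
  m <- reference_model("neca_wt", bleach_rate = 0, static_fraction = 0)
  # frame-aligned dwells render without intermediate transition frames
  set.seed(9)
  states <- c(1, 2, 3, 2, 1, 2, 1, 2, 3, 2)
  dwell_frames <- sample(3:10, 10, replace = TRUE)
  path <- tibble::tibble(substate = states, state = states,
                         dwell_s = dwell_frames * 0.1)
  attr(path, "duration") <- sum(path$dwell_s)
  attr(path, "bleach_time") <- Inf
  tr <- render_trace(path, m, noise = FALSE)
  fit <- fit_hmm(tr, k_max = 3)
  vp <- viterbi_path(fit, tr)
  truth <- rep(states, dwell_frames)
  expect_equal(vp$state, truth)
  expect_equal(fit$means, c(1, 2, 3), tolerance = 1e-6)
})

test_that("pooled fitted emission means recover the generating levels", {
  cfg <- reference_config("apo_wt", n_traces = 40, seed = 15,
                          static_fraction = 0)
  ds <- simulate_dataset(cfg)
  sel <- select_traces(ds$traces)
  id <- idealize_traces(sel, seed = 15)
  two_state <- id$fits[id$fits$n_states == 2, ]
  lo <- tapply(two_state$mean, two_state$molecule_id, min)
  hi <- tapply(two_state$mean, two_state$molecule_id, max)
  expect_lt(abs(median(lo) - 1), 0.05)
  expect_lt(abs(median(hi) - 2), 0.05)
})

test_that("framewise decode accuracy is high at the reference noise level", {
  cfg <- reference_config("neca_wt", n_traces = 25, seed = 16,
                          static_fraction = 0)
  ds <- simulate_dataset(cfg)
  sel <- select_traces(ds$traces)
  id <- idealize_traces(sel, seed = 16)
  acc <- c()
  for (mid in unique(id$frames$molecule_id)) {
    g <- id$frames[id$frames$molecule_id == mid, ]
    tru <- ds$truth[ds$truth$molecule_id == mid, ]
    states <- true_frame_states(tru$path[[1]], ds$model, nrow(g))
    # map decoded levels to coarse states by nearest generating level
    dec <- vapply(g$level, function(v) which.min(abs(v - c(1, 2, 3))),
                  integer(1))
    acc <- c(acc, mean(dec == states))
  }
  expect_gt(mean(acc), 0.97)
})

test_that("dwell extraction censors trace ends and filters blips", {
  frames <- tibble::tibble(
    molecule_id = "m", time_s = (0:6) / 10,
    state = c(1, 1, 2, 2, 2, 1, 1), level = c(1, 1, 2, 2, 2, 1, 1))
  out <- extract_dwells(frames, 0.1, 2)
  completed <- out$dwells[!out$dwells$censored, ]
  expect_equal(nrow(completed), 1L)
  expect_equal(completed$state, 2)
  expect_equal(completed$duration_s, 0.3)
  expect_equal(completed$exit_state, 1)
  expect_equal(nrow(out$events), 1L)

  blip <- tibble::tibble(
    molecule_id = "m", time_s = (0:4) / 10,
    state = c(1, 1, 2, 1, 1), level = c(1, 1, 2, 1, 1))
  out2 <- extract_dwells(blip, 0.1, 2)
  expect_equal(nrow(out2$dwells), 1L)   # blip removed, one censored run
  expect_equal(nrow(out2$events), 0L)
  expect_identical(merge_short_dwells(c(1, 1, 2, 1, 1), 2), rep(1, 5))
})

test_that("completed dwells equal transition events exactly (bookkeeping)", {
  cfg <- reference_config("apo_wt", n_traces = 25, seed = 17,
                          static_fraction = 0)
  ds <- simulate_dataset(cfg)
  sel <- select_traces(ds$traces)
  id <- idealize_traces(sel, seed = 17)
  # consensus two-state labels: split fitted levels at the midpoint
  fr <- id$frames
  fr$coarse <- assign_state(fr$level, define_cutoffs(c(1, 2)))
  out <- extract_dwells(fr, 0.1, 2, state_col = "coarse")
  completed <- out$dwells[!out$dwells$censored, ]
  expect_equal(nrow(completed), nrow(out$events))
  # two-state system: every completed state-1 dwell exits to state 2
  n1 <- sum(completed$state == 1)
  n12 <- sum(out$events$from_state == 1 & out$events$to_state == 2)
  expect_equal(n1, n12)
})

test_that("short traces are rejected by the HMM precondition", {
  tr <- tibble::tibble(time_s = (0:9) / 10, intensity = rnorm(10, 1, 0.1))
  expect_error(fit_hmm(tr), "too short")
})
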
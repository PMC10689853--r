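test_that("zero-rate model dwells in the initial state for the whole window", {
  m <- kinetic_model(matrix(0, 2, 2), emission_means = c(1, 2),
                     bleach_rate = 0,
                     initial_distribution = c(1, 0))
  p <- simulate_hidden_path(m, t_end = 10, seed = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$state, 1L)
  expect_equal(p$dwell_s, 10)
})

test_that("dwell times are exponential with the substate exit rate", {
  m <- reference_model("apo_wt", bleach_rate = 0, static_fraction = 0)
  set.seed(2)
  dwells <- c()
  while (length(dwells) < 5000) {
    p <- simulate_hidden_path(m, t_end = 500)
    if (nrow(p) <= 2) next
    interior <- seq_len(nrow(p))[-c(1, nrow(p))]
    dwells <- c(dwells, p$dwell_s[interior][p$state[interior] == 1])
  }
  mu_hat <- mean(dwells)
  sem <- sd(dwells) / sqrt(length(dwells))
  expect_lt(abs(mu_hat - 1 / 0.345), 3 * sem + 0.02)
})

test_that("long-run occupancy matches the stationary distribution", {
  m <- reference_model("apo_wt", bleach_rate = 0, static_fraction = 0)
  p <- simulate_hidden_path(m, t_end = 5000, seed = 3)
  occ1 <- sum(p$dwell_s[p$state == 1]) / sum(p$dwell_s)
  expect_lt(abs(occ1 - 0.63), 0.02)
})

test_that("frame rendering integrates occupancy exactly and adds calibrated noise", {
  m <- kinetic_model(matrix(0, 3, 3), emission_means = c(1, 2, 3),
                     bleach_rate = 0, frame_interval = 0.1)
  # constant state 2, no noise: every frame exactly 2
  path <- tibble::tibble(substate = 2L, state = 2L, dwell_s = 1.0)
  attr(path, "duration") <- 1.0
  attr(path, "bleach_time") <- Inf
  tr <- render_trace(path, m, noise = FALSE)
  expect_equal(tr$intensity, rep(2, 10))

  # 0.05 s in state 3 then 0.05 s in state 2 within one frame -> 2.5
  path2 <- tibble::tibble(substate = c(3L, 2L), state = c(3L, 2L),
                          dwell_s = c(0.05, 0.05))
  attr(path2, "duration") <- 0.1
  attr(path2, "bleach_time") <- Inf
  tr2 <- render_trace(path2, m, noise = FALSE)
  expect_equal(tr2$intensity, 2.5)

  # noise moment check on a long constant segment
  m15 <- kinetic_model(matrix(0, 2, 2), emission_means = c(1, 2),
                       emission_sigma = 0.15, bleach_rate = 0,
                       initial_distribution = c(1, 0))
  p3 <- simulate_hidden_path(m15, t_end = 2000, seed = 4)
  tr3 <- render_trace(p3, m15, seed = 5)
  expect_lt(abs(sd(tr3$intensity) - 0.15), 0.01)
})

test_that("frames after photobleaching sit at baseline", {
  m <- kinetic_model(matrix(0, 2, 2), emission_means = c(1, 2),
                     bleach_rate = 0, initial_distribution = c(0, 1))
  path <- tibble::tibble(substate = 2L, state = 2L, dwell_s = 2)
  attr(path, "duration") <- 2
  attr(path, "bleach_time") <- 2
  tr <- render_trace(path, m, noise = FALSE, post_bleach_s = 1)
  expect_equal(tr$intensity[1:20], rep(2, 20))
  expect_equal(tr$intensity[21:30], rep(0, 10))
})

test_that("static trace count follows the deterministic rounding rule", {
  cfg <- reference_config("apo_wt", n_traces = 100, seed = 9)
  ds <- simulate_dataset(cfg)
  expect_equal(sum(ds$truth$static), floor(100 * 0.55 + 0.5))
  expect_true(all(ds$truth$n_transitions[ds$truth$static] == 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- reference_config("keq24", n_traces = 12, seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth$bleach_time_s, b$truth$bleach_time_s)
})

test_that("bleach times pooled over traces are exponential with mean 1/bleach_rate", {
  m <- reference_model("apo_wt")  # bleach mean 30 s
  set.seed(10)
  bt <- replicate(1000, {
    p <- simulate_hidden_path(m, t_end = 1e9)
    attr(p, "bleach_time")
  })
  expect_lt(abs(mean(bt) - 30) / 30, 0.10)
})

test_that("substate expansion yields the analytic bi-exponential dwell mixture", {
  m <- reference_model("substates", bleach_rate = 0, static_fraction = 0)
  set.seed(11)
  dwells <- c()
  while (length(dwells) < 5000) {
    p <- simulate_hidden_path(m, t_end = 2000)
    keep <- seq_len(nrow(p))[-c(1, nrow(p))]
    dwells <- c(dwells, p$dwell_s[keep][p$state[keep] == 1])
  }
  dwells <- dwells[1:5000]
  # entries into state 1 split 50/50 between exit rates 1.0 and 0.2
  mix_cdf <- function(q) 0.5 * pexp(q, 1.0) + 0.5 * pexp(q, 0.2)
  ks <- suppressWarnings(ks.test(dwells, mix_cdf))
  expect_gt(ks$p.value, 0.01)
})
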
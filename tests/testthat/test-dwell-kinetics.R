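test_that("Freedman-Diaconis width matches the direct formula", {
  # oracle: IQR by linear interpolation on 1..8 is Q3 - Q1 = 6.25 - 2.75
  x <- 1:8
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(q, c(2.75, 6.25))
  expect_equal(fd_bin_width(x), 2 * 3.5 / 8^(1 / 3))
  expect_equal(fd_bin_width(x), 3.5)
  # scale equivariance
  expect_equal(fd_bin_width(2 * x), 2 * fd_bin_width(x))
  # degenerate: all equal durations trigger the range fallback
  expect_equal(fd_bin_width(rep(2, 9)), 0)
  y <- c(rep(2, 30), 2.0001)
  expect_equal(fd_bin_width(y), diff(range(y)) / sqrt(31))
  expect_error(fd_bin_width(1:3), "at least 4")
})

test_that("noiseless exponential counts are recovered to machine precision", {
  x <- seq(0.05, 6, by = 0.1)
  counts <- 100 * exp(-0.5 * x)
  bins <- tibble::tibble(mid = x, count = counts,
                         sigma = sqrt(pmax(counts, 1)))
  fit <- tracekin:::exp_fit_one(bins, k_init = 1, A_init = 50)
  expect_equal(fit$A, 100, tolerance = 1e-6)
  expect_equal(fit$k, 0.5, tolerance = 1e-8)
})

test_that("bi-exponential fit recovers mixture parameters within 15%", {
  set.seed(21)
  k1 <- 2.0
  k2 <- 0.2
  d <- ifelse(runif(5000) < 0.5, rexp(5000, k1), rexp(5000, k2))
  fit <- fit_exponentials(d)
  expect_false(fit$bi$degenerate)
  expect_lt(abs(fit$bi$k1 - k1) / k1, 0.15)
  expect_lt(abs(fit$bi$k2 - k2) / k2, 0.15)
  # count-histogram amplitudes scale as p_i * k_i, so a 50/50 mixture has
  # an analytic fast-amplitude percentage of 100 k1 / (k1 + k2)
  a1_true <- 100 * k1 / (k1 + k2)
  expect_lt(abs(fit$bi$a1 - a1_true) / a1_true, 0.15)
  expect_equal(fit$bi$a1 + fit$bi$a2, 100, tolerance = 1e-6)
  expect_gte(fit$bi$k1, fit$bi$k2)
})

test_that("model selection is calibrated on mono and bi ground truth", {
  set.seed(22)
  mono_sel <- replicate(100, {
    select_model(fit_exponentials(rexp(500, 0.5)))
  })
  expect_gte(mean(mono_sel == "mono"), 0.8)

  # state-1 dwells of the substate model: 50/50 entries into exits 1.0/0.2
  bi_sel <- replicate(100, {
    d <- ifelse(runif(500) < 0.5, rexp(500, 1.0), rexp(500, 0.2))
    select_model(fit_exponentials(d))
  })
  expect_gte(mean(bi_sel == "bi"), 0.8)
})

test_that("identical reduced chi-squared falls to mono (parsimony)", {
  fit <- structure(list(
    mono = list(A = 10, k = 1, k_se = 0.1, red_chisq = 1.0),
    bi = list(A1 = 5, k1 = 2, A2 = 5, k2 = 0.5, a1 = 50, a2 = 50,
              red_chisq = 1.0, degenerate = FALSE,
              vcov = matrix(NA_real_, 4, 4)),
    n = 100), class = "tk_expfit")
  expect_equal(select_model(fit), "mono")
  fit$bi$red_chisq <- 0.85
  expect_equal(select_model(fit), "bi")
  fit$bi$degenerate <- TRUE
  expect_equal(select_model(fit), "mono")
})

test_that("weighted rate reduces correctly in closed form", {
  base <- list(mono = list(A = 10, k = 1, k_se = 0.1, red_chisq = 2),
               n = 100)
  # a2 = 0: weighted rate equals k1 exactly
  f0 <- structure(c(base, list(bi = list(
    A1 = 10, k1 = 1, A2 = 0, k2 = 0.25, a1 = 100, a2 = 0,
    red_chisq = 1, degenerate = FALSE,
    vcov = matrix(NA_real_, 4, 4)))), class = "tk_expfit")
  expect_equal(weighted_rate(f0, "bi")$k, 1)

  # a1 = a2 = 50%, k1 = 1, k2 = 0.25: 1/k = 0.5 + 2 -> k = 0.4
  f1 <- structure(c(base, list(bi = list(
    A1 = 5, k1 = 1, A2 = 5, k2 = 0.25, a1 = 50, a2 = 50,
    red_chisq = 1, degenerate = FALSE,
    vcov = matrix(NA_real_, 4, 4)))), class = "tk_expfit")
  expect_equal(weighted_rate(f1, "bi")$k, 0.4)

  # a1 = 70%, k1 = 1, a2 = 30%, k2 = 0.1 -> 1/3.7
  f2 <- structure(c(base, list(bi = list(
    A1 = 7, k1 = 1, A2 = 3, k2 = 0.1, a1 = 70, a2 = 30,
    red_chisq = 1, degenerate = FALSE,
    vcov = matrix(NA_real_, 4, 4)))), class = "tk_expfit")
  expect_equal(weighted_rate(f2, "bi")$k, 1 / 3.7, tolerance = 1e-9)
})

test_that("equilibrium ratio propagates uncertainty by the quadrature formula", {
  r <- keq_ratio(0.2, 0.1, 0.02, 0.01)
  expect_equal(r$keq, 2)
  expect_equal(r$sd, 2 * sqrt(0.01 + 0.01), tolerance = 1e-12)
  expect_equal(r$sd, 0.283, tolerance = 1e-3)
  expect_equal(keq_ratio(0.3, 0.3)$keq, 1)
  expect_error(keq_ratio(0, 1), "positive")
  # reciprocal pairs multiply to one by construction
  fw <- keq_ratio(0.55, 0.23)
  bw <- keq_ratio(0.23, 0.55)
  expect_equal(fw$keq * bw$keq, 1, tolerance = 1e-9)
})

test_that("mean occupancy pools exit classes with SEM", {
  dwells <- tibble::tibble(
    molecule_id = "m", state = c(1, 1, 1), duration_s = c(2, 3, 4),
    exit_state = c(2, 2, 2), level = 1, exit_level = 2,
    censored = FALSE)
  occ <- mean_occupancy(dwells)
  expect_equal(occ$mean_occupancy_s, 3)
  expect_equal(occ$sem, 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(occ$sem, 0.577, tolerance = 1e-3)
  # a single dwell has no SEM
  one <- dwells[1, ]
  expect_true(is.na(mean_occupancy(one)$sem))
  # sandwich bound: a dwell mixture over substate exit rates has its mean
  # between the reciprocals of the fastest and slowest total exit rate
  m <- reference_model("substates")
  exits <- rowSums(m$rates)[m$coarse_of == 1]
  entry <- m$rates[3, 1:2] / sum(m$rates[3, 1:2])
  mix_mean <- sum(entry / exits)
  expect_gte(mix_mean, 1 / max(exits))
  expect_lte(mix_mean, 1 / min(exits))
})

test_that("dwell_kinetics assembles per-class rates and keq tables", {
  set.seed(23)
  n <- 400
  dwells <- tibble::tibble(
    molecule_id = "m",
    state = rep(c(1, 2), each = n),
    duration_s = c(rexp(n, 0.55), rexp(n, 0.23)),
    exit_state = rep(c(2, 1), each = n),
    level = rep(c(1, 2), each = n), exit_level = rep(c(2, 1), each = n),
    censored = FALSE)
  kin <- dwell_kinetics(dwells)
  expect_equal(nrow(kin$rates), 2L)
  expect_equal(kin$keq$pair, "1,2")
  expect_lt(abs(kin$keq$keq - 0.55 / 0.23) / (0.55 / 0.23), 0.2)
  expect_equal(kin$occupancy$state, c(1, 2))
})
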
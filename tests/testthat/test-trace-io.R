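test_that("trace tables round-trip through delimited text", {
  cfg <- reference_config("apo_wt", n_traces = 4, seed = 5)
  ds <- simulate_dataset(cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_traces(ds$traces, f)
  back <- read_traces(f)
  expect_equal(nrow(back), nrow(ds$traces))
  expect_equal(back$intensity, ds$traces$intensity, tolerance = 1e-9)
  expect_equal(back$time_s, ds$traces$time_s, tolerance = 1e-9)
  expect_true(all(selection_log(back)$accepted))
})

test_that("malformed and irregular traces are rejected with logged reasons", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,time_s,intensity",
               "a,0.0,1.0", "a,0.1,1.1", "a,0.2,oops",
               "b,0.0,1.0", "b,0.1,1.2", "b,0.2,1.1",
               "c,0.0,1.0", "c,0.1,1.0", "c,0.35,1.0"), f)
  tr <- read_traces(f)
  lg <- selection_log(tr)
  expect_equal(sort(unique(tr$molecule_id)), "b")
  expect_match(lg$reason[lg$molecule_id == "a"], "malformed_row")
  expect_equal(lg$reason[lg$molecule_id == "c"], "nonuniform_spacing")
  expect_equal(sum(lg$accepted), 1L)
  # every molecule appears exactly once in the log
  expect_equal(sort(lg$molecule_id), c("a", "b", "c"))
})

test_that("missing required columns raise a format error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,t,intensity", "a,0,1"), f)
  expect_error(read_traces(f), "missing required column")
})

test_that("photobleach detection finds single-step drops and censors non-bleachers", {
  set.seed(6)
  drop_at <- 100
  y <- c(rnorm(drop_at - 1, 2, 0.15), rnorm(101, 0, 0.15))
  tr <- tibble::tibble(molecule_id = "m1",
                       time_s = (seq_along(y) - 1) * 0.1, intensity = y)
  bl <- detect_photobleach(tr)
  expect_false(bl$censored)
  expect_lt(abs(bl$bleach_frame - drop_at), 4)

  y2 <- rnorm(200, 2, 0.15)  # never drops
  tr2 <- tibble::tibble(molecule_id = "m2",
                        time_s = (seq_along(y2) - 1) * 0.1, intensity = y2)
  expect_true(detect_photobleach(tr2)$censored)

  # switching trace that ends in its lowest emission state is not "bleached"
  y3 <- c(rnorm(60, 2, 0.15), rnorm(140, 1, 0.15))
  tr3 <- tibble::tibble(molecule_id = "m3",
                        time_s = (seq_along(y3) - 1) * 0.1, intensity = y3)
  expect_true(detect_photobleach(tr3)$censored)
})

test_that("multi-step bleaching staircases are flagged, reversible switching is not", {
  set.seed(41)
  # two-dye staircase: 2 -> 1 -> baseline, strictly monotone
  y <- c(rnorm(60, 2, 0.15), rnorm(60, 1, 0.15), rnorm(60, 0, 0.15))
  tr <- tibble::tibble(molecule_id = "m", time_s = (seq_along(y) - 1) / 10,
                       intensity = y)
  expect_true(detect_photobleach(tr)$multistep)
  # conformational switching revisits levels: same levels, non-monotone
  y2 <- c(rnorm(40, 1, 0.15), rnorm(40, 2, 0.15), rnorm(40, 1, 0.15),
          rnorm(40, 0, 0.15))
  tr2 <- tibble::tibble(molecule_id = "m", time_s = (seq_along(y2) - 1) / 10,
                        intensity = y2)
  bl2 <- detect_photobleach(tr2)
  expect_false(bl2$multistep)
  expect_false(bl2$censored)
})

test_that("select_traces trims to the pre-bleach segment and logs rejections", {
  cfg <- reference_config("apo_wt", n_traces = 40, seed = 8)
  ds <- simulate_dataset(cfg)
  sel <- select_traces(ds$traces)
  lg <- selection_log(sel)
  expect_equal(nrow(lg), 40L)
  expect_true(all(table(lg$molecule_id) == 1))
  # recovered bleach-time mean within 10% of the generating 30 s
  truth <- ds$truth
  bl <- detect_photobleach(ds$traces)
  got <- bl$bleach_frame[!bl$censored] * 0.1
  want <- truth$bleach_time_s[match(bl$molecule_id[!bl$censored],
                                    truth$molecule_id)]
  expect_lt(median(abs(got - want)), 0.5)
})

test_that("normalization rescales to unit state-1 level and is idempotent", {
  tr <- tibble::tibble(molecule_id = "m", time_s = (0:5) / 10,
                       intensity = c(200, 400, 600, 200, 400, 200))
  nm <- normalize_traces(tr, 200)
  expect_equal(nm$intensity, c(1, 2, 3, 1, 2, 1))
  expect_identical(normalize_traces(nm, 1)$intensity, nm$intensity)
  expect_error(normalize_traces(tr, -1), "> 0")

  per <- tibble::tibble(molecule_id = "m", state1_mean = 200)
  expect_equal(normalize_traces(tr, per)$intensity, c(1, 2, 3, 1, 2, 1))
})

test_that("trace selection is monotone under dataset growth", {
  cfg <- reference_config("apo_wt", n_traces = 12, seed = 13)
  ds <- simulate_dataset(cfg)
  sel_small <- selection_log(select_traces(ds$traces))
  extra <- simulate_dataset(reference_config("apo_wt", n_traces = 6,
                                             seed = 14))$traces
  extra$molecule_id <- paste0("x", extra$molecule_id)
  sel_big <- selection_log(select_traces(dplyr::bind_rows(ds$traces, extra)))
  accepted_small <- sel_small$molecule_id[sel_small$accepted]
  accepted_big <- sel_big$molecule_id[sel_big$accepted]
  expect_true(all(accepted_small %in% accepted_big))
})
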
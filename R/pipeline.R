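#' Run the full trace-analysis pipeline
#'
#' Composes the whole analysis on either a simulated reference dataset or
#' a trace table: select traces with single-step photobleaching and trim
#' to the pre-bleach segment; idealize each trace with a per-trace
#' Gaussian HMM; normalize to the lowest-intensity state; keep dynamic
#' traces; build the transition density plot and derive consensus state
#' centers and cutoffs; compile the pooled intensity histogram and fit
#' multipeak Gaussians with TDP-fixed centers; classify transitions;
#' and fit per-class dwell-time kinetics (mono/bi-exponential selection,
#' amplitude-weighted rates, equilibrium rate-constant ratios, mean
#' occupancy times). Deterministic given the input and seed.
#'
#' @param config a [reference_config()] (simulated input), or `NULL` when
#'   `traces` is given.
#' @param traces long trace tibble (raw intensities including the
#'   post-bleach baseline), e.g. from [read_traces()].
#' @param n_states number of consensus states; `NULL` detects it from the
#'   TDP.
#' @param seed root seed for simulation and HMM restarts; defaults to the
#'   config seed.
#' @param condition label for the report.
#' @param k_max,min_dwell_frames,baseline_sd_mult,bin_width,n_restarts
#'   analysis parameters, see the stage functions.
#' @return object of class `tk_report`; see [tidy.tk_report()] and
#'   [glance.tk_report()].
#' @export
run_pipeline <- function(config = NULL, traces = NULL, n_states = NULL,
                         seed = NULL, condition = NULL, k_max = 3,
                         min_dwell_frames = 2, baseline_sd_mult = 3,
                         bin_width = 0.05, n_restarts = 5) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "tk_config"))
    if (is.null(seed)) seed <- config$seed
    if (is.null(condition)) condition <- config$name
    if (is.null(n_states)) n_states <- max(config$model$coarse_of)
    dataset <- simulate_dataset(config, seed = seed)
    traces <- dataset$traces
    frame_interval <- config$model$frame_interval
  } else {
    if (is.null(traces)) stop("supply `config` or `traces`", call. = FALSE)
    if (is.null(seed)) seed <- 1L
    if (is.null(condition)) {
      condition <- if ("condition" %in% names(traces)) {
        as.character(traces$condition[1])
      } else {
        "unnamed"
      }
    }
    t1 <- traces$time_s[traces$molecule_id == traces$molecule_id[1]]
    frame_interval <- stats::median(diff(sort(t1)))
  }

  n_total <- length(unique(traces$molecule_id))

  # -- selection: single-step photobleach, pre-bleach trim --
  selected <- select_traces(traces, baseline_sd_mult = baseline_sd_mult)
  sel_log <- selection_log(selected)
  n_selected <- sum(sel_log$accepted)
  if (n_selected == 0) stop("no traces passed selection", call. = FALSE)

  # -- per-trace HMM idealization (scale-free) --
  ideal <- idealize_traces(selected, k_max = k_max,
                           n_restarts = n_restarts, seed = seed)

  # -- normalize to the lowest-intensity state of each molecule --
  state1 <- ideal$fits |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(state1_mean = min(.data$mean), .groups = "drop")
  frames <- ideal$frames |>
    dplyr::left_join(state1, by = "molecule_id") |>
    dplyr::mutate(intensity = .data$intensity / .data$state1_mean,
                  level = .data$level / .data$state1_mean) |>
    dplyr::select(-"state1_mean")

  # -- dynamic classification --
  dyn <- classify_dynamic(frames, min_dwell_frames)
  dynamic_ids <- dyn$molecule_id[dyn$dynamic]
  n_dynamic <- length(dynamic_ids)
  if (n_dynamic == 0) stop("no dynamic traces after filtering", call. = FALSE)
  dframes <- frames[frames$molecule_id %in% dynamic_ids, ]

  # -- TDP from per-trace fitted levels --
  pass1 <- extract_dwells(dframes, frame_interval, min_dwell_frames)
  tdp <- build_tdp(pass1$events)
  centers <- find_peak_centers(tdp, n_states)
  cutoffs <- define_cutoffs(centers)
  K <- length(centers)

  # -- consensus coarse states; dwells and transitions --
  dframes$coarse <- assign_state(dframes$level, cutoffs)
  pass2 <- extract_dwells(dframes, frame_interval, min_dwell_frames,
                          state_col = "coarse")
  transitions <- classify_transitions(pass2$events, cutoffs)

  # -- population histogram and multipeak fit --
  hist <- compile_histogram(dframes, bin_width = bin_width)
  histfit <- fit_multipeak(hist, centers)
  areas <- peak_areas(histfit)

  # -- dwell-time kinetics --
  kinetics <- dwell_kinetics(pass2$dwells)

  structure(list(
    condition = condition, seed = seed, n_states = K,
    selection = tibble::tibble(
      total = n_total, accepted = n_selected,
      rejected = n_total - n_selected,
      dynamic = n_dynamic, static = n_selected - n_dynamic),
    selection_log = sel_log,
    centers = centers, boundaries = cutoffs$boundaries,
    areas = areas, red_chisq = histfit$red_chisq,
    histogram_fit = histfit, tdp = tdp,
    transitions = transitions, dwells = pass2$dwells,
    rates = kinetics$rates, keq = kinetics$keq,
    occupancy = kinetics$occupancy,
    frame_interval = frame_interval,
    version = as.character(utils::packageVersion("tracekin")),
    config_hash = config_fingerprint(list(
      condition = condition, seed = seed, k_max = k_max,
      min_dwell_frames = min_dwell_frames,
      baseline_sd_mult = baseline_sd_mult, bin_width = bin_width,
      n_restarts = n_restarts, n_states = n_states))),
    class = "tk_report")
}

# small deterministic fingerprint of the run configuration
config_fingerprint <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.tk_report <- function(x, ...) {
  cat(sprintf("<tk_report> %s (seed %d, config %s)\n",
              x$condition, x$seed, x$config_hash))
  cat(sprintf("  traces: %d total, %d accepted, %d dynamic\n",
              x$selection$total, x$selection$accepted, x$selection$dynamic))
  cat("  state centers:",
      paste(format(x$centers, digits = 3), collapse = ", "), "\n")
  cat("  fractional areas:",
      paste(sprintf("%.1f%%", 100 * x$areas$fraction), collapse = ", "),
      sprintf(" (red chi-sq %.2f)\n", x$red_chisq))
  if (!is.na(x$transitions$skip_fraction)) {
    cat(sprintf("  1<->%d transitions: %.2f%% of %d\n", x$n_states,
                100 * x$transitions$skip_fraction,
                x$transitions$n_transitions))
  }
  if (!is.null(x$keq) && nrow(x$keq) > 0) {
    cat("  k_eq:", paste(sprintf("(%s) %.2f +/- %.2f", x$keq$pair,
                                 x$keq$keq, x$keq$sd), collapse = "; "), "\n")
  }
  cat("  mean occupancy (s):",
      paste(sprintf("state %d: %.2f +/- %.2f", x$occupancy$state,
                    x$occupancy$mean_occupancy_s, x$occupancy$sem),
            collapse = "; "), "\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the machine-readable report (`report.json`) plus the intermediate
#' artifacts as delimited text: selection log, TDP grid, histogram with
#' fit, dwell table and per-class rate table.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "tk_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$selection_log, file.path(dir, "selection_log.tsv"))
  readr::write_tsv(tidy.tk_tdp(report$tdp), file.path(dir, "tdp_grid.tsv"))
  hf <- report$histogram_fit
  readr::write_tsv(
    tibble::tibble(bin_mid = hf$histogram$bin_mid,
                   count = hf$histogram$count, se = hf$histogram$se,
                   model = hf$fitted),
    file.path(dir, "histogram_fit.tsv"))
  readr::write_tsv(report$dwells, file.path(dir, "dwells.tsv"))
  readr::write_tsv(report$rates, file.path(dir, "rates.tsv"))
  jsonlite::write_json(report_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# list representation of the report for JSON serialization
report_json <- function(report) {
  list(
    condition = report$condition, seed = report$seed,
    version = report$version, config_hash = report$config_hash,
    n_states = report$n_states,
    selection = as.list(report$selection),
    centers = report$centers, boundaries = report$boundaries,
    areas = report$areas, red_chisq = report$red_chisq,
    transition_classes = report$transitions$classes,
    n_transitions = report$transitions$n_transitions,
    skip_fraction = report$transitions$skip_fraction,
    rates = report$rates, keq = report$keq,
    occupancy = report$occupancy)
}

#' Compare pipeline reports across conditions
#'
#' Aligns state areas, equilibrium rate-constant ratios and mean occupancy
#' times across two or more conditions and reports each condition's values
#' next to their change from the first (reference) condition. Conditions
#' with different state counts are compared on the shared states with a
#' warning.
#'
#' @param reports list of [run_pipeline()] results (>= 2).
#' @return object of class `tk_comparison`: list with `table` (one row per
#'   condition) and `deltas` (same columns, minus the first row's values).
#' @export
compare_conditions <- function(reports) {
  stopifnot(length(reports) >= 2,
            all(vapply(reports, inherits, logical(1), "tk_report")))
  Ks <- vapply(reports, function(r) r$n_states, numeric(1))
  K <- min(Ks)
  if (length(unique(Ks)) > 1) {
    warning("reports have different state counts; comparing the ", K,
            " shared state(s)", call. = FALSE)
  }
  row_of <- function(r) {
    out <- tibble::tibble(condition = r$condition)
    for (s in seq_len(K)) {
      out[[sprintf("area_state%d", s)]] <-
        if (s <= nrow(r$areas)) r$areas$fraction[s] else NA_real_
      occ <- r$occupancy$mean_occupancy_s[r$occupancy$state == s]
      out[[sprintf("occupancy_state%d", s)]] <-
        if (length(occ) == 1) occ else NA_real_
    }
    for (p in c("1,2", "2,3")) {
      if (p == "2,3" && K < 3) next
      v <- if (!is.null(r$keq)) r$keq$keq[r$keq$pair == p] else numeric(0)
      out[[paste0("keq_", gsub(",", "", p))]] <-
        if (length(v) == 1) v else NA_real_
    }
    out
  }
  tab <- dplyr::bind_rows(purrr::map(reports, row_of))
  num <- names(tab)[vapply(tab, is.numeric, logical(1))]
  deltas <- tab
  for (cn in num) deltas[[cn]] <- tab[[cn]] - tab[[cn]][1]
  structure(list(table = tab, deltas = deltas), class = "tk_comparison")
}

#' @export
print.tk_comparison <- function(x, ...) {
  cat("<tk_comparison>\n")
  print(x$table)
  cat("deltas vs first condition:\n")
  print(x$deltas)
  invisible(x)
}
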
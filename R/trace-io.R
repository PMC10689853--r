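#' Write traces to a delimited text file
#'
#' Long-form trace table: one row per frame with columns `molecule_id`,
#' `time_s`, `intensity` and any extra metadata columns (e.g. `condition`).
#'
#' @param traces tibble of traces (long form).
#' @param path output file; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(all(c("molecule_id", "time_s", "intensity") %in% names(traces)))
  if (grepl("\\.csv$", path)) {
    readr::write_csv(traces, path)
  } else {
    readr::write_tsv(traces, path)
  }
  invisible(path)
}

#' Read traces from a delimited text file
#'
#' Reads a long-form trace table (CSV or TSV, auto-detected), groups rows
#' by molecule and sorts them by time. Molecules with malformed rows
#' (non-numeric time or intensity) or with non-uniform frame spacing are
#' rejected and recorded in the selection log.
#'
#' @param path file with columns `molecule_id`, `time_s`, `intensity`
#'   (extra columns are kept).
#' @param spacing_tol tolerance (seconds) for uniform frame spacing.
#' @return tibble of accepted traces with a `selection_log` attribute
#'   (tibble `molecule_id`, `accepted`, `reason`); retrieve it with
#'   [selection_log()].
#' @export
read_traces <- function(path, spacing_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- suppressWarnings(readr::read_delim(
    path, delim = NULL, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())))
  need <- c("molecule_id", "time_s", "intensity")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw$.row <- seq_len(nrow(raw))
  raw$time_num <- suppressWarnings(as.numeric(raw$time_s))
  raw$int_num <- suppressWarnings(as.numeric(raw$intensity))

  log_entries <- list()
  keep <- list()
  for (id in unique(raw$molecule_id)) {
    g <- raw[raw$molecule_id == id, ]
    bad <- is.na(g$time_num) | is.na(g$int_num)
    if (any(bad)) {
      log_entries[[id]] <- tibble::tibble(
        molecule_id = id, accepted = FALSE,
        reason = sprintf("malformed_row:%s",
                         paste(g$.row[bad], collapse = ",")))
      next
    }
    g <- g[order(g$time_num), ]
    if (nrow(g) >= 3) {
      d <- diff(g$time_num)
      if (max(d) - min(d) > spacing_tol) {
        log_entries[[id]] <- tibble::tibble(
          molecule_id = id, accepted = FALSE, reason = "nonuniform_spacing")
        next
      }
    }
    log_entries[[id]] <- tibble::tibble(molecule_id = id, accepted = TRUE,
                                        reason = "ok")
    keep[[id]] <- g
  }
  extra <- setdiff(names(raw), c(need, ".row", "time_num", "int_num"))
  out <- dplyr::bind_rows(keep)
  if (nrow(out) == 0) {
    out <- tibble::tibble(molecule_id = character(), time_s = numeric(),
                          intensity = numeric())
  } else {
    out <- dplyr::tibble(molecule_id = out$molecule_id,
                         time_s = out$time_num, intensity = out$int_num,
                         out[, extra, drop = FALSE])
  }
  attr(out, "selection_log") <- dplyr::bind_rows(log_entries)
  out
}

#' Selection log of a trace table
#'
#' @param traces object carrying a `selection_log` attribute
#'   ([read_traces()], [select_traces()]).
#' @return tibble with one row per molecule: `molecule_id`, `accepted`,
#'   `reason`.
#' @export
selection_log <- function(traces) {
  attr(traces, "selection_log")
}

# Segment a smoothed trace into sustained levels: a new segment opens when
# the signal departs from the current level by more than `tol` and stays
# away for the confirmation window. Returns per-segment level and length.
segment_levels <- function(m, tol, confirm = 5) {
  n <- length(m)
  level <- numeric(0)
  len <- integer(0)
  cur <- stats::median(m[seq_len(min(10, n))])
  start <- 1L
  i <- 1L
  while (i <= n) {
    if (abs(m[i] - cur) > tol &&
        abs(stats::median(m[i:min(i + confirm - 1L, n)]) - cur) > tol) {
      level <- c(level, cur)
      len <- c(len, i - start)
      cur <- stats::median(m[i:min(i + 9L, n)])
      start <- i
    }
    i <- i + 1L
  }
  list(level = c(level, cur), length = c(len, n - start + 1L))
}

# Single-trace photobleach detection on an intensity vector.
# Returns list(bleach_frame, censored, multistep).
detect_photobleach_vec <- function(y, baseline_sd_mult = 3) {
  n <- length(y)
  if (n < 10) return(list(bleach_frame = NA_integer_, censored = TRUE,
                          multistep = FALSE))
  m <- stats::runmed(y, 5)
  noise_sd <- stats::mad(diff(y)) / sqrt(2)
  if (noise_sd <= 0) noise_sd <- stats::sd(y) / 10 + 1e-12
  baseline <- stats::median(m[max(1, n - 9):n])
  thr <- baseline + baseline_sd_mult * noise_sd

  above <- which(m >= thr)
  if (length(above) == 0 || max(above) >= n - 2) {
    # never sustainedly above threshold, or never drops for good
    return(list(bleach_frame = NA_integer_, censored = TRUE,
                multistep = FALSE))
  }
  bleach <- max(above) + 1L
  pre <- m[seq_len(bleach - 1L)]
  # the pre-bleach record must sit essentially entirely above the baseline
  # threshold, and the baseline must be detector background (well below the
  # emission levels) rather than the lowest emission state of a switching
  # trace; otherwise the trace never truly bleached
  if (mean(pre < thr) > 0.02 || baseline > 0.25 * stats::median(pre)) {
    return(list(bleach_frame = NA_integer_, censored = TRUE,
                multistep = FALSE))
  }
  # multi-step guard: dye loss is irreversible, so two or more distinct
  # sustained pre-baseline levels forming a monotone non-increasing
  # staircase indicate several fluorophores; reversible conformational
  # switching revisits levels and does not trip this
  seg <- segment_levels(as.vector(m), baseline_sd_mult * noise_sd)
  sustained <- seg$level[seg$length >= 10]
  multistep <- all(diff(seg$level) < 0) && length(sustained) >= 3 &&
    all(diff(sustained) < 0)
  list(bleach_frame = bleach, censored = FALSE, multistep = multistep)
}

#' Detect single-step photobleaching
#'
#' Locates, per molecule, the first frame after which the running median of
#' the intensity stays below `baseline + baseline_sd_mult * noise_sd` for
#' the remainder of the trace, where the baseline is the terminal sustained
#' level and the noise sd is estimated robustly from frame-to-frame
#' differences. Traces that never drop are censored; traces whose
#' post-drop record shows a second sustained non-baseline level are flagged
#' as multi-step.
#'
#' @param traces long tibble of traces.
#' @param baseline_sd_mult threshold multiplier on the noise sd.
#' @return tibble with one row per molecule: `molecule_id`, `bleach_frame`
#'   (NA when censored), `censored`, `multistep`.
#' @export
detect_photobleach <- function(traces, baseline_sd_mult = 3) {
  traces |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::summarise(
      res = list(detect_photobleach_vec(.data$intensity, baseline_sd_mult)),
      .groups = "drop") |>
    dplyr::mutate(
      bleach_frame = purrr::map_int(.data$res, ~ as.integer(.x$bleach_frame)),
      censored = purrr::map_lgl(.data$res, "censored"),
      multistep = purrr::map_lgl(.data$res, "multistep")) |>
    dplyr::select(-"res")
}

#' Select analyzable traces and trim them to the pre-bleach segment
#'
#' Applies the selection rules used for single-molecule trajectories:
#' a trace must show single-step photobleaching (censored and multi-step
#' traces are rejected) and retain at least `min_frames` pre-bleach frames.
#' Accepted traces are truncated to their pre-bleach segment, since all
#' downstream statistics (histograms, dwell times) concern pre-bleach
#' dynamics only.
#'
#' @param traces long tibble of traces.
#' @param baseline_sd_mult passed to [detect_photobleach()].
#' @param min_frames minimum pre-bleach frames for a trace to be usable.
#' @return tibble of pre-bleach frames of accepted molecules, with a
#'   `selection_log` attribute (reasons: `ok`, `no_single_step_bleach`,
#'   `multistep_bleach`, `too_short`).
#' @export
select_traces <- function(traces, baseline_sd_mult = 3, min_frames = 20) {
  bl <- detect_photobleach(traces, baseline_sd_mult)
  bl$reason <- dplyr::case_when(
    bl$multistep ~ "multistep_bleach",
    bl$censored ~ "no_single_step_bleach",
    bl$bleach_frame - 1L < min_frames ~ "too_short",
    TRUE ~ "ok")
  keep <- bl$molecule_id[bl$reason == "ok"]
  cut <- stats::setNames(bl$bleach_frame, bl$molecule_id)
  out <- traces |>
    dplyr::filter(.data$molecule_id %in% keep) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() < cut[.data$molecule_id[1]]) |>
    dplyr::ungroup()
  attr(out, "selection_log") <- tibble::tibble(
    molecule_id = bl$molecule_id, accepted = bl$reason == "ok",
    reason = bl$reason)
  out
}

#' Normalize traces to the lowest-intensity state
#'
#' Divides each molecule's intensities by its state-1 (lowest emission
#' level) mean, so that the inactive state sits at 1.0 and states above it
#' at integer multiples of the inter-state spacing. Normalization is
#' idempotent when `state1_mean = 1`.
#'
#' @param traces long tibble of traces.
#' @param state1_mean either a single positive number applied to all
#'   molecules or a tibble (`molecule_id`, `state1_mean`) with per-molecule
#'   values, typically the lowest fitted emission mean of the per-trace HMM.
#' @return tibble with normalized `intensity` and attribute
#'   `normalized = TRUE`.
#' @export
normalize_traces <- function(traces, state1_mean) {
  if (is.numeric(state1_mean) && length(state1_mean) == 1) {
    if (state1_mean <= 0) stop("`state1_mean` must be > 0", call. = FALSE)
    out <- dplyr::mutate(traces, intensity = .data$intensity / state1_mean)
  } else {
    stopifnot(is.data.frame(state1_mean),
              all(c("molecule_id", "state1_mean") %in% names(state1_mean)))
    if (any(state1_mean$state1_mean <= 0)) {
      stop("`state1_mean` must be > 0 for every molecule", call. = FALSE)
    }
    out <- traces |>
      dplyr::left_join(state1_mean, by = "molecule_id") |>
      dplyr::mutate(intensity = .data$intensity / .data$state1_mean) |>
      dplyr::select(-"state1_mean")
  }
  attr(out, "normalized") <- TRUE
  attr(out, "selection_log") <- attr(traces, "selection_log")
  out
}
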
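#' Fit a Gaussian-emission hidden Markov model to one trace
#'
#' Maximum-likelihood fit by Baum-Welch EM from multiple seeded restarts
#' (k-means-style quantile initialization of the means, jittered across
#' restarts; the noise sd initialized from a robust frame-difference
#' estimate; a sticky uniform transition matrix with 0.9 self-transition).
#' After fitting with `k_max` states, states whose emission means are
#' closer than the merge tolerance are combined and states with stationary
#' occupancy below 1% are pruned, and the model is refit with the reduced
#' state count until stable. The fit is scale-free: the merge tolerance is
#' interpreted relative to the lowest fitted emission mean, so raw
#' (unnormalized) traces are handled identically.
#'
#' @param trace tibble with columns `time_s` and `intensity` for a single
#'   molecule (pre-bleach segment, at least 20 frames).
#' @param k_max maximum number of emission states to consider.
#' @param n_restarts EM restarts per state count.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param merge_tol states with fitted means closer than
#'   `merge_tol * min(mean)` are merged (0.3 normalized units by default,
#'   well under the unit spacing between genuine states).
#' @param min_occupancy states below this stationary occupancy are pruned.
#' @param seed integer seed controlling the restart jitter.
#' @return object of class `tk_hmm`: fitted `means`, `sds` (ascending by
#'   mean), `trans` (per-frame transition probabilities), `init`,
#'   `occupancy`, `loglik`, `loglik_trace`, `converged`, `iterations`,
#'   `n_states`.
#' @export
fit_hmm <- function(trace, k_max = 3, n_restarts = 5, tol = 1e-6,
                    max_iter = 500, merge_tol = 0.3, min_occupancy = 0.01,
                    seed = 1) {
  y <- trace$intensity
  if (length(y) < 20) {
    stop("trace too short for HMM fitting (< 20 pre-bleach frames)",
         call. = FALSE)
  }
  set.seed(seed)
  k <- as.integer(k_max)
  fit <- NULL
  for (round in 1:5) {
    # the full restart budget matters only for the initial fit; refits at a
    # reduced state count start from an already-resolved level structure
    r_round <- if (round == 1) n_restarts else min(n_restarts, 2)
    fit <- fit_hmm_k(y, k, r_round, tol, max_iter)
    eff_tol <- if (min(fit$mu) > 0) merge_tol * min(fit$mu) else merge_tol
    groups <- merge_groups(fit$mu, eff_tol)
    occ_g <- as.numeric(tapply(fit$occupancy, groups, sum))
    keep_g <- which(occ_g >= min_occupancy)
    if (length(keep_g) == 0) keep_g <- which.max(occ_g)
    k_new <- length(keep_g)
    if (k_new == k) break
    k <- k_new
  }
  ord <- order(fit$mu)
  structure(list(
    means = fit$mu[ord], sds = fit$sigma[ord],
    trans = fit$trans[ord, ord, drop = FALSE],
    init = fit$init[ord], occupancy = fit$occupancy[ord],
    loglik = fit$loglik, loglik_trace = fit$loglik_trace,
    converged = fit$converged, iterations = fit$iterations,
    n_states = length(ord), n_frames = length(y)),
    class = "tk_hmm")
}

# single-linkage grouping of sorted means with gap threshold
merge_groups <- function(mu, tol) {
  ord <- order(mu)
  g <- integer(length(mu))
  gi <- 1L
  g[ord[1]] <- gi
  if (length(mu) > 1) {
    for (i in 2:length(mu)) {
      if (mu[ord[i]] - mu[ord[i - 1]] > tol) gi <- gi + 1L
      g[ord[i]] <- gi
    }
  }
  g
}

# best-of-restarts EM fit at fixed state count
fit_hmm_k <- function(y, k, n_restarts, tol, max_iter) {
  sigma_floor <- 1e-4
  sd0 <- stats::mad(diff(y)) / sqrt(2)
  if (!is.finite(sd0) || sd0 < 0.01 * max(abs(y), 1e-6)) {
    sd0 <- max(stats::sd(y), sigma_floor)
  }
  if (k == 1) {
    fit <- baum_welch_cpp(y, mean(y), max(stats::sd(y), sigma_floor),
                          matrix(1, 1, 1), 1, max_iter, tol, sigma_floor)
    return(fit)
  }
  centers0 <- as.numeric(stats::quantile(y, (2 * seq_len(k) - 1) / (2 * k)))
  spread <- max(diff(range(y)), 1e-6)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu0 <- if (r == 1) centers0 else {
      sort(centers0 + stats::rnorm(k, 0, 0.15 * spread))
    }
    A0 <- matrix(0.1 / (k - 1), k, k)
    diag(A0) <- 0.9
    fit <- baum_welch_cpp(y, mu0, rep(sd0, k), A0, rep(1 / k, k),
                          max_iter, tol, sigma_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' @export
print.tk_hmm <- function(x, ...) {
  cat(sprintf("<tk_hmm> %d state(s), loglik %.2f, %s in %d iterations\n",
              x$n_states, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("  means:", paste(format(x$means, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Viterbi decoding of a trace under a fitted HMM
#'
#' Computes the globally most probable state sequence and its joint
#' log-probability.
#'
#' @param fit a [fit_hmm()] result.
#' @param trace the tibble the model was fitted to.
#' @return tibble with columns `time_s`, `intensity`, `state` (index into
#'   the fit's states, ascending by mean) and `level` (fitted emission mean
#'   of the decoded state); attribute `logprob`.
#' @export
viterbi_path <- function(fit, trace) {
  v <- viterbi_cpp(trace$intensity, fit$means, fit$sds, fit$trans, fit$init)
  out <- tibble::tibble(time_s = trace$time_s,
                        intensity = trace$intensity,
                        state = as.integer(v$path),
                        level = fit$means[v$path])
  attr(out, "logprob") <- v$logprob
  out
}

#' Idealize every trace in a set
#'
#' Per-molecule HMM fit plus Viterbi decoding. The fit is performed on each
#' molecule's own intensity scale; use the lowest fitted emission mean per
#' molecule to normalize afterwards (see [normalize_traces()]).
#'
#' @param traces long tibble of (pre-bleach) traces.
#' @inheritParams fit_hmm
#' @return object of class `tk_idealized`: list with `frames` (tibble
#'   `molecule_id`, `time_s`, `intensity`, `state`, `level`) and `fits`
#'   (tibble `molecule_id`, `state`, `mean`, `sd`, `occupancy`, `loglik`,
#'   `converged`, `n_states`).
#' @export
idealize_traces <- function(traces, k_max = 3, n_restarts = 5, tol = 1e-6,
                            max_iter = 500, merge_tol = 0.3, seed = 1) {
  ids <- unique(traces$molecule_id)
  frames <- vector("list", length(ids))
  fits <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- traces[traces$molecule_id == ids[i], ]
    tr <- tr[order(tr$time_s), ]
    fit <- fit_hmm(tr, k_max = k_max, n_restarts = n_restarts, tol = tol,
                   max_iter = max_iter, merge_tol = merge_tol,
                   seed = seed + i)
    vp <- viterbi_path(fit, tr)
    vp$molecule_id <- ids[i]
    frames[[i]] <- vp[, c("molecule_id", "time_s", "intensity", "state",
                          "level")]
    fits[[i]] <- tibble::tibble(
      molecule_id = ids[i], state = seq_len(fit$n_states),
      mean = fit$means, sd = fit$sds, occupancy = fit$occupancy,
      loglik = fit$loglik, converged = fit$converged,
      n_states = fit$n_states)
  }
  structure(list(frames = dplyr::bind_rows(frames),
                 fits = dplyr::bind_rows(fits)),
            class = "tk_idealized")
}

#' @export
print.tk_idealized <- function(x, ...) {
  cat(sprintf("<tk_idealized> %d molecule(s), %d frames\n",
              length(unique(x$frames$molecule_id)), nrow(x$frames)))
  invisible(x)
}

#' Merge idealized runs shorter than the minimum dwell
#'
#' Suppresses single-frame blips from the decoded path: any run of
#' consecutive identical labels shorter than `min_frames` is absorbed into
#' its longer flanking run (the only neighbor at the trace edges),
#' repeating from the shortest offending run until every surviving run
#' meets the minimum.
#'
#' @param states vector of per-frame labels (integers or levels).
#' @param min_frames minimum surviving run length in frames.
#' @return vector of labels of the same length.
#' @export
merge_short_dwells <- function(states, min_frames = 2) {
  repeat {
    r <- rle(as.vector(states))
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_frames)
    if (length(short) == 0) break
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    if (i == 1) {
      donor <- 2
    } else if (i == length(r$lengths)) {
      donor <- i - 1
    } else {
      donor <- if (r$lengths[i + 1] > r$lengths[i - 1]) i + 1 else i - 1
    }
    states[starts[i]:ends[i]] <- r$values[donor]
  }
  states
}

#' Classify traces as dynamic or static
#'
#' A trace is dynamic when at least one transition survives minimum-dwell
#' filtering of its idealized path. Static traces are excluded from all
#' downstream statistics.
#'
#' @param idealized a [idealize_traces()] result (or its `frames` tibble).
#' @param min_dwell_frames minimum dwell filter, in frames.
#' @return tibble with one row per molecule: `molecule_id`, `dynamic`.
#' @export
classify_dynamic <- function(idealized, min_dwell_frames = 2) {
  frames <- if (inherits(idealized, "tk_idealized")) idealized$frames else idealized
  frames |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::summarise(
      dynamic = length(rle(merge_short_dwells(.data$state,
                                              min_dwell_frames))$values) > 1,
      .groups = "drop")
}

#' Extract dwells and transition events from idealized paths
#'
#' Applies the minimum-dwell filter, then converts each molecule's run-length
#' encoding into dwell records. The first and last dwell of every trace are
#' censored (their start or end was not observed) and excluded from all
#' dwell statistics; transition events are the exits of completed dwells,
#' so per trace the number of completed dwells equals the number of
#' transition events exactly.
#'
#' @param frames tibble with columns `molecule_id`, `time_s`, plus a state
#'   column and a numeric level column.
#' @param frame_interval frame spacing in seconds.
#' @param min_dwell_frames minimum dwell filter, in frames.
#' @param state_col,level_col names of the state and fitted-level columns.
#' @return list with `dwells` (tibble: `molecule_id`, `state`,
#'   `duration_s`, `exit_state`, `level`, `exit_level`, `censored`) and
#'   `events` (tibble: `molecule_id`, `time_s`, `from_state`, `to_state`,
#'   `from_level`, `to_level`), where events are completed-dwell exits.
#' @export
extract_dwells <- function(frames, frame_interval = 0.1,
                           min_dwell_frames = 2,
                           state_col = "state", level_col = "level") {
  ids <- unique(frames$molecule_id)
  dwell_list <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- frames[frames$molecule_id == ids[i], ]
    g <- g[order(g$time_s), ]
    st <- merge_short_dwells(g[[state_col]], min_dwell_frames)
    r <- rle(as.vector(st))
    nruns <- length(r$lengths)
    # representative fitted level per run (mean of decoded levels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    lev <- vapply(seq_len(nruns), function(j) {
      mean(g[[level_col]][starts[j]:ends[j]])
    }, numeric(1))
    dwell_list[[i]] <- tibble::tibble(
      molecule_id = ids[i],
      state = r$values,
      duration_s = r$lengths * frame_interval,
      exit_state = c(r$values[-1], NA),
      level = lev,
      exit_level = c(lev[-1], NA),
      end_time_s = g$time_s[ends],
      censored = seq_len(nruns) %in% c(1L, nruns))
  }
  dwells <- dplyr::bind_rows(dwell_list)
  completed <- dwells[!dwells$censored, ]
  events <- tibble::tibble(
    molecule_id = completed$molecule_id,
    time_s = completed$end_time_s,
    from_state = completed$state,
    to_state = completed$exit_state,
    from_level = completed$level,
    to_level = completed$exit_level)
  dwells$end_time_s <- NULL
  list(dwells = dwells, events = events)
}
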
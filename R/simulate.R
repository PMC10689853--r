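#' Simulate one hidden state path by exact stochastic simulation
#'
#' Draws a continuous-time trajectory of the conformational chain: the
#' dwell in each substate is exponential with that substate's total exit
#' rate and the next substate is chosen proportionally to the outgoing
#' rates. Photobleaching truncates the path; because the bleach rate is
#' uniform across substates, the bleach time is drawn once as an
#' independent exponential and the conformational chain is simulated up to
#' `min(bleach, t_end)`, which is distributionally exact.
#'
#' @param model a [kinetic_model()].
#' @param t_end maximum simulated time in seconds (> 0).
#' @param seed optional integer seed; when given, the path is reproducible.
#' @return tibble with one row per visited substate: `substate`, `state`
#'   (coarse), `dwell_s`. Attributes: `bleach_time` (`Inf` when censored at
#'   `t_end`) and `duration` (total path length,
#'   `min(t_end, bleach_time)`).
#' @export
simulate_hidden_path <- function(model, t_end, seed = NULL) {
  stopifnot(inherits(model, "tk_model"))
  if (t_end <= 0) stop("`t_end` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  bleach_time <- if (model$bleach_rate > 0) {
    stats::rexp(1, model$bleach_rate)
  } else {
    Inf
  }
  duration <- min(t_end, bleach_time)

  exit_rates <- rowSums(model$rates)
  cur <- sample.int(nrow(model$rates), 1, prob = model$initial_distribution)
  t_now <- 0
  subs <- integer(0)
  dwells <- numeric(0)
  repeat {
    r <- exit_rates[cur]
    dwell <- if (r > 0) stats::rexp(1, r) else Inf
    if (t_now + dwell >= duration) {
      subs <- c(subs, cur)
      dwells <- c(dwells, duration - t_now)
      break
    }
    subs <- c(subs, cur)
    dwells <- c(dwells, dwell)
    t_now <- t_now + dwell
    cur <- sample.int(nrow(model$rates), 1, prob = model$rates[cur, ])
  }

  out <- tibble::tibble(substate = subs,
                        state = model$coarse_of[subs],
                        dwell_s = dwells)
  attr(out, "bleach_time") <- if (bleach_time <= t_end) bleach_time else Inf
  attr(out, "duration") <- duration
  out
}

#' Render a hidden path into a framewise fluorescence trace
#'
#' Integrates the hidden path over each camera frame: the noiseless frame
#' value is the occupancy-time-weighted mean of the coarse-state emission
#' levels within the frame (so a transition crossing a frame boundary
#' produces an intermediate intensity), frames after photobleaching sit at
#' zero, and i.i.d. Gaussian noise of sd `emission_sigma` is added to every
#' frame. When the molecule bleaches before `t_total`, a stretch of
#' baseline frames (`post_bleach_s`) is appended so that single-step
#' photobleach detection has a baseline to find.
#'
#' @param path a hidden path from [simulate_hidden_path()].
#' @param model the generating [kinetic_model()].
#' @param seed optional integer seed for the noise draw.
#' @param post_bleach_s seconds of baseline appended after an observed
#'   bleach event.
#' @param noise logical; `FALSE` renders the noiseless integrated levels.
#' @return tibble with columns `time_s` (frame start) and `intensity`.
#' @export
render_trace <- function(path, model, seed = NULL, post_bleach_s = 5,
                         noise = TRUE) {
  stopifnot(inherits(model, "tk_model"))
  if (!is.null(seed)) set.seed(seed)
  dt <- model$frame_interval
  duration <- attr(path, "duration")
  bleach <- attr(path, "bleach_time")
  if (is.null(duration)) duration <- sum(path$dwell_s)
  if (is.null(bleach)) bleach <- Inf

  t_total <- if (is.finite(bleach)) duration + post_bleach_s else duration
  n_frames <- floor(t_total / dt + 1e-9)
  if (n_frames < 1) n_frames <- 1

  # piecewise-constant emission level; cumulative integral at breakpoints
  levels <- model$emission_means[path$state]
  brk <- c(0, cumsum(path$dwell_s))
  if (is.finite(bleach)) {
    brk <- c(brk, t_total)
    levels <- c(levels, 0)
  }
  cumint <- c(0, cumsum(levels * diff(brk)))
  edges <- seq(0, by = dt, length.out = n_frames + 1)
  edges[edges > brk[length(brk)]] <- brk[length(brk)]
  Fi <- stats::approx(brk, cumint, xout = edges, rule = 2)$y
  values <- diff(Fi) / dt

  if (noise) {
    values <- values + stats::rnorm(n_frames, 0, model$emission_sigma)
  }
  tibble::tibble(time_s = edges[-length(edges)], intensity = values)
}

#' Simulate a dataset of single-molecule traces
#'
#' Generates `n_traces` fluorescence trajectories from a reference
#' configuration or a model. A fraction `static_fraction` of the traces is
#' transition-free (all inter-state rates zeroed; random initial state and
#' photobleaching retained), emulating the static single-step-bleaching
#' contaminants seen in real fields of view. The number of static traces is
#' exactly `floor(n * static_fraction + 0.5)`. The whole dataset is
#' deterministic given the seed.
#'
#' @param config a [reference_config()], or a [kinetic_model()] when
#'   `n_traces`/`seed` are given explicitly.
#' @param n_traces,seed required when `config` is a bare model.
#' @param t_cap hard cap on trace duration in seconds.
#' @param post_bleach_s baseline seconds appended after a bleach event.
#' @param condition optional label attached to every trace.
#' @return an object of class `tk_dataset`: a list with `traces` (long
#'   tibble: `molecule_id`, `time_s`, `intensity`, `condition`), `truth`
#'   (per-molecule tibble: `molecule_id`, `static`, `bleach_time_s`,
#'   `n_transitions`, and a `path` list-column of hidden paths) and the
#'   generating `model`.
#' @export
simulate_dataset <- function(config, n_traces = NULL, seed = NULL,
                             t_cap = 120, post_bleach_s = 5,
                             condition = NULL) {
  if (inherits(config, "tk_config")) {
    model <- config$model
    if (is.null(n_traces)) n_traces <- config$n_traces
    if (is.null(seed)) seed <- config$seed
    if (is.null(condition)) condition <- config$name
  } else if (inherits(config, "tk_model")) {
    model <- config
    if (is.null(n_traces) || is.null(seed)) {
      stop("`n_traces` and `seed` are required with a bare model",
           call. = FALSE)
    }
    if (is.null(condition)) condition <- "unnamed"
  } else {
    stop("`config` must be a tk_config or tk_model", call. = FALSE)
  }
  if (n_traces < 1) stop("`n_traces` must be >= 1", call. = FALSE)

  n_static <- floor(n_traces * model$static_fraction + 0.5)
  set.seed(seed)
  static_idx <- sample.int(n_traces, n_static)
  trace_seeds <- sample.int(.Machine$integer.max - 1L, n_traces)

  static_model <- model
  static_model$rates[] <- 0
  # static molecules still start in a random state with the same weights
  static_model$initial_distribution <- model$initial_distribution

  ids <- sprintf("mol%04d", seq_len(n_traces))
  per_trace <- purrr::map(seq_len(n_traces), function(i) {
    m_i <- if (i %in% static_idx) static_model else model
    set.seed(trace_seeds[i])
    path <- simulate_hidden_path(m_i, t_end = t_cap)
    tr <- render_trace(path, m_i, post_bleach_s = post_bleach_s)
    list(trace = tr, path = path)
  })

  traces <- purrr::map2(per_trace, ids, function(p, id) {
    dplyr::mutate(p$trace, molecule_id = id, .before = 1)
  })
  traces <- dplyr::bind_rows(traces)
  traces$condition <- condition

  truth <- tibble::tibble(
    molecule_id = ids,
    static = seq_len(n_traces) %in% static_idx,
    bleach_time_s = purrr::map_dbl(per_trace,
                                   ~ attr(.x$path, "bleach_time")),
    n_transitions = purrr::map_int(per_trace, function(p) {
      s <- p$path$state
      sum(s[-1] != s[-length(s)])
    }),
    path = purrr::map(per_trace, "path"))

  structure(list(traces = traces, truth = truth, model = model,
                 condition = condition, seed = seed, n_traces = n_traces),
            class = "tk_dataset")
}

#' @export
print.tk_dataset <- function(x, ...) {
  cat(sprintf("<tk_dataset> %s: %d traces (%d static), %d frames, seed %d\n",
              x$condition, x$n_traces, sum(x$truth$static),
              nrow(x$traces), x$seed))
  invisible(x)
}

#' True coarse state per frame of a simulated trace
#'
#' Majority-occupancy coarse state within each frame of the rendered trace,
#' used to score idealization accuracy against ground truth.
#'
#' @param path hidden path from [simulate_hidden_path()].
#' @param model generating model.
#' @param n_frames number of frames to label (pre-bleach frames of the
#'   rendered trace).
#' @return integer vector of coarse states, length `n_frames`.
#' @export
true_frame_states <- function(path, model, n_frames) {
  dt <- model$frame_interval
  brk <- c(0, cumsum(path$dwell_s))
  K <- max(model$coarse_of)
  vapply(seq_len(n_frames), function(i) {
    lo <- (i - 1) * dt
    hi <- i * dt
    occ <- numeric(K)
    for (j in seq_len(nrow(path))) {
      ov <- max(0, min(hi, brk[j + 1]) - max(lo, brk[j]))
      occ[path$state[j]] <- occ[path$state[j]] + ov
    }
    which.max(occ)
  }, integer(1))
}
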
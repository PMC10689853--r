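#' Define a continuous-time kinetic model for single-molecule traces
#'
#' A kinetic model describes a receptor switching among a small number of
#' coarse conformational states (2 or 3), each with a distinct normalized
#' fluorescence emission level. A coarse state may optionally be expanded
#' into several hidden kinetic substates that share the same emission level
#' but exit at different rates; pooled dwell times in such a state follow a
#' multi-exponential mixture even though the emission record cannot tell the
#' substates apart. Photobleaching is modeled as an absorbing dark state
#' reached at a uniform rate from every substate.
#'
#' @param rates square numeric matrix of transition rate constants between
#'   substates, in s^-1. `rates[i, j]` is the rate from substate `i` to
#'   substate `j`; the diagonal is ignored. All off-diagonal entries must be
#'   non-negative.
#' @param coarse_of integer vector mapping each substate (row of `rates`) to
#'   its coarse state index `1..K`. Defaults to the identity (no substates).
#' @param emission_means numeric vector of normalized emission levels, one
#'   per coarse state, strictly increasing with the state index. The lowest
#'   (inactive) state is conventionally at 1.0 and neighboring states are
#'   one normalized unit apart.
#' @param emission_sigma Gaussian noise standard deviation per frame, in
#'   normalized intensity units.
#' @param bleach_rate photobleaching rate in s^-1 (mean fluorophore lifetime
#'   `1/bleach_rate`); 0 disables bleaching.
#' @param frame_interval camera integration time in seconds.
#' @param static_fraction fraction in `[0, 1]` of simulated traces that are
#'   transition-free (static) contaminants.
#' @param initial_distribution probability of starting in each substate.
#'   Defaults to the stationary distribution of the conformational chain.
#'
#' @return An object of class `tk_model`.
#' @examples
#' m <- kinetic_model(rbind(c(0, 0.345), c(0.587, 0)),
#'                    emission_means = c(1, 2))
#' stationary_distribution(m)
#' @export
kinetic_model <- function(rates,
                          coarse_of = seq_len(nrow(rates)),
                          emission_means,
                          emission_sigma = 0.15,
                          bleach_rate = 1 / 30,
                          frame_interval = 0.1,
                          static_fraction = 0.55,
                          initial_distribution = NULL) {
  rates <- as.matrix(rates)
  m <- nrow(rates)
  if (ncol(rates) != m) stop("`rates` must be a square matrix", call. = FALSE)
  diag(rates) <- 0
  bad <- which(rates < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative rate for substate pair (%d -> %d)",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  coarse_of <- as.integer(coarse_of)
  if (length(coarse_of) != m) {
    stop("`coarse_of` must map every substate to a coarse state", call. = FALSE)
  }
  K <- max(coarse_of)
  if (!setequal(unique(coarse_of), seq_len(K))) {
    stop("coarse states must be labeled 1..K without gaps", call. = FALSE)
  }
  if (length(emission_means) != K) {
    stop("`emission_means` must have one level per coarse state", call. = FALSE)
  }
  if (any(diff(emission_means) <= 0)) {
    stop("`emission_means` must be strictly increasing with state index",
         call. = FALSE)
  }
  if (emission_sigma <= 0) stop("`emission_sigma` must be > 0", call. = FALSE)
  if (bleach_rate < 0) stop("`bleach_rate` must be >= 0", call. = FALSE)
  if (frame_interval <= 0) stop("`frame_interval` must be > 0", call. = FALSE)
  if (static_fraction < 0 || static_fraction > 1) {
    stop("`static_fraction` must lie in [0, 1]", call. = FALSE)
  }

  model <- structure(
    list(rates = rates, coarse_of = coarse_of,
         emission_means = as.numeric(emission_means),
         emission_sigma = emission_sigma, bleach_rate = bleach_rate,
         frame_interval = frame_interval, static_fraction = static_fraction,
         initial_distribution = NULL),
    class = "tk_model")

  if (is.null(initial_distribution)) {
    initial_distribution <- substate_stationary(model)
  }
  initial_distribution <- as.numeric(initial_distribution)
  if (length(initial_distribution) != m ||
      abs(sum(initial_distribution) - 1) > 1e-9 ||
      any(initial_distribution < 0)) {
    stop("`initial_distribution` must be a probability vector over substates",
         call. = FALSE)
  }
  model$initial_distribution <- initial_distribution
  model
}

#' @export
print.tk_model <- function(x, ...) {
  K <- max(x$coarse_of)
  cat(sprintf("<tk_model> %d coarse state(s), %d substate(s)\n",
              K, nrow(x$rates)))
  cat("  emission means:", paste(format(x$emission_means), collapse = ", "),
      sprintf(" (sigma = %g)\n", x$emission_sigma))
  cat(sprintf("  bleach rate: %g s^-1; frame: %g s; static fraction: %g\n",
              x$bleach_rate, x$frame_interval, x$static_fraction))
  invisible(x)
}

#' Build the continuous-time generator matrix of a kinetic model
#'
#' Returns the rate (generator) matrix over substates, with an extra
#' absorbing "bleached" state appended as the final row/column. Off-diagonal
#' entries are the transition rate constants; every substate additionally
#' flows into the bleached state at `bleach_rate`; each diagonal entry is
#' minus its row sum so that rows sum to zero.
#'
#' @param model a [kinetic_model()].
#' @return numeric matrix of size `(m + 1) x (m + 1)` where `m` is the
#'   number of substates; the last state is the absorbing bleached state.
#' @export
generator_matrix <- function(model) {
  stopifnot(inherits(model, "tk_model"))
  m <- nrow(model$rates)
  Q <- matrix(0, m + 1, m + 1)
  Q[seq_len(m), seq_len(m)] <- model$rates
  Q[seq_len(m), m + 1] <- model$bleach_rate
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  labs <- c(paste0("s", seq_len(m)), "bleached")
  dimnames(Q) <- list(labs, labs)
  Q
}

# stationary distribution of the conformational chain (bleaching excluded),
# solved as the null space of t(Q)
substate_stationary <- function(model) {
  R <- model$rates
  diag(R) <- 0
  diag(R) <- -rowSums(R)
  m <- nrow(R)
  if (all(R == 0)) return(rep(1 / m, m))
  # solve pi Q = 0, sum(pi) = 1 by replacing one balance equation
  A <- rbind(t(R)[-m, , drop = FALSE], rep(1, m))
  b <- c(rep(0, m - 1), 1)
  pi_hat <- solve(A, b)
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat / sum(pi_hat)
}

#' Stationary distribution over coarse states
#'
#' Solves the global balance equations of the conformational chain (the
#' generator without its bleached state) and aggregates substate
#' probabilities by coarse state. This is the occupancy distribution the
#' population histogram of an infinitely long, bleach-free experiment
#' would measure.
#'
#' @param model a [kinetic_model()].
#' @return tibble with columns `state` and `probability`.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "tk_model"))
  p <- substate_stationary(model)
  tibble::tibble(state = sort(unique(model$coarse_of)),
                 probability = as.numeric(
                   tapply(p, model$coarse_of, sum)[as.character(sort(unique(model$coarse_of)))]))
}

#' Reference kinetic models
#'
#' Shipped, read-only kinetic models whose rate constants are fixed by
#' algebra from the occupancies and mean dwell times the analysis is meant
#' to recover: the stationary distribution of each chain equals the target
#' fractional state populations and the state-1 exit rate equals the
#' reciprocal of the target mean occupancy time.
#'
#' * `apo_wt` — two states; k(1-2) = 0.345 (mean state-1 dwell 2.9 s),
#'   k(2-1) = 0.587; stationary populations (63%, 37%).
#' * `neca_wt` — three sequential states; populations (49%, 37%, 14%).
#' * `neca_wt_minigs` — three states; populations (42%, 37%, 21%);
#'   state-1 exit 0.556 s^-1 (mean dwell 1.8 s).
#' * `keq24` — two states with k(1-2)/k(2-1) = 0.550/0.229 = 2.4.
#' * `cam` — three states; state-1 exit 0.667 s^-1 (mean dwell 1.5 s).
#' * `substates` — two coarse states, state 1 split into fast/slow hidden
#'   substates (exit rates 1.0 and 0.2 s^-1, equal entry), giving
#'   bi-exponential state-1 dwells.
#'
#' Direct 1-3 rates are zero in all three-state models (strictly
#' sequential activation through the intermediate state).
#'
#' @param name one of `"apo_wt"`, `"neca_wt"`, `"neca_wt_minigs"`,
#'   `"keq24"`, `"cam"`, `"substates"`.
#' @param ... overrides passed on to [kinetic_model()] (e.g.
#'   `emission_sigma`, `static_fraction`).
#' @return a [kinetic_model()].
#' @export
reference_model <- function(name = c("apo_wt", "neca_wt", "neca_wt_minigs",
                                     "keq24", "cam", "substates"), ...) {
  name <- match.arg(name)
  two <- function(k12, k21) rbind(c(0, k12), c(k21, 0))
  three <- function(k12, k21, k23, k32) {
    rbind(c(0, k12, 0), c(k21, 0, k23), c(0, k32, 0))
  }
  def <- switch(
    name,
    apo_wt = list(rates = two(0.345, 0.587), coarse = 1:2, means = c(1, 2)),
    neca_wt = list(rates = three(0.345, 0.457, 0.227, 0.600),
                   coarse = 1:3, means = c(1, 2, 3)),
    neca_wt_minigs = list(rates = three(0.556, 0.631, 0.341, 0.600),
                          coarse = 1:3, means = c(1, 2, 3)),
    keq24 = list(rates = two(0.550, 0.229), coarse = 1:2, means = c(1, 2)),
    cam = list(rates = three(0.667, 0.533, 0.267, 0.533),
               coarse = 1:3, means = c(1, 2, 3)),
    substates = list(
      # substates 1a (fast exit 1.0/s) and 1b (slow exit 0.2/s) share the
      # state-1 emission level; re-entry from state 2 splits 50/50
      rates = rbind(c(0, 0, 1.0),
                    c(0, 0, 0.2),
                    c(0.25, 0.25, 0)),
      coarse = c(1L, 1L, 2L), means = c(1, 2)))
  args <- list(rates = def$rates, coarse_of = def$coarse,
               emission_means = def$means)
  args <- utils::modifyList(args, list(...))
  do.call(kinetic_model, args)
}

#' Reference simulation configurations
#'
#' Bundles a [reference_model()] with a dataset size and seed, mirroring
#' the scale of a typical single-condition experiment (300 molecules).
#'
#' @param name reference model name, see [reference_model()].
#' @param n_traces number of molecules to simulate.
#' @param seed integer seed making the dataset reproducible.
#' @param ... model overrides passed to [reference_model()].
#' @return an object of class `tk_config`.
#' @export
reference_config <- function(name, n_traces = 300, seed = 42, ...) {
  model <- reference_model(name, ...)
  structure(list(name = name, model = model,
                 n_traces = as.integer(n_traces), seed = as.integer(seed)),
            class = "tk_config")
}

#' @export
print.tk_config <- function(x, ...) {
  cat(sprintf("<tk_config> %s: %d traces, seed %d\n",
              x$name, x$n_traces, x$seed))
  print(x$model)
  invisible(x)
}
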
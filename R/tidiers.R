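#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted HMM
#'
#' @param x a [fit_hmm()] result.
#' @param ... unused.
#' @return tibble with one row per state: `state`, `mean`, `sd`,
#'   `occupancy`, `self_transition`.
#' @export
tidy.tk_hmm <- function(x, ...) {
  tibble::tibble(state = seq_len(x$n_states), mean = x$means, sd = x$sds,
                 occupancy = x$occupancy,
                 self_transition = diag(x$trans))
}

#' @rdname tidy.tk_hmm
#' @return for `glance()`: one-row tibble with `n_states`, `n_frames`,
#'   `loglik`, `converged`, `iterations`.
#' @export
glance.tk_hmm <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, n_frames = x$n_frames,
                 loglik = x$loglik, converged = x$converged,
                 iterations = x$iterations)
}

#' Tidy a multipeak Gaussian histogram fit
#'
#' @param x a [fit_multipeak()] result.
#' @param ... unused.
#' @return tibble with one row per peak: `state`, `amplitude`, `center`,
#'   `width`, `area`, `fraction`, `fraction_se`.
#' @export
tidy.tk_histfit <- function(x, ...) {
  x$peaks
}

#' @rdname tidy.tk_histfit
#' @return for `glance()`: one-row tibble with `y0`, `red_chisq`,
#'   `n_bins`, `converged`.
#' @export
glance.tk_histfit <- function(x, ...) {
  tibble::tibble(y0 = x$y0, red_chisq = x$red_chisq, n_bins = x$n_bins,
                 converged = x$converged)
}

#' Tidy a dwell-time exponential fit
#'
#' @param x a [fit_exponentials()] result.
#' @param ... unused.
#' @return tibble with one row per model component: `model`, `component`,
#'   `amplitude`, `amplitude_pct`, `k`.
#' @export
tidy.tk_expfit <- function(x, ...) {
  rows <- list(tibble::tibble(model = "mono", component = 1L,
                              amplitude = x$mono$A, amplitude_pct = 100,
                              k = x$mono$k))
  if (!is.null(x$bi)) {
    rows[[2]] <- tibble::tibble(
      model = "bi", component = 1:2,
      amplitude = c(x$bi$A1, x$bi$A2),
      amplitude_pct = c(x$bi$a1, x$bi$a2),
      k = c(x$bi$k1, x$bi$k2))
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.tk_expfit
#' @return for `glance()`: one-row tibble with dwell count, reduced
#'   chi-squared of both models, the selected model and its
#'   amplitude-weighted rate.
#' @export
glance.tk_expfit <- function(x, ...) {
  sel <- select_model(x)
  wr <- weighted_rate(x, sel)
  tibble::tibble(n = x$n, red_chisq_mono = x$mono$red_chisq,
                 red_chisq_bi = if (!is.null(x$bi)) x$bi$red_chisq else NA_real_,
                 model = sel, k = wr$k, k_se = wr$k_se)
}

#' Tidy a pipeline report
#'
#' Long table of every headline quantity in the report, one row per
#' (quantity, state or state pair).
#'
#' @param x a [run_pipeline()] result.
#' @param ... unused.
#' @return tibble with columns `quantity`, `state`, `value`, `se`.
#' @export
tidy.tk_report <- function(x, ...) {
  rows <- list(
    tibble::tibble(quantity = "center", state = as.character(x$areas$state),
                   value = x$centers, se = NA_real_),
    tibble::tibble(quantity = "fractional_area",
                   state = as.character(x$areas$state),
                   value = x$areas$fraction, se = x$areas$fraction_se),
    tibble::tibble(quantity = "mean_occupancy_s",
                   state = as.character(x$occupancy$state),
                   value = x$occupancy$mean_occupancy_s,
                   se = x$occupancy$sem))
  if (nrow(x$rates) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = "rate_constant",
      state = sprintf("%d->%d", x$rates$from_state, x$rates$to_state),
      value = x$rates$k, se = x$rates$k_se)
  }
  if (!is.null(x$keq) && nrow(x$keq) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = "keq", state = x$keq$pair, value = x$keq$keq,
      se = x$keq$sd)
  }
  if (!is.na(x$transitions$skip_fraction)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = "skip_fraction", state = sprintf("1<->%d", x$n_states),
      value = x$transitions$skip_fraction, se = NA_real_)
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.tk_report
#' @return for `glance()`: one-row tibble with selection counts, state
#'   count, histogram reduced chi-squared and transition count.
#' @export
glance.tk_report <- function(x, ...) {
  tibble::tibble(condition = x$condition, n_states = x$n_states,
                 total = x$selection$total, accepted = x$selection$accepted,
                 dynamic = x$selection$dynamic,
                 n_transitions = x$transitions$n_transitions,
                 red_chisq = x$red_chisq, seed = x$seed)
}
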
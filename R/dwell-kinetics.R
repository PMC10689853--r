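#' Freedman-Diaconis bin width for dwell-time histograms
#'
#' `width = 2 * IQR(x) / n^(1/3)`, with quartiles computed by linear
#' interpolation between order statistics (the standard spreadsheet
#' convention, `stats::quantile` type 7). When the IQR is zero (all
#' durations identical to frame precision) the fallback `range / sqrt(n)`
#' is used; if that is also zero the frame interval would be a sensible
#' floor, left to the caller.
#'
#' @param durations numeric vector of dwell durations in seconds (n >= 4).
#' @return bin width in seconds.
#' @export
fd_bin_width <- function(durations) {
  n <- length(durations)
  if (n < 4) {
    stop("need at least 4 dwells for Freedman-Diaconis binning; ",
         "pool transition classes instead", call. = FALSE)
  }
  iqr <- diff(stats::quantile(durations, c(0.25, 0.75), names = FALSE,
                              type = 7))
  if (iqr > 0) {
    2 * iqr / n^(1 / 3)
  } else {
    diff(range(durations)) / sqrt(n)
  }
}

# bin a dwell sample and return centers/counts with Poisson errors
bin_dwells <- function(durations, bin_width = NULL) {
  if (is.null(bin_width)) bin_width <- fd_bin_width(durations)
  if (bin_width <= 0) bin_width <- max(durations) / 10 + 1e-9
  lo <- floor(min(durations) / bin_width) * bin_width
  breaks <- seq(lo, max(durations) + bin_width, by = bin_width)
  h <- graphics::hist(durations, breaks = breaks, plot = FALSE)
  tibble::tibble(mid = h$mids, count = h$counts,
                 sigma = sqrt(pmax(h$counts, 1)))
}

exp_fit_one <- function(bins, k_init, A_init) {
  fn <- function(par) (bins$count - par[1] * exp(-par[2] * bins$mid)) /
    bins$sigma
  fit <- minpack.lm::nls.lm(
    par = c(A = A_init, k = k_init), lower = c(0, 1e-9),
    fn = fn, control = minpack.lm::nls.lm.control(maxiter = 500))
  chisq <- sum(fit$fvec^2)
  dof <- max(nrow(bins) - 2, 1)
  vc <- tryCatch(solve(fit$hessian) * chisq / dof,
                 error = function(e) matrix(NA_real_, 2, 2))
  list(A = unname(fit$par[1]), k = unname(fit$par[2]),
       k_se = sqrt(abs(vc[2, 2])), red_chisq = chisq / dof,
       vcov = vc, converged = fit$info > 0)
}

exp_fit_two <- function(bins, k_init, A_init) {
  fn <- function(par) {
    (bins$count - par[1] * exp(-par[2] * bins$mid) -
       par[3] * exp(-par[4] * bins$mid)) / bins$sigma
  }
  fit <- minpack.lm::nls.lm(
    par = c(A1 = A_init * 0.5, k1 = k_init * 3,
            A2 = A_init * 0.5, k2 = k_init / 3),
    lower = c(0, 1e-9, 0, 1e-9),
    fn = fn, control = minpack.lm::nls.lm.control(maxiter = 1000))
  par <- fit$par
  chisq <- sum(fit$fvec^2)
  dof <- max(nrow(bins) - 4, 1)
  vc <- tryCatch(solve(fit$hessian) * chisq / dof,
                 error = function(e) matrix(NA_real_, 4, 4))
  # fast component first, by convention
  if (par[2] < par[4]) {
    par <- par[c(3, 4, 1, 2)]
    vc <- vc[c(3, 4, 1, 2), c(3, 4, 1, 2)]
  }
  list(A1 = unname(par[1]), k1 = unname(par[2]),
       A2 = unname(par[3]), k2 = unname(par[4]),
       red_chisq = chisq / dof, vcov = vc, converged = fit$info > 0)
}

#' Fit mono- and bi-exponential decays to a dwell-time distribution
#'
#' Bins the completed dwell durations (Freedman-Diaconis width by default)
#' and fits both candidate decay models to the binned counts by weighted
#' least squares with Poisson errors `sigma_b = sqrt(max(count, 1))`:
#' `A * exp(-k * x)` and `A1 * exp(-k1 * x) + A2 * exp(-k2 * x)`.
#' Amplitudes of the bi-exponential are reported both raw and normalized
#' to percentages (`a1 + a2 = 100`), with the fast component first. A
#' bi-exponential whose rate constants agree within 5% or whose minor
#' amplitude falls below 2% is degenerate (indistinguishable from mono).
#' Below `min_n_bi` dwells only the mono model is attempted.
#'
#' @param durations completed dwell durations in seconds.
#' @param bin_width histogram bin width; default Freedman-Diaconis.
#' @param min_n_mono,min_n_bi minimum dwell counts to attempt each model.
#' @return object of class `tk_expfit`: list with `mono` (A, k, k_se,
#'   red_chisq), `bi` (A1, k1, A2, k2, a1, a2 in percent, red_chisq,
#'   degenerate) or `NULL`, `n`, `bins`.
#' @export
fit_exponentials <- function(durations, bin_width = NULL,
                             min_n_mono = 10, min_n_bi = 25) {
  n <- length(durations)
  if (n < min_n_mono) {
    stop(sprintf("only %d dwells; need >= %d for an exponential fit",
                 n, min_n_mono), call. = FALSE)
  }
  bins <- bin_dwells(durations, bin_width)
  xmin <- min(durations)
  k0 <- 1 / max(mean(durations) - xmin, 1e-6)
  A0 <- max(bins$count)

  mono <- exp_fit_one(bins, k0, A0)
  bi <- NULL
  if (n >= min_n_bi && nrow(bins) >= 6) {
    bi <- exp_fit_two(bins, k0, A0)
    tot <- bi$A1 + bi$A2
    bi$a1 <- 100 * bi$A1 / tot
    bi$a2 <- 100 * bi$A2 / tot
    bi$degenerate <- !bi$converged ||
      abs(bi$k1 - bi$k2) / max(bi$k1, bi$k2) < 0.05 ||
      min(bi$a1, bi$a2) < 2
  }
  structure(list(mono = mono, bi = bi, n = n, bins = bins),
            class = "tk_expfit")
}

#' @export
print.tk_expfit <- function(x, ...) {
  cat(sprintf("<tk_expfit> n = %d dwells\n", x$n))
  cat(sprintf("  mono: A = %.1f, k = %.3f /s (red chi-sq %.3f)\n",
              x$mono$A, x$mono$k, x$mono$red_chisq))
  if (!is.null(x$bi)) {
    cat(sprintf(
      "  bi:   a1 = %.0f%% k1 = %.3f /s, a2 = %.0f%% k2 = %.3f /s (red chi-sq %.3f)%s\n",
      x$bi$a1, x$bi$k1, x$bi$a2, x$bi$k2, x$bi$red_chisq,
      if (isTRUE(x$bi$degenerate)) " [degenerate]" else ""))
  }
  cat("  selected:", select_model(x), "\n")
  invisible(x)
}

#' Select mono- or bi-exponential by reduced chi-squared
#'
#' The bi-exponential is selected only when its reduced chi-squared
#' improves on the mono fit by more than `improvement` (10% relative by
#' default) and the fit is non-degenerate; ties and marginal improvements
#' fall to the mono model (parsimony).
#'
#' @param fit a [fit_exponentials()] result.
#' @param improvement minimum relative reduction in reduced chi-squared
#'   required to prefer the bi-exponential.
#' @return `"mono"` or `"bi"`.
#' @export
select_model <- function(fit, improvement = 0.10) {
  stopifnot(inherits(fit, "tk_expfit"))
  if (is.null(fit$bi) || isTRUE(fit$bi$degenerate)) return("mono")
  if (fit$bi$red_chisq < (1 - improvement) * fit$mono$red_chisq) "bi"
  else "mono"
}

#' Amplitude-weighted rate constant of a dwell-time fit
#'
#' For the mono-exponential the rate is `k` itself. For the bi-exponential
#' the two rate constants are averaged by their normalized amplitudes
#' through `1/k = a1/k1 + a2/k2` (amplitude fractions summing to 1), the
#' harmonic form that preserves the mean dwell time of the mixture.
#' Uncertainty is first-order propagation from the fit covariance.
#'
#' @param fit a [fit_exponentials()] result.
#' @param model which model's rate to report; default the selected one.
#' @return list with `k` (s^-1), `k_se` and `model`.
#' @export
weighted_rate <- function(fit, model = select_model(fit)) {
  stopifnot(inherits(fit, "tk_expfit"))
  if (model == "mono" || is.null(fit$bi)) {
    return(list(k = fit$mono$k, k_se = fit$mono$k_se, model = "mono"))
  }
  b <- fit$bi
  kbar_fun <- function(p) {
    a1 <- p[1] / (p[1] + p[3])
    a2 <- p[3] / (p[1] + p[3])
    1 / (a1 / p[2] + a2 / p[4])
  }
  p <- c(b$A1, b$k1, b$A2, b$k2)
  kbar <- kbar_fun(p)
  se <- NA_real_
  if (all(is.finite(b$vcov))) {
    eps <- pmax(abs(p) * 1e-6, 1e-10)
    g <- vapply(1:4, function(i) {
      ph <- p; ph[i] <- ph[i] + eps[i]
      pl <- p; pl[i] <- pl[i] - eps[i]
      (kbar_fun(ph) - kbar_fun(pl)) / (2 * eps[i])
    }, numeric(1))
    se <- sqrt(abs(drop(t(g) %*% b$vcov %*% g)))
  }
  list(k = kbar, k_se = se, model = "bi")
}

#' Equilibrium rate-constant ratio between two states
#'
#' `k_eq(i, j) = k_ij / k_ji`, with standard deviation from first-order
#' propagation: `SD(r)/r = sqrt((SD_ij/k_ij)^2 + (SD_ji/k_ji)^2)`. A ratio
#' above 1 means the kinetic equilibrium favors state j over state i.
#'
#' @param k_ij,k_ji forward and reverse rate constants (s^-1, > 0).
#' @param sd_ij,sd_ji their standard deviations.
#' @return list with `keq` and `sd`.
#' @export
keq_ratio <- function(k_ij, k_ji, sd_ij = 0, sd_ji = 0) {
  if (!is.finite(k_ij) || !is.finite(k_ji) || k_ij <= 0 || k_ji <= 0) {
    stop("rate constants must be positive", call. = FALSE)
  }
  r <- k_ij / k_ji
  list(keq = r, sd = r * sqrt((sd_ij / k_ij)^2 + (sd_ji / k_ji)^2))
}

#' Mean occupancy time per state
#'
#' Arithmetic mean of the completed (non-censored) dwell durations in each
#' state, pooled over all exit classes, with `SEM = SD / sqrt(n)` (`NA`
#' for a single dwell).
#'
#' @param dwells dwell tibble from [extract_dwells()] (uses rows with
#'   `censored == FALSE`).
#' @return tibble with columns `state`, `mean_occupancy_s`, `sem`, `n`.
#' @export
mean_occupancy <- function(dwells) {
  d <- dwells[!dwells$censored, ]
  if (nrow(d) == 0) stop("no completed dwells", call. = FALSE)
  d |>
    dplyr::group_by(state = .data$state) |>
    dplyr::summarise(mean_occupancy_s = mean(.data$duration_s),
                     sem = stats::sd(.data$duration_s) /
                       sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$state)
}

#' Per-transition-class dwell kinetics
#'
#' Partitions the completed dwells by (state, exit state) class, fits both
#' exponential models per class, selects one by reduced chi-squared, and
#' reports the amplitude-weighted rate constant for every class together
#' with equilibrium rate-constant ratios for each adjacent state pair.
#'
#' @param dwells dwell tibble from [extract_dwells()].
#' @param min_n_mono,min_n_bi per-class dwell count thresholds, see
#'   [fit_exponentials()].
#' @param improvement model-selection threshold, see [select_model()].
#' @return object of class `tk_kinetics`: list with `rates` (tibble:
#'   `from_state`, `to_state`, `n`, `model`, `k`, `k_se`, per-model
#'   reduced chi-squared and bi-exponential components), `keq` (tibble:
#'   `pair`, `keq`, `sd`) and `occupancy` (from [mean_occupancy()]).
#' @export
dwell_kinetics <- function(dwells, min_n_mono = 10, min_n_bi = 25,
                           improvement = 0.10) {
  d <- dwells[!dwells$censored & !is.na(dwells$exit_state), ]
  classes <- d |>
    dplyr::count(.data$state, .data$exit_state) |>
    dplyr::filter(.data$n >= min_n_mono)
  rows <- purrr::pmap(classes, function(state, exit_state, n) {
    dur <- d$duration_s[d$state == state & d$exit_state == exit_state]
    fit <- fit_exponentials(dur, min_n_mono = min_n_mono,
                            min_n_bi = min_n_bi)
    model <- select_model(fit, improvement)
    wr <- weighted_rate(fit, model)
    tibble::tibble(
      from_state = state, to_state = exit_state, n = n, model = model,
      k = wr$k, k_se = wr$k_se,
      red_chisq_mono = fit$mono$red_chisq,
      red_chisq_bi = if (!is.null(fit$bi)) fit$bi$red_chisq else NA_real_,
      a1 = if (!is.null(fit$bi)) fit$bi$a1 else NA_real_,
      k1 = if (!is.null(fit$bi)) fit$bi$k1 else NA_real_,
      a2 = if (!is.null(fit$bi)) fit$bi$a2 else NA_real_,
      k2 = if (!is.null(fit$bi)) fit$bi$k2 else NA_real_)
  })
  rates <- dplyr::bind_rows(rows)

  keq <- NULL
  if (nrow(rates) > 0) {
    K <- max(c(rates$from_state, rates$to_state))
    pairs <- purrr::map(seq_len(K - 1), function(i) {
      fw <- rates[rates$from_state == i & rates$to_state == i + 1, ]
      bw <- rates[rates$from_state == i + 1 & rates$to_state == i, ]
      if (nrow(fw) == 0 || nrow(bw) == 0) return(NULL)
      r <- keq_ratio(fw$k, bw$k,
                     ifelse(is.na(fw$k_se), 0, fw$k_se),
                     ifelse(is.na(bw$k_se), 0, bw$k_se))
      tibble::tibble(pair = sprintf("%d,%d", i, i + 1),
                     keq = r$keq, sd = r$sd)
    })
    keq <- dplyr::bind_rows(pairs)
  }

  structure(list(rates = rates, keq = keq, occupancy = mean_occupancy(dwells)),
            class = "tk_kinetics")
}

#' @export
print.tk_kinetics <- function(x, ...) {
  cat("<tk_kinetics>\n")
  print(x$rates)
  if (!is.null(x$keq) && nrow(x$keq) > 0) {
    cat("equilibrium rate-constant ratios:\n")
    print(x$keq)
  }
  cat("mean occupancy times:\n")
  print(x$occupancy)
  invisible(x)
}
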
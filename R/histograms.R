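#' Compile a pooled normalized-intensity histogram
#'
#' Pools all pre-bleach frames of the supplied (dynamic, normalized)
#' traces into one intensity histogram. The per-bin standard error is
#' multinomial, `SE_b = sqrt(N p_b (1 - p_b))` on the count scale: each
#' frame is treated as one draw over the bins. (A molecule-level bootstrap
#' would widen these errors because frames within one molecule are
#' autocorrelated; see the package vignette.)
#'
#' @param traces long tibble of normalized dynamic traces (or the `frames`
#'   tibble of an idealized set) with an `intensity` column.
#' @param bin_width histogram bin width in normalized intensity units.
#' @return object of class `tk_histogram`: tibble with columns `bin_mid`,
#'   `count`, `se`, `density`, plus attributes `bin_width`, `n_frames`,
#'   `n_molecules`.
#' @export
compile_histogram <- function(traces, bin_width = 0.05) {
  y <- traces$intensity
  if (length(y) == 0) stop("no frames to histogram", call. = FALSE)
  lo <- floor(min(y) / bin_width) * bin_width
  hi <- ceiling(max(y) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(y, breaks = breaks, plot = FALSE)
  n <- length(y)
  p <- h$counts / n
  out <- tibble::tibble(bin_mid = h$mids, count = h$counts,
                        se = sqrt(n * p * (1 - p)),
                        density = p / bin_width)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- n
  attr(out, "n_molecules") <- if ("molecule_id" %in% names(traces)) {
    length(unique(traces$molecule_id))
  } else {
    NA_integer_
  }
  class(out) <- c("tk_histogram", class(out))
  out
}

#' Fit a multipeak Gaussian model to a population histogram
#'
#' Weighted nonlinear least squares of
#' `y(x) = y0 + sum_i A_i * exp(-((x - mu_i) / sigma_i)^2)`
#' to the binned counts, where `y0` is the baseline, `A_i` the peak
#' amplitude, `mu_i` the peak center and `sigma_i` the peak width. Peak
#' centers are initialized at the TDP-derived consensus state centers and
#' allowed to vary within `center_window` of them; amplitudes are bound
#' non-negative and widths to `[0.05, 0.5]` to prevent peak-swallowing
#' degeneracies. Bin weights are `1 / SE^2`, with zero-SE bins given the
#' median weight. Goodness of fit is the reduced chi-squared.
#'
#' @param hist a [compile_histogram()] result.
#' @param centers TDP-derived peak centers (one per state), see
#'   [find_peak_centers()].
#' @param center_window allowed deviation of each fitted center from its
#'   TDP value.
#' @param sigma_bounds lower/upper bounds on peak widths.
#' @return object of class `tk_histfit`: list with `y0`, `peaks` (tibble
#'   `state`, `amplitude`, `center`, `width`, `area`, `fraction`,
#'   `fraction_se`), `red_chisq`, `converged`, `vcov`, `n_bins` and the
#'   input histogram.
#' @export
fit_multipeak <- function(hist, centers, center_window = 0.15,
                          sigma_bounds = c(0.05, 0.5)) {
  centers <- sort(as.numeric(centers))
  np <- length(centers)
  x <- hist$bin_mid
  y <- hist$count
  w <- 1 / hist$se^2
  w[!is.finite(w)] <- NA
  w[is.na(w)] <- stats::median(w, na.rm = TRUE)
  if (all(is.na(w))) w <- rep(1, length(y))

  amp0 <- vapply(centers, function(m) {
    max(y[abs(x - m) <= 0.15], 1)
  }, numeric(1))
  start <- c(y0 = 0,
             stats::setNames(amp0, paste0("A", seq_len(np))),
             stats::setNames(centers, paste0("mu", seq_len(np))),
             stats::setNames(rep(0.15, np), paste0("sg", seq_len(np))))
  lower <- c(0, rep(0, np), centers - center_window,
             rep(sigma_bounds[1], np))
  upper <- c(max(y), rep(2 * max(y), np), centers + center_window,
             rep(sigma_bounds[2], np))

  model_fun <- function(par) {
    yhat <- rep(par[1], length(x))
    for (i in seq_len(np)) {
      yhat <- yhat + par[1 + i] *
        exp(-((x - par[1 + np + i]) / par[1 + 2 * np + i])^2)
    }
    yhat
  }
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = lower, upper = upper,
    fn = function(par) sqrt(w) * (y - model_fun(par)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 0) {
    stop("multipeak Gaussian fit failed to converge: ", fit$message,
         call. = FALSE)
  }
  par <- fit$par
  npar <- length(par)
  red_chisq <- sum((sqrt(w) * (y - model_fun(par)))^2) /
    max(length(y) - npar, 1)
  vc <- tryCatch(solve(fit$hessian) *
                   sum(fit$fvec^2) / max(length(y) - npar, 1),
                 error = function(e) matrix(NA_real_, npar, npar))

  A <- par[1 + seq_len(np)]
  mu <- par[1 + np + seq_len(np)]
  sg <- par[1 + 2 * np + seq_len(np)]
  areas <- A * sg * sqrt(pi)
  fractions <- areas / sum(areas)

  # delta-method SE of each fractional area from the fit covariance
  frac_se <- rep(NA_real_, np)
  if (all(is.finite(vc))) {
    for (i in seq_len(np)) {
      g <- numeric(npar)
      S <- sum(areas)
      for (j in seq_len(np)) {
        dA <- sg[j] * sqrt(pi)
        dS <- A[j] * sqrt(pi)
        ind <- (i == j)
        g[1 + j] <- (ind * dA * S - areas[i] * dA) / S^2
        g[1 + 2 * np + j] <- (ind * dS * S - areas[i] * dS) / S^2
      }
      frac_se[i] <- sqrt(drop(t(g) %*% vc %*% g))
    }
  }

  structure(list(
    y0 = unname(par[1]),
    peaks = tibble::tibble(state = seq_len(np), amplitude = unname(A),
                           center = unname(mu), width = unname(sg),
                           area = unname(areas),
                           fraction = unname(fractions),
                           fraction_se = frac_se),
    red_chisq = red_chisq, converged = fit$info > 0, vcov = vc,
    n_bins = length(y), histogram = hist,
    fitted = model_fun(par)),
    class = "tk_histfit")
}

#' @export
print.tk_histfit <- function(x, ...) {
  cat(sprintf("<tk_histfit> %d peak(s), reduced chi-sq %.3f, y0 = %.2f\n",
              nrow(x$peaks), x$red_chisq, x$y0))
  print(x$peaks)
  invisible(x)
}

#' Fractional peak areas of a multipeak Gaussian fit
#'
#' The absolute area of each peak is the analytic integral of its term,
#' `A_i * sigma_i * sqrt(pi)`; fractional areas divide by the summed area.
#'
#' @param fit a [fit_multipeak()] result.
#' @return tibble with columns `state`, `area`, `fraction`, `fraction_se`.
#' @export
peak_areas <- function(fit) {
  stopifnot(inherits(fit, "tk_histfit"))
  fit$peaks[, c("state", "area", "fraction", "fraction_se")]
}
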
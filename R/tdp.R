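#' Build a two-dimensional transition density plot
#'
#' Gaussian kernel density of (initial, final) normalized intensities over
#' all transition events, on a fixed grid. Off-diagonal clusters identify
#' exchanging state pairs; the diagonal band is empty by construction
#' because self-transitions do not exist after idealization (events closer
#' to the diagonal than `diag_tol` are dropped as a guard).
#'
#' @param events tibble of transition events with columns `from_level` and
#'   `to_level` (normalized intensities), e.g. from [extract_dwells()].
#' @param grid_step grid spacing in normalized intensity units.
#' @param bandwidth Gaussian kernel standard deviation.
#' @param range grid range (applied to both axes).
#' @param diag_tol half-width of the excluded diagonal band.
#' @return object of class `tk_tdp`: list with `density` (matrix, rows =
#'   initial intensity, columns = final), `x`/`y` grid vectors,
#'   `n_transitions`, `bandwidth`, `grid_step`.
#' @export
build_tdp <- function(events, grid_step = 0.02, bandwidth = 0.08,
                      range = c(0.5, 3.5), diag_tol = 0.3) {
  x <- events$from_level
  y <- events$to_level
  keep <- abs(x - y) >= diag_tol
  x <- x[keep]
  y <- y[keep]
  if (length(x) == 0) {
    stop("no off-diagonal transition events; cannot build a TDP",
         call. = FALSE)
  }
  gx <- seq(range[1], range[2], by = grid_step)
  # separable Gaussian kernel: density = (1/n) sum_i K(gx - x_i) K(gy - y_i)
  Kx <- stats::dnorm(outer(gx, x, "-"), sd = bandwidth)
  Ky <- stats::dnorm(outer(gx, y, "-"), sd = bandwidth)
  dens <- Kx %*% t(Ky) / length(x)
  dens <- dens / (sum(dens) * grid_step^2)
  structure(list(density = dens, x = gx, y = gx,
                 n_transitions = length(x), bandwidth = bandwidth,
                 grid_step = grid_step),
            class = "tk_tdp")
}

#' @export
print.tk_tdp <- function(x, ...) {
  cat(sprintf("<tk_tdp> %d x %d grid, n = %d transitions\n",
              length(x$x), length(x$y), x$n_transitions))
  invisible(x)
}

#' Convert a TDP to a long tibble
#'
#' @param x a [build_tdp()] result.
#' @param ... unused.
#' @return tibble with columns `initial`, `final`, `density`.
#' @export
tidy.tk_tdp <- function(x, ...) {
  tibble::tibble(initial = rep(x$x, times = length(x$y)),
                 final = rep(x$y, each = length(x$x)),
                 density = as.vector(x$density))
}

# local maxima of the TDP grid above a relative threshold
tdp_local_maxima <- function(tdp, rel_threshold = 0.05) {
  d <- tdp$density
  n <- nrow(d)
  thr <- rel_threshold * max(d)
  peaks <- list()
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      v <- d[i, j]
      if (v < thr) next
      nb <- d[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v >= max(nb)) {
        peaks[[length(peaks) + 1]] <- c(x = tdp$x[i], y = tdp$y[j],
                                        density = v)
      }
    }
  }
  if (length(peaks) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(),
                          density = numeric()))
  }
  tibble::as_tibble(do.call(rbind, peaks))
}

#' Locate consensus state centers from a TDP
#'
#' Finds the local maxima of the transition density, then pools the
#' initial- and final-intensity coordinates of all peaks and clusters them
#' into `n_states` groups (1-D k-means seeded at the coordinate
#' quantiles, weighted by peak density). The density-weighted mean of each
#' group — which averages the two marginal projections of every symmetric
#' peak pair — is the consensus emission level of one state. Because peak
#' pairs enter through both coordinates, the centers are invariant to
#' mirroring the TDP about its diagonal.
#'
#' @param tdp a [build_tdp()] result.
#' @param n_states number of consensus states (2 or 3); `NULL` detects the
#'   number of well-separated intensity levels automatically.
#' @param rel_threshold peaks below this fraction of the maximum density
#'   are ignored.
#' @param gap_tol minimum intensity gap separating two distinct state
#'   levels (normalized units; half the nominal unit spacing).
#' @return numeric vector of centers, strictly increasing.
#' @export
find_peak_centers <- function(tdp, n_states = NULL, rel_threshold = 0.05,
                              gap_tol = 0.5) {
  peaks <- tdp_local_maxima(tdp, rel_threshold)
  if (nrow(peaks) == 0) stop("no TDP peaks found", call. = FALSE)
  coords <- c(peaks$x, peaks$y)
  w <- rep(peaks$density, 2)
  groups <- merge_groups(coords, gap_tol)
  ng <- max(groups)
  if (!is.null(n_states) && ng < n_states &&
      diff(range(coords)) > gap_tol) {
    # gap clustering can chain distinct levels through stray peaks; fall
    # back to density-weighted 1-D k-means seeded at coordinate quantiles
    centers <- as.numeric(stats::quantile(
      coords, (2 * seq_len(n_states) - 1) / (2 * n_states), names = FALSE))
    for (it in 1:100) {
      g <- vapply(coords, function(v) which.min(abs(v - centers)),
                  integer(1))
      upd <- vapply(seq_len(n_states), function(k) {
        if (!any(g == k)) return(centers[k])
        sum(coords[g == k] * w[g == k]) / sum(w[g == k])
      }, numeric(1))
      if (max(abs(upd - centers)) < 1e-12) break
      centers <- upd
    }
    groups <- vapply(coords, function(v) which.min(abs(v - centers)),
                     integer(1))
    ng <- length(unique(groups))
    groups <- match(groups, sort(unique(groups)))
  }
  if (!is.null(n_states)) {
    if (ng < n_states) {
      stop(sprintf(paste("TDP shows only %d distinct intensity level(s);",
                         "reduce `n_states` below %d"), ng, n_states),
           call. = FALSE)
    }
    if (ng > n_states) {
      # keep the n_states groups carrying the most transition density
      mass <- tapply(w, groups, sum)
      keep <- as.integer(names(sort(mass, decreasing = TRUE)))[seq_len(n_states)]
      sel <- groups %in% keep
      coords <- coords[sel]
      w <- w[sel]
      groups <- match(groups[sel], sort(keep))
    }
  }
  centers <- vapply(sort(unique(groups)), function(g) {
    sum(coords[groups == g] * w[groups == g]) / sum(w[groups == g])
  }, numeric(1))
  sort(centers)
}

#' Define intensity cutoffs between consensus states
#'
#' The boundary between adjacent states is the midpoint of their TDP peak
#' centers — the symmetric, assumption-free partition of the intensity
#' axis.
#'
#' @param centers strictly increasing numeric vector of state centers.
#' @return object of class `tk_cutoffs`: list with `centers` and
#'   `boundaries` (length `length(centers) - 1`).
#' @export
define_cutoffs <- function(centers) {
  centers <- as.numeric(centers)
  if (length(centers) < 2) {
    stop("need at least 2 centers to define cutoffs", call. = FALSE)
  }
  if (any(diff(centers) <= 0)) {
    stop("`centers` must be strictly increasing", call. = FALSE)
  }
  structure(list(centers = centers,
                 boundaries = (centers[-1] + centers[-length(centers)]) / 2),
            class = "tk_cutoffs")
}

#' @export
print.tk_cutoffs <- function(x, ...) {
  cat("<tk_cutoffs> centers:",
      paste(format(x$centers, digits = 4), collapse = ", "),
      "| boundaries:",
      paste(format(x$boundaries, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Assign a coarse state to each intensity level
#'
#' @param level numeric vector of normalized intensities.
#' @param cutoffs a [define_cutoffs()] result.
#' @return integer vector of state indices (1..K). A level exactly on a
#'   boundary is assigned to the lower state (deterministic tie-break).
#' @export
assign_state <- function(level, cutoffs) {
  b <- cutoffs$boundaries
  out <- rep(1L, length(level))
  for (k in seq_along(b)) out[level > b[k]] <- k + 1L
  out
}

#' Classify transition events into state-pair classes
#'
#' Assigns every transition event a (from, to) state pair by which side of
#' each cutoff boundary its initial and final intensities fall, and
#' tabulates counts and fractions per class. The fraction of direct
#' transitions between the lowest and highest state (skipping the
#' intermediate) is reported explicitly, since sequential activation
#' predicts it to be rare.
#'
#' @param events tibble with `from_level` and `to_level` columns.
#' @param cutoffs a [define_cutoffs()] result.
#' @return object of class `tk_transitions`: list with `classes` (tibble
#'   `from_state`, `to_state`, `count`, `fraction`), `n_transitions`, and
#'   `skip_fraction` (1<->K fraction; `NA` for 2-state systems).
#' @export
classify_transitions <- function(events, cutoffs) {
  from <- assign_state(events$from_level, cutoffs)
  to <- assign_state(events$to_level, cutoffs)
  K <- length(cutoffs$centers)
  classes <- tibble::tibble(from_state = from, to_state = to) |>
    dplyr::count(.data$from_state, .data$to_state, name = "count") |>
    dplyr::mutate(fraction = .data$count / sum(.data$count))
  skip <- if (K >= 3) {
    sum(classes$count[(classes$from_state == 1 & classes$to_state == K) |
                        (classes$from_state == K & classes$to_state == 1)]) /
      sum(classes$count)
  } else {
    NA_real_
  }
  structure(list(classes = classes, n_transitions = length(from),
                 skip_fraction = skip),
            class = "tk_transitions")
}

#' @export
print.tk_transitions <- function(x, ...) {
  cat(sprintf("<tk_transitions> n = %d\n", x$n_transitions))
  print(x$classes)
  if (!is.na(x$skip_fraction)) {
    cat(sprintf("  1<->%d skip fraction: %.2f%%\n",
                max(x$classes$from_state, x$classes$to_state),
                100 * x$skip_fraction))
  }
  invisible(x)
}
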
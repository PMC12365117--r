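#' Locate the interior global extremum of a peak/valley-shaped series
#'
#' Returns the index of the global maximum if the series is peak-shaped
#' (interior maximum) and otherwise of the global minimum; the extremum must
#' be strictly interior. Ties are broken toward the earliest time point.
#'
#' @param z Numeric series (>= 7 points so both segments keep >= 3 points
#'   plus the shared extremum).
#' @param times Observation times, strictly increasing.
#' @return Integer index of the extremum.
#' @export
find_global_extremum <- function(z, times) {
  stopifnot(length(z) == length(times), length(z) >= 7)
  n <- length(z)
  i_max <- which.max(z)   # which.max/min already take the earliest tie
  i_min <- which.min(z)
  idx <- if (i_max > 1 && i_max < n) i_max
         else if (i_min > 1 && i_min < n) i_min
         else stop("monotonic; use monotonic fitting")
  as.integer(idx)
}

#' Piecewise logistic fit for peak- or valley-shaped profiles
#'
#' Splits the series at its interior global extremum, fits each side with
#' [fit_best()] (the extremum point is shared), vertically shifts the right
#' segment so the two fitted curves meet exactly at the extremum time
#' (zero-order continuity), then smooths the concatenated analytic curve
#' with a quadratic B-spline on a dense time grid, which enforces
#' first-derivative continuity at the junction. Reported values are the
#' spline evaluated at the observed times.
#'
#' @param z Numeric series.
#' @param times Observation times, strictly increasing.
#' @param grid_n Size of the dense grid used for spline smoothing.
#' @return Object of class `piecewise_fit`: list with `t_peak`, `peak_index`,
#'   `left_fit`, `right_fit`, `offset_right`, `k_left`, `k_right`, `k_avg`,
#'   `smoothed` (at observed times), `mse` (observed vs smoothed),
#'   `spline_ode_mse` (dense-grid MSE between spline and aligned segments,
#'   normalized by squared signal range), `converged`.
#' @export
fit_piecewise <- function(z, times, grid_n = 200) {
  idx <- find_global_extremum(z, times)
  t_peak <- times[idx]
  fail <- structure(list(converged = FALSE, t_peak = t_peak,
                         peak_index = idx), class = "piecewise_fit")
  # each segment needs >= 3 points besides the shared extremum (the ODE
  # fitter itself needs 4 points)
  if (idx < 4 || idx > length(z) - 3) return(fail)

  left  <- fit_best(z[1:idx], times[1:idx])
  right <- fit_best(z[idx:length(z)], times[idx:length(z)])
  if (!isTRUE(left$converged) || !isTRUE(right$converged)) return(fail)

  eval_fit <- function(fit, t)
    reconstruct_original(t, fit$k, fit$a, fit$b,
                         fit$fitted_original[1], fit$t_start)
  offset_right <- eval_fit(left, t_peak) - eval_fit(right, t_peak)

  # dense concatenated analytic curve (left of the peak from the left
  # segment, right of it from the aligned right segment)
  grid <- seq(times[1], times[length(times)], length.out = grid_n)
  grid <- sort(unique(c(grid, t_peak)))
  curve <- ifelse(grid <= t_peak,
                  eval_fit(left, grid),
                  eval_fit(right, grid) + offset_right)

  # quadratic B-spline with a knot at the junction; C1-smooth there
  inner <- seq(times[1], times[length(times)], length.out = 26)
  knots <- sort(unique(c(inner[-c(1, length(inner))], t_peak)))
  basis <- splines::bs(grid, knots = knots, degree = 2, intercept = TRUE,
                       Boundary.knots = range(grid))
  sfit <- stats::lm.fit(x = basis, y = curve)
  spline_grid <- drop(basis %*% sfit$coefficients)
  obs_basis <- splines::bs(times, knots = knots, degree = 2, intercept = TRUE,
                           Boundary.knots = range(grid))
  smoothed <- drop(obs_basis %*% sfit$coefficients)

  rng <- diff(range(z))
  structure(list(
    converged = TRUE, t_peak = t_peak, peak_index = idx,
    left_fit = left, right_fit = right, offset_right = offset_right,
    k_left = left$k, k_right = right$k,
    k_avg = (abs(left$k) + abs(right$k)) / 2,
    smoothed = smoothed, mse = mean((z - smoothed)^2),
    spline_ode_mse = mean((spline_grid - curve)^2) / rng^2,
    aligned_at_peak = eval_fit(left, t_peak),
    times = times
  ), class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<piecewise_fit> non-converged (peak at day", x$t_peak, ")\n")
  } else {
    cat(sprintf(
      "<piecewise_fit> peak day %.3g; k_left = %.3g, k_right = %.3g, k_avg = %.3g, mse = %.3g\n",
      x$t_peak, x$k_left, x$k_right, x$k_avg, x$mse))
  }
  invisible(x)
}
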
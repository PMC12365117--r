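# Attained bounds of the two normalization ranges. The "unit" range is
# [1e-5, 1]; the "shifted" range is the unit range moved up by one, so its
# attained bounds are [1 + 1e-5, 2]. Storing the attained bounds makes
# normalization/inversion an exact round trip.
.range_bounds <- function(range_id) {
  switch(range_id,
    unit    = c(1e-5, 1),
    shifted = c(1 + 1e-5, 2),
    stop("unknown range_id: ", range_id)
  )
}

#' Min-max normalize a genomic signal vector
#'
#' Rescales a raw signal vector `z` onto one of the two ranges used before
#' logistic-ODE fitting: the unit range \eqn{[10^{-5}, 1]} (suited to signals
#' that include an acceleration phase) or the shifted range (unit range plus
#' one, bounds \eqn{[1 + 10^{-5}, 2]}), which places data onto the
#' deceleration half of the logistic curve.
#'
#' @param z Numeric vector of raw signal values (finite, non-constant).
#' @param times Numeric vector of observation times (days), strictly
#'   increasing, same length as `z`.
#' @param range_id `"unit"` or `"shifted"`.
#' @return An object of class `normalized_series`: a list with `y_star`,
#'   `times`, `range_id`, `R_min`, `R_max`, `z_min`, `z_max`.
#' @export
minmax_normalize <- function(z, times, range_id = c("unit", "shifted")) {
  range_id <- match.arg(range_id)
  stopifnot(is.numeric(z), is.numeric(times), length(z) == length(times))
  if (!all(is.finite(z))) stop("non-finite values in series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  z_min <- min(z); z_max <- max(z)
  if (z_max == z_min) stop("degenerate series: constant vector")
  unit <- (z - z_min) * (1 - 1e-5) / (z_max - z_min) + 1e-5
  y_star <- if (range_id == "shifted") unit + 1 else unit
  b <- .range_bounds(range_id)
  structure(list(y_star = y_star, times = times, range_id = range_id,
                 R_min = b[1], R_max = b[2], z_min = z_min, z_max = z_max),
            class = "normalized_series")
}

#' Map normalized logistic parameters back to original units
#'
#' Inverts the min-max normalization for the asymptote parameters: the same
#' affine map that carried `z` onto `[R_min, R_max]` is applied in reverse to
#' `a*` and `b*`. The rate constant k is invariant under this map and is not
#' transformed.
#'
#' @param a_star,b_star Lower/upper asymptotes in normalized space.
#' @param range_id `"unit"` or `"shifted"`.
#' @param z_min,z_max Original data range used for normalization.
#' @return Named list with `a` and `b` in original units.
#' @export
inverse_transform_params <- function(a_star, b_star, range_id, z_min, z_max) {
  stopifnot(z_max > z_min)
  b <- .range_bounds(range_id)
  R_min <- b[1]; R_max <- b[2]
  back <- function(v) (v - R_min) * (z_max - z_min) / (R_max - R_min) + z_min
  list(a = back(a_star), b = back(b_star))
}

#' Closed-form solution of the simplified logistic ODE
#'
#' Evaluates \eqn{y^*(t) = b^* C^* e^{k^* t} / (b^* + C^* e^{k^* t})} with the
#' integration constant fixed by the initial condition
#' \eqn{y^*(t_{start}) = y^*_{start}}. Computed in log-space
#' (\eqn{y^*(t) = b^* \sigma(k^*(t - t_{start}) - \ln(b^*/y^*_{start} - 1))},
#' with \eqn{\sigma} the standard logistic) so it never overflows for large
#' \eqn{|k^* t|}.
#'
#' @param t Numeric vector of times (days).
#' @param k_star Rate constant (per day, nonzero sign allowed either way).
#' @param b_star Upper asymptote (> 0).
#' @param y_start_star Initial value, strictly inside (0, b_star).
#' @param t_start Time of the initial condition.
#' @return Numeric vector `y_star(t)`.
#' @export
analytic_solution <- function(t, k_star, b_star, y_start_star, t_start) {
  if (b_star <= 0) stop("b_star must be positive")
  if (y_start_star <= 0 || y_start_star >= b_star)
    stop("y_start_star must lie strictly inside (0, b_star)")
  b_star * stats::plogis(k_star * (t - t_start) - log(b_star / y_start_star - 1))
}

#' Analytic logistic curve in the original data range
#'
#' Evaluates \eqn{z(t) = (b-a) C e^{kt} / (1 + C e^{kt}) + a} with C fixed by
#' \eqn{z(t_{start}) = z_{start}}. This is the generalized-logistic curve the
#' fitted normalized solution maps onto under the inverse min-max transform.
#'
#' @param t Times (days).
#' @param k Rate constant.
#' @param a,b Lower/upper asymptotes in original units, `b > a`.
#' @param z_start Initial value, strictly inside (a, b).
#' @param t_start Time of the initial condition.
#' @return Numeric vector `z(t)`.
#' @export
reconstruct_original <- function(t, k, a, b, z_start, t_start) {
  if (b <= a) stop("requires b > a")
  if (z_start <= a || z_start >= b)
    stop("z_start outside (a, b)")
  a + (b - a) * stats::plogis(k * (t - t_start) + log((z_start - a) / (b - z_start)))
}

# Residual model used by the optimizer; returns large residuals instead of
# NaN when the optimizer steps outside the valid region (b <= y_start).
.logistic_model <- function(par, times, y, y_start, t_start) {
  k <- par[["k"]]; b <- par[["b"]]
  if (!is.finite(k) || !is.finite(b) || b <= y_start) {
    return(rep(1e6, length(y)))
  }
  y - b * stats::plogis(k * (times - t_start) - log(b / y_start - 1))
}

#' Fit the simplified logistic ODE to one normalized series
#'
#' Nonlinear least squares of the closed-form logistic solution against the
#' normalized values, over (k*, b*), starting from the given initial guesses.
#' The initial value y*_start is pinned to the first observation, so the
#' fitted curve passes through it exactly. The search is constrained to the
#' logistic parameter space (b* > y*_start, |k*| <= 50, b* <= 10); if the
#' optimizer fails or exits that space a non-converged record is returned
#' rather than an error.
#'
#' @param series A `normalized_series` from [minmax_normalize()].
#' @param k_init Initial guess for k* (default 0.9; use -0.9 for decreasing).
#' @param b_init Initial guess for b* (default 1.5).
#' @param max_evals Maximum residual evaluations for the optimizer.
#' @return An object of class `logistic_fit` (see [fit_best()]); check the
#'   `converged` field.
#' @export
fit_simplified_ode <- function(series, k_init = 0.9, b_init = 1.5,
                               max_evals = 5000) {
  stopifnot(inherits(series, "normalized_series"))
  y <- series$y_star; times <- series$times
  if (length(y) < 4) stop("need at least 4 time points")
  y_start <- y[1]; t_start <- times[1]

  fail <- function() .fit_record(series, k_init, converged = FALSE)

  if (stats::sd(y) == 0) return(fail())
  b_lo <- max(1e-6, y_start * (1 + 1e-9))
  b0 <- max(b_init, b_lo * (1 + 1e-6))
  res <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = c(k = k_init, b = b0),
      lower = c(k = -50, b = b_lo), upper = c(k = 50, b = 10),
      fn = .logistic_model, times = times, y = y,
      y_start = y_start, t_start = t_start,
      control = minpack.lm::nls.lm.control(maxfev = max_evals, maxiter = 1000,
                                           ftol = 1e-15, ptol = 1e-15))),
    error = function(e) NULL)
  if (is.null(res)) return(fail())
  k <- res$par[["k"]]; b <- res$par[["b"]]
  if (!is.finite(k) || !is.finite(b) || b <= 0 || b <= y_start) return(fail())
  fitted <- analytic_solution(times, k, b, y_start, t_start)
  mse <- mean((y - fitted)^2)
  if (!is.finite(mse) || mse >= 1e6) return(fail())
  .fit_record(series, k_init, converged = TRUE, k_star = k, b_star = b,
              fitted = fitted, mse = mse)
}

# Assemble a logistic_fit record (converged or not) from a normalized series.
.fit_record <- function(series, k_init, converged, k_star = NA_real_,
                        b_star = NA_real_, fitted = NULL, mse = NA_real_) {
  y_start <- series$y_star[1]; t_start <- series$times[1]
  if (converged) {
    ab <- inverse_transform_params(0, b_star, series$range_id,
                                   series$z_min, series$z_max)
    C_star <- y_start / ((1 - y_start / b_star) * exp(k_star * t_start))
    z_start <- inverse_transform_params(y_start, y_start, series$range_id,
                                        series$z_min, series$z_max)$a
    fitted_orig <- reconstruct_original(series$times, k_star, ab$a, ab$b,
                                        z_start, t_start)
  } else {
    ab <- list(a = NA_real_, b = NA_real_)
    C_star <- NA_real_
    fitted_orig <- NULL
  }
  structure(list(
    k_star = k_star, b_star = b_star, a_star = if (converged) 0 else NA_real_,
    k = k_star, a = ab$a, b = ab$b, C_star = C_star,
    y_start_star = y_start, t_start = t_start,
    mse = mse, range_id = series$range_id,
    z_min = series$z_min, z_max = series$z_max,
    k_init = k_init, converged = converged,
    fitted_normalized = fitted, fitted_original = fitted_orig,
    times = series$times
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<logistic_fit> non-converged (range", x$range_id,
        ", k_init", x$k_init, ")\n")
  } else {
    cat(sprintf(
      "<logistic_fit> k = %.4g, b = %.4g (b* = %.4g, range %s), mse = %.3g\n",
      x$k, x$b, x$b_star, x$range_id, x$mse))
  }
  invisible(x)
}

#' Fit all four initial-guess/range candidates for a raw series
#'
#' Runs the simplified-ODE fit for the four combinations
#' (unit/+k, unit/-k, shifted/+k, shifted/-k) in that (tie-break) order.
#'
#' @inheritParams fit_best
#' @return List of four `logistic_fit` records (an entry may be NULL when
#'   normalization itself fails, e.g. a constant series).
#' @export
fit_candidates <- function(z, times, k_init = 0.9, b_init = 1.5,
                           max_evals = 5000) {
  combos <- list(c("unit", 1), c("unit", -1), c("shifted", 1), c("shifted", -1))
  lapply(combos, function(cmb) {
    series <- tryCatch(minmax_normalize(z, times, cmb[[1]]),
                       error = function(e) NULL)
    if (is.null(series)) return(NULL)
    fit_simplified_ode(series, k_init = as.numeric(cmb[[2]]) * abs(k_init),
                       b_init = b_init, max_evals = max_evals)
  })
}

#' Fit a raw series with all four initial-guess/range combinations
#'
#' Runs the simplified-ODE fit on the series normalized to the unit and
#' shifted ranges, each with positive and negative initial rate guesses
#' (+0.9/-0.9), discards candidates that fail to converge on a positive b*,
#' and returns the converged candidate with the lowest normalized-space MSE.
#' MSE ties are broken deterministically: unit range before shifted, positive
#' k_init before negative.
#'
#' @param z Raw signal vector.
#' @param times Observation times (days), strictly increasing.
#' @param k_init Magnitude of the rate initial guess (both signs are tried).
#' @param b_init Initial guess for b*.
#' @param max_evals Maximum residual evaluations per candidate.
#' @return A `logistic_fit`; `converged = FALSE` if all four candidates fail.
#' @export
fit_best <- function(z, times, k_init = 0.9, b_init = 1.5, max_evals = 5000) {
  cands <- fit_candidates(z, times, k_init = k_init, b_init = b_init,
                          max_evals = max_evals)
  ok <- !vapply(cands, is.null, logical(1)) &
    vapply(cands, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) {
    # emit a non-converged record carrying the data context if possible
    series <- tryCatch(minmax_normalize(z, times, "unit"),
                       error = function(e) NULL)
    if (is.null(series)) {
      return(structure(list(converged = FALSE, mse = NA_real_,
                            k = NA_real_, b = NA_real_, a = NA_real_,
                            k_star = NA_real_, b_star = NA_real_,
                            range_id = NA_character_, times = times),
                       class = "logistic_fit"))
    }
    return(.fit_record(series, k_init, converged = FALSE))
  }
  mses <- vapply(cands, function(f) if (isTRUE(f$converged)) f$mse else Inf,
                 numeric(1))
  # candidate order is already the declared tie-break order; which.min picks
  # the first minimum
  cands[[which.min(mses)]]
}

#' Characteristic times of a fitted logistic curve
#'
#' Computes the inflection (switching) time and the effective start/end of
#' the transition from the normalized parameters:
#' \deqn{t_{switch} = \frac{1}{k^*}\ln(b^*/y^*_{start} - 1) + t_{start}}
#' \deqn{t_{minimum} = \frac{1}{k^*}\ln(10^{-16} b^*/y^*_{start}) + t_{start}}
#' \deqn{t_{saturation} = \frac{1}{k^*}\ln(99 b^*/y^*_{start} - 99) + t_{start}}
#' When the switching-time log argument is not positive (y*_start >= b*, a fit
#' past its inflection before observation), t_switch is the -Inf sentinel.
#'
#' @param k_star Rate constant (nonzero).
#' @param b_star Upper asymptote (> 0).
#' @param y_start_star Initial normalized value.
#' @param t_start First observed day.
#' @return Named list `t_switch`, `t_minimum`, `t_saturation` (days; may be
#'   infinite sentinels when a log argument is non-positive).
#' @export
characteristic_times <- function(k_star, b_star, y_start_star, t_start) {
  if (k_star == 0) stop("k_star must be nonzero")
  safe_log_time <- function(arg) {
    arg <- unname(arg)
    if (arg <= 0) -Inf
    else unname(log(arg) / k_star + t_start)
  }
  list(
    t_switch     = safe_log_time(b_star / y_start_star - 1),
    t_minimum    = safe_log_time(1e-16 * b_star / y_start_star),
    t_saturation = safe_log_time(99 * b_star / y_start_star - 99)
  )
}

#' Classify a kinetic profile from its switching time
#'
#' A profile is a switcher if the inflection falls inside the observed
#' window, a decelerator if it happened before the first observed day
#' (including the -Inf sentinel), and an accelerator if it is projected after
#' the last observed day.
#'
#' @param t_switch Switching time (days; may be +-Inf).
#' @param t_start,t_end Observed window bounds, `t_start < t_end`.
#' @return One of `"switcher"`, `"decelerator"`, `"accelerator"`.
#' @export
classify_kinetics <- function(t_switch, t_start, t_end) {
  stopifnot(t_start < t_end)
  ifelse(t_switch < t_start, "decelerator",
         ifelse(t_switch > t_end, "accelerator", "switcher"))
}

#' Annotate a converged fit with direction, times and kinetic class
#'
#' @param fit A converged `logistic_fit`.
#' @param t_end Last day of the observed window (default: last fitted time).
#' @return List with `direction`, `t_switch`, `t_minimum`, `t_saturation`,
#'   `kinetic_class`.
#' @export
annotate_kinetics <- function(fit, t_end = max(fit$times)) {
  stopifnot(inherits(fit, "logistic_fit"), isTRUE(fit$converged))
  ct <- characteristic_times(fit$k_star, fit$b_star, fit$y_start_star,
                             fit$t_start)
  c(list(direction = if (fit$k_star > 0) "activated" else "repressed",
         kinetic_class = classify_kinetics(ct$t_switch, fit$t_start, t_end)),
    ct)
}

#' Fit every row of a feature-by-time matrix
#'
#' Convenience driver: [fit_best()] on each row, with kinetic annotation for
#' converged rows.
#'
#' @param mat Numeric matrix, rows = features, columns = time points.
#' @param times Numeric time points (days), one per column.
#' @param t_end End of the kinetic-classification window (default last time).
#' @return List with `params` (data.frame, one row per feature: feature_id,
#'   converged, range_used, k, b, a, mse, direction, t_switch, t_minimum,
#'   t_saturation, kinetic_class) and `fitted` (matrix of fitted values in
#'   the original range; NA rows for non-converged fits).
#' @export
fit_matrix <- function(mat, times, t_end = max(times)) {
  stopifnot(is.matrix(mat), ncol(mat) == length(times))
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("feature_", seq_len(nrow(mat)))
  fitted <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  rows <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    fit <- fit_best(mat[i, ], times)
    if (isTRUE(fit$converged)) {
      ann <- annotate_kinetics(fit, t_end = t_end)
      fitted[i, ] <- fit$fitted_original
      rows[[i]] <- data.frame(
        feature_id = ids[i], converged = TRUE, range_used = fit$range_id,
        k = fit$k, b = fit$b, a = fit$a, mse = fit$mse,
        direction = ann$direction, t_switch = ann$t_switch,
        t_minimum = ann$t_minimum, t_saturation = ann$t_saturation,
        kinetic_class = ann$kinetic_class, stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        feature_id = ids[i], converged = FALSE, range_used = NA_character_,
        k = NA_real_, b = NA_real_, a = NA_real_, mse = NA_real_,
        direction = NA_character_, t_switch = NA_real_,
        t_minimum = NA_real_, t_saturation = NA_real_,
        kinetic_class = NA_character_, stringsAsFactors = FALSE)
    }
  }
  list(params = do.call(rbind, rows), fitted = fitted)
}

#' Group features into (|k|, b) quadrants by k-means
#'
#' Clusters standardized (|k|, b) pairs with k-means (K = 3, multiple
#' restarts under a fixed seed) and names the clusters by centroid position:
#' Q1 = high |k| & low b, Q2 = low & low, Q3 = low |k| & high b. The Q4
#' region (high |k| and high b) is reported empty when no centroid falls
#' above the centroid midrange in both coordinates.
#'
#' @param k Numeric vector of rate constants (sign ignored).
#' @param b Numeric vector of saturation levels, same length.
#' @param K Number of clusters (default 3).
#' @param seed Seed for the k-means restarts.
#' @param nstart Number of random restarts.
#' @return List with `quadrant` (character vector of labels per point),
#'   `centers` (original-scale centroids), `q4_empty` (logical).
#' @export
cluster_quadrants <- function(k, b, K = 3, seed = 1, nstart = 25) {
  stopifnot(length(k) == length(b))
  pts <- cbind(abs_k = abs(k), b = b)
  if (nrow(unique(pts)) < K) stop("fewer than K distinct (|k|, b) points")
  std <- scale(pts)
  km <- local({
    old <- .Random.seed_exists()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
    stats::kmeans(std, centers = K, nstart = nstart, iter.max = 100)
  })
  cen <- km$centers
  # name clusters: Q3 = highest b centroid; among the rest Q1 = highest |k|;
  # remaining centroids are Q2
  lab <- rep("Q2", K)
  lab[which.max(cen[, "b"])] <- "Q3"
  rest <- setdiff(seq_len(K), which.max(cen[, "b"]))
  lab[rest[which.max(cen[rest, "abs_k"])]] <- "Q1"
  mid_k <- mean(range(cen[, "abs_k"])); mid_b <- mean(range(cen[, "b"]))
  q4_empty <- !any(cen[, "abs_k"] > mid_k & cen[, "b"] > mid_b)
  centers_orig <- t(apply(cen, 1, function(r)
    r * attr(std, "scaled:scale") + attr(std, "scaled:center")))
  rownames(centers_orig) <- lab
  list(quadrant = lab[km$cluster], centers = centers_orig, q4_empty = q4_empty)
}

# Save/restore .Random.seed so seeded internals do not disturb the caller's
# RNG stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
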
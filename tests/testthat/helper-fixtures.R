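# shared fixtures: the 8-point developmental time grid and small builders

dev_times <- function() c(seq(10.5, 16.5, by = 1), 21)

# a normalized_series built directly from closed-form values (no re-scaling)
make_series <- function(k, b, y0, times = dev_times(), noise = 0,
                        range_id = "unit") {
  y <- analytic_solution(times, k, b, y0, times[1])
  if (noise > 0) y <- y + stats::rnorm(length(y), 0, noise * diff(range(y)))
  structure(list(y_star = y, times = times, range_id = range_id,
                 R_min = 1e-5, R_max = 1, z_min = 0, z_max = 1),
            class = "normalized_series")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
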
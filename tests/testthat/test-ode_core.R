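test_that("min-max normalization maps endpoints and shifts by one unit", {
  tt <- dev_times()
  z <- c(3, 4, 6, 9, 12, 14, 15, 15.5)
  u <- minmax_normalize(z, tt, "unit")
  expect_equal(u$y_star[which.min(z)], 1e-5)
  expect_equal(u$y_star[which.max(z)], 1)
  s <- minmax_normalize(z, tt, "shifted")
  expect_equal(s$y_star, u$y_star + 1)
  expect_error(minmax_normalize(rep(2, 8), tt), "degenerate")
})

test_that("normalization round-trips through the inverse parameter map", {
  tt <- dev_times()
  set.seed(4)
  z <- rnorm(8, 5, 2)
  for (rg in c("unit", "shifted")) {
    s <- minmax_normalize(z, tt, rg)
    back <- inverse_transform_params(s$y_star, s$y_star, rg, s$z_min, s$z_max)
    expect_equal(back$a, z, tolerance = 1e-14)
  }
})

test_that("inverse parameter transform maps range endpoints to data endpoints", {
  expect_equal(inverse_transform_params(1e-5, 1, "unit", 0, 10)$a, 0)
  expect_equal(inverse_transform_params(1e-5, 1, "unit", 0, 10)$b, 10)
  # arbitrary (a*, b*) forward-then-invert identity
  ab <- inverse_transform_params(0.23, 1.7, "unit", 2, 9)
  fw <- function(v, zmin, zmax) (v - zmin) * (1 - 1e-5) / (zmax - zmin) + 1e-5
  expect_equal(fw(ab$a, 2, 9), 0.23, tolerance = 1e-14)
  expect_equal(fw(ab$b, 2, 9), 1.7, tolerance = 1e-14)
})

test_that("closed-form solution honours initial condition, asymptote and inflection", {
  k <- 0.9; b <- 1; y0 <- 0.1; t0 <- 10.5
  expect_equal(analytic_solution(t0, k, b, y0, t0), y0)
  expect_equal(analytic_solution(1e4, k, b, y0, t0), b, tolerance = 1e-12)
  tsw <- characteristic_times(k, b, y0, t0)$t_switch
  expect_equal(analytic_solution(tsw, k, b, y0, t0), b / 2, tolerance = 1e-12)
  expect_error(analytic_solution(11, k, b, y_start_star = 1.2, t0))
  # no overflow at extreme |k t|
  expect_true(is.finite(analytic_solution(2000, 1.5, 1, 0.1, t0)))
})

test_that("closed-form solution satisfies the simplified ODE on a grid", {
  grid <- seq(10.5, 21, length.out = 400)
  h <- 1e-6
  for (par in list(c(0.9, 1, 0.05), c(-0.7, 1.4, 1.2), c(1.5, 2, 0.4))) {
    k <- par[1]; b <- par[2]; y0 <- par[3]
    y <- analytic_solution(grid, k, b, y0, 10.5)
    dy <- (analytic_solution(grid + h, k, b, y0, 10.5) -
           analytic_solution(grid - h, k, b, y0, 10.5)) / (2 * h)
    rhs <- k * y * (1 - y / b)
    # relative to the derivative scale (the residual floor is set by the
    # finite-difference roundoff where the curve saturates)
    expect_lt(max(abs(dy - rhs)) / max(abs(rhs)), 1e-6)
  }
})

test_that("noiseless normalized series are recovered near-exactly", {
  s <- make_series(0.9, 1.0, 1e-2)
  f <- fit_simplified_ode(s, k_init = 0.9)
  expect_true(f$converged)
  expect_rel_equal(f$k_star, 0.9, 1e-3)
  expect_rel_equal(f$b_star, 1.0, 1e-3)
  # fitted curve pinned at the first observation
  expect_equal(f$fitted_normalized[1], s$y_star[1], tolerance = 1e-10)
})

test_that("a constant normalized series yields a non-converged record", {
  s <- structure(list(y_star = rep(0.5, 8), times = dev_times(),
                      range_id = "unit", R_min = 1e-5, R_max = 1,
                      z_min = 0, z_max = 1),
                 class = "normalized_series")
  f <- fit_simplified_ode(s)
  expect_false(f$converged)
  expect_true(is.na(f$k_star))
})

test_that("decreasing series favour the negative initial rate guess", {
  s <- make_series(-0.9, 1.0, 0.9)
  fp <- fit_simplified_ode(s, k_init = 0.9)
  fn <- fit_simplified_ode(s, k_init = -0.9)
  expect_true(fn$converged)
  expect_lt(fn$mse, fp$mse %||% Inf)
  expect_lt(fn$k_star, 0)
})

test_that("best-candidate selection returns the minimum-MSE converged fit", {
  tt <- dev_times()
  spec <- simulation_spec(n_features = 25, noise_sd_fraction = 0.02, seed = 31)
  sim <- simulate_logistic_matrix(spec)
  for (i in seq_len(nrow(sim$matrix))) {
    z <- sim$matrix[i, ]
    cands <- fit_candidates(z, tt)
    best <- fit_best(z, tt)
    mses <- vapply(cands, function(f)
      if (!is.null(f) && isTRUE(f$converged)) f$mse else Inf, numeric(1))
    if (isTRUE(best$converged)) {
      expect_equal(best$mse, min(mses))
      expect_true(all(best$mse <= mses))
    } else {
      expect_true(all(!is.finite(mses)))
    }
  }
})

test_that("a full increasing sigmoid is fit on the unit range with k > 0", {
  tt <- dev_times()
  # fast full-range sigmoid: traverses 1e-5 -> 1 inside the window
  z <- analytic_solution(tt, 1.4, 1.37, 1e-5, tt[1])
  z <- z / max(z)
  f <- fit_best(5 * z + 2, tt)
  expect_true(f$converged)
  expect_equal(f$range_id, "unit")
  expect_gt(f$k, 0)
})

test_that("a pure deceleration tail converges with t_switch before the window", {
  tt <- dev_times()
  z <- analytic_solution(tt, 0.6, 1, 0.9, tt[1])   # starts at 0.9 b
  f <- fit_best(z, tt)
  expect_true(f$converged)
  ann <- annotate_kinetics(f)
  expect_lt(ann$t_switch, tt[1])
  expect_equal(ann$kinetic_class, "decelerator")
})

test_that("fitted curves are strictly monotone with the sign of k", {
  spec <- simulation_spec(n_features = 20, noise_sd_fraction = 0.02, seed = 12)
  sim <- simulate_logistic_matrix(spec)
  for (i in seq_len(20)) {
    f <- fit_best(sim$matrix[i, ], sim$times)
    if (!isTRUE(f$converged)) next
    d <- diff(f$fitted_normalized)
    if (f$k_star > 0) expect_true(all(d > 0)) else expect_true(all(d < 0))
  }
})

test_that("fitted k is invariant under positive affine rescaling of the input", {
  tt <- dev_times()
  spec <- simulation_spec(n_features = 10, noise_sd_fraction = 0.02, seed = 77)
  sim <- simulate_logistic_matrix(spec)
  for (i in seq_len(5)) {
    z <- sim$matrix[i, ]
    f1 <- fit_best(z, tt)
    f2 <- fit_best(3.7 * z + 11, tt)
    expect_equal(f1$k, f2$k, tolerance = 1e-6)
  }
})

test_that("reconstruction in the original range commutes with the inverse map", {
  tt <- dev_times()
  z <- analytic_solution(tt, 0.8, 4, 0.7, tt[1]) + 1
  f <- fit_best(z, tt)
  expect_true(f$converged)
  # z(t_start) = z_start
  expect_equal(f$fitted_original[1],
               reconstruct_original(tt[1], f$k, f$a, f$b,
                                    f$fitted_original[1], tt[1]))
  # inverse-mapped normalized solution equals the original-range curve
  inv <- inverse_transform_params(f$fitted_normalized, f$fitted_normalized,
                                  f$range_id, f$z_min, f$z_max)
  expect_equal(inv$a, f$fitted_original, tolerance = 1e-9)
  expect_error(reconstruct_original(tt, 0.8, 0, 4, z_start = 5, tt[1]),
               "outside")
})

test_that("the reconstructed curve inflects once, at t_switch", {
  tt <- dev_times()
  grid <- seq(tt[1], tt[8], length.out = 4000)
  # exact curve: relative start 0.15 of the span puts the inflection at
  # t_start + ln(1/0.15 - 1)/k, inside the window
  k <- 0.9; a <- 1; b <- 5; z0 <- a + 0.15 * (b - a)
  tsw <- tt[1] + log(1 / 0.15 - 1) / k
  zc <- reconstruct_original(grid, k, a, b, z0, tt[1])
  d1 <- diff(zc)
  expect_equal(grid[which.max(abs(d1))], tsw, tolerance = 2 * diff(grid[1:2]))
  d2 <- diff(d1)
  expect_equal(sum(diff(sign(d2)) != 0), 1)
  # and the same holds for a fitted full-sigmoid row (generator truth)
  spec <- simulation_spec(n_features = 200, noise_sd_fraction = 0, seed = 88)
  sim <- simulate_logistic_matrix(spec)
  i <- which(sim$truth$archetype == "full" &
               sim$truth$kinetic_class == "switcher")[1]
  expect_false(is.na(i))
  f <- fit_best(sim$matrix[i, ], tt)
  ann <- annotate_kinetics(f)
  zf <- reconstruct_original(grid, f$k, f$a, f$b, f$fitted_original[1], tt[1])
  expect_equal(grid[which.max(abs(diff(zf)))], ann$t_switch,
               tolerance = 2 * diff(grid[1:2]))
})

test_that("characteristic times follow their closed forms and sentinels", {
  ct <- characteristic_times(0.9, 1, 0.5, 10.5)
  expect_equal(ct$t_switch, 10.5)
  ct2 <- characteristic_times(0.9, 1, 0.99, 10.5)
  expect_equal(ct2$t_saturation, 10.5, tolerance = 1e-12)
  ct3 <- characteristic_times(0.9, 1, 0.1, 10.5)
  expect_equal(ct3$t_switch, 10.5 + log(9) / 0.9)
  expect_equal(ct3$t_minimum, 10.5 + log(1e-16 / 0.1) / 0.9)
  expect_equal(ct3$t_saturation, 10.5 + log(99 / 0.1 - 99) / 0.9)
  expect_error(characteristic_times(0, 1, 0.1, 10.5), "nonzero")
  # past-inflection sentinel
  expect_equal(characteristic_times(0.9, 1, 1.2, 10.5)$t_switch, -Inf)
})

test_that("kinetic classes partition the time axis at the window bounds", {
  expect_equal(classify_kinetics(12, 10.5, 21), "switcher")
  expect_equal(classify_kinetics(25, 10.5, 21), "accelerator")
  expect_equal(classify_kinetics(9, 10.5, 21), "decelerator")
  expect_equal(classify_kinetics(-Inf, 10.5, 21), "decelerator")
  expect_equal(classify_kinetics(10.5, 10.5, 21), "switcher")
  expect_equal(classify_kinetics(21, 10.5, 21), "switcher")
})

test_that("quadrant clustering recovers well-separated archetype blobs", {
  set.seed(9)
  n <- 80
  blob <- function(kc, bc) cbind(rnorm(n, kc, 0.05), rnorm(n, bc, 0.2))
  pts <- rbind(blob(1.3, 1), blob(0.25, 1), blob(0.25, 8))
  truth <- rep(c("Q1", "Q2", "Q3"), each = n)
  cl <- cluster_quadrants(pts[, 1], pts[, 2], seed = 1)
  expect_gte(mean(cl$quadrant == truth), 0.99)
  expect_true(cl$q4_empty)
  # invariance to order and restart seed
  perm <- sample(nrow(pts))
  cl2 <- cluster_quadrants(pts[perm, 1], pts[perm, 2], seed = 99)
  expect_gte(mean(cl2$quadrant == truth[perm]), 0.99)
  expect_error(cluster_quadrants(rep(1, 5), rep(2, 5)), "distinct")
})
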
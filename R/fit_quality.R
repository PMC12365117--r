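#' Two-component Gaussian mixture triage of fit MSEs
#'
#' Models the distribution of per-feature mean squared errors as a mixture
#' of two Gaussians - one of low-MSE acceptable fits, one of high-MSE
#' unacceptable fits - by EM, and places a cut point between the component
#' means where the posterior responsibilities are equal. Fits with MSE above
#' the cut point are labeled unacceptable.
#'
#' EM is initialized deterministically by a 2-means split of the values
#' (centers at the 25th and 75th percentiles) and iterated to a log-likelihood
#' tolerance of 1e-8 (at most `max_iter` iterations); the log-likelihood is
#' asserted non-decreasing at every step. Components are ordered by mean.
#'
#' @param mse Numeric vector of at least 20 finite, non-negative values with
#'   nonzero variance.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return Object of class `gmm_partition`: list with `means`, `sds`,
#'   `weights` (low component first), `cutpoint`, `labels`
#'   ("acceptable"/"unacceptable" per value), `posterior` (n x 2), `loglik`,
#'   `loglik_trace`, `iterations`.
#' @export
fit_gmm2 <- function(mse, max_iter = 1000, tol = 1e-8) {
  x <- as.numeric(mse)
  if (length(x) < 20) stop("need at least 20 MSE values")
  if (!all(is.finite(x))) stop("non-finite MSE values")
  if (any(x < 0)) stop("negative MSE values")
  if (stats::sd(x) == 0) stop("zero variance in MSE values: nothing to partition")

  n <- length(x)
  # deterministic 2-means init
  centers <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (centers[1] == centers[2]) centers <- range(x)
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(centers, 2, 1)))
  grp <- km$cluster
  if (min(table(grp)) < 2)
    grp <- ifelse(x <= stats::median(x), 1L, 2L)
  mu <- tapply(x, grp, mean)
  sg <- tapply(x, grp, stats::sd)
  sg[!is.finite(sg) | sg < 1e-12] <- stats::sd(x) / 10
  w <- as.numeric(table(factor(grp, levels = 1:2))) / n

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    # E step (log-space for stability)
    lg <- cbind(log(w[1]) + stats::dnorm(x, mu[1], sg[1], log = TRUE),
                log(w[2]) + stats::dnorm(x, mu[2], sg[2], log = TRUE))
    m <- pmax(lg[, 1], lg[, 2])
    lse <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
    ll <- sum(lse)
    if (ll < ll_old - 1e-6)
      stop("EM log-likelihood decreased; numerical failure")
    loglik_trace <- c(loglik_trace, ll)
    post <- exp(lg - lse)
    # M step
    nk <- colSums(post)
    if (any(nk / n < 1e-3))
      stop("mixture component collapsed (weight < 1e-3); ",
           "the MSE distribution may be unimodal - all fits may be acceptable")
    w <- nk / n
    mu <- colSums(post * x) / nk
    sg <- sqrt(colSums(post * (x - rep(mu, each = n))^2) / nk)
    if (any(sg < 1e-12))
      stop("mixture component collapsed (sd < 1e-12); ",
           "the MSE distribution may be degenerate")
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    if (iter >= max_iter) break
    ll_old <- ll
  }
  # order components by mean (low = acceptable)
  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]; post <- post[, ord]

  cut <- .gmm_cutpoint(mu, sg, w)
  labels <- ifelse(x > cut, "unacceptable", "acceptable")
  structure(list(means = unname(mu), sds = unname(sg), weights = unname(w),
                 cutpoint = cut, labels = labels, posterior = post,
                 loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace, iterations = iter),
            class = "gmm_partition")
}

# Equal-posterior point between the two component means: solve
# w1 N(x|m1,s1) = w2 N(x|m2,s2), a quadratic in x, and keep the root
# between the means (midpoint fallback if degenerate).
.gmm_cutpoint <- function(mu, sg, w) {
  A <- 1 / (2 * sg[2]^2) - 1 / (2 * sg[1]^2)
  B <- mu[1] / sg[1]^2 - mu[2] / sg[2]^2
  Cc <- mu[2]^2 / (2 * sg[2]^2) - mu[1]^2 / (2 * sg[1]^2) +
    log(w[1] / sg[1]) - log(w[2] / sg[2])
  roots <- if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) numeric(0) else -Cc / B
  } else {
    disc <- B^2 - 4 * A * Cc
    if (disc < 0) numeric(0)
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside) >= 1) inside[1] else mean(mu)
}

#' @export
print.gmm_partition <- function(x, ...) {
  cat(sprintf(
    "<gmm_partition> means %.4g / %.4g, sds %.3g / %.3g, weights %.2f / %.2f\n",
    x$means[1], x$means[2], x$sds[1], x$sds[2], x$weights[1], x$weights[2]))
  cat(sprintf("  cutpoint %.5g; %d acceptable, %d unacceptable (EM iters %d)\n",
              x$cutpoint, sum(x$labels == "acceptable"),
              sum(x$labels == "unacceptable"), x$iterations))
  invisible(x)
}
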
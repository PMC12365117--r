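#' Remove replicate/assay batch effects from a time-series matrix
#'
#' Least-squares batch correction jointly with the time-course design: batch
#' factors are coded sum-to-zero, their coefficients estimated alongside a
#' linear time covariate, and the batch terms subtracted, so the grand mean
#' and the time trend are preserved. One or two batch factors are supported
#' (e.g. biological replicate, and assay when harmonizing DNase- and
#' ATAC-seq columns). Delegates to `limma::removeBatchEffect`.
#'
#' @param mat Numeric matrix, features x samples.
#' @param batch Factor (or coercible) of length `ncol(mat)`.
#' @param batch2 Optional second batch factor.
#' @param design_time Numeric covariate of length `ncol(mat)` (days); the
#'   time course is protected from removal.
#' @return Corrected matrix, same shape as `mat`.
#' @export
remove_batch_effects <- function(mat, batch, batch2 = NULL, design_time) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  batch <- as.factor(batch)
  if (length(batch) != ncol(mat))
    stop("batch length must equal number of columns")
  if (length(design_time) != ncol(mat))
    stop("design_time length must equal number of columns")
  if (!is.null(batch2)) {
    batch2 <- as.factor(batch2)
    if (length(batch2) != ncol(mat))
      stop("batch2 length must equal number of columns")
  }
  if (nlevels(batch) < 2 && (is.null(batch2) || nlevels(batch2) < 2))
    return(mat)
  design <- cbind(Intercept = 1, time = design_time)
  # confounding check: the joint model must have full column rank
  bt <- if (nlevels(batch) >= 2)
    stats::model.matrix(~batch)[, -1, drop = FALSE]
  else matrix(0, ncol(mat), 0)
  joint <- cbind(design, bt)
  if (qr(joint)$rank < ncol(joint))
    stop("batch factor 'batch' is confounded with the time design")
  if (!is.null(batch2)) {
    bt2 <- stats::model.matrix(~batch2)[, -1, drop = FALSE]
    joint2 <- cbind(design, bt, bt2)
    if (qr(joint2)$rank < ncol(joint2))
      stop("batch factor 'batch2' is confounded with the time design")
  }
  out <- limma::removeBatchEffect(
    mat, batch = if (nlevels(batch) >= 2) batch else NULL,
    batch2 = batch2, design = design)
  dimnames(out) <- dimnames(mat)
  out
}

#' Shift a matrix into the positive range
#'
#' If the global minimum of the matrix is negative (as batch correction can
#' produce), its absolute value is added to every entry, moving the whole
#' matrix upward while preserving all pairwise differences exactly.
#'
#' @param mat Finite numeric matrix.
#' @return List with `matrix` (shifted) and `shift` (scalar added; 0 if the
#'   input was already non-negative).
#' @export
shift_to_positive <- function(mat) {
  stopifnot(is.numeric(mat))
  if (!all(is.finite(mat))) stop("non-finite entries in matrix")
  m <- min(mat)
  shift <- if (m < 0) abs(m) else 0
  list(matrix = mat + shift, shift = shift)
}

#' Quantile normalization across columns
#'
#' Replaces each column's sorted values with the mean of sorted values
#' across columns, restored to the original ranks; tied ranks receive the
#' average of the corresponding means. Delegates to
#' `limma::normalizeQuantiles`.
#'
#' @param mat Numeric matrix (columns = samples to harmonize) or data.frame
#'   of equal-length numeric columns.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (!all(is.finite(mat))) stop("non-finite entries in matrix")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Polynomial time-course test for dynamic features
#'
#' Per feature, regresses the (replicate-pooled) observations on polynomials
#' of time of degree 1 and degree 2 and computes the overall F-test p-value
#' against the intercept-only model for each degree. P-values are BH-adjusted
#' across features within each degree; a feature is dynamic when its minimum
#' adjusted p-value is below `alpha` in at least one of the two designs.
#'
#' @param mat Numeric matrix, features x observations (replicate columns
#'   pooled; NAs allowed).
#' @param times Numeric time (days) per column.
#' @param alpha Final significance cutoff on BH-adjusted p-values.
#' @param min_obs Minimum finite observations per feature; features below
#'   are excluded (flagged, not an error).
#' @return data.frame: feature_id, n_obs, p_linear, p_quadratic,
#'   adj_p_linear, adj_p_quadratic, is_dynamic, tested.
#' @export
polynomial_timecourse_test <- function(mat, times, alpha = 0.01, min_obs = 5) {
  stopifnot(is.matrix(mat), ncol(mat) == length(times))
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("feature_", seq_len(nrow(mat)))
  n_obs <- rowSums(is.finite(mat))
  tested <- n_obs >= min_obs
  pval_for_degree <- function(y, t, degree) {
    ok <- is.finite(y)
    y <- y[ok]; t <- t[ok]
    if (length(unique(t)) <= degree) return(NA_real_)
    sst <- sum((y - mean(y))^2)
    if (sst < .Machine$double.eps * max(1, mean(y)^2) * length(y)) return(1)
    fit <- stats::lm(y ~ stats::poly(t, degree, raw = TRUE))
    sse <- sum(stats::residuals(fit)^2)
    df1 <- degree; df2 <- length(y) - degree - 1
    if (df2 <= 0) return(NA_real_)
    fstat <- ((sst - sse) / df1) / (sse / df2)
    if (!is.finite(fstat)) return(1)
    stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  p1 <- p2 <- rep(NA_real_, nrow(mat))
  for (i in which(tested)) {
    p1[i] <- pval_for_degree(mat[i, ], times, 1)
    p2[i] <- pval_for_degree(mat[i, ], times, 2)
  }
  adj1 <- adj2 <- rep(NA_real_, nrow(mat))
  adj1[tested] <- stats::p.adjust(p1[tested], method = "BH")
  adj2[tested] <- stats::p.adjust(p2[tested], method = "BH")
  is_dyn <- tested & (pmin(adj1, adj2, na.rm = TRUE) < alpha)
  is_dyn[!tested] <- NA
  data.frame(feature_id = ids, n_obs = n_obs,
             p_linear = p1, p_quadratic = p2,
             adj_p_linear = adj1, adj_p_quadratic = adj2,
             is_dynamic = is_dyn, tested = tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Average replicate columns per time point
#'
#' Collapses a features x (time x replicate) matrix to one column per time
#' point by averaging finite replicate values.
#'
#' @param mat Numeric matrix, features x samples.
#' @param times Numeric time per column (repeated across replicates).
#' @return List with `matrix` (features x unique times, increasing) and
#'   `times`.
#' @export
average_replicates <- function(mat, times) {
  stopifnot(is.matrix(mat), ncol(mat) == length(times))
  ut <- sort(unique(times))
  out <- sapply(ut, function(tt)
    rowMeans(mat[, times == tt, drop = FALSE], na.rm = TRUE))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), as.character(ut)))
  list(matrix = out, times = ut)
}
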
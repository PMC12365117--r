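# Canonical on-disk dialects: TSV (UTF-8, '.' decimal) for matrices and
# parameter tables, 6-column BED for intervals. Matrices carry feature ids
# in the first column and numeric time headers.

#' Read a feature-by-time matrix from TSV
#'
#' First column = feature id, remaining headers = numeric times (days).
#' Columns are reordered to ascending time when needed (with a notice);
#' duplicate feature ids and ragged rows are rejected.
#'
#' @param path TSV file path.
#' @return List with `matrix` (rownames = feature ids) and `times`.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a feature_id column plus times")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate feature id: ", dup)
  }
  times <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (anyNA(times)) {
    bad <- colnames(df)[-1][is.na(times)][1]
    stop("non-numeric time header: '", bad, "'")
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric matrix entries")
  rownames(mat) <- ids
  if (is.unsorted(times)) {
    message("time columns out of order; reordering ascending")
    ord <- order(times)
    mat <- mat[, ord, drop = FALSE]
    times <- times[ord]
  }
  list(matrix = mat, times = times)
}

#' Write a feature-by-time matrix to TSV
#'
#' @param mat Numeric matrix with feature-id rownames.
#' @param times Numeric times, one per column.
#' @param path Output path.
#' @export
write_matrix <- function(mat, times, path) {
  stopifnot(is.matrix(mat), ncol(mat) == length(times))
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", as.character(times))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fitted-parameter table to TSV
#'
#' Stable column order (feature_id, converged, range_used, k, b, a, mse,
#' direction, t_switch, t_minimum, t_saturation, kinetic_class[, quadrant]),
#' floats at 6 significant digits, NA sentinels for non-converged rows.
#'
#' @param params data.frame from [fit_matrix()] (optionally with extra
#'   columns, kept after the canonical ones).
#' @param path Output path.
#' @export
write_params <- function(params, path) {
  canon <- c("feature_id", "converged", "range_used", "k", "b", "a", "mse",
             "direction", "t_switch", "t_minimum", "t_saturation",
             "kinetic_class")
  missing_cols <- setdiff(canon, names(params))
  if (length(missing_cols))
    stop("params table missing columns: ", paste(missing_cols, collapse = ", "))
  params <- params[, c(canon, setdiff(names(params), canon)), drop = FALSE]
  num <- vapply(params, is.numeric, logical(1))
  params[num] <- lapply(params[num], signif, digits = 6)
  utils::write.table(params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED file of intervals
#'
#' @param path BED file path.
#' @return data.frame: chrom, start, end, id, score, strand (0-based
#'   half-open coordinates).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             id = if (!is.null(gr$name)) gr$name else
               paste0("interval_", seq_along(gr)),
             score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write intervals to a 6-column BED file
#'
#' @param df data.frame with chrom, start, end, id and optionally score,
#'   strand (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  out <- data.frame(df$chrom, as.integer(df$start), as.integer(df$end),
                    df$id, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a samples metadata table
#'
#' TSV with columns `sample`, `time`, `replicate` and optionally `assay`,
#' describing the columns of a replicate-level matrix.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "replicate")
  if (!all(need %in% names(df)))
    stop("samples table requires columns: ", paste(need, collapse = ", "))
  df$time <- as.numeric(df$time)
  df
}
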
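# Coordinates throughout are 0-based half-open (BED convention); conversion
# to the 1-based closed GenomicRanges convention happens only inside these
# helpers.

.df_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "id") %in% names(df)))
  if (any(df$start >= df$end)) stop("intervals require start < end")
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[is.na(strand) | strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand, id = df$id)
}

#' Link each cCRE to its nearest gene by linear distance
#'
#' Pairs every cCRE interval with the gene minimizing the gap distance
#' (0 when overlapping or adjacent). Ties are broken deterministically:
#' leftmost gene start, then lexicographic gene id; all tied gene ids are
#' reported in a `ties` column. cCREs on chromosomes without genes are
#' returned unlinked (`gene_id` NA) and flagged.
#'
#' @param ccres,genes data.frames with columns `chrom`, `start`, `end`, `id`
#'   (0-based half-open); `genes` may carry `strand`.
#' @return data.frame: ccre_id, gene_id, distance_bp, ties (comma-separated
#'   tied gene ids, "" if none), linked (logical).
#' @export
nearest_gene <- function(ccres, genes) {
  cg <- .df_to_granges(ccres)
  gg <- .df_to_granges(genes)
  out <- data.frame(ccre_id = ccres$id, gene_id = NA_character_,
                    distance_bp = NA_real_, ties = "",
                    linked = FALSE, stringsAsFactors = FALSE)
  for (chrom in unique(ccres$chrom)) {
    ci <- which(ccres$chrom == chrom)
    gi <- which(genes$chrom == chrom)
    if (length(gi) == 0) next
    # gap-distance matrix ccres x genes on this chromosome (0 = overlap or
    # adjacency), one vectorized pass per gene
    dmat <- vapply(gi, function(j)
      GenomicRanges::distance(cg[ci], gg[j], ignore.strand = TRUE),
      numeric(length(ci)))
    dmat <- matrix(dmat, nrow = length(ci))
    for (r in seq_along(ci)) {
      d <- dmat[r, ]
      tied <- which(d == min(d))
      ids <- genes$id[gi[tied]]
      ord <- order(genes$start[gi[tied]], ids)
      out$gene_id[ci[r]] <- ids[ord[1]]
      out$distance_bp[ci[r]] <- min(d)
      out$linked[ci[r]] <- TRUE
      if (length(tied) > 1)
        out$ties[ci[r]] <- paste(sort(ids), collapse = ",")
    }
  }
  out
}

#' Strand-aware distance from a cCRE to a gene's TSS
#'
#' The TSS is the interval start for a `+` gene and `end - 1` for a `-`
#' gene (0-based). The distance is the gap between the cCRE interval and the
#' TSS base (0 when the cCRE contains the TSS); a cCRE is distal when this
#' distance is strictly greater than 2000 bp.
#'
#' @param ccre One-row data.frame (or list) with `start`, `end`.
#' @param gene One-row data.frame (or list) with `start`, `end`, `strand`.
#' @param distal_bp Distal threshold (strict inequality), default 2000.
#' @return List with `distance` (bp) and `is_distal`.
#' @export
tss_distance <- function(ccre, gene, distal_bp = 2000) {
  strand <- as.character(gene$strand)
  if (is.na(strand) || !strand %in% c("+", "-"))
    stop("gene strand required for TSS distance")
  tss <- if (strand == "+") gene$start else gene$end - 1
  # gap between the cCRE [start, end) and the TSS base [tss, tss + 1),
  # same gap convention as nearest_gene (adjacent = 0)
  d <- if (tss >= ccre$start && tss < ccre$end) 0
       else if (tss < ccre$start) ccre$start - (tss + 1)
       else tss - ccre$end
  list(distance = d, is_distal = d > distal_bp)
}

#' Pearson correlation sign between gene and cCRE trajectories
#'
#' Computed on the fitted (smoothed) trajectories; a positive correlation is
#' interpreted as enhancer-like regulation (open chromatin tracks with
#' expression), a negative one as silencer-like.
#'
#' @param gene_traj,ccre_traj Equal-length numeric trajectories.
#' @return List with `r` and `sign` ("enhancer-like"/"silencer-like"); both
#'   NA when either trajectory is constant.
#' @export
correlation_sign <- function(gene_traj, ccre_traj) {
  stopifnot(length(gene_traj) == length(ccre_traj))
  if (stats::sd(gene_traj) == 0 || stats::sd(ccre_traj) == 0)
    return(list(r = NA_real_, sign = NA_character_))
  r <- stats::cor(gene_traj, ccre_traj)
  list(r = r, sign = if (r > 0) "enhancer-like" else "silencer-like")
}

#' Classify a gene as mono- or poly-pattern and assign a regulatory group
#'
#' A gene is mono-pattern when all its linked cCREs share one k-sign
#' (a single linked cCRE is the simplest mono-pattern case) and poly-pattern
#' when both increasing and decreasing cCREs are linked. The regulatory
#' group's enhancer/silencer side is the majority correlation sign among the
#' linked cCREs; genes with an exact sign tie are flagged and given no group.
#'
#' @param k_signs Numeric (or sign) vector of fitted k values of the linked
#'   cCREs.
#' @param corr_signs Character vector ("enhancer-like"/"silencer-like") per
#'   linked cCRE (NA entries are dropped).
#' @return List with `n_ccres`, `pattern` ("mono"/"poly"), `group` (e.g.
#'   "enhancer-poly"; NA on tie), `tie` (logical).
#' @export
classify_pattern <- function(k_signs, corr_signs) {
  stopifnot(length(k_signs) >= 1)
  s <- sign(k_signs)
  pattern <- if (all(s > 0) || all(s < 0)) "mono" else "poly"
  cs <- corr_signs[!is.na(corr_signs)]
  n_enh <- sum(cs == "enhancer-like")
  n_sil <- sum(cs == "silencer-like")
  tie <- length(cs) > 0 && n_enh == n_sil
  side <- if (length(cs) == 0 || tie) NA_character_
          else if (n_enh > n_sil) "enhancer" else "silencer"
  list(n_ccres = length(k_signs), pattern = pattern,
       group = if (is.na(side)) NA_character_ else paste(side, pattern, sep = "-"),
       tie = tie)
}

#' Build the full cCRE-gene link table
#'
#' Combines nearest-gene assignment, TSS distance/distal flags, trajectory
#' correlations and proximity ranks into one table, and summarizes genes
#' into pattern records.
#'
#' @param ccres,genes Interval data.frames (see [nearest_gene()]); `genes`
#'   must carry `strand` for TSS distances.
#' @param ccre_fitted,gene_fitted Matrices of fitted trajectories (rows
#'   named by interval ids, columns = time points).
#' @param ccre_k Named numeric vector of fitted k per cCRE.
#' @param distal_bp Distal threshold in bp.
#' @return List with `links` (ccre_id, gene_id, distance_bp, tss_distance,
#'   is_distal, r, sign, proximity_rank, ties) and `gene_patterns` (gene_id,
#'   n_ccres, pattern, group, tie).
#' @export
build_links <- function(ccres, genes, ccre_fitted, gene_fitted, ccre_k,
                        distal_bp = 2000) {
  nl <- nearest_gene(ccres, genes)
  nl <- nl[nl$linked, , drop = FALSE]
  gene_ix <- match(nl$gene_id, genes$id)
  ccre_ix <- match(nl$ccre_id, ccres$id)
  td <- vapply(seq_len(nrow(nl)), function(i) {
    tss_distance(ccres[ccre_ix[i], ], genes[gene_ix[i], ], distal_bp)$distance
  }, numeric(1))
  rs <- lapply(seq_len(nrow(nl)), function(i) {
    g <- nl$gene_id[i]; cc <- nl$ccre_id[i]
    if (!g %in% rownames(gene_fitted) || !cc %in% rownames(ccre_fitted))
      return(list(r = NA_real_, sign = NA_character_))
    correlation_sign(gene_fitted[g, ], ccre_fitted[cc, ])
  })
  links <- data.frame(
    ccre_id = nl$ccre_id, gene_id = nl$gene_id,
    distance_bp = nl$distance_bp, tss_distance = td,
    is_distal = td > distal_bp,
    r = vapply(rs, function(x) x$r, numeric(1)),
    sign = vapply(rs, function(x)
      if (is.null(x$sign) || is.na(x$sign)) NA_character_ else x$sign,
      character(1)),
    ties = nl$ties, stringsAsFactors = FALSE)
  links <- links[order(links$gene_id, links$distance_bp, links$ccre_id), ]
  links$proximity_rank <- stats::ave(
    links$distance_bp, links$gene_id, FUN = seq_along)
  rownames(links) <- NULL

  gp <- lapply(split(links, links$gene_id), function(d) {
    ks <- ccre_k[d$ccre_id]
    ks <- ks[is.finite(ks)]
    if (length(ks) == 0) return(NULL)
    cp <- classify_pattern(ks, d$sign)
    data.frame(gene_id = d$gene_id[1], n_ccres = cp$n_ccres,
               pattern = cp$pattern, group = cp$group, tie = cp$tie,
               stringsAsFactors = FALSE)
  })
  gene_patterns <- do.call(rbind, gp[!vapply(gp, is.null, logical(1))])
  rownames(gene_patterns) <- NULL
  list(links = links, gene_patterns = gene_patterns)
}

#' Expression fold change over the time course
#'
#' Difference between the maximum and minimum of a (log2-scale) expression
#' trajectory; non-negative, zero only for a constant trajectory.
#'
#' @param traj Numeric trajectory.
#' @return Scalar fold change.
#' @export
fold_change <- function(traj) max(traj) - min(traj)

#' Interaction model of cCRE count and regulatory pattern
#'
#' Fits `y ~ x + z + x:z` - where `x` is the mean number of linked cCREs,
#' `z` the mono(0)/poly(1) pattern indicator and `x:z` their interaction -
#' by logistic regression (binary `y`, e.g. annotation-term membership) or
#' ordinary least squares (continuous `y`, e.g. expression fold change).
#' Variance inflation factors are computed per non-intercept coefficient as
#' 1/(1 - R^2) of each model-matrix column on the others.
#'
#' @param y Response vector (binary for `family = "logistic"`).
#' @param x Numeric predictor (mean cCRE count per gene).
#' @param z Binary pattern indicator (0 = mono, 1 = poly).
#' @param family `"logistic"` or `"linear"`.
#' @return List with `coefficients` (intercept, a = x, b = z, c = x:z),
#'   `p_values`, `vif`, `separation` (logical flag for logistic fits),
#'   `model` (the underlying `glm`/`lm`).
#' @export
fit_interaction_model <- function(y, x, z, family = c("logistic", "linear")) {
  family <- match.arg(family)
  stopifnot(length(y) == length(x), length(x) == length(z))
  if (length(unique(z)) < 2)
    stop("pattern indicator z is constant: interaction inestimable")
  if (length(y) <= 10) stop("need n > 10 observations")
  dat <- data.frame(y = y, x = x, z = z)
  separation <- FALSE
  if (family == "logistic") {
    fit <- withCallingHandlers(
      stats::glm(y ~ x + z + x:z, data = dat,
                 family = stats::binomial(link = "logit")),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (separation)
      warning("possible perfect separation; coefficients unreliable")
  } else {
    fit <- stats::lm(y ~ x + z + x:z, data = dat)
  }
  sm <- summary(fit)$coefficients
  pcol <- if (family == "logistic") "Pr(>|z|)" else "Pr(>|t|)"
  mm <- stats::model.matrix(fit)[, -1, drop = FALSE]
  vif <- vapply(seq_len(ncol(mm)), function(j) {
    r2 <- summary(stats::lm(mm[, j] ~ mm[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(mm)
  co <- stats::coef(fit)
  list(coefficients = c(intercept = unname(co["(Intercept)"]),
                        a = unname(co["x"]), b = unname(co["z"]),
                        c = unname(co["x:z"])),
       std_errors = c(intercept = sm["(Intercept)", 2], a = sm["x", 2],
                      b = sm["z", 2], c = sm["x:z", 2]),
       p_values = c(intercept = sm["(Intercept)", pcol], a = sm["x", pcol],
                    b = sm["z", pcol], c = sm["x:z", pcol]),
       vif = vif, separation = separation, model = fit)
}

#' Hypergeometric enrichment of a gene set in an annotation term
#'
#' Helper for user-supplied gene-term membership tables: over-representation
#' p-value of `hits` term members among `drawn` selected genes out of a
#' universe of `total` genes containing `term_size` members.
#'
#' @param hits Number of selected genes annotated to the term.
#' @param drawn Number of selected genes.
#' @param term_size Number of universe genes annotated to the term.
#' @param total Universe size.
#' @return Upper-tail hypergeometric p-value.
#' @export
hypergeom_enrichment <- function(hits, drawn, term_size, total) {
  stats::phyper(hits - 1, term_size, total - term_size, drawn,
                lower.tail = FALSE)
}
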
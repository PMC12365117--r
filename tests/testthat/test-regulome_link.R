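iv <- function(chrom, start, end, id, strand = "+")
  data.frame(chrom = chrom, start = start, end = end, id = id,
             strand = strand, stringsAsFactors = FALSE)

# all-pairs brute-force nearest gene under the gap-distance convention
brute_nearest <- function(ccres, genes) {
  gap <- function(s1, e1, s2, e2) max(0, s2 - e1, s1 - e2)
  vapply(seq_len(nrow(ccres)), function(i) {
    g <- genes[genes$chrom == ccres$chrom[i], ]
    if (nrow(g) == 0) return(NA_character_)
    d <- vapply(seq_len(nrow(g)), function(j)
      gap(ccres$start[i], ccres$end[i], g$start[j], g$end[j]), numeric(1))
    cand <- g[d == min(d), ]
    cand <- cand[order(cand$start, cand$id), ]
    cand$id[1]
  }, character(1))
}

test_that("nearest-gene assignment follows linear gap distance", {
  ccres <- iv("chr1", 100, 200, "c1", ".")
  genes <- rbind(iv("chr1", 300, 400, "g1"), iv("chr1", 1000, 1100, "g2"))
  nl <- nearest_gene(ccres, genes)
  expect_equal(nl$gene_id, "g1")
  expect_equal(nl$distance_bp, 100)
  # overlap gives distance zero
  nl2 <- nearest_gene(iv("chr1", 350, 360, "c2", "."), genes)
  expect_equal(nl2$distance_bp, 0)
  # equidistant: leftmost chosen, ties reported
  genes3 <- rbind(iv("chr1", 0, 50, "gL"), iv("chr1", 250, 300, "gR"))
  nl3 <- nearest_gene(iv("chr1", 100, 200, "c3", "."), genes3)
  expect_equal(nl3$gene_id, "gL")
  expect_equal(nl3$ties, "gL,gR")
  # chromosome without genes: unlinked, flagged
  nl4 <- nearest_gene(iv("chrX", 0, 10, "c4", "."), genes)
  expect_false(nl4$linked)
  expect_true(is.na(nl4$gene_id))
})

test_that("nearest-gene matches all-pairs brute force on random intervals", {
  set.seed(61)
  n <- 300
  rand_iv <- function(n, prefix) {
    st <- sample.int(5e5, n)
    iv(sample(c("chr1", "chr2"), n, TRUE), st, st + sample.int(2000, n),
       paste0(prefix, seq_len(n)), ".")
  }
  ccres <- rand_iv(n, "c")
  genes <- rand_iv(80, "g")
  nl <- nearest_gene(ccres, genes)
  expect_equal(nl$gene_id, brute_nearest(ccres, genes))
})

test_that("TSS distance is strand-aware with a strict distal cutoff", {
  gene_p <- iv("chr1", 5000, 8000, "gp", "+")
  gene_m <- iv("chr1", 5000, 8000, "gm", "-")
  # containing the TSS
  expect_equal(tss_distance(iv("chr1", 4900, 5100, "c", "."), gene_p)$distance, 0)
  expect_false(tss_distance(iv("chr1", 4900, 5100, "c", "."), gene_p)$is_distal)
  # minus strand: TSS at end - 1
  expect_equal(tss_distance(iv("chr1", 7990, 8010, "c", "."), gene_m)$distance, 0)
  td <- tss_distance(iv("chr1", 9000, 9100, "c", "."), gene_m)
  expect_equal(td$distance, 9000 - 8000)
  # exactly 2000 away is NOT distal (strict inequality)
  td2k <- tss_distance(iv("chr1", 3000, 2999 + 1, "c", "."),
                       iv("chr1", 5000, 8000, "g", "+"))
  expect_equal(td2k$distance, 5000 - 3000)
  expect_false(td2k$is_distal)
  td2k1 <- tss_distance(iv("chr1", 2998, 2999, "c", "."), gene_p)
  expect_equal(td2k1$distance, 2001)
  expect_true(td2k1$is_distal)
  expect_error(tss_distance(iv("chr1", 0, 10, "c", "."),
                            iv("chr1", 5, 9, "g", ".")), "strand")
})

test_that("TSS distance agrees with a per-base brute force", {
  set.seed(67)
  for (rep in 1:20) {
    cs <- sample.int(5000, 1); ce <- cs + sample.int(500, 1)
    gs <- sample.int(5000, 1); ge <- gs + sample.int(500, 1)
    strand <- sample(c("+", "-"), 1)
    tss <- if (strand == "+") gs else ge - 1
    bases <- cs:(ce - 1)
    # gap convention: bases strictly between the TSS base and the interval
    brute <- if (tss %in% bases) 0 else min(abs(bases - tss)) - 1
    d <- tss_distance(iv("chr1", cs, ce, "c", "."),
                      iv("chr1", gs, ge, "g", strand))$distance
    expect_equal(d, brute)
  }
})

test_that("mono/poly pattern and regulatory side follow k-signs and correlations", {
  p1 <- classify_pattern(c(0.5, 0.2, 1.1),
                         rep("enhancer-like", 3))
  expect_equal(p1$pattern, "mono")
  expect_equal(p1$group, "enhancer-mono")
  p2 <- classify_pattern(c(0.5, 0.2, -1.1),
                         c("enhancer-like", "enhancer-like", "silencer-like"))
  expect_equal(p2$pattern, "poly")
  expect_equal(p2$group, "enhancer-poly")
  p3 <- classify_pattern(0.7, "silencer-like")
  expect_equal(p3$pattern, "mono")
  expect_equal(p3$group, "silencer-mono")
  # exact correlation tie: flagged, no group
  p4 <- classify_pattern(c(1, -1), c("enhancer-like", "silencer-like"))
  expect_true(p4$tie)
  expect_true(is.na(p4$group))
  # invariance to cCRE order
  ord <- c(3, 1, 2)
  p5 <- classify_pattern(c(0.5, 0.2, -1.1)[ord],
                         c("enhancer-like", "enhancer-like",
                           "silencer-like")[ord])
  expect_equal(p5$pattern, p2$pattern)
  expect_equal(p5$group, p2$group)
})

test_that("correlation sign matches the textbook Pearson formula", {
  x <- c(1, 2, 3, 5, 8, 9, 9.5, 10)
  expect_equal(correlation_sign(x, x)$r, 1)
  expect_equal(correlation_sign(x, x)$sign, "enhancer-like")
  expect_equal(correlation_sign(x, -x)$r, -1)
  expect_equal(correlation_sign(x, -x)$sign, "silencer-like")
  set.seed(71)
  a <- rnorm(8); b <- rnorm(8)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlation_sign(a, b)$r, manual, tolerance = 1e-12)
  expect_true(is.na(correlation_sign(rep(1, 8), a)$r))
})

test_that("fold change is the max-min span and zero only for constants", {
  expect_equal(fold_change(c(2, 5, 3)), 3)
  expect_equal(fold_change(rep(4, 8)), 0)
  set.seed(73)
  for (i in 1:10) expect_gte(fold_change(rnorm(8)), 0)
})

test_that("interaction model recovers simulated coefficients within 3 SE", {
  set.seed(79)
  n <- 2000
  x <- rnorm(n, 5, 2)
  z <- rbinom(n, 1, 0.5)
  a <- 0.3; b <- -0.8; cc <- 0.25
  eta <- -1 + a * x + b * z + cc * x * z
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_interaction_model(y, x, z, family = "logistic")
  for (nm in c("a", "b", "c")) {
    truth <- c(a = a, b = b, c = cc)[nm]
    expect_lt(abs(fit$coefficients[nm] - truth), 3 * fit$std_errors[nm])
  }
  # linear family on a continuous response
  yl <- 1 + a * x + b * z + cc * x * z + rnorm(n, 0, 0.5)
  fl <- fit_interaction_model(yl, x, z, family = "linear")
  expect_lt(abs(fl$coefficients["c"] - cc), 3 * fl$std_errors["c"])
  expect_error(fit_interaction_model(y, x, rep(1, n)), "constant")
})

test_that("orthogonalized predictors report VIFs below 1.5", {
  set.seed(83)
  n <- 400
  x <- scale(rnorm(n), scale = FALSE)
  z <- rep(c(0, 1), n / 2)
  zc <- z - mean(z)
  w <- x * zc                     # balanced design: x, z, x:z orthogonal
  y <- rbinom(n, 1, plogis(0.5 * x + zc + 0.2 * w))
  fit <- fit_interaction_model(y, as.numeric(x), zc, family = "logistic")
  expect_true(all(fit$vif < 1.5))
})
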
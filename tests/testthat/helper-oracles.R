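# Independent first-principles oracles used across the suite. Everything in
# this file is deliberately naive (per-base boolean vectors, explicit
# enumeration, explicit dendrogram construction) and shares no code with the
# package internals it checks.

# ---- per-base interval arithmetic on a single chromosome (<= 10 kb) -------

# logical coverage vector over [0, len) from 0-based half-open intervals
ob_cover <- function(start0, end0, len) {
  v <- logical(len)
  for (k in seq_along(start0)) {
    if (end0[k] > start0[k]) v[(start0[k] + 1L):end0[k]] <- TRUE
  }
  v
}

ob_jaccard <- function(a_start, a_end, b_start, b_end, len) {
  va <- ob_cover(a_start, a_end, len)
  vb <- ob_cover(b_start, b_end, len)
  sum(va & vb) / sum(va | vb)
}

# maximal runs of covered bases -> 0-based half-open intervals
ob_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# random 0-based half-open intervals on one chromosome
random_intervals <- function(n, len, max_w = 200L) {
  w <- sample.int(max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(len - wi, 1L) - 1L, integer(1))
  data.frame(start = s, end = s + w)
}

gr_from_0based <- function(df, chrom = "chrT", strand = "*", ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = strand, ...)
}

# ---- Fisher exact p by explicit fixed-margin enumeration -------------------

enum_fisher_p <- function(a, b, c, d, alternative) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0L, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[support == a]
  switch(alternative,
         greater = sum(p[support >= a]),
         less = sum(p[support <= a]),
         two.sided = sum(p[p <= p_obs * (1 + 1e-7)]))
}

# ---- cophenetic correlation from an explicit UPGMA dendrogram walk ---------

# average-linkage agglomeration where the distance between clusters is the
# mean of the ORIGINAL pairwise dissimilarities; the cophenetic distance of
# two leaves is the merge height at which they first share a cluster
upgma_cophenetic <- function(D) {
  M <- nrow(D)
  clusters <- as.list(seq_len(M))
  Tm <- matrix(0, M, M)
  while (length(clusters) > 1L) {
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      dd <- mean(D[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(j, i) }
    }
    ci <- clusters[[best[1L]]]
    cj <- clusters[[best[2L]]]
    Tm[ci, cj] <- best_d
    Tm[cj, ci] <- best_d
    clusters[[best[1L]]] <- c(ci, cj)
    clusters[[best[2L]]] <- NULL
  }
  Tm
}

oracle_cpcc <- function(C) {
  D <- 1 - C
  diag(D) <- 0
  Tm <- upgma_cophenetic(D)
  ut <- upper.tri(D)
  stats::cor(D[ut], Tm[ut])
}

# random symmetric consensus-like matrix: entries in [0,1], unit diagonal
random_consensus <- function(M) {
  C <- matrix(0, M, M)
  C[upper.tri(C)] <- runif(M * (M - 1) / 2)
  C <- C + t(C)
  diag(C) <- 1
  C
}

# block-structured consensus built from planted cluster labels
block_consensus <- function(labels) {
  outer(labels, labels, "==") * 1
}

# ---- misc ------------------------------------------------------------------

# quick PeakSet builder from 0-based coordinates
mk_peaks <- function(rbp, starts, ends, counts = 10L, method = "m",
                     replicate = "r1", strand = "*", chrom = "chrT") {
  gr <- GenomicRanges::GRanges(rep_len(chrom, length(starts)),
                               IRanges::IRanges(starts + 1L, ends),
                               strand = rep_len(strand, length(starts)),
                               read_count = as.integer(rep_len(counts,
                                                               length(starts))))
  PeakSet(rbp, method, replicate, gr)
}
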
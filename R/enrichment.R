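# Downstream validation statistics for RBP groups: protein-association
# permutation support, known-motif enrichment, RNA half-life enrichment,
# and exon-inclusion (PSI) enrichment.

#' A validated 2x2 contingency table
#'
#' Row 1 = (present, absent) in set 1; row 2 = (present, absent) in set 2.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return a `ContingencyTable2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  structure(as.list(cells), class = "ContingencyTable2x2")
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$c, tab$b, tab$d), 2L, 2L)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric p-value (conditional on the margins) plus the sample
#' odds ratio `ad / bc` (`Inf` when `bc = 0`, `NaN` for a degenerate
#' `0/0`).
#'
#' @param table a `ContingencyTable2x2` (see [contingency_2x2()]).
#' @param alternative `"greater"` (default; enrichment of cell `a`),
#'   `"less"`, or `"two.sided"`.
#' @return an `EnrichmentResult`: list with `table`, `odds_ratio`,
#'   `p_value`, `log2_ratio` (NA here; filled by the fraction-based
#'   wrappers).
#' @export
fisher_exact <- function(table,
                         alternative = c("greater", "less", "two.sided")) {
  if (!inherits(table, "ContingencyTable2x2"))
    stop("`table` must be a ContingencyTable2x2")
  alternative <- match.arg(alternative)
  p <- stats::fisher.test(as_matrix_2x2(table),
                          alternative = alternative)$p.value
  or <- (table$a * table$d) / (table$b * table$c)
  structure(list(table = table, odds_ratio = or,
                 p_value = min(p, 1), log2_ratio = NA_real_,
                 alternative = alternative),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "<EnrichmentResult> a=%d b=%d c=%d d=%d | OR = %.4g, p = %.4g (%s)",
    x$table$a, x$table$b, x$table$c, x$table$d,
    x$odds_ratio, x$p_value, x$alternative))
  if (!is.na(x$log2_ratio)) cat(sprintf(", log2 ratio = %.4g", x$log2_ratio))
  cat("\n")
  invisible(x)
}

#' Read a protein-association edge list
#'
#' @param path TSV with columns `rbp_a`, `rbp_b`, `evidence` (e.g.
#'   physical, co-expression, pathway, domain, genetic, co-localization).
#'   Self-edges are dropped; duplicate undirected edges per evidence type
#'   are collapsed.
#' @return an `AssociationNetwork`: data frame of unordered edges.
#' @export
read_network_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("rbp_a", "rbp_b", "evidence")
  if (!all(need %in% names(tab)))
    stop("network TSV must have columns: ", paste(need, collapse = ", "))
  association_network(tab)
}

#' Construct an association network from an edge data frame
#'
#' @param edges data frame with columns `rbp_a`, `rbp_b`, `evidence`.
#' @return an `AssociationNetwork` (canonicalized, deduplicated, no
#'   self-edges).
#' @export
association_network <- function(edges) {
  edges <- edges[edges$rbp_a != edges$rbp_b, , drop = FALSE]
  lo <- pmin(edges$rbp_a, edges$rbp_b)
  hi <- pmax(edges$rbp_a, edges$rbp_b)
  out <- unique(data.frame(rbp_a = lo, rbp_b = hi,
                           evidence = edges$evidence,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("AssociationNetwork", "data.frame")
  out
}

#' Permutation support test for an RBP group
#'
#' The statistic is the number of network edges of one evidence type with
#' both endpoints inside the group. Its null distribution is built from
#' `n_perm` uniform random subsets of `universe` of the same size, and the
#' smoothed p-value `(1 + #{perm >= observed}) / (1 + n_perm)` is reported
#' per evidence type.
#'
#' @param members character vector of group members (>= 2, all in
#'   `universe`), or one element of an `rbp_groups` object.
#' @param universe all candidate RBP ids.
#' @param network an `AssociationNetwork`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return a data frame with columns `evidence`, `observed`, `p_value`.
#' @export
permutation_group_support <- function(members, universe, network,
                                      n_perm = 10000L, seed = 1L) {
  if (is.data.frame(members)) members <- members$rbp_id
  members <- unique(as.character(members))
  if (length(members) < 2L) stop("a group needs at least 2 members")
  if (!all(members %in% universe))
    stop("group members must be a subset of the universe")
  types <- sort(unique(network$evidence))
  idx_a <- lapply(types, function(t) match(network$rbp_a[network$evidence == t],
                                           universe))
  idx_b <- lapply(types, function(t) match(network$rbp_b[network$evidence == t],
                                           universe))
  count_internal <- function(memb) {
    vapply(seq_along(types), function(k) {
      ia <- idx_a[[k]]; ib <- idx_b[[k]]
      keep <- !is.na(ia) & !is.na(ib)
      sum(memb[ia[keep]] & memb[ib[keep]])
    }, numeric(1))
  }
  memb_obs <- universe %in% members
  observed <- count_internal(memb_obs)
  size <- length(members)
  exceed <- rep(0L, length(types))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      memb <- logical(length(universe))
      memb[sample.int(length(universe), size)] <- TRUE
      exceed <- exceed + as.integer(count_internal(memb) >= observed)
    }
  })
  data.frame(evidence = types, observed = observed,
             p_value = (1 + exceed) / (1 + n_perm))
}

# IUPAC nucleotide codes accepted in motif strings (RNA U == DNA T).
.iupac_letters <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

#' Fraction of sequences containing a known motif
#'
#' Counts a sequence once when the IUPAC motif occurs at least once on the
#' given (sense) strand; T and U are treated as the same letter.
#'
#' @param sequences character vector of nucleotide sequences (already
#'   strand-resolved).
#' @param motif IUPAC motif string, e.g. `"AAUAAA"` or `"WGUA"`.
#' @return list with `count` (sequences containing the motif) and
#'   `fraction`.
#' @export
known_motif_fraction <- function(sequences, motif) {
  if (length(sequences) == 0L) stop("`sequences` must be non-empty")
  motif <- toupper(motif)
  letters_m <- strsplit(motif, "")[[1L]]
  bad <- setdiff(letters_m, .iupac_letters)
  if (length(bad))
    stop("invalid IUPAC letter(s) in motif: ", paste(bad, collapse = ", "))
  motif_dna <- chartr("U", "T", motif)
  seq_dna <- Biostrings::DNAStringSet(chartr("Uu", "Tt",
                                             toupper(sequences)))
  n_hit <- Biostrings::vcountPattern(motif_dna, seq_dna, fixed = FALSE)
  count <- sum(n_hit > 0)
  list(count = count, fraction = count / length(sequences))
}

#' Motif enrichment: group binding sites vs an individual RBP's peaks
#'
#' Builds the 2x2 table (with/without motif x group sites/RBP peaks) and
#' tests for over-representation of the motif among the group's sites with
#' a one-sided Fisher test.
#'
#' @param group_sites_with_motif,group_sites_total counts for the group's
#'   binding sites.
#' @param rbp_peaks_with_motif,rbp_peaks_total counts for the individual
#'   RBP's peaks.
#' @return an `EnrichmentResult` with `log2_ratio` of the two fractions.
#' @export
motif_enrichment_group_vs_rbp <- function(group_sites_with_motif,
                                          group_sites_total,
                                          rbp_peaks_with_motif,
                                          rbp_peaks_total) {
  if (group_sites_with_motif > group_sites_total ||
      rbp_peaks_with_motif > rbp_peaks_total)
    stop("with-motif counts cannot exceed totals")
  tab <- contingency_2x2(group_sites_with_motif,
                         group_sites_total - group_sites_with_motif,
                         rbp_peaks_with_motif,
                         rbp_peaks_total - rbp_peaks_with_motif)
  res <- fisher_exact(tab, "greater")
  f_g <- group_sites_with_motif / group_sites_total
  f_r <- rbp_peaks_with_motif / rbp_peaks_total
  res$log2_ratio <- log2(f_g / f_r)
  res
}

#' Half-life enrichment of binding among fast-decaying genes
#'
#' Classifies genes into short half-life (below the `pct_low` percentile)
#' and long half-life (above the `pct_high` percentile) classes, computes
#' the fraction of each class carrying at least one binding site, and tests
#' enrichment of binding among short-lived genes (one-sided Fisher on the
#' 2x2 class x bound table). `log2_ratio` is
#' `log2(fraction_short / fraction_long)`.
#'
#' @param site_gene_hits named logical vector: does each gene carry a site?
#' @param halflife named numeric vector of half-lives (minutes) on the same
#'   genes.
#' @param pct_low,pct_high percentile cutoffs (defaults 0.20 / 0.80).
#' @return an `EnrichmentResult`.
#' @export
halflife_enrichment <- function(site_gene_hits, halflife,
                                pct_low = 0.20, pct_high = 0.80) {
  genes <- intersect(names(site_gene_hits), names(halflife))
  if (length(genes) == 0L) stop("no shared genes between the two tables")
  hit <- site_gene_hits[genes]
  hl <- halflife[genes]
  cut <- stats::quantile(hl, c(pct_low, pct_high), type = 7, names = FALSE)
  short <- hl < cut[1L]
  long <- hl > cut[2L]
  if (!any(short) || !any(long))
    stop("empty half-life class; check the percentile cutoffs")
  f_short <- mean(hit[short])
  f_long <- mean(hit[long])
  tab <- contingency_2x2(sum(hit[short]), sum(short) - sum(hit[short]),
                         sum(hit[long]), sum(long) - sum(hit[long]))
  res <- fisher_exact(tab, "greater")
  if (f_short == 0 && f_long == 0) {
    warning("no bound gene in either half-life class; log2 ratio undefined")
    res$log2_ratio <- NaN
  } else {
    res$log2_ratio <- log2(f_short / f_long)
  }
  res
}

#' Splicing enrichment of binding near alternatively spliced exons
#'
#' Exons with PSI below `as_max` are treated as alternatively spliced (AS),
#' exons with PSI above `const_min` as constitutive; exons in between are
#' ignored. An exon is "bound" when any site overlaps the window extending
#' `window_bp` bases up- and downstream of it. Tests enrichment of binding
#' near AS exons; `log2_ratio` is `log2(fraction_AS /
#' fraction_constitutive)`.
#'
#' @param sites merged-site `GRanges`.
#' @param exons `GRanges` with a numeric `psi` metadata column in \[0, 1\].
#' @param window_bp flank size in bases (default 2000).
#' @param as_max,const_min PSI cutoffs (defaults 0.2 / 0.8).
#' @return an `EnrichmentResult`.
#' @export
splicing_enrichment <- function(sites, exons, window_bp = 2000L,
                                as_max = 0.2, const_min = 0.8) {
  psi <- exons$psi
  if (is.null(psi)) stop("`exons` needs a `psi` metadata column")
  if (any(psi < 0 | psi > 1)) stop("PSI scores must lie in [0, 1]")
  as_class <- psi < as_max
  const_class <- psi > const_min
  if (!any(as_class) || !any(const_class))
    stop("empty exon class; check the PSI cutoffs")
  win <- exons
  start(win) <- pmax(1L, start(exons) - as.integer(window_bp))
  end(win) <- end(exons) + as.integer(window_bp)
  hit <- IRanges::overlapsAny(win, sites, ignore.strand = TRUE)
  f_as <- mean(hit[as_class])
  f_const <- mean(hit[const_class])
  tab <- contingency_2x2(sum(hit[as_class]),
                         sum(as_class) - sum(hit[as_class]),
                         sum(hit[const_class]),
                         sum(const_class) - sum(hit[const_class]))
  res <- fisher_exact(tab, "greater")
  if (f_as == 0 && f_const == 0) {
    warning("no bound exon in either class; log2 ratio undefined")
    res$log2_ratio <- NaN
  } else {
    res$log2_ratio <- log2(f_as / f_const)
  }
  res
}
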
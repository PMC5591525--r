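# Enrichment statistics: Fisher, permutation support, motif scan,
# half-life and PSI class enrichment.

test_that("Fisher test matches hypergeometric enumeration on key tables", {
  res <- fisher_exact(contingency_2x2(5, 5, 5, 5), "two.sided")
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)

  res <- fisher_exact(contingency_2x2(10, 0, 0, 10), "greater")
  expect_equal(res$p_value, 1 / choose(20, 10))
  expect_equal(res$odds_ratio, Inf)

  set.seed(51)
  for (i in 1:60) {
    cells <- as.integer(rmultinom(1, sample(8:40, 1), runif(4, 0.1, 1)))
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(fisher_exact(tab, alt)$p_value,
                   enum_fisher_p(cells[1], cells[2], cells[3], cells[4],
                                 alt),
                   tolerance = 1e-12)
    }
  }
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("permutation support hits the distribution extremes exactly", {
  universe <- sprintf("R%02d", 1:20)
  grp <- universe[1:4]
  # fully connected group inside an otherwise empty network
  prs <- t(combn(grp, 2))
  net <- association_network(data.frame(rbp_a = prs[, 1], rbp_b = prs[, 2],
                                        evidence = "physical"))
  res <- permutation_group_support(grp, universe, net, n_perm = 500,
                                   seed = 3)
  expect_equal(res$observed, 6)
  expect_equal(res$p_value, 1 / 501)
  # zero internal edges -> p = 1 (every permutation ties or beats 0)
  net2 <- association_network(data.frame(rbp_a = "R10", rbp_b = "R11",
                                         evidence = "physical"))
  res2 <- permutation_group_support(c("R01", "R02"), universe, net2,
                                    n_perm = 200, seed = 3)
  expect_equal(res2$p_value, 1)
  # determinism
  res3 <- permutation_group_support(grp, universe, net, n_perm = 500,
                                    seed = 3)
  expect_identical(res, res3)
  expect_error(permutation_group_support("R01", universe, net), "2 members")
  expect_error(permutation_group_support(c("X", "Y"), universe, net),
               "subset")
})

test_that("IUPAC motif scanning counts sequences, not occurrences", {
  out <- known_motif_fraction(c("AAUAAA", "CCCCCC"), "AAUAAA")
  expect_equal(out$count, 1)
  expect_equal(out$fraction, 0.5)
  expect_equal(known_motif_fraction("AUGUAC", "UGUA")$count, 1)
  # degenerate base W = A or U
  expect_equal(known_motif_fraction(c("AGUAAA", "UGUAAA", "CGUAAA"),
                                    "WGUA")$count, 2)
  # T/U equivalence both directions
  expect_equal(known_motif_fraction("ATGTAC", "UGUA")$count, 1)
  # duplicates count separately; order irrelevant
  expect_equal(known_motif_fraction(c("AAUAAA", "AAUAAA", "GGG"),
                                    "AAUAAA")$count, 2)
  expect_error(known_motif_fraction(character(0), "AAA"), "non-empty")
  expect_error(known_motif_fraction("AAA", "AXA"), "IUPAC")
})

test_that("group-vs-RBP motif enrichment builds the stated table", {
  res <- motif_enrichment_group_vs_rbp(30, 100, 3, 100)
  expect_equal(res$table$a, 30)
  expect_equal(res$table$b, 70)
  expect_equal(res$table$c, 3)
  expect_equal(res$table$d, 97)
  expect_equal(res$p_value, enum_fisher_p(30, 70, 3, 97, "greater"))
  expect_equal(res$log2_ratio, log2(0.3 / 0.03))
  # equal fractions: odds ratio 1
  expect_equal(motif_enrichment_group_vs_rbp(10, 100, 10, 100)$odds_ratio, 1)
  # depleted direction: one-sided p above 0.5
  expect_gt(motif_enrichment_group_vs_rbp(2, 100, 30, 100)$p_value, 0.5)
  expect_error(motif_enrichment_group_vs_rbp(11, 10, 1, 10), "exceed")
})

test_that("half-life classes follow sort-based percentiles and give the stated ratio", {
  set.seed(52)
  genes <- sprintf("G%03d", 1:200)
  hl <- setNames(rlnorm(200, log(90), 0.8), genes)
  hits <- setNames(runif(200) < 0.3, genes)
  res <- halflife_enrichment(hits, hl)
  lo <- quantile(hl, 0.2, type = 7, names = FALSE)
  hi <- quantile(hl, 0.8, type = 7, names = FALSE)
  short <- hl < lo
  long <- hl > hi
  expect_equal(res$table$a + res$table$b, sum(short))
  expect_equal(res$table$c + res$table$d, sum(long))
  expect_equal(res$log2_ratio, log2(mean(hits[short]) / mean(hits[long])))
  expect_equal(res$p_value,
               enum_fisher_p(res$table$a, res$table$b, res$table$c,
                             res$table$d, "greater"))
  # identical fractions -> log2 ratio 0
  hl2 <- setNames(c(1:100), sprintf("g%d", 1:100))
  hit2 <- setNames(rep(c(TRUE, FALSE), 50), names(hl2))
  expect_equal(halflife_enrichment(hit2, hl2)$log2_ratio, 0)
  # fractions 0.4 vs 0.1 -> exactly 2
  hit3 <- setNames(rep(FALSE, 100), names(hl2))
  hit3[names(hl2)[hl2 <= 19]][1:8] <- TRUE    # 8 of 20 short   (0.4)
  hit3[names(hl2)[hl2 >= 81]][1:2] <- TRUE    # 2 of 20 long    (0.1)
  expect_equal(halflife_enrichment(hit3, hl2)$log2_ratio, 2)
})

test_that("splicing windows use the 2-kb flank with half-open arithmetic", {
  exon <- gr_from_0based(data.frame(start = 10000, end = 10120))
  exon$psi <- 0.1
  const <- gr_from_0based(data.frame(start = 50000, end = 50120))
  const$psi <- 0.95
  exons <- c(exon, const)
  site_hit <- gr_from_0based(data.frame(start = 10000 - 1999 - 40,
                                        end = 10000 - 1999))
  site_miss <- gr_from_0based(data.frame(start = 10000 - 2001 - 40,
                                         end = 10000 - 2001))
  # gap of 1999 bases -> inside the window
  res <- splicing_enrichment(site_hit, exons)
  expect_equal(res$table$a, 1)
  # gap of 2001 bases -> outside (no bound exon at all here)
  expect_warning(res2 <- splicing_enrichment(site_miss, exons), "undefined")
  expect_equal(res2$table$a, 0)
  # mid-PSI exon belongs to neither class
  mid <- exon
  mid$psi <- 0.5
  res3 <- splicing_enrichment(site_hit, c(exons, mid))
  expect_equal(res3$table$a + res3$table$b, 1)   # still one AS exon
  # no sites anywhere -> NaN ratio with a warning
  far <- gr_from_0based(data.frame(start = 90000, end = 90040))
  expect_warning(res4 <- splicing_enrichment(far, exons), "undefined")
  expect_true(is.nan(res4$log2_ratio))
  bad <- exon
  bad$psi <- 1.2
  expect_error(splicing_enrichment(site_hit, bad), "PSI")
})
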
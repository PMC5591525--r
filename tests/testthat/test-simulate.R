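# Synthetic-scenario generator: determinism, planted structure, confounding.

small_cfg <- function(...) {
  scenario_config(n_rbps = 6L, n_groups = 2L, n_sites = 200L,
                  genome = c(chrS1 = 6e5), background_peak_rate = 10,
                  noise_edges = 5L, ...)
}

test_that("identical configurations give byte-identical scenarios", {
  d1 <- file.path(tempdir(), "scn_a")
  d2 <- file.path(tempdir(), "scn_b")
  s1 <- generate_scenario(small_cfg(seed = 5L), d1)
  s2 <- generate_scenario(small_cfg(seed = 5L), d2)
  for (nm in names(s1$files)) {
    f1 <- s1$files[[nm]]
    f2 <- s2$files[[nm]]
    expect_identical(readLines(f1), readLines(f2), label = nm)
  }
  for (bed in list.files(file.path(d1, "peaks"), full.names = FALSE))
    expect_identical(readLines(file.path(d1, "peaks", bed)),
                     readLines(file.path(d2, "peaks", bed)), label = bed)
  # a different seed changes the data
  s3 <- generate_scenario(small_cfg(seed = 6L), file.path(tempdir(), "scn_c"))
  expect_false(identical(readLines(s1$files[["background"]]),
                         readLines(s3$files[["background"]])))
})

test_that("noiseless scenarios place every planted site in every member track", {
  d <- file.path(tempdir(), "scn_noiseless")
  scn <- generate_scenario(
    scenario_config(n_rbps = 6L, n_groups = 2L, n_sites = 200L,
                    genome = c(chrS1 = 6e5), noise_edges = 5L,
                    seed = 9L, dropout_prob = 0, background_peak_rate = 0,
                    count_noise = "none", expr_meanlog = 1), d)
  peak_sets <- read_peak_manifest(scn$files[["manifest"]])
  truth <- scn$truth
  sites_gr <- GenomicRanges::GRanges(
    truth$site_coords$chrom,
    IRanges::IRanges(truth$site_coords$start + 1L, truth$site_coords$end))
  for (ps in peak_sets) {
    j <- match(ps$rbp_id, truth$rbp_ids)
    member_groups <- which(vapply(truth$membership, function(m)
      ps$rbp_id %in% m, logical(1)))
    mine <- truth$site_group %in% member_groups
    hit <- IRanges::overlapsAny(sites_gr, ps$peaks)
    # every site of this RBP's groups present, no other planted site present
    expect_true(all(hit[mine]))
    expect_false(any(hit[!mine]))
  }
})

test_that("per-RBP peak counts scale with memberships, dropout, and noise", {
  d <- file.path(tempdir(), "scn_counts")
  cfg <- scenario_config(n_rbps = 6L, n_groups = 2L, n_sites = 600L,
                         genome = c(chrS1 = 2e6), dropout_prob = 0.3,
                         background_peak_rate = 40, seed = 13L,
                         expr_meanlog = 1)
  scn <- generate_scenario(cfg, d)
  peak_sets <- read_peak_manifest(scn$files[["manifest"]])
  per_group_sites <- 300
  for (ps in peak_sets) {
    expected <- per_group_sites * (1 - cfg$dropout_prob) +
      cfg$background_peak_rate
    # 3 sigma on the Poisson background + binomial dropout
    sd3 <- 3 * sqrt(per_group_sites * 0.3 * 0.7 + cfg$background_peak_rate)
    # small extra loss from near-zero expression sites
    expect_gt(length(ps), expected - sd3 - 25)
    expect_lt(length(ps), expected + sd3)
  }
})

test_that("occupancy removes the planted expression confounding", {
  d <- file.path(tempdir(), "scn_confound")
  scn <- generate_scenario(
    scenario_config(n_rbps = 6L, n_groups = 2L, n_sites = 400L,
                    genome = c(chrS1 = 1.5e6), dropout_prob = 0,
                    background_peak_rate = 0, count_noise = "none",
                    expr_meanlog = 1, seed = 21L), d)
  peak_sets <- read_peak_manifest(scn$files[["manifest"]])
  truth <- scn$truth
  sites_gr <- GenomicRanges::GRanges(
    truth$site_coords$chrom,
    IRanges::IRanges(truth$site_coords$start + 1L, truth$site_coords$end))
  sites_gr$site_id <- truth$site_ids
  clip <- signal_from_peaks(peak_sets, sites_gr)
  bg <- signal_from_track(scn$files[["background"]], sites_gr)
  occ <- build_occupancy(clip, bg)
  expr <- truth$site_expression[match(occ$site_ids, truth$site_ids)]
  # raw CLIP RPM tracks expression; occupancy does not
  for (j in seq_len(ncol(occ$V))) {
    bound <- occ$V[, j] > 0
    if (sum(bound) < 50) next
    rho_raw <- cor(clip$counts[match(occ$site_ids, truth$site_ids), j][bound],
                   expr[bound], method = "spearman")
    rho_occ <- cor(occ$V[bound, j], expr[bound], method = "spearman")
    expect_gt(rho_raw, 0.5)
    expect_lt(abs(rho_occ), 0.2)
  }
})

test_that("side tables carry the planted enrichment signal", {
  d <- file.path(tempdir(), "scn_sides")
  scn <- generate_scenario(small_cfg(seed = 31L), d)
  truth <- scn$truth
  hl <- read.table(scn$files[["halflife"]], header = TRUE, sep = "\t")
  short <- hl$half_life_min < quantile(hl$half_life_min, 0.2)
  # genes hosting decay-group sites dominate the short-half-life tail
  expect_gt(mean(hl$gene_id[short] %in% truth$decay_genes), 0.9)
  psi <- read.table(scn$files[["psi"]], header = TRUE, sep = "\t")
  expect_equal(sum(psi$psi < 0.2), sum(truth$as_exon))
  net <- read_network_tsv(scn$files[["network"]])
  planted <- net[net$evidence == "physical", ]
  for (g in truth$membership)
    expect_true(all(utils::combn(sort(g), 2, paste, collapse = "|") %in%
                      paste(planted$rbp_a, planted$rbp_b, sep = "|")))
})

test_that("infeasible geometry is rejected", {
  expect_error(generate_scenario(
    scenario_config(n_sites = 5000L, genome = c(chrS1 = 1e5), seed = 1L),
    file.path(tempdir(), "scn_bad")), "geometry")
})

test_that("the promiscuous knob plants one RBP in two groups", {
  cfg <- scenario_config(n_rbps = 9L, n_groups = 3L, promiscuous_rbp = TRUE,
                         n_sites = 300L, genome = c(chrS1 = 1e6), seed = 2L)
  expect_true(cfg$membership[1L, 1L] && cfg$membership[2L, 1L])
  d <- file.path(tempdir(), "scn_promisc")
  scn <- generate_scenario(cfg, d)
  expect_true("RBP01" %in% scn$truth$membership[[1]] &&
                "RBP01" %in% scn$truth$membership[[2]])
})
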
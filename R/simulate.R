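# Seeded synthetic CLIP scenarios with planted co-binding structure.
#
# The generator emulates the statistical structure the pipeline is built to
# recover: several RBPs share each planted group's binding sites; raw read
# counts confound binding strength with site-level transcript abundance
# (which the occupancy normalization must remove); per-RBP dropout thins
# true sites; Poisson background peaks add noise; and the side tables
# (half-life, PSI, association network) carry planted signal for the
# enrichment statistics.

#' Configuration of a synthetic co-binding scenario
#'
#' Defaults describe the standard validation scenario: 12 RBPs in 3
#' disjoint groups of 4, 1500 planted sites (500 per group), 30% per-RBP
#' dropout of true sites, 2 replicates per RBP, log-normal binding
#' strengths and site expression (the expression spread creates the
#' abundance confounding), and 50 background noise peaks per track.
#'
#' @param n_rbps number of RBPs M.
#' @param n_groups number of planted groups G (`G <= M`).
#' @param n_sites total planted binding sites N (split evenly over groups).
#' @param genome named integer vector of chromosome lengths.
#' @param site_width width of planted sites in bp.
#' @param membership optional G x M logical matrix (overlapping memberships
#'   allowed); default: disjoint equal blocks.
#' @param promiscuous_rbp also place RBP 1 in group 2 (tests soft
#'   clustering).
#' @param strength_meanlog,strength_sdlog log-normal binding-strength
#'   parameters.
#' @param expr_meanlog,expr_sdlog log-normal site-expression parameters.
#' @param depth_factor expected reads per unit strength x expression.
#' @param dropout_prob probability that an RBP misses one of its true sites
#'   entirely.
#' @param background_peak_rate Poisson mean of noise peaks per track.
#' @param n_replicas biological replicates per RBP.
#' @param read_depth nominal total mapped reads per track (for RPM).
#' @param count_noise `"poisson"` (default) or `"none"` (deterministic
#'   expected counts; the noiseless setting).
#' @param decay_group group whose host genes get short half-lives.
#' @param splicing_group group whose nearby exons get low PSI.
#' @param network_evidence evidence type of planted within-group edges.
#' @param noise_edges number of random extra network edges.
#' @param seed integer seed; the whole scenario is a deterministic function
#'   of the configuration.
#' @return a `ScenarioConfig` list.
#' @export
scenario_config <- function(n_rbps = 12L, n_groups = 3L, n_sites = 1500L,
                            genome = c(chrS1 = 2e6, chrS2 = 2e6),
                            site_width = 40L,
                            membership = NULL, promiscuous_rbp = FALSE,
                            strength_meanlog = 0, strength_sdlog = 0.5,
                            expr_meanlog = 0, expr_sdlog = 1,
                            depth_factor = 30,
                            dropout_prob = 0.3,
                            background_peak_rate = 50,
                            n_replicas = 2L,
                            read_depth = 1e6,
                            count_noise = c("poisson", "none"),
                            decay_group = 1L, splicing_group = 2L,
                            network_evidence = "physical",
                            noise_edges = 20L,
                            seed = 1L) {
  count_noise <- match.arg(count_noise)
  if (n_groups > n_rbps) stop("need n_groups <= n_rbps")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)")
  if (n_sites < n_groups) stop("need at least one site per group")
  if (is.null(membership)) {
    membership <- matrix(FALSE, n_groups, n_rbps)
    # contiguous equal-ish blocks of RBPs per group
    sizes <- diff(floor(seq(0, n_rbps, length.out = n_groups + 1)))
    idx <- 1L
    for (g in seq_len(n_groups)) {
      membership[g, idx:(idx + sizes[g] - 1L)] <- TRUE
      idx <- idx + sizes[g]
    }
    if (promiscuous_rbp && n_groups >= 2L) membership[2L, 1L] <- TRUE
  }
  if (!all(dim(membership) == c(n_groups, n_rbps)))
    stop("membership must be a G x M matrix")
  structure(list(
    n_rbps = as.integer(n_rbps), n_groups = as.integer(n_groups),
    n_sites = as.integer(n_sites), genome = genome,
    site_width = as.integer(site_width), membership = membership,
    strength_meanlog = strength_meanlog, strength_sdlog = strength_sdlog,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    depth_factor = depth_factor, dropout_prob = dropout_prob,
    background_peak_rate = background_peak_rate,
    n_replicas = as.integer(n_replicas), read_depth = read_depth,
    count_noise = count_noise, decay_group = as.integer(decay_group),
    splicing_group = as.integer(splicing_group),
    network_evidence = network_evidence,
    noise_edges = as.integer(noise_edges), seed = as.integer(seed)
  ), class = "ScenarioConfig")
}

#' Generate a synthetic scenario on disk
#'
#' Writes, under `out_dir`: per-RBP/replicate peak BEDs plus a manifest;
#' a background expression TSV (site-proportional RNA-seq counts); a toy
#' GTF whose genes host the planted sites; half-life and PSI side tables
#' with planted signal in the designated groups; a protein-association
#' edge list containing all within-group pairs plus noise edges; and the
#' ground truth as JSON. Byte-identical output for identical
#' configurations.
#'
#' @param config a `ScenarioConfig`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `files` (named paths), `truth` (planted
#'   memberships, site assignments, expression, labels, edges) and
#'   `config`.
#' @export
generate_scenario <- function(config, out_dir) {
  stopifnot(inherits(config, "ScenarioConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, .generate_scenario_impl(config, out_dir))
}

.generate_scenario_impl <- function(cfg, out_dir) {
  M <- cfg$n_rbps; G <- cfg$n_groups; N <- cfg$n_sites
  rbps <- sprintf("RBP%02d", seq_len(M))
  w <- cfg$site_width

  # --- site geometry: evenly spaced slots with jitter, split over chroms ---
  glen <- cfg$genome
  n_per_chr <- round(N * glen / sum(glen))
  n_per_chr[length(n_per_chr)] <- N - sum(n_per_chr[-length(n_per_chr)])
  spacing <- as.integer(glen / pmax(n_per_chr, 1L))
  if (any(spacing < w + 20L))
    stop("infeasible geometry: sites exceed the genome")
  chrom <- rep(names(glen), n_per_chr)
  start0 <- as.integer(unlist(lapply(seq_along(glen), function(ci) {
    n <- n_per_chr[ci]
    base <- (seq_len(n) - 1L) * spacing[ci] + 10L
    base + sample.int(max(spacing[ci] - w - 20L, 1L), n, replace = TRUE)
  }), use.names = FALSE))
  # groups laid out in runs of 10 consecutive sites, so each toy gene
  # (10 sites) hosts exactly one group
  site_group <- rep(rep(seq_len(G), length.out = ceiling(N / 10)),
                    each = 10L)[seq_len(N)]
  site_ids <- sprintf("s%05d", seq_len(N))

  expr <- rlnorm(N, cfg$expr_meanlog, cfg$expr_sdlog)

  # --- per-RBP peak files -------------------------------------------------
  peaks_dir <- file.path(out_dir, "peaks")
  dir.create(peaks_dir, showWarnings = FALSE)
  manifest <- list()
  for (j in seq_len(M)) {
    member_groups <- which(cfg$membership[, j])
    mine <- which(site_group %in% member_groups)
    strength <- rlnorm(length(mine), cfg$strength_meanlog,
                       cfg$strength_sdlog)
    kept <- runif(length(mine)) >= cfg$dropout_prob
    lambda <- strength * expr[mine] * cfg$depth_factor
    for (rep_i in seq_len(cfg$n_replicas)) {
      counts <- if (cfg$count_noise == "poisson") rpois(length(mine), lambda)
                else round(lambda)
      use <- kept & counts > 0
      bed <- data.frame(chrom = chrom[mine][use],
                        start = start0[mine][use],
                        end = start0[mine][use] + w,
                        name = site_ids[mine][use],
                        score = counts[use],
                        strand = "+")
      # background noise peaks at random positions
      n_noise <- rpois(1L, cfg$background_peak_rate)
      if (n_noise > 0L) {
        ci <- sample.int(length(glen), n_noise, replace = TRUE)
        st <- vapply(ci, function(k)
          sample.int(as.integer(glen[k]) - w - 1L, 1L), integer(1))
        bed <- rbind(bed, data.frame(
          chrom = names(glen)[ci], start = st, end = st + w,
          name = sprintf("noise_%s_r%d_%03d", rbps[j], rep_i,
                         seq_len(n_noise)),
          score = rpois(n_noise, 8) + 1L, strand = "+"))
      }
      bed <- bed[order(bed$chrom, bed$start), ]
      bed <- bed[!duplicated(bed[, c("chrom", "start", "end")]), ]
      f <- file.path(peaks_dir,
                     sprintf("%s_rep%d.bed", rbps[j], rep_i))
      utils::write.table(bed, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = file.path("peaks", basename(f)), rbp_id = rbps[j],
        method = "sim", replicate = paste0("rep", rep_i))
    }
  }
  manifest <- do.call(rbind, manifest)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- background expression track (RNA-seq proxy) ------------------------
  bg_counts <- if (cfg$count_noise == "poisson")
    rpois(N, expr * cfg$depth_factor) else pmax(round(expr *
                                                        cfg$depth_factor), 1L)
  background <- data.frame(chrom = chrom, start = start0, end = start0 + w,
                           count = bg_counts)
  background_path <- file.path(out_dir, "background.tsv")
  utils::write.table(background, background_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tracks <- data.frame(
    track_id = c(paste(rep(rbps, each = cfg$n_replicas),
                       paste0("rep", seq_len(cfg$n_replicas)), sep = "_"),
                 "rnaseq"),
    kind = c(rep("clip", M * cfg$n_replicas), "rnaseq"),
    total_mapped = cfg$read_depth)
  tracks_path <- file.path(out_dir, "tracks.tsv")
  utils::write.table(tracks, tracks_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- toy gene annotation: one gene per run of 10 consecutive sites ------
  genes_of_site <- ceiling(seq_len(N) / 10)
  gtf_rows <- list()
  gene_rows <- list()
  for (gi in unique(genes_of_site)) {
    idx <- which(genes_of_site == gi)
    if (length(unique(chrom[idx])) > 1L) { # genes must not span chromosomes
      idx <- idx[chrom[idx] == chrom[idx][1L]]
      genes_of_site[setdiff(which(genes_of_site == gi), idx)] <- gi + 0.5
    }
    gid <- sprintf("GENE%04d", gi)
    g_start <- min(start0[idx]) - 5L
    g_end <- max(start0[idx]) + w + 5L
    attr_s <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_type "protein_coding";',
                      gid, gid)
    for (type in c("gene", "transcript", "exon", "CDS"))
      gtf_rows[[length(gtf_rows) + 1L]] <- data.frame(
        chrom = chrom[idx][1L], src = "sim", type = type,
        start = g_start + 1L, end = g_end, score = ".", strand = "+",
        frame = ".", attrs = attr_s)
    gene_rows[[length(gene_rows) + 1L]] <-
      data.frame(gene_id = gid, sites = I(list(idx)))
  }
  gtf_path <- file.path(out_dir, "annotation.gtf")
  utils::write.table(do.call(rbind, gtf_rows), gtf_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  gene_tab <- do.call(rbind, gene_rows)

  # --- half-life table: genes hosting decay-group sites decay fast --------
  hosts_decay <- vapply(gene_tab$sites, function(idx)
    any(site_group[idx] == cfg$decay_group), logical(1))
  halflife <- ifelse(hosts_decay,
                     rlnorm(nrow(gene_tab), log(30), 0.25),
                     rlnorm(nrow(gene_tab), log(150), 0.35))
  halflife_path <- file.path(out_dir, "halflife.tsv")
  utils::write.table(data.frame(gene_id = gene_tab$gene_id,
                                half_life_min = round(halflife, 2)),
                     halflife_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- PSI table: exons ~500 bp downstream of a sample of sites -----------
  exon_site <- seq(1L, N, by = 3L)
  ex_start <- start0[exon_site] + w + 500L
  near_splice <- site_group[exon_site] == cfg$splicing_group
  psi <- ifelse(near_splice, runif(length(exon_site), 0, 0.15),
                runif(length(exon_site), 0.85, 1))
  psi_path <- file.path(out_dir, "psi.tsv")
  utils::write.table(data.frame(chrom = chrom[exon_site], start = ex_start,
                                end = ex_start + 120L, strand = "+",
                                psi = round(psi, 4)),
                     psi_path, sep = "\t", quote = FALSE, row.names = FALSE)

  # --- association network: all within-group pairs + noise edges ----------
  edges <- list()
  for (g in seq_len(G)) {
    memb <- rbps[cfg$membership[g, ]]
    if (length(memb) >= 2L) {
      prs <- utils::combn(memb, 2L)
      edges[[length(edges) + 1L]] <- data.frame(
        rbp_a = prs[1L, ], rbp_b = prs[2L, ],
        evidence = cfg$network_evidence)
    }
  }
  if (cfg$noise_edges > 0L) {
    na_ <- sample(rbps, cfg$noise_edges, replace = TRUE)
    nb_ <- sample(rbps, cfg$noise_edges, replace = TRUE)
    keep <- na_ != nb_
    edges[[length(edges) + 1L]] <- data.frame(
      rbp_a = na_[keep], rbp_b = nb_[keep], evidence = "co-expression")
  }
  network <- association_network(do.call(rbind, edges))
  network_path <- file.path(out_dir, "network.tsv")
  utils::write.table(network, network_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- ground truth -------------------------------------------------------
  truth <- list(
    rbp_ids = rbps,
    membership = lapply(seq_len(G), function(g) rbps[cfg$membership[g, ]]),
    site_ids = site_ids,
    site_group = site_group,
    site_coords = data.frame(chrom = chrom, start = start0,
                             end = start0 + w),
    site_expression = expr,
    decay_genes = gene_tab$gene_id[hosts_decay],
    as_exon = near_splice,
    planted_edges = network[network$evidence == cfg$network_evidence, ]
  )
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(
    rbp_ids = rbps,
    membership = truth$membership,
    site_group = site_group,
    decay_genes = truth$decay_genes,
    n_as_exons = sum(near_splice)
  ), truth_path, auto_unbox = FALSE, digits = NA)

  invisible(list(
    files = c(manifest = manifest_path, background = background_path,
              tracks = tracks_path, gtf = gtf_path,
              halflife = halflife_path, psi = psi_path,
              network = network_path, truth = truth_path),
    truth = truth, config = cfg))
}
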
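# End-to-end orchestration: peaks -> sites -> occupancy -> NMF -> groups ->
# enrichment, with a serialized config and run log for provenance.

#' Assemble a pipeline configuration
#'
#' @param manifest peak manifest TSV (see [read_peak_manifest()]).
#' @param background background coverage TSV (see [signal_from_track()]).
#' @param out_dir output directory.
#' @param gtf optional annotation GTF.
#' @param network,halflife,psi optional side tables for the enrichment
#'   stage.
#' @param primary_method peak caller whose coordinates are kept when
#'   intersecting methods; default: prefer `"piranha"`, else the first
#'   method seen.
#' @param min_reads,min_replicas replicate filter (see [filter_replicas()]).
#' @param bin_len,step long-site splitting (see [split_long_sites()]).
#' @param quantile occupancy scaling quantile.
#' @param min_rbps co-binding filter (see [filter_cobound()]).
#' @param ranks ranks to scan; `NULL` skips the scan.
#' @param runs_schedule run counts per scanned rank.
#' @param rank rank used for the final factorization; `NULL` picks the
#'   scanned candidate with the highest mean dispersion coefficient.
#' @param n_runs restarts for the final factorization.
#' @param membership_threshold group-membership cutoff on scaled
#'   coefficients.
#' @param spec_threshold,coeff_quantile site-association rules (see
#'   [associate_sites()]).
#' @param n_perm network permutation count.
#' @param seed master seed for every seeded stage.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(manifest, background, out_dir,
                            gtf = NULL, network = NULL, halflife = NULL,
                            psi = NULL,
                            primary_method = NULL,
                            min_reads = 4L, min_replicas = 2L,
                            bin_len = 100L, step = 50L,
                            quantile = 0.95, min_rbps = 2L,
                            ranks = 5:20,
                            runs_schedule = c(10, 30, 50, 80, 100),
                            rank = NULL, n_runs = 100L,
                            membership_threshold = 0.2,
                            spec_threshold = 0.8, coeff_quantile = 0.80,
                            n_perm = 10000L, seed = 1L) {
  .assert_scalar_number(quantile, "quantile", 0, 1, strict_lower = TRUE)
  .assert_scalar_number(membership_threshold, "membership_threshold", 0, 1,
                        strict_lower = TRUE, strict_upper = TRUE)
  .assert_scalar_number(spec_threshold, "spec_threshold", 0, 1)
  .assert_scalar_number(coeff_quantile, "coeff_quantile", 0, 1,
                        strict_lower = TRUE)
  structure(list(
    manifest = manifest, background = background, out_dir = out_dir,
    gtf = gtf, network = network, halflife = halflife, psi = psi,
    primary_method = primary_method,
    min_reads = as.integer(min_reads),
    min_replicas = as.integer(min_replicas),
    bin_len = as.integer(bin_len), step = as.integer(step),
    quantile = quantile, min_rbps = as.integer(min_rbps),
    ranks = ranks, runs_schedule = runs_schedule, rank = rank,
    n_runs = as.integer(n_runs),
    membership_threshold = membership_threshold,
    spec_threshold = spec_threshold, coeff_quantile = coeff_quantile,
    n_perm = as.integer(n_perm), seed = as.integer(seed)
  ), class = "PipelineConfig")
}

#' Run the full co-binding pipeline
#'
#' Stages: read peaks per the manifest; per RBP, intersect peak-calling
#' methods (when several are present) and apply the replicate filter; merge
#' all RBPs' peaks into unified sites, split long sites, annotate (when a
#' GTF is given); build and filter the occupancy matrix; scan ranks (when
#' `ranks` is set); factorize at the chosen rank keeping the best of
#' `n_runs` restarts; call group membership and site associations; run the
#' enrichment statistics for every side table provided. All stage outputs,
#' the serialized configuration, and a run log with per-stage counts land
#' in `config$out_dir`.
#'
#' @param config a `PipelineConfig`.
#' @return invisibly, a list with the main in-memory results and the paths
#'   of all written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) writeLines(sprintf(...), log_con)
  logmsg("rbpcobind %s | seed %d",
         as.character(utils::packageVersion("rbpcobind")), config$seed)
  cfg_plain <- unclass(config)
  cfg_plain <- cfg_plain[!vapply(cfg_plain, is.null, logical(1))]
  yaml::write_yaml(cfg_plain, file.path(out, "config.yaml"))

  # --- stage 1: peaks -----------------------------------------------------
  peak_sets <- read_peak_manifest(config$manifest)
  logmsg("read %d peak tracks (%d peaks total)", length(peak_sets),
         sum(vapply(peak_sets, length, integer(1))))
  by_rbp <- split(peak_sets,
                  vapply(peak_sets, function(p) p$rbp_id, character(1)))

  prepped <- lapply(by_rbp, function(tracks) {
    methods_here <- unique(vapply(tracks, function(p) p$method, character(1)))
    if (length(methods_here) == 1L) return(tracks)
    prim <- config$primary_method %||%
      (if ("piranha" %in% methods_here) "piranha" else methods_here[1L])
    others <- setdiff(methods_here, prim)
    lapply(Filter(function(p) p$method == prim, tracks), function(p) {
      for (om in others) {
        against <- Filter(function(q) q$method == om &&
                            q$replicate == p$replicate, tracks)
        if (length(against) == 0L)
          against <- Filter(function(q) q$method == om, tracks)
        if (length(against) > 0L)
          p <- intersect_methods(p, against[[1L]])
      }
      p
    })
  })
  filtered <- lapply(prepped, function(tracks)
    filter_replicas(tracks, min_reads = config$min_reads,
                    min_replicas = config$min_replicas))
  logmsg("replicate filter: %s",
         paste(sprintf("%s=%d", names(filtered),
                       vapply(filtered, length, integer(1))),
               collapse = " "))

  # --- stage 2: merged sites ----------------------------------------------
  sites <- merge_sites(unname(filtered))
  n_merged <- length(sites)
  sites <- split_long_sites(sites, bin_len = config$bin_len,
                            step = config$step)
  logmsg("merged sites: %d (%d after splitting long sites)", n_merged,
         length(sites))
  if (!is.null(config$gtf)) {
    model <- read_annotation_gtf(config$gtf)
    sites <- annotate_sites(sites, model)
  }
  sites_path <- file.path(out, "sites.bed")
  write_sites_bed(sites, sites_path)

  # --- stage 3: occupancy -------------------------------------------------
  # CLIP signal per RBP: summed peak read counts over replicates, taken
  # from the method-intersected (pre-replicate-pooling) tracks
  clip <- signal_from_peaks(unlist(prepped, recursive = FALSE), sites)
  bg <- signal_from_track(config$background, sites)
  occ <- build_occupancy(clip, bg, quantile = config$quantile)
  logmsg("occupancy: %d sites with background signal", nrow(occ$V))
  occ <- filter_cobound(occ, min_rbps = config$min_rbps)
  logmsg("co-binding filter: %d sites x %d RBPs", nrow(occ$V), ncol(occ$V))
  occ_path <- file.path(out, "occupancy.tsv")
  write_occupancy_tsv(occ, occ_path)

  # --- stage 4: rank selection --------------------------------------------
  scan <- NULL
  rank <- config$rank
  if (!is.null(config$ranks) && length(config$ranks) > 0L) {
    scan <- rank_scan(occ$V, ranks = config$ranks,
                      runs_schedule = config$runs_schedule,
                      base_seed = config$seed)
    write_rank_scan_tsv(scan, file.path(out, "rank_scan.tsv"))
    logmsg("rank scan: candidates %s",
           paste(scan$candidates, collapse = ", "))
    if (is.null(rank)) {
      dc_cand <- scan$summary[scan$summary$dc_local_max, ]
      rank <- if (nrow(dc_cand)) dc_cand$rank[which.max(dc_cand$dc_mean)]
              else scan$summary$rank[which.max(scan$summary$dc_mean)]
    }
  }
  if (is.null(rank))
    stop("no factorization rank: set `rank` or provide `ranks` to scan")
  logmsg("selected rank: %d", rank)

  # --- stage 5: factorization and group calling ---------------------------
  run <- best_run(occ$V, R = rank, n_runs = config$n_runs,
                  base_seed = .wrap_seed(config$seed + 7919L))
  logmsg("best of %d runs: KL = %.6g (seed %d)", config$n_runs,
         run$kl_error, run$seed)
  write_nmf_run(run, file.path(out, "nmf"))

  H_scaled <- scale_coefficients(run$H)
  groups <- suppressWarnings(
    call_members(H_scaled, threshold = config$membership_threshold))
  assoc <- associate_sites(run$W, spec_threshold = config$spec_threshold,
                           coeff_quantile = config$coeff_quantile)
  groups_path <- file.path(out, "groups.tsv")
  assoc_path <- file.path(out, "associations.tsv")
  write_group_tables(groups, assoc, groups_path, assoc_path)
  logmsg("groups: %d | site associations: %d", length(groups), nrow(assoc))

  # --- stage 6: enrichment ------------------------------------------------
  enrich <- list()
  site_lookup <- setNames(seq_along(sites), sites$site_id)
  if (!is.null(config$network)) {
    network <- read_network_tsv(config$network)
    universe <- occ$rbp_ids
    enrich$network <- do.call(rbind, lapply(names(groups), function(g) {
      memb <- intersect(groups[[g]]$rbp_id, universe)
      if (length(memb) < 2L) return(NULL)
      res <- permutation_group_support(memb, universe, network,
                                       n_perm = config$n_perm,
                                       seed = .wrap_seed(config$seed + 104729L))
      cbind(group = g, res)
    }))
    utils::write.table(enrich$network, file.path(out, "network_support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$halflife) || !is.null(config$psi)) {
    assoc_sites_by_group <- split(assoc$site_id, assoc$group)
    if (!is.null(config$halflife)) {
      hl_tab <- utils::read.table(config$halflife, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
      model <- read_annotation_gtf(config$gtf)
      enrich$halflife <- lapply(assoc_sites_by_group, function(sids) {
        gsites <- sites[site_lookup[sids]]
        ov <- GenomicRanges::findOverlaps(model$genes, gsites,
                                          ignore.strand = TRUE)
        bound <- model$genes$gene_id[unique(queryHits(ov))]
        hits <- setNames(hl_tab$gene_id %in% bound, hl_tab$gene_id)
        halflife_enrichment(hits, setNames(hl_tab$half_life_min,
                                           hl_tab$gene_id))
      })
    }
    if (!is.null(config$psi)) {
      psi_tab <- utils::read.table(config$psi, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
      exons <- GenomicRanges::GRanges(psi_tab$chrom,
                                      IRanges::IRanges(psi_tab$start + 1L,
                                                       psi_tab$end),
                                      strand = psi_tab$strand,
                                      psi = psi_tab$psi)
      enrich$splicing <- lapply(assoc_sites_by_group, function(sids)
        splicing_enrichment(sites[site_lookup[sids]], exons))
    }
  }

  logmsg("done")
  invisible(list(
    sites = sites, occupancy = occ, scan = scan, rank = rank, run = run,
    groups = groups, associations = assoc, enrichment = enrich,
    paths = c(sites = sites_path, occupancy = occ_path,
              groups = groups_path, associations = assoc_path,
              log = log_path)))
}
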
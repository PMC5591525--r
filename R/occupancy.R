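# Occupancy profile matrix: normalized, bounded binding-site occupancy.
#
# CLIP read coverage at a site mixes binding affinity with transcript
# abundance. Treating RBP-site binding as an equilibrium, the fraction of
# transcript copies bound at a site (the occupancy, in [0,1]) is proportional
# to CLIP RPM divided by background RNA-seq RPM (eCLIP input RPM for eCLIP).
# Each RBP's ratios are scaled by their 95% quantile, under the assumption
# that an RBP's most strongly bound sites are near-fully occupied, and capped
# at 1.

#' Reads per million mapped reads
#'
#' @param count read count (non-negative).
#' @param total_mapped total mapped reads of the track (> 0).
#' @return `count * 1e6 / total_mapped` (vectorized).
#' @export
compute_rpm <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) stop("`total_mapped` must be > 0")
  if (any(count < 0)) stop("`count` must be >= 0")
  count * 1e6 / total_mapped
}

#' Bundle per-site counts with track depth
#'
#' @param counts numeric matrix (sites x tracks) or vector (single track) of
#'   raw read counts.
#' @param total_mapped total mapped reads, one per track.
#' @param kind `"clip"`, `"rnaseq"` or `"eclip_input"`.
#' @return a `SignalTable` object.
#' @export
signal_table <- function(counts, total_mapped,
                         kind = c("clip", "rnaseq", "eclip_input")) {
  kind <- match.arg(kind)
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1L)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (length(total_mapped) != ncol(counts))
    stop("`total_mapped` must have one entry per track")
  if (any(total_mapped <= 0)) stop("total mapped reads must be > 0")
  structure(list(counts = counts, total_mapped = as.numeric(total_mapped),
                 kind = kind),
            class = "SignalTable")
}

#' Count CLIP signal on merged sites from peak read counts
#'
#' For each RBP, sums the `read_count` of all its peaks (across the supplied
#' peak sets, e.g. replicates) that overlap each merged site.
#'
#' @param peak_sets list of `PeakSet`s (possibly several per RBP).
#' @param sites merged-site `GRanges`.
#' @param total_mapped named vector of total mapped reads per RBP; defaults
#'   to the summed read counts per RBP (RPM then cancels in scaling).
#' @return a `SignalTable` of kind `"clip"` with one column per RBP, ordered
#'   by first appearance.
#' @export
signal_from_peaks <- function(peak_sets, sites, total_mapped = NULL) {
  rbps <- unique(vapply(peak_sets, function(p) p$rbp_id, character(1)))
  counts <- matrix(0, nrow = length(sites), ncol = length(rbps),
                   dimnames = list(sites$site_id, rbps))
  for (ps in peak_sets) {
    ov <- GenomicRanges::findOverlaps(sites, ps$peaks)
    if (length(ov) == 0L) next
    agg <- tapply(ps$peaks$read_count[subjectHits(ov)], queryHits(ov), sum)
    counts[as.integer(names(agg)), ps$rbp_id] <-
      counts[as.integer(names(agg)), ps$rbp_id] + as.numeric(agg)
  }
  if (is.null(total_mapped)) {
    total_mapped <- pmax(colSums(counts), 1)
  } else {
    total_mapped <- total_mapped[rbps]
  }
  signal_table(counts, total_mapped, kind = "clip")
}

#' Count background signal on merged sites from a coverage table
#'
#' Sums the counts of background (total RNA-seq or eCLIP input) intervals
#' overlapping each site.
#'
#' @param track `GRanges` with a `count` metadata column, or a data frame /
#'   TSV path with columns `chrom`, `start`, `end`, `count` (0-based
#'   half-open).
#' @param sites merged-site `GRanges`.
#' @param total_mapped total mapped reads of the background track; defaults
#'   to the sum of the track counts.
#' @param kind `"rnaseq"` (default) or `"eclip_input"`.
#' @return a single-column `SignalTable`.
#' @export
signal_from_track <- function(track, sites, total_mapped = NULL,
                              kind = "rnaseq") {
  if (is.character(track))
    track <- utils::read.table(track, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  if (is.data.frame(track)) {
    track <- GenomicRanges::GRanges(track$chrom,
                                    IRanges::IRanges(track$start + 1L,
                                                     track$end),
                                    count = track$count)
  }
  if (is.null(track$count)) stop("background track needs a `count` column")
  counts <- rep(0, length(sites))
  ov <- GenomicRanges::findOverlaps(sites, track, ignore.strand = TRUE)
  if (length(ov)) {
    agg <- tapply(track$count[subjectHits(ov)], queryHits(ov), sum)
    counts[as.integer(names(agg))] <- as.numeric(agg)
  }
  if (is.null(total_mapped)) total_mapped <- max(sum(track$count), 1)
  st <- signal_table(counts, total_mapped, kind = kind)
  rownames(st$counts) <- sites$site_id
  st
}

#' Build the occupancy profile matrix
#'
#' Computes per-site, per-RBP occupancy: the ratio of CLIP RPM to background
#' RPM, scaled per RBP by the `quantile` quantile of its strictly positive
#' ratios and capped at 1. Sites with zero raw background signal are dropped
#' (occupancy is undefined without transcript evidence).
#'
#' @param clip `SignalTable` of kind `"clip"` (sites x RBPs).
#' @param background single-track `SignalTable` of kind `"rnaseq"` or
#'   `"eclip_input"`, on the same sites in the same order.
#' @param site_ids site identifiers; defaults to the clip table's row names.
#' @param quantile scaling quantile in (0, 1\] (default 0.95).
#' @return an `OccupancyMatrix`: list with `V` (sites x RBPs, entries in
#'   \[0,1\]), `site_ids`, `rbp_ids`, `q95` (the per-RBP scaling quantiles).
#' @export
build_occupancy <- function(clip, background, site_ids = NULL,
                            quantile = 0.95) {
  if (!inherits(clip, "SignalTable") || !inherits(background, "SignalTable"))
    stop("`clip` and `background` must be SignalTable objects")
  if (clip$kind != "clip") stop("`clip` must have kind 'clip'")
  if (background$kind == "clip")
    stop("`background` must be an rnaseq or eclip_input table")
  if (ncol(background$counts) != 1L)
    stop("`background` must be a single track")
  if (nrow(background$counts) != nrow(clip$counts))
    stop("clip and background tables cover different site sets")
  .assert_scalar_number(quantile, "quantile", 0, 1, strict_lower = TRUE)

  if (is.null(site_ids)) site_ids <- rownames(clip$counts)
  if (is.null(site_ids)) site_ids <- sprintf("site_%05d",
                                             seq_len(nrow(clip$counts)))
  rbp_ids <- colnames(clip$counts) %||%
    sprintf("rbp_%02d", seq_len(ncol(clip$counts)))

  clip_rpm <- sweep(clip$counts, 2L, clip$total_mapped, "/") * 1e6
  bg_count <- as.numeric(background$counts[, 1L])
  bg_rpm <- compute_rpm(bg_count, background$total_mapped)

  keep <- bg_count > 0  # zero raw background reads = no transcript evidence
  if (!any(keep)) stop("no site has background signal")
  ratio <- clip_rpm[keep, , drop = FALSE] / bg_rpm[keep]

  q95 <- vapply(seq_len(ncol(ratio)), function(j)
    positive_quantile(ratio[, j], quantile), numeric(1))
  if (anyNA(q95))
    stop("no positive occupancy ratio for RBP(s): ",
         paste(rbp_ids[is.na(q95)], collapse = ", "))
  V <- pmin(sweep(ratio, 2L, q95, "/"), 1)
  dimnames(V) <- list(site_ids[keep], rbp_ids)
  structure(list(V = V, site_ids = site_ids[keep], rbp_ids = rbp_ids,
                 q95 = setNames(q95, rbp_ids)),
            class = "OccupancyMatrix")
}

#' @export
print.OccupancyMatrix <- function(x, ...) {
  cat(sprintf("<OccupancyMatrix> %d sites x %d RBPs\n",
              nrow(x$V), ncol(x$V)))
  invisible(x)
}

#' Drop sites bound by too few RBPs
#'
#' Sites with occupancy evidence for only one RBP carry no co-binding
#' information; only rows with at least `min_rbps` strictly positive entries
#' are retained.
#'
#' @param occ an `OccupancyMatrix`.
#' @param min_rbps minimum number of RBPs with positive occupancy
#'   (default 2).
#' @return a filtered `OccupancyMatrix`.
#' @export
filter_cobound <- function(occ, min_rbps = 2L) {
  if (!inherits(occ, "OccupancyMatrix"))
    stop("`occ` must be an OccupancyMatrix")
  keep <- rowSums(occ$V > 0) >= min_rbps
  if (!any(keep))
    stop("no site is bound by at least ", min_rbps, " RBPs")
  structure(list(V = occ$V[keep, , drop = FALSE],
                 site_ids = occ$site_ids[keep],
                 rbp_ids = occ$rbp_ids, q95 = occ$q95),
            class = "OccupancyMatrix")
}

#' Write / read an occupancy matrix as TSV plus a q95 sidecar JSON
#'
#' @param occ an `OccupancyMatrix`.
#' @param path output TSV path (sites in rows, RBPs in columns); the scaling
#'   quantiles go to `paste0(path, ".q95.json")`.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(occ, path) {
  tab <- data.frame(site_id = occ$site_ids, occ$V, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(occ$q95), paste0(path, ".q95.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
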
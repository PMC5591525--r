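# Interval comparison and merging for CLIP binding peaks.
#
# Strand handling, throughout: when every range in both inputs carries an
# explicit strand, set operations are strand-aware; as soon as one side
# contains unstranded ("*") ranges the comparison is strand-blind. Overlap
# queries (findOverlaps) get this behaviour natively from GenomicRanges.

.harmonize_strand <- function(a, b) {
  if (any(as.character(strand(a)) == "*") ||
      any(as.character(strand(b)) == "*")) {
    strand(a) <- "*"
    strand(b) <- "*"
  }
  lv <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- lv
  seqlevels(b) <- lv
  list(a = a, b = b)
}

#' Jaccard similarity of two peak sets
#'
#' Per-base Jaccard index: the number of bases covered by both sets divided
#' by the number of bases covered by either. Used to quantify agreement
#' between peak callers or biological replicates of the same RBP, where raw
#' peak lists often disagree substantially.
#'
#' @param a,b `PeakSet` or `GRanges` objects on the same genome naming
#'   convention.
#' @return a number in \[0, 1\].
#' @export
#' @examples
#' g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' g2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' jaccard_similarity(g1, g2)  # 50 / 150
jaccard_similarity <- function(a, b) {
  ga <- peak_ranges(a)
  gb <- peak_ranges(b)
  if (length(ga) == 0L && length(gb) == 0L)
    stop("jaccard_similarity is undefined for two empty peak sets")
  h <- .harmonize_strand(ga, gb)
  ra <- GenomicRanges::reduce(h$a)
  rb <- GenomicRanges::reduce(h$b)
  inter <- sum(width(GenomicRanges::intersect(ra, rb)))
  uni <- sum(width(GenomicRanges::union(ra, rb)))
  inter / uni
}

#' Keep peaks confirmed by a second peak caller
#'
#' Retains the peaks of `primary` that overlap at least `min_overlap_bp`
#' bases with any peak of `other` called on the same RBP (e.g. keep
#' Piranha peaks confirmed by PARalyzer). Retained peaks keep the primary
#' caller's coordinates and read counts.
#'
#' @param primary,other `PeakSet`s for the same `rbp_id`.
#' @param min_overlap_bp minimum overlap in bases (default 1).
#' @return a `PeakSet` (subset of `primary`).
#' @export
intersect_methods <- function(primary, other, min_overlap_bp = 1L) {
  if (!inherits(primary, "PeakSet") || !inherits(other, "PeakSet"))
    stop("`primary` and `other` must be PeakSet objects")
  if (primary$rbp_id != other$rbp_id)
    stop(sprintf("rbp_id mismatch: '%s' vs '%s'",
                 primary$rbp_id, other$rbp_id))
  hits <- GenomicRanges::findOverlaps(primary$peaks, other$peaks,
                                      minoverlap = as.integer(min_overlap_bp))
  keep <- sort(unique(queryHits(hits)))
  out <- primary
  out$peaks <- primary$peaks[keep]
  out$method <- paste(primary$method, other$method, sep = "+")
  out
}

#' Filter peaks by read support across biological replicates
#'
#' Implements the semi-overlap replicate rule: a peak is kept when it has at
#' least `min_reads` reads and overlaps (>= 1 bp) a peak that also has at
#' least `min_reads` reads in at least `min_replicas - 1` other replicates.
#' With a single replicate only the read-count filter applies. Kept peaks
#' from all replicates are pooled and overlapping or bookended coordinates
#' are coalesced; the coalesced peak's `read_count` is the maximum of its
#' contributors.
#'
#' @param replicas list of `PeakSet`s sharing one `rbp_id`.
#' @param min_reads minimum read count per peak (default 4, i.e. more than
#'   3 reads).
#' @param min_replicas number of replicates a peak must be supported in
#'   (default 2).
#' @return a single pooled `PeakSet`.
#' @export
filter_replicas <- function(replicas, min_reads = 4L, min_replicas = 2L) {
  if (!is.list(replicas) || length(replicas) == 0L)
    stop("`replicas` must be a non-empty list of PeakSet objects")
  if (!all(vapply(replicas, inherits, logical(1), "PeakSet")))
    stop("all replicas must be PeakSet objects")
  rbp <- unique(vapply(replicas, function(x) x$rbp_id, character(1)))
  if (length(rbp) != 1L)
    stop("replicas span multiple rbp_ids: ", paste(rbp, collapse = ", "))

  qualifying <- lapply(replicas, function(ps)
    ps$peaks[ps$peaks$read_count >= min_reads])

  if (length(replicas) == 1L) {
    kept <- qualifying[[1L]]
  } else {
    kept_list <- lapply(seq_along(qualifying), function(i) {
      q <- qualifying[[i]]
      if (length(q) == 0L) return(q)
      support <- rep(0L, length(q))
      for (j in seq_along(qualifying)) {
        if (j == i) next
        support <- support +
          as.integer(IRanges::overlapsAny(q, qualifying[[j]]))
      }
      q[support >= (min_replicas - 1L)]
    })
    kept <- do.call(c, kept_list)
  }

  if (length(kept) == 0L) {
    merged <- GenomicRanges::GRanges(read_count = integer(0))
  } else {
    merged <- GenomicRanges::reduce(kept, ignore.strand =
                                      any(as.character(strand(kept)) == "*"))
    ov <- GenomicRanges::findOverlaps(merged, kept)
    rc <- rep(0L, length(merged))
    agg <- tapply(kept$read_count[subjectHits(ov)], queryHits(ov), max)
    rc[as.integer(names(agg))] <- as.integer(agg)
    merged$read_count <- rc
  }
  PeakSet(rbp, method = replicas[[1L]]$method, replicate = "pooled", merged)
}

#' Merge per-RBP peaks into a unified set of binding sites
#'
#' Pools the (already method- and replicate-filtered) peaks of all RBPs and
#' coalesces overlapping or bookended intervals into merged binding sites.
#' Each site records which RBPs contributed at least one overlapping peak.
#'
#' @param all_rbp_peaks list of `PeakSet`s, one per RBP.
#' @return a sorted `GRanges` with metadata columns `site_id`,
#'   `source_rbps` (CharacterList), `annotation` (`NA` until
#'   [annotate_sites()]), and `parent_id` (`NA` until [split_long_sites()]).
#' @export
merge_sites <- function(all_rbp_peaks) {
  if (!is.list(all_rbp_peaks) || length(all_rbp_peaks) == 0L)
    stop("`all_rbp_peaks` must be a non-empty list")
  grs <- lapply(all_rbp_peaks, peak_ranges)
  lv <- Reduce(union, lapply(grs, seqlevels))
  grs <- lapply(grs, function(g) { seqlevels(g) <- lv; g })
  pooled <- do.call(c, lapply(grs, GenomicRanges::granges))
  blind <- any(as.character(strand(pooled)) == "*")
  if (blind) strand(pooled) <- "*"
  sites <- sort(GenomicRanges::reduce(pooled))

  src <- vector("list", length(sites))
  for (i in seq_along(all_rbp_peaks)) {
    ps <- all_rbp_peaks[[i]]
    g <- grs[[i]]
    if (blind) strand(g) <- "*"
    hit <- unique(queryHits(GenomicRanges::findOverlaps(sites, g)))
    id <- if (inherits(ps, "PeakSet")) ps$rbp_id else paste0("set", i)
    for (k in hit) src[[k]] <- c(src[[k]], id)
  }
  sites$site_id <- sprintf("site_%05d", seq_along(sites))
  sites$source_rbps <- IRanges::CharacterList(lapply(src, function(s)
    sort(unique(s %||% character(0)))))
  sites$annotation <- NA_character_
  sites$parent_id <- NA_character_
  sites
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Split long merged sites into overlapping fixed-length bins
#'
#' Sites longer than `bin_len` bias downstream per-site statistics, so they
#' are replaced by `bin_len`-bp bins advancing by `step` bp (offsets 0,
#' `step`, 2 `step`, ... while the bin still fits). When the last regular bin
#' ends before the site does, one extra bin anchored at the site end is
#' appended so that every base stays covered. Bins inherit the parent's
#' sources and record its `site_id` as `parent_id`.
#'
#' @param sites merged-site `GRanges` (see [merge_sites()]).
#' @param bin_len bin length in bp (default 100).
#' @param step bin offset step in bp (default 50; consecutive bins overlap
#'   `bin_len - step` bases).
#' @return a `GRanges` in which every interval has width <= `bin_len`.
#' @export
split_long_sites <- function(sites, bin_len = 100L, step = 50L) {
  bin_len <- as.integer(bin_len)
  step <- as.integer(step)
  if (!(bin_len > step && step > 0L))
    stop("need bin_len > step > 0")
  w <- width(sites)
  long <- which(w > bin_len)
  if (length(long) == 0L) return(sites)

  pieces <- lapply(long, function(i) {
    len <- w[i]
    offs <- seq.int(0L, len - bin_len, by = step)
    if (max(offs) + bin_len < len) offs <- c(offs, len - bin_len)
    g <- GenomicRanges::GRanges(
      seqnames = rep(seqnames(sites)[i], length(offs)),
      ranges = IRanges::IRanges(start = start(sites)[i] + offs,
                                width = bin_len),
      strand = rep(strand(sites)[i], length(offs))
    )
    mcols(g) <- mcols(sites)[rep(i, length(offs)), , drop = FALSE]
    g$parent_id <- sites$site_id[i]
    g$site_id <- sprintf("%s.%02d", sites$site_id[i], seq_along(offs))
    g
  })
  out <- c(sites[-long], do.call(c, pieces))
  sort(out, ignore.strand = TRUE)
}
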
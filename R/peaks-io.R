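#' Construct a peak set for one RBP / peak caller / replicate
#'
#' A `PeakSet` bundles the binding peaks of one CLIP-seq track: one RBP,
#' called by one method, in one biological replicate. Coordinates are held as
#' a [GenomicRanges::GRanges] with a `read_count` metadata column; BED input
#' (0-based half-open) is converted to the 1-based closed convention GRanges
#' uses on read and converted back on write.
#'
#' @param rbp_id RBP identifier (non-empty string).
#' @param method peak caller label, e.g. `"piranha"`, `"paralyzer"`,
#'   `"clipper"`.
#' @param replicate replicate label.
#' @param peaks `GRanges` with integer metadata column `read_count`
#'   (and optionally `score`). Strand `"."` in input files becomes `"*"`.
#' @return an object of class `PeakSet`.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50),
#'                              read_count = 10L)
#' PeakSet("RBP1", "piranha", "rep1", gr)
PeakSet <- function(rbp_id, method, replicate, peaks) {
  if (!is.character(rbp_id) || length(rbp_id) != 1L || !nzchar(rbp_id))
    stop("`rbp_id` must be a non-empty string")
  if (!methods::is(peaks, "GRanges"))
    stop("`peaks` must be a GRanges")
  if (is.null(peaks$read_count)) peaks$read_count <- 0L
  if (any(peaks$read_count < 0)) stop("read counts must be >= 0")
  if (any(GenomicRanges::width(peaks) < 1L)) stop("peaks must have width >= 1")
  peaks <- sort(peaks, ignore.strand = TRUE)
  key <- paste(seqnames(peaks), start(peaks), end(peaks), strand(peaks))
  if (anyDuplicated(key)) stop("duplicate (chrom,start,end,strand) peaks")
  structure(
    list(rbp_id = rbp_id, method = as.character(method),
         replicate = as.character(replicate), peaks = peaks),
    class = "PeakSet"
  )
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("<PeakSet> %s | %s | %s : %d peaks\n",
              x$rbp_id, x$method, x$replicate, length(x$peaks)))
  invisible(x)
}

#' @export
length.PeakSet <- function(x) length(x$peaks)

# Extract the GRanges from a PeakSet or pass a GRanges through.
peak_ranges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (inherits(x, "PeakSet")) return(x$peaks)
  stop("expected a PeakSet or GRanges")
}

#' Read one BED peak file into a PeakSet
#'
#' Expects BED6-like columns (chrom, start, end, name, score, strand). The
#' read count backing the replicate filter is taken from `count_col`
#' (default: the BED score column). Missing strand is stored as `"*"`.
#'
#' @param path BED file path.
#' @param rbp_id,method,replicate track identity (see [PeakSet()]).
#' @param count_col 1-based column index holding the per-peak read count.
#' @return a `PeakSet`.
#' @export
read_peak_bed <- function(path, rbp_id, method, replicate, count_col = 5L) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3L) stop("BED file needs >= 3 columns: ", path)
  strand <- if (ncol(tab) >= 6L) tab[[6L]] else "."
  strand[!strand %in% c("+", "-")] <- "*"
  counts <- if (ncol(tab) >= count_col) round(as.numeric(tab[[count_col]])) else 0
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1L]],
    ranges = IRanges::IRanges(start = tab[[2L]] + 1L, end = tab[[3L]]),
    strand = strand,
    read_count = as.integer(counts)
  )
  if (ncol(tab) >= 5L && count_col != 5L) gr$score <- as.numeric(tab[[5L]])
  PeakSet(rbp_id, method, replicate, gr)
}

#' Read a peak-file manifest
#'
#' The manifest is a TSV with header columns `file`, `rbp_id`, `method`,
#' `replicate`; `file` paths are resolved relative to `base_dir` (default:
#' the manifest's own directory).
#'
#' @param path manifest TSV.
#' @param base_dir directory against which relative file paths are resolved.
#' @param count_col passed to [read_peak_bed()].
#' @return a list of `PeakSet` objects.
#' @export
read_peak_manifest <- function(path, base_dir = dirname(path), count_col = 5L) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("file", "rbp_id", "method", "replicate")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base_dir, man$file[i])
    if (!file.exists(f)) stop("manifest entry points to a missing file: ",
                              man$file[i])
    read_peak_bed(f, man$rbp_id[i], man$method[i], man$replicate[i],
                  count_col = count_col)
  })
}

#' Write merged binding sites as BED
#'
#' Emits BED6 with 0-based half-open coordinates; the name field is
#' `site_id|annotation` (annotation `NA` when the sites were not annotated),
#' and the score field the number of contributing RBPs.
#'
#' @param sites `GRanges` of merged sites (from [merge_sites()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  ann <- if (is.null(sites$annotation)) rep(NA_character_, length(sites))
         else sites$annotation
  n_src <- if (is.null(sites$source_rbps)) rep(0L, length(sites))
           else lengths(sites$source_rbps)
  strand <- as.character(strand(sites))
  strand[strand == "*"] <- "."
  tab <- data.frame(
    chrom = as.character(seqnames(sites)),
    start = start(sites) - 1L,
    end = end(sites),
    name = paste(sites$site_id, ann, sep = "|"),
    score = n_src,
    strand = strand
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
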
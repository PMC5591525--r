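# Genomic annotation of merged binding sites.

#' Priority order of annotation categories
#'
#' Sites overlapping several feature classes take the first matching label in
#' this order; `"intergenic"` is used for sites overlapping no gene and
#' `"others"` for sites inside a gene but in none of the feature classes.
#'
#' @return character vector of category labels.
#' @export
annotation_priority <- function() {
  c("CDS", "canonical_ncRNA", "three_prime_UTR", "five_prime_UTR",
    "lncRNA_exon", "pseudogene", "intron")
}

# Gene biotypes counted as canonical non-coding RNA classes
# (miRNA, snRNA, snoRNA, tRNA, rRNA, Y RNA, 7SK).
.canonical_nc_types <- c("miRNA", "snRNA", "snoRNA", "tRNA", "Mt_tRNA",
                         "rRNA", "Mt_rRNA", "Y_RNA", "7SK", "scRNA",
                         "vault_RNA", "vaultRNA")

#' Build an annotation model from per-class feature ranges
#'
#' @param features named list of `GRanges`, with names drawn from
#'   [annotation_priority()]. Missing classes are treated as empty.
#' @param genes `GRanges` of gene bodies (used to separate `"others"` from
#'   `"intergenic"`).
#' @return an object of class `AnnotationModel`.
#' @export
annotation_model <- function(features, genes) {
  if (!methods::is(genes, "GRanges")) stop("`genes` must be a GRanges")
  bad <- setdiff(names(features), annotation_priority())
  if (length(bad))
    stop("unknown feature classes: ", paste(bad, collapse = ", "))
  for (f in features)
    if (!methods::is(f, "GRanges")) stop("features must be GRanges")
  empty <- GenomicRanges::GRanges()
  full <- setNames(
    lapply(annotation_priority(), function(cl) features[[cl]] %||% empty),
    annotation_priority()
  )
  structure(list(features = full, genes = genes), class = "AnnotationModel")
}

#' @export
print.AnnotationModel <- function(x, ...) {
  cat("<AnnotationModel>\n")
  for (cl in names(x$features))
    cat(sprintf("  %-16s %6d features\n", cl, length(x$features[[cl]])))
  cat(sprintf("  %-16s %6d ranges\n", "genes", length(x$genes)))
  invisible(x)
}

#' Load an annotation model from a GTF file
#'
#' Best-effort mapping of a GENCODE-dialect GTF onto the fixed feature
#' classes: `CDS` records, exon records of canonical ncRNA / lncRNA /
#' pseudogene biotypes, explicit `three_prime_utr` / `five_prime_utr`
#' records (generic `UTR` records are classified by their position relative
#' to the transcript's CDS), and introns computed as gene bodies minus all
#' exons.
#'
#' @param path GTF file.
#' @param lnc_types gene biotypes treated as lncRNA.
#' @param nc_types gene biotypes treated as canonical ncRNA.
#' @return an `AnnotationModel`.
#' @export
read_annotation_gtf <- function(path,
                                lnc_types = c("lncRNA", "lincRNA",
                                              "antisense"),
                                nc_types = .canonical_nc_types) {
  gtf <- rtracklayer::import(path, format = "gtf")
  type <- tolower(as.character(gtf$type))

  genes <- gtf[type == "gene"]
  if (length(genes) == 0L) { # fall back to transcript extents
    tx <- gtf[type == "transcript"]
    genes <- if (length(tx)) GenomicRanges::reduce(tx) else
      GenomicRanges::reduce(gtf)
  }
  exons <- gtf[type == "exon"]
  exon_bt <- (gtf$gene_type %||% gtf$gene_biotype %||%
                rep(NA_character_, length(gtf)))[type == "exon"]
  cds <- gtf[type == "cds"]

  utr3 <- gtf[type == "three_prime_utr"]
  utr5 <- gtf[type == "five_prime_utr"]
  utr <- gtf[type == "utr"]
  if (length(utr)) {
    # classify generic UTR records against the CDS span of their transcript
    txid <- utr$transcript_id
    cds_by_tx <- split(cds, cds$transcript_id)
    cls <- vapply(seq_along(utr), function(i) {
      cr <- cds_by_tx[[txid[i]]]
      if (is.null(cr) || length(cr) == 0L) return(NA_character_)
      plus <- as.character(strand(utr[i])) != "-"
      before <- end(utr[i]) <= min(start(cr))
      if (xor(plus, !before)) "five" else "three"
    }, character(1))
    utr5 <- c(utr5, utr[!is.na(cls) & cls == "five"])
    utr3 <- c(utr3, utr[!is.na(cls) & cls == "three"])
  }

  feats <- list(
    CDS = cds,
    canonical_ncRNA = exons[exon_bt %in% nc_types],
    three_prime_UTR = utr3,
    five_prime_UTR = utr5,
    lncRNA_exon = exons[exon_bt %in% lnc_types],
    pseudogene = exons[!is.na(exon_bt) & grepl("pseudogene", exon_bt)],
    intron = GenomicRanges::setdiff(GenomicRanges::reduce(genes),
                                    GenomicRanges::reduce(exons))
  )
  annotation_model(feats, genes = genes)
}

#' Annotate merged binding sites by genomic feature class
#'
#' Each site gets the first category of [annotation_priority()] whose
#' features it overlaps by at least one base; sites overlapping no feature
#' are `"intergenic"` when outside every gene body and `"others"` otherwise.
#' Overlap is strand-aware except where either side is unstranded.
#'
#' @param sites merged-site `GRanges`.
#' @param model an `AnnotationModel`.
#' @return `sites` with the `annotation` metadata column filled in.
#' @export
annotate_sites <- function(sites, model) {
  if (!inherits(model, "AnnotationModel"))
    stop("`model` must be an AnnotationModel")
  ann <- rep(NA_character_, length(sites))
  for (cl in annotation_priority()) {
    feats <- model$features[[cl]]
    if (length(feats) == 0L) next
    todo <- is.na(ann)
    if (!any(todo)) break
    hit <- IRanges::overlapsAny(sites[todo], feats)
    ann[which(todo)[hit]] <- cl
  }
  rest <- is.na(ann)
  if (any(rest)) {
    in_gene <- IRanges::overlapsAny(sites[rest], model$genes)
    ann[which(rest)[in_gene]] <- "others"
    ann[which(rest)[!in_gene]] <- "intergenic"
  }
  sites$annotation <- ann
  sites
}

#' Annotate a single site
#'
#' Scalar convenience wrapper around [annotate_sites()].
#'
#' @param site a length-1 `GRanges`.
#' @param model an `AnnotationModel`.
#' @return the category label.
#' @export
annotate_site <- function(site, model) {
  stopifnot(length(site) == 1L)
  annotate_sites(site, model)$annotation
}
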
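# RBP group membership from the coefficient matrix H, and site-to-group
# association from the basis matrix W.

#' Scale a coefficient matrix by column to 0-1
#'
#' Each column (RBP) of `H` is divided by its maximum, so the scaled weight
#' expresses how strongly the RBP loads each group relative to its own
#' strongest group. All-zero columns are left at zero with a warning.
#'
#' @param H coefficient matrix (groups x RBPs) or an `NMFRun`.
#' @return a matrix of the same shape with column maxima 1 (or 0).
#' @export
scale_coefficients <- function(H) {
  if (inherits(H, "NMFRun")) H <- H$H
  if (any(H < 0)) stop("H must be non-negative")
  mx <- apply(H, 2L, max)
  zero <- mx == 0
  if (any(zero)) {
    warning("all-zero coefficient column(s): ",
            paste(colnames(H)[zero] %||% which(zero), collapse = ", "))
    mx[zero] <- 1
  }
  sweep(H, 2L, mx, "/")
}

#' Call group membership from scaled coefficients
#'
#' RBP j belongs to group r when its scaled coefficient exceeds `threshold`.
#' Because the clustering is soft, an RBP can be a member of several groups;
#' empty groups are kept (with no members). RBPs below threshold everywhere
#' are left unassigned with a warning.
#'
#' @param H_scaled column-scaled coefficient matrix (see
#'   [scale_coefficients()]).
#' @param threshold membership cutoff in (0, 1), exclusive (default 0.2).
#' @return an `rbp_groups` object: list of per-group data frames with
#'   columns `rbp_id`, `scaled_weight`.
#' @export
call_members <- function(H_scaled, threshold = 0.2) {
  .assert_scalar_number(threshold, "threshold", 0, 1,
                        strict_lower = TRUE, strict_upper = TRUE)
  R <- nrow(H_scaled)
  rbps <- colnames(H_scaled) %||% sprintf("rbp_%02d", seq_len(ncol(H_scaled)))
  groups <- lapply(seq_len(R), function(r) {
    in_r <- H_scaled[r, ] > threshold
    data.frame(rbp_id = rbps[in_r],
               scaled_weight = unname(H_scaled[r, in_r]))
  })
  names(groups) <- rownames(H_scaled) %||% paste0("group", seq_len(R))
  unassigned <- colSums(H_scaled > threshold) == 0
  if (any(unassigned))
    warning("RBP(s) below threshold in every group: ",
            paste(rbps[unassigned], collapse = ", "))
  structure(groups, class = "rbp_groups", threshold = threshold)
}

#' @export
print.rbp_groups <- function(x, ...) {
  cat(sprintf("<rbp_groups> %d groups (membership threshold %.2f)\n",
              length(x), attr(x, "threshold")))
  for (g in names(x))
    cat(sprintf("  %s: %s\n", g,
                if (nrow(x[[g]])) paste(x[[g]]$rbp_id, collapse = ", ")
                else "(empty)"))
  invisible(x)
}

#' @export
#' @method as.data.frame rbp_groups
as.data.frame.rbp_groups <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x), function(g)
    if (nrow(x[[g]])) cbind(group = g, x[[g]]) else NULL))
  if (is.null(out))
    out <- data.frame(group = character(0), rbp_id = character(0),
                      scaled_weight = numeric(0))
  rownames(out) <- NULL
  out
}

#' Entropy-based basis-specificity score of one site
#'
#' Normalizes the site's basis row to a probability vector `p` over the R
#' groups and returns `1 + (1/log2 R) * sum_r p_r log2 p_r` (with
#' `0 log 0 = 0`): 1 when the site loads a single group, 0 when it loads all
#' groups uniformly. Invariant to rescaling of the row.
#'
#' @param w_row non-negative basis row of length R >= 2, not all zero.
#' @return a number in \[0, 1\].
#' @export
kim_specificity <- function(w_row) {
  w_row <- as.numeric(w_row)
  R <- length(w_row)
  if (R < 2L) stop("specificity is undefined for a single group (R = 1)")
  if (any(w_row < 0)) stop("basis row must be non-negative")
  s <- sum(w_row)
  if (s == 0) stop("basis row is all zero")
  p <- w_row / s
  pos <- p > 0
  1 + sum(p[pos] * log2(p[pos])) / log2(R)
}

#' Associate binding sites to RBP groups
#'
#' A site is associated to group r when (i) its basis-specificity score
#' exceeds `spec_threshold` — it loads essentially one group, ruling out
#' unspecific high-abundance binding — and (ii) its basis coefficient
#' `W[i, r]` exceeds the `coeff_quantile` quantile of the strictly positive
#' entries of column r. All-zero basis rows cannot be associated and are
#' skipped.
#'
#' @param W basis matrix (sites x groups) or an `NMFRun`.
#' @param spec_threshold basis-specificity cutoff (default 0.8).
#' @param coeff_quantile per-column coefficient quantile (default 0.80).
#' @param site_ids site identifiers; defaults to `rownames(W)`.
#' @return a data frame with columns `site_id`, `group`,
#'   `basis_coefficient`, `specificity` (one row per passing site-group
#'   pair).
#' @export
associate_sites <- function(W, spec_threshold = 0.8, coeff_quantile = 0.80,
                            site_ids = NULL) {
  if (inherits(W, "NMFRun")) W <- W$W
  .assert_scalar_number(spec_threshold, "spec_threshold", 0, 1)
  .assert_scalar_number(coeff_quantile, "coeff_quantile", 0, 1,
                        strict_lower = TRUE)
  if (ncol(W) < 2L) stop("need at least two groups to score specificity")
  if (is.null(site_ids))
    site_ids <- rownames(W) %||% sprintf("site_%05d", seq_len(nrow(W)))
  groups <- colnames(W) %||% paste0("group", seq_len(ncol(W)))

  rs <- rowSums(W)
  spec <- rep(NA_real_, nrow(W))
  ok <- rs > 0
  spec[ok] <- apply(W[ok, , drop = FALSE], 1L, kim_specificity)

  qcol <- vapply(seq_len(ncol(W)), function(r)
    positive_quantile(W[, r], coeff_quantile), numeric(1))

  rows <- list()
  for (r in seq_len(ncol(W))) {
    if (is.na(qcol[r])) next
    hit <- which(ok & spec > spec_threshold & W[, r] > qcol[r])
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = site_ids[hit], group = groups[r],
        basis_coefficient = unname(W[hit, r]),
        specificity = unname(spec[hit]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(0), group = character(0),
               basis_coefficient = numeric(0), specificity = numeric(0))
  out <- out[order(out$group, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write group membership and site associations as TSV
#'
#' @param groups an `rbp_groups` object.
#' @param associations data frame from [associate_sites()].
#' @param groups_path,assoc_path output paths.
#' @return invisibly, the two paths.
#' @export
write_group_tables <- function(groups, associations, groups_path,
                               assoc_path) {
  utils::write.table(as.data.frame(groups), groups_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(associations, assoc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(groups_path, assoc_path))
}
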
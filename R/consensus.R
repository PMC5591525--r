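# Consensus clustering diagnostics over repeated NMF runs, used to choose
# the factorization rank (the number of RBP groups).

#' Connectivity matrix of one factorization
#'
#' Each RBP (column of `H`) is hard-assigned to the group with its largest
#' coefficient (ties go to the smallest group index); `C_k(i, j) = 1` when
#' RBPs i and j land in the same group.
#'
#' @param H coefficient matrix (rank x RBPs) of one run, or an `NMFRun`.
#' @return a symmetric binary M x M matrix with unit diagonal.
#' @export
connectivity_matrix <- function(H) {
  if (inherits(H, "NMFRun")) H <- H$H
  assign <- apply(H, 2L, which.max) # which.max returns the first maximum
  Ck <- outer(assign, assign, "==") * 1
  dimnames(Ck) <- list(colnames(H), colnames(H))
  Ck
}

#' Consensus matrix over multiple factorization runs
#'
#' Elementwise mean of the runs' connectivity matrices: `C(i, j)` is the
#' fraction of runs in which RBPs i and j co-cluster.
#'
#' @param runs list of `NMFRun`s with identical rank and RBP set.
#' @return a symmetric M x M matrix with entries in \[0, 1\] and unit
#'   diagonal.
#' @export
consensus_matrix <- function(runs) {
  if (length(runs) == 0L) stop("`runs` must be non-empty")
  M <- ncol(runs[[1L]]$H)
  R <- runs[[1L]]$rank
  for (r in runs)
    if (ncol(r$H) != M || r$rank != R)
      stop("all runs must share the same rank and number of RBPs")
  Reduce(`+`, lapply(runs, connectivity_matrix)) / length(runs)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Measures how faithfully average-linkage hierarchical clustering of the
#' consensus dissimilarities `D = 1 - C` preserves them: the Pearson
#' correlation between the upper triangles of `D` and the dendrogram's
#' cophenetic distance matrix. 1 indicates perfectly stable clustering.
#' When either distance vector is constant (e.g. a perfect consensus) the
#' correlation is undefined and 1 is returned: the clustering is maximally
#' stable.
#'
#' @param C consensus matrix, M >= 3.
#' @return a number in \[-1, 1\].
#' @export
cophenetic_cc <- function(C) {
  M <- nrow(C)
  if (M < 3L) stop("cophenetic correlation needs M >= 3")
  D <- 1 - C
  diag(D) <- 0
  d <- stats::as.dist(D)
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(coph) == 0) return(1.0)
  stats::cor(as.vector(d), as.vector(coph))
}

#' Dispersion coefficient of a consensus matrix
#'
#' `(1 / M^2) * sum_ij 4 (C(i,j) - 1/2)^2`: how far entries sit from the
#' maximally unstable value 0.5, normalized so a perfect 0/1 consensus
#' scores 1.
#'
#' @param C consensus matrix.
#' @return a number in \[0, 1\].
#' @export
dispersion <- function(C) {
  mean(4 * (C - 0.5)^2)
}

#' Scan factorization ranks with consensus diagnostics
#'
#' For every rank and every run count in `runs_schedule`, factorizes `V`
#' that many times from distinct seeds, builds the consensus matrix, and
#' records its cophenetic correlation (CPCC) and dispersion (DC). Per-rank
#' means across the schedule are summarized, and ranks that are local maxima
#' of mean CPCC or mean DC along the rank axis are flagged as candidate
#' numbers of groups ("local maximum" = strictly greater than both
#' neighbors; endpoints compare against their single neighbor).
#'
#' @param V occupancy matrix (or any non-negative matrix).
#' @param ranks integer ranks to scan (default 5:20); ranks exceeding
#'   `min(dim(V))` are dropped with a warning.
#' @param runs_schedule run counts per rank (default `c(10, 30, 50, 80,
#'   100)`).
#' @param base_seed first seed; every factorization gets a distinct
#'   deterministic seed derived from it.
#' @param max_iter,tol passed to [factorize()].
#' @param keep_consensus keep each rank's consensus matrices in the result.
#' @return a `rank_scan` object: list with `stats` (one row per rank x
#'   schedule entry), `summary` (per-rank means/min/max and local-maximum
#'   flags), `candidates` (ranks flagged for either diagnostic), and
#'   optionally `consensus`.
#' @export
rank_scan <- function(V, ranks = 5:20, runs_schedule = c(10, 30, 50, 80, 100),
                      base_seed = 1L, max_iter = 2000L, tol = 1e-5,
                      keep_consensus = FALSE) {
  V <- as.matrix(V)
  ranks <- sort(unique(as.integer(ranks)))
  ok <- ranks <= min(dim(V))
  if (!all(ok)) {
    warning("dropping ranks above min(dim(V)) = ", min(dim(V)))
    ranks <- ranks[ok]
  }
  if (length(ranks) == 0L) stop("no feasible rank to scan")

  stats_rows <- list()
  consensus <- list()
  offset <- 0L
  for (R in ranks) {
    cons_R <- list()
    for (n in runs_schedule) {
      seeds <- .wrap_seed(base_seed + offset + seq_len(n) - 1L)
      offset <- offset + n
      runs <- lapply(seeds, function(s)
        factorize(V, R, seed = s, max_iter = max_iter, tol = tol))
      C <- consensus_matrix(runs)
      cons_R[[as.character(n)]] <- C
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        rank = R, n_runs = n, cpcc = cophenetic_cc(C), dc = dispersion(C))
    }
    if (keep_consensus) consensus[[as.character(R)]] <- cons_R
  }
  stats <- do.call(rbind, stats_rows)

  summ <- do.call(rbind, lapply(ranks, function(R) {
    s <- stats[stats$rank == R, ]
    data.frame(rank = R,
               cpcc_mean = mean(s$cpcc), cpcc_min = min(s$cpcc),
               cpcc_max = max(s$cpcc),
               dc_mean = mean(s$dc), dc_min = min(s$dc), dc_max = max(s$dc))
  }))
  summ$cpcc_local_max <- .local_maxima(summ$cpcc_mean)
  summ$dc_local_max <- .local_maxima(summ$dc_mean)

  structure(list(
    stats = stats, summary = summ,
    candidates = sort(unique(summ$rank[summ$cpcc_local_max |
                                         summ$dc_local_max])),
    consensus = if (keep_consensus) consensus else NULL,
    base_seed = as.integer(base_seed), runs_schedule = runs_schedule
  ), class = "rank_scan")
}

# strictly-greater local maxima; endpoints qualify against their one
# neighbor; a single point is trivially a maximum
.local_maxima <- function(x) {
  n <- length(x)
  if (n == 1L) return(TRUE)
  left <- c(Inf * -1, x[-n])
  right <- c(x[-1L], -Inf)
  x > left & x > right
}

#' @export
print.rank_scan <- function(x, ...) {
  cat("<rank_scan>\n")
  print(x$summary, row.names = FALSE)
  cat("candidate ranks:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Write a rank-scan report as TSV
#'
#' @param scan a `rank_scan` object.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_rank_scan_tsv <- function(scan, path) {
  utils::write.table(scan$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Best factorization at a fixed rank
#'
#' Runs [factorize()] with seeds `base_seed .. base_seed + n_runs - 1` and
#' returns the run with the smallest KL error (ties: smallest seed).
#'
#' @param V non-negative matrix.
#' @param R rank.
#' @param n_runs number of restarts (default 100).
#' @param base_seed first seed.
#' @param max_iter,tol passed to [factorize()].
#' @return the best `NMFRun`.
#' @export
best_run <- function(V, R, n_runs = 100L, base_seed = 1L,
                     max_iter = 2000L, tol = 1e-5) {
  best <- NULL
  for (k in seq_len(n_runs)) {
    run <- factorize(V, R, seed = .wrap_seed(base_seed + k - 1L),
                     max_iter = max_iter, tol = tol)
    if (is.null(best) || run$kl_error < best$kl_error) best <- run
  }
  best
}
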
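# Kullback-Leibler non-negative matrix factorization, V ~ W H.

#' Generalized Kullback-Leibler divergence between V and W H
#'
#' `sum_ij [ V_ij log(V_ij / (WH)_ij) - V_ij + (WH)_ij ]` with the convention
#' `0 log 0 = 0`. Entries where `(WH)_ij = 0` but `V_ij > 0` make the
#' divergence infinite.
#'
#' @param V non-negative data matrix (sites x RBPs).
#' @param W non-negative basis matrix (sites x rank).
#' @param H non-negative coefficient matrix (rank x RBPs).
#' @return a non-negative number (possibly `Inf`).
#' @export
kl_divergence <- function(V, W, H) {
  if (any(V < 0) || any(W < 0) || any(H < 0))
    stop("V, W, H must be non-negative")
  WH <- W %*% H
  if (nrow(WH) != nrow(V) || ncol(WH) != ncol(V))
    stop("non-conformant shapes")
  if (any(WH == 0 & V > 0)) return(Inf)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' Factorize a non-negative matrix under the KL objective
#'
#' Standard multiplicative updates
#' (`H <- H * (W'(V/WH)) / (W'1)`, `W <- W * ((V/WH)H') / (1H')`) from a
#' seeded strictly positive uniform initialization. Iteration stops when the
#' relative decrease of the objective falls below `tol` or after `max_iter`
#' updates. The same `(V, R, seed)` always yields the same result.
#'
#' @param V non-negative matrix with no all-zero row or column.
#' @param R factorization rank, `R <= min(dim(V))`.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of update sweeps (default 2000).
#' @param tol relative objective-decrease convergence threshold
#'   (default 1e-5).
#' @param track_objective record the objective after every sweep (for
#'   diagnostics; slightly larger result object).
#' @return an `NMFRun`: list with `W`, `H`, `rank`, `seed`, `kl_error`,
#'   `n_iter`, `converged`, and `objective_trace` (`NULL` unless tracked).
#' @export
factorize <- function(V, R, seed, max_iter = 2000L, tol = 1e-5,
                      track_objective = FALSE) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  R <- as.integer(R)
  if (R < 1L || R > min(dim(V)))
    stop(sprintf("rank R = %d must be in 1..min(N, M) = %d", R, min(dim(V))))
  init <- with_seed(seed, list(
    W = matrix(stats::runif(nrow(V) * R, 1e-6, 1), nrow(V), R),
    H = matrix(stats::runif(R * ncol(V), 1e-6, 1), R, ncol(V))
  ))
  fit <- nmf_kl_cpp(V, init$W, init$H, as.integer(max_iter), tol,
                    track_objective)
  dimnames(fit$W) <- list(rownames(V), paste0("group", seq_len(R)))
  dimnames(fit$H) <- list(paste0("group", seq_len(R)), colnames(V))
  structure(list(W = fit$W, H = fit$H, rank = R, seed = as.integer(seed),
                 kl_error = fit$kl_error, n_iter = fit$n_iter,
                 converged = fit$converged,
                 objective_trace = fit$objective_trace),
            class = "NMFRun")
}

#' @export
print.NMFRun <- function(x, ...) {
  cat(sprintf(
    "<NMFRun> rank %d, seed %d: KL = %.6g after %d iterations (%s)\n",
    x$rank, x$seed, x$kl_error, x$n_iter,
    if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Write an NMF run to disk
#'
#' `W` and `H` as TSV (with site/RBP/group headers), run metadata as JSON.
#'
#' @param run an `NMFRun`.
#' @param prefix output path prefix; writes `<prefix>_W.tsv`,
#'   `<prefix>_H.tsv`, `<prefix>_run.json`.
#' @return the metadata path, invisibly.
#' @export
write_nmf_run <- function(run, prefix) {
  utils::write.table(data.frame(site_id = rownames(run$W), run$W,
                                check.names = FALSE),
                     paste0(prefix, "_W.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(group = rownames(run$H), run$H,
                                check.names = FALSE),
                     paste0(prefix, "_H.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- paste0(prefix, "_run.json")
  jsonlite::write_json(list(rank = run$rank, seed = run$seed,
                            kl_error = run$kl_error, n_iter = run$n_iter,
                            converged = run$converged),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(meta)
}
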
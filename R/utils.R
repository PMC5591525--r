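#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals do not perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Keep derived seeds within the 32-bit integer range R accepts.
.wrap_seed <- function(x) as.integer(x %% 2147483647)

#' Quantile of the strictly positive entries of a vector
#'
#' Linear-interpolation (type 7) quantile computed over `x[x > 0]` only.
#' Zeros are excluded so that sparse columns do not deflate the scaling
#' quantile.
#'
#' @param x numeric vector.
#' @param probs quantile level in (0, 1].
#' @return the quantile, or `NA_real_` when no entry is positive.
#' @keywords internal
#' @noRd
positive_quantile <- function(x, probs) {
  pos <- x[x > 0]
  if (length(pos) == 0L) return(NA_real_)
  unname(stats::quantile(pos, probs = probs, type = 7, names = FALSE))
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name))
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("`%s` = %s is outside its allowed domain", name, format(x)))
  invisible(x)
}
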
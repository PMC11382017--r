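#' Pearson product-moment correlation with explicit degeneracy signaling
#'
#' Standard Pearson correlation between two equal-length vectors. Unlike
#' [stats::cor()], degenerate inputs (length < 3 or zero variance in either
#' vector) are signaled distinctly by returning `NA_real_` rather than raising
#' a condition, so cross-validation summaries can count and exclude undefined
#' folds.
#'
#' @param a,b numeric vectors of equal length.
#' @return A single numeric value in \[-1, 1\], or `NA_real_` when undefined.
#' @export
#' @examples
#' pearson(1:10, 2 * (1:10) + 3) # 1
pearson <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) return(NA_real_)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) return(NA_real_)
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  mean((a - mean(a)) * (b - mean(b))) * length(a) / (length(a) - 1) / (sa * sb)
}

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's RNG state afterwards so library calls do not perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a stream-specific 31-bit sub-seed from a base seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 19991L + as.integer(stream) * 7919L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
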
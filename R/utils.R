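#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; keeps results independent across
# stages/resamples while remaining a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single non-negative integer", name),
         call. = FALSE)
  }
}

# Sample (n-1)-denominator relative standard deviation, in percent.

#' Relative standard deviation of replicate peak areas
#'
#' Computes `100 * sd(x) / mean(x)` with the sample (n-1) standard
#' deviation, the reproducibility metric used to assess pooled-QC replicate
#' precision (tolerances of 20% for UPLC-MS and 30% for GC-MS are the usual
#' guidelines).
#'
#' @param values numeric vector of peak areas; `NA`s are dropped.
#' @return RSD in percent (scalar).
#' @examples
#' compute_rsd(c(8, 10, 12))  # 20
#' @export
compute_rsd <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L)
    stop("RSD requires at least 2 non-missing replicate values", call. = FALSE)
  m <- mean(v)
  if (m == 0) stop("RSD undefined for zero-mean values", call. = FALSE)
  100 * stats::sd(v) / m
}
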
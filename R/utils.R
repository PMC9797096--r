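# Internal helpers shared across modules.

Z_CLIP <- 38

#' Convert t statistics to Z scores
#'
#' Maps Student-t statistics to standard-normal quantiles through the tail
#' probability, working in log space so that extreme t values do not saturate
#' before the clip.
#'
#' @param t numeric vector/matrix of t statistics.
#' @param df residual degrees of freedom.
#' @param clip absolute clipping bound for the returned Z values.
#' @return numeric object of the same shape as `t`.
#' @keywords internal
t_to_z <- function(t, df, clip = Z_CLIP) {
  z <- t
  neg <- !is.na(t) & t < 0
  # lower tail for negative t, upper tail for positive: both stay small in log
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(t[!neg], df, lower.tail = FALSE,
                                     log.p = TRUE), log.p = TRUE)
  pmin(pmax(z, -clip), clip)
}

# Sample skewness (biased, moment definition): m3 / m2^(3/2).
skewness <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^3) / m2^1.5
}

# Demean columns of a matrix.
demean_cols <- function(x) sweep(x, 2L, colMeans(x), "-")

# Scale columns to unit SD (denominator n-1); zero-variance columns left at 0.
scale_cols <- function(x) {
  s <- apply(x, 2L, stats::sd)
  s[s == 0] <- 1
  sweep(x, 2L, s, "/")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
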
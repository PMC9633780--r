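# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn inform
NULL

# z-score a numeric vector; constant vectors map to 0 rather than NaN.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# column-wise standardisation using externally supplied statistics
scale_by <- function(X, center, scale) {
  scale[scale == 0 | !is.finite(scale)] <- 1
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  sqrt((colSums(X^2) - n * mu^2) / (n - 1))
}

# Longest contiguous run of TRUE, returned as number of elements.
longest_run <- function(mask) {
  if (!any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

# All contiguous runs of TRUE as a two-column matrix of start/end indices.
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Seed scoping: evaluate expr with a local RNG seeded by `seed` (if non-NULL),
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(seed, expr)
}

# Derive a bounded child seed from a master seed and a counter, keeping the
# result well inside 32-bit integer range.
child_seed <- function(seed, counter) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + counter) %% 2147483587L)
}

# Truncated normal sampler by rejection (lower truncation only).
rtnorm_lower <- function(n, mean, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)), mean, sd)
    out <- c(out, x[x > lower])
  }
  out[seq_len(n)]
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive scalar", name))
  }
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
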
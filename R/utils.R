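## Internal helpers shared across modules.

# Deterministic child-seed derivation: a fixed Lehmer-style mix of the master
# seed and a stream counter.  Streams are allocated so that adding a subject
# (or ROI) never changes the seed handed to earlier ones.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647  # 2^31 - 1, keeps set.seed() input in integer range
  x <- (abs(as.numeric(seed)) %% m) + 1
  x <- (x * 48271 + as.numeric(stream) * 69621) %% m
  as.integer(x)
}

# Run an expression under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "voxelencode_invalid_config")
  }
  as.integer(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "voxelencode_invalid_config")
  }
  as.numeric(x)
}

# Pearson correlation that maps zero-variance inputs to 0 (with an optional
# warning) instead of NA; the degenerate case carries no predictive signal.
safe_cor <- function(x, y, warn_degenerate = FALSE) {
  sx <- sd(x)
  sy <- sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    if (warn_degenerate) {
      warn("Zero-variance input to correlation; returning 0.")
    }
    return(0)
  }
  as.numeric(cor(x, y))
}

# Column-wise Pearson correlation between paired columns of two matrices.
col_cor <- function(A, B) {
  n <- nrow(A)
  ma <- colMeans(A)
  mb <- colMeans(B)
  sab <- colMeans(A * B) - ma * mb
  sa <- colMeans(A * A) - ma^2
  sb <- colMeans(B * B) - mb^2
  out <- sab / sqrt(sa * sb)
  out[!is.finite(out)] <- 0
  out
}

# Higher nearest-rank empirical quantile: the ceiling(q * n)-th order
# statistic.  Conservative and exactly reproducible.
nearest_rank_quantile <- function(x, q) {
  stopifnot(length(x) >= 1L, q > 0, q <= 1)
  xs <- sort(x)
  xs[max(1L, ceiling(q * length(xs)))]
}
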
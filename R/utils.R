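# Internal helpers shared across modules.

#' @importFrom stats cor sd rnorm runif quantile pt p.adjust dgamma acf
#' @importFrom utils head tail write.table read.delim
NULL

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_int <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_invalid("`%s` must be a single integer", name)
  if (x < min) stop_invalid("`%s` must be >= %s", name, format(min))
  as.integer(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid("`%s` must be a numeric matrix", name)
  if (any(!is.finite(x)))
    stop_invalid("`%s` contains non-finite values", name)
  x
}

# Spearman rank correlation; complete observations.
spearman <- function(x, y) stats::cor(x, y, method = "spearman")

# Rank-normalize to [0, 1]; ties averaged.
rank01 <- function(x) {
  n <- length(x)
  if (n == 1L) return(0.5)
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

# Column demeaning without dropping attributes we care about.
demean_cols <- function(x) sweep(x, 2L, colMeans(x), "-")

# OLS residuals of `y` (matrix) on `x` plus an intercept. lm.fit handles
# rank deficiency through pivoted QR; residuals are the unique projection
# complement regardless of which basis columns are kept.
ols_residuals <- function(y, x) {
  X <- cbind(`(intercept)` = 1, x)
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1L)
  res
}

# Derive a stream-specific sub-seed from a user seed; stays inside the 32-bit
# signed-integer range R requires of set.seed().
sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}

# Dependency-free content fingerprint used for output provenance records.
# Numeric payloads are reduced to a deterministic moment/stripe summary and a
# polynomial hash is taken over its bytes; fast even for large matrices, and
# stable across sessions for identical content. Not cryptographic.
content_hash <- function(x) {
  summarize <- function(v) {
    v <- as.double(v)
    stripe <- v[seq(1L, length(v), length.out = min(64L, length(v)))]
    c(length(v), sum(v), sum(v^2), stripe)
  }
  payload <- if (is.numeric(x)) c(dim(x), summarize(x)) else
    utils::head(as.double(serialize(x, NULL, version = 2L)), 8192L)
  bytes <- as.double(serialize(signif(payload, 12), NULL, version = 2L))
  mod <- 2^31 - 1
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% mod
  sprintf("poly257:%010.0f", h)
}
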
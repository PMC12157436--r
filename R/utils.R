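# Internal numerical helpers shared across modules.

# log(1 - exp(-u)) computed stably for u >= 0; returns -Inf at u = 0.
log1mexp <- function(u) {
  out <- numeric(length(u))
  small <- u <= log(2)
  # for small u, -expm1(-u) loses no precision; for large u, exp(-u) underflows first
  out[small] <- log(-expm1(-u[small]))
  out[!small] <- log1p(-exp(-u[!small]))
  out
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

.is_scalar <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# Batch-means standard error of the mean for a (possibly autocorrelated) chain.
batch_means_se <- function(x, n_batches = 50L) {
  n <- length(x)
  .assert(n >= 2L * n_batches, "chain too short for batch means")
  b <- n %/% n_batches
  m <- matrix(x[seq_len(b * n_batches)], nrow = b)
  bm <- colMeans(m)
  sqrt(stats::var(bm) / n_batches)
}
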
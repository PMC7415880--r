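# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rbinom rnbinom var median sd cor dnorm
#'   kmeans dist quantile setNames
#' @importFrom utils read.delim write.table head modifyList
NULL

# log(sum(exp(x))) along rows of a matrix, numerically stable
.row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

.logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert_count_vector <- function(x, what = "x") {
  if (!is.numeric(x) || any(!is.finite(x)))
    .stopf("%s must be finite numeric", what)
  if (any(x < 0) || any(x != floor(x)))
    .stopf("%s must contain non-negative integers", what)
  invisible(x)
}

# Derive a stream-specific seed from a base seed so that independent
# random draws (split, masking, init, shuffling) do not collide.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}
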
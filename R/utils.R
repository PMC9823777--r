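# shared small helpers

# Probabilities are kept strictly inside (0,1) so the Bernoulli log-likelihood
# and its gradient stay finite. The bound is a documented package constant.
.PROB_EPS <- 1e-6

clipProb <- function(p) pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)

# one-hot encode 0-based labels into an N x K matrix
oneHot <- function(labels, nClasses) {
  m <- matrix(0, length(labels), nClasses)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

# derive a child seed that stays inside 32-bit integer range
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}

# largest-remainder apportionment of n into parts proportional to `ratio`
largestRemainder <- function(n, ratio) {
  q <- n * ratio / sum(ratio)
  fl <- floor(q)
  rem <- as.integer(n - sum(fl))
  if (rem > 0L) {
    extra <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1L
  }
  as.integer(fl)
}

# stacked-matrix view of an N x W x C signal array: (N*W) x C, sample-major
stackSignals <- function(signals) {
  d <- dim(signals)
  matrix(aperm(signals, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
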
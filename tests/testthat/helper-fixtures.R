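# shared fixture builders; everything is generated in code at test time

tinySpec <- function(seed = 1L, nPerClass = 8L, windowLen = 16L,
                     nChannels = 3L, noiseSd = 0.3) {
  syntheticSpec(
    nClasses = 3L, nPerClass = nPerClass, windowLen = windowLen,
    nChannels = nChannels, noiseSd = noiseSd, seed = seed
  )
}

tinyDataset <- function(seed = 1L, ...) {
  normalizeDataset(generateDataset(tinySpec(seed = seed, ...)))
}

# central finite-difference gradient of scalar fn at x (vector), elementwise
numGrad <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x
    xm <- x
    xp[j] <- x[j] + h
    xm[j] <- x[j] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}
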
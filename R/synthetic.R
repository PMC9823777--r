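#' Specification of a synthetic HAR-like dataset
#'
#' Describes a synthetic multichannel activity-recognition dataset: `nClasses`
#' activity classes, `nPerClass` windows each, `windowLen` timesteps over
#' `nChannels` channels (an IMU contributes six: 3-axis accelerometer plus
#' 3-axis gyroscope), with additive Gaussian sensor noise of standard
#' deviation `noiseSd` on top of unit-order class signatures.
#'
#' @param nClasses integer >= 2, number of activity classes.
#' @param nPerClass integer >= 1, windows generated per class.
#' @param windowLen integer >= 8, timesteps per window.
#' @param nChannels integer >= 1, signal channels.
#' @param noiseSd numeric >= 0, sd of the additive Gaussian noise. The class
#'   signatures have amplitudes of order 1, so the default 0.5 gives clearly
#'   separable but non-trivial classes.
#' @param seed integer seed; identical spec + seed reproduce the dataset
#'   bit-for-bit.
#' @return a validated list of class `"syntheticSpec"`.
#' @examples
#' sp <- syntheticSpec(nClasses = 3, nPerClass = 10, windowLen = 32)
#' @export
syntheticSpec <- function(nClasses = 3L, nPerClass = 90L, windowLen = 64L,
                          nChannels = 6L, noiseSd = 0.5, seed = 1L) {
  nClasses <- as.integer(nClasses)
  nPerClass <- as.integer(nPerClass)
  windowLen <- as.integer(windowLen)
  nChannels <- as.integer(nChannels)
  if (is.na(nClasses) || nClasses < 2L) stop("nClasses must be >= 2")
  if (is.na(nPerClass) || nPerClass < 1L) stop("nPerClass must be >= 1")
  if (is.na(windowLen) || windowLen < 8L) stop("windowLen must be >= 8")
  if (is.na(nChannels) || nChannels < 1L) stop("nChannels must be >= 1")
  if (!is.finite(noiseSd) || noiseSd < 0) stop("noiseSd must be >= 0")
  structure(
    list(
      nClasses = nClasses, nPerClass = nPerClass, windowLen = windowLen,
      nChannels = nChannels, noiseSd = noiseSd, seed = as.integer(seed)
    ),
    class = "syntheticSpec"
  )
}

# Deterministic per-class/channel signature constants. Classes differ in base
# frequency (k+1 cycles per window); channels differ in amplitude, phase and a
# small class-specific DC offset, so no single channel is sufficient on its
# own but the joint signature is unambiguous.
signatureParams <- function(nClasses, nChannels) {
  k <- rep(seq_len(nClasses) - 1L, each = nChannels)
  c0 <- rep(seq_len(nChannels) - 1L, times = nClasses)
  list(
    freq = matrix(k + 1, nClasses, nChannels, byrow = FALSE),
    amp = matrix(0.6 + 0.5 * ((k * 3 + c0) %% 5) / 4, nClasses, nChannels),
    phase = matrix(2 * pi * c0 / nChannels + pi * k / nClasses,
      nClasses, nChannels),
    dc = matrix(0.2 * ((k + c0) %% 3 - 1), nClasses, nChannels)
  )
}

#' Generate a synthetic HAR-like windowed dataset
#'
#' Each class carries a deterministic multichannel signature — a sinusoid of
#' class-specific frequency with channel-specific amplitude, phase and DC
#' offset — plus zero-mean Gaussian noise. Windows are assigned to
#' train/validation/test splits in a 4:2:3 ratio by seeded shuffling, with
#' split sizes apportioned by largest remainder (they always sum to N).
#'
#' @param spec a [syntheticSpec()].
#' @return a [WindowedDataset-class].
#' @examples
#' ds <- generateDataset(syntheticSpec(nClasses = 3, nPerClass = 9))
#' table(splits(ds))
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed)
  K <- spec$nClasses
  N <- K * spec$nPerClass
  W <- spec$windowLen
  C <- spec$nChannels
  pars <- signatureParams(K, C)
  tgrid <- seq_len(W) / W
  labels <- rep(seq_len(K) - 1L, each = spec$nPerClass)
  sig <- array(0, c(N, W, C))
  for (i in seq_len(N)) {
    k <- labels[i] + 1L
    for (c0 in seq_len(C)) {
      sig[i, , c0] <- pars$dc[k, c0] + pars$amp[k, c0] *
        sin(2 * pi * pars$freq[k, c0] * tgrid + pars$phase[k, c0])
    }
  }
  if (spec$noiseSd > 0) {
    sig <- sig + array(stats::rnorm(N * W * C, sd = spec$noiseSd), c(N, W, C))
  }
  counts <- largestRemainder(N, c(4, 2, 3))
  tags <- rep(c("train", "validation", "test"), counts)
  split <- tags[sample.int(N)] # seeded shuffle of split assignment
  methods::new("WindowedDataset",
    signals = sig, labels = labels, split = split,
    nClasses = K, channelStats = data.frame()
  )
}

#' Inject seeded label corruption into the training split
#'
#' Flips the labels of `round(rate * N_train)` uniformly chosen training
#' windows to a uniformly drawn *different* class, emulating annotation noise.
#' Validation and test labels are never touched. The returned record stores
#' the flipped indices and original labels — the ground truth against which
#' corrupted-sample discovery is scored.
#'
#' @param ds a [WindowedDataset-class] with a non-empty training split.
#' @param rate numeric in `[0, 1]`; the study condition is 0.2.
#' @param seed integer seed for the corruption draw.
#' @return a list with elements `dataset` (corrupted copy) and `record`
#'   (a [CorruptionRecord-class]).
#' @examples
#' ds <- generateDataset(syntheticSpec(nPerClass = 15))
#' cr <- corruptLabels(ds, rate = 0.2, seed = 7)
#' length(corruptedIndices(cr$record))
#' @export
corruptLabels <- function(ds, rate = 0.2, seed = 1L) {
  stopifnot(is(ds, "WindowedDataset"))
  if (!is.finite(rate) || rate < 0 || rate > 1) stop("rate must be in [0,1]")
  K <- ds@nClasses
  if (K < 2L) stop("label corruption needs at least 2 classes")
  trainIdx <- which(ds@split == "train")
  if (!length(trainIdx)) stop("training split is empty")
  nFlip <- round(rate * length(trainIdx))
  set.seed(as.integer(seed))
  if (nFlip == 0L) {
    rec <- methods::new("CorruptionRecord",
      indices = integer(), originalLabels = integer(),
      rate = rate, seed = as.integer(seed)
    )
    return(list(dataset = ds, record = rec))
  }
  flip <- sort(sample(trainIdx, nFlip))
  labels <- ds@labels
  orig <- labels[flip]
  # uniform draw over the K-1 other classes
  newLab <- vapply(orig, function(y) {
    alt <- setdiff(seq_len(K) - 1L, y)
    if (length(alt) == 1L) alt else sample(alt, 1L)
  }, integer(1))
  labels[flip] <- newLab
  out <- ds
  out@labels <- labels
  methods::validObject(out)
  rec <- methods::new("CorruptionRecord",
    indices = as.integer(flip), originalLabels = as.integer(orig),
    rate = rate, seed = as.integer(seed)
  )
  list(dataset = out, record = rec)
}
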
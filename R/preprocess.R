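#' Sliding-window configuration
#'
#' Standard HAR windowing: fixed window length with fractional overlap.
#' Common configurations are window 128 at 50% overlap (smartphone IMU at
#' 50 Hz), window 80 at 50% (20 Hz accelerometer) and window 100 at 50%
#' (100 Hz body-worn IMUs).
#'
#' @param windowLen positive integer, timesteps per window.
#' @param overlapFraction numeric in `[0, 1)`; stride is
#'   `round(windowLen * (1 - overlapFraction))` and must be >= 1.
#' @param padTo optional positive integer: recordings shorter than
#'   `windowLen` are zero-padded to this length instead of erroring.
#' @return a validated list of class `"windowingConfig"`.
#' @export
windowingConfig <- function(windowLen = 128L, overlapFraction = 0.5,
                            padTo = NULL) {
  windowLen <- as.integer(windowLen)
  if (is.na(windowLen) || windowLen < 1L) stop("windowLen must be positive")
  if (!is.finite(overlapFraction) || overlapFraction < 0 || overlapFraction >= 1) {
    stop("overlapFraction must be in [0,1)")
  }
  stride <- as.integer(round(windowLen * (1 - overlapFraction)))
  if (stride < 1L) stop("stride rounds to zero; reduce overlapFraction")
  if (!is.null(padTo)) {
    padTo <- as.integer(padTo)
    if (is.na(padTo) || padTo < windowLen) stop("padTo must be >= windowLen")
  }
  structure(
    list(
      windowLen = windowLen, overlapFraction = overlapFraction,
      stride = stride, padTo = padTo
    ),
    class = "windowingConfig"
  )
}

#' Cut a continuous recording into overlapping windows
#'
#' Windows start at positions `0, stride, 2*stride, ...`; the count is
#' `floor((L - W) / stride) + 1`. Each window's label is the majority label of
#' its timesteps, with ties broken by the label at the window midpoint.
#'
#' @param series numeric matrix `L x C` (timesteps by channels).
#' @param labelsPerTimestep integer vector of length `L` (0-based labels).
#' @param cfg a [windowingConfig()].
#' @return a list with `windows` (array `n x W x C`) and `labels` (integer).
#' @examples
#' x <- matrix(rnorm(256 * 3), 256, 3)
#' lab <- rep(0L, 256)
#' out <- slideWindows(x, lab, windowingConfig(128, 0.5))
#' dim(out$windows) # 3 windows
#' @export
slideWindows <- function(series, labelsPerTimestep, cfg) {
  stopifnot(inherits(cfg, "windowingConfig"), is.matrix(series))
  L <- nrow(series)
  W <- cfg$windowLen
  if (length(labelsPerTimestep) != L) {
    stop("labelsPerTimestep must have one label per timestep")
  }
  if (L < W) {
    if (is.null(cfg$padTo)) {
      stop("recording shorter than the window length (set padTo to zero-pad)")
    }
    series <- zeroPad(series, cfg$padTo)
    labelsPerTimestep <- c(
      labelsPerTimestep,
      rep(labelsPerTimestep[L], cfg$padTo - L)
    )
    L <- cfg$padTo
  }
  stride <- cfg$stride
  n <- (L - W) %/% stride + 1L
  starts <- (seq_len(n) - 1L) * stride
  windows <- array(0, c(n, W, ncol(series)))
  labels <- integer(n)
  for (i in seq_len(n)) {
    rows <- (starts[i] + 1L):(starts[i] + W)
    windows[i, , ] <- series[rows, , drop = FALSE]
    lab <- labelsPerTimestep[rows]
    tb <- table(lab)
    top <- names(tb)[tb == max(tb)]
    if (length(top) == 1L) {
      labels[i] <- as.integer(top)
    } else {
      labels[i] <- lab[(W + 1L) %/% 2L] # midpoint tie-break
    }
  }
  list(windows = windows, labels = labels, starts = starts)
}

#' Zero-pad a window to a target length
#'
#' @param window numeric matrix `L x C`.
#' @param targetLen integer >= `L`.
#' @return a `targetLen x C` matrix with zeros appended.
#' @export
zeroPad <- function(window, targetLen) {
  stopifnot(is.matrix(window))
  targetLen <- as.integer(targetLen)
  L <- nrow(window)
  if (L > targetLen) stop("window longer than targetLen; refusing to truncate")
  if (L == targetLen) return(window)
  rbind(window, matrix(0, targetLen - L, ncol(window)))
}

#' Per-channel z-score normalisation using training-split statistics
#'
#' Channel means and standard deviations are computed on the training split
#' only and applied verbatim to every split, so no information leaks from
#' validation or test data. A zero-variance channel keeps sd 1 (with a
#' warning), which maps a constant channel to all zeros.
#'
#' @param ds a [WindowedDataset-class] with a non-empty training split.
#' @return the normalised dataset, with `channelStats` filled in.
#' @export
normalizeDataset <- function(ds) {
  stopifnot(is(ds, "WindowedDataset"))
  trainIdx <- which(ds@split == "train")
  if (!length(trainIdx)) stop("training split is empty")
  C <- dim(ds@signals)[3L]
  mu <- numeric(C)
  sd_ <- numeric(C)
  for (c0 in seq_len(C)) {
    x <- ds@signals[trainIdx, , c0]
    mu[c0] <- mean(x)
    s <- stats::sd(as.vector(x))
    if (!is.finite(s) || s == 0) {
      warning(sprintf("channel %d has zero variance; sd set to 1", c0))
      s <- 1
    }
    sd_[c0] <- s
  }
  out <- ds
  for (c0 in seq_len(C)) {
    out@signals[, , c0] <- (ds@signals[, , c0] - mu[c0]) / sd_[c0]
  }
  out@channelStats <- data.frame(mean = mu, sd = sd_)
  methods::validObject(out)
  out
}

#' Apply previously stored normalisation statistics
#'
#' Applies `(x - mean) / sd` per channel using the statistics in `stats`,
#' e.g. to normalise held-out data with training-split statistics.
#'
#' @param signals numeric array `N x W x C`.
#' @param stats data.frame with `mean` and `sd` columns (one row per channel).
#' @return the normalised array.
#' @export
applyChannelStats <- function(signals, stats) {
  stopifnot(nrow(stats) == dim(signals)[3L])
  for (c0 in seq_len(nrow(stats))) {
    signals[, , c0] <- (signals[, , c0] - stats$mean[c0]) / stats$sd[c0]
  }
  signals
}

#' Oversampling augmentation of minority classes
#'
#' Raises every training-split class to `targetPerClass` windows by
#' duplicating seeded-random training windows of that class with additive
#' Gaussian jitter (sd = `jitterSd` times the per-channel sd). Only the
#' training split is augmented; validation and test are untouched. This is a
#' deliberately simple jitter-duplication scheme standing in for
#' dataset-specific augmentation recipes.
#'
#' @param ds a [WindowedDataset-class].
#' @param targetPerClass integer target count per training class.
#' @param jitterSd numeric >= 0, jitter scale relative to channel sd.
#' @param seed integer seed.
#' @return the augmented dataset.
#' @export
oversampleAugment <- function(ds, targetPerClass, jitterSd = 0.05, seed = 1L) {
  stopifnot(is(ds, "WindowedDataset"))
  trainIdx <- which(ds@split == "train")
  counts <- table(factor(ds@labels[trainIdx], levels = seq_len(ds@nClasses) - 1L))
  if (targetPerClass < max(counts)) {
    warning("targetPerClass below the current maximum class count; no-op")
    return(ds)
  }
  set.seed(as.integer(seed))
  d <- dim(ds@signals)
  chSd <- vapply(
    seq_len(d[3L]),
    function(c0) stats::sd(as.vector(ds@signals[trainIdx, , c0])),
    numeric(1)
  )
  addSig <- list()
  addLab <- integer()
  for (k in seq_len(ds@nClasses) - 1L) {
    classIdx <- trainIdx[ds@labels[trainIdx] == k]
    need <- targetPerClass - length(classIdx)
    if (need <= 0L || !length(classIdx)) next
    picks <- sample(classIdx, need, replace = TRUE)
    for (p in picks) {
      w <- ds@signals[p, , ]
      if (jitterSd > 0) {
        w <- w + matrix(stats::rnorm(d[2L] * d[3L]), d[2L], d[3L]) *
          rep(jitterSd * chSd, each = d[2L])
      }
      addSig[[length(addSig) + 1L]] <- w
      addLab <- c(addLab, k)
    }
  }
  if (!length(addSig)) return(ds)
  nAdd <- length(addSig)
  sig <- array(0, c(d[1L] + nAdd, d[2L], d[3L]))
  sig[seq_len(d[1L]), , ] <- ds@signals
  for (i in seq_len(nAdd)) sig[d[1L] + i, , ] <- addSig[[i]]
  methods::new("WindowedDataset",
    signals = sig,
    labels = c(ds@labels, addLab),
    split = c(ds@split, rep("train", nAdd)),
    nClasses = ds@nClasses,
    channelStats = ds@channelStats
  )
}

#' Integer-factor decimation of a continuous recording
#'
#' Keeps every `factor`-th timestep. This is plain decimation without an
#' anti-aliasing filter; it is intended for over-sampled low-frequency
#' movement signals where aliasing is negligible.
#'
#' @param series numeric matrix `L x C`.
#' @param factor positive integer decimation factor.
#' @return the decimated matrix.
#' @export
decimateSeries <- function(series, factor) {
  factor <- as.integer(factor)
  stopifnot(is.matrix(series), factor >= 1L)
  series[seq(1L, nrow(series), by = factor), , drop = FALSE]
}
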
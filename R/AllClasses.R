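#' WindowedDataset: fixed-length multichannel windows with labels and splits
#'
#' The universal currency of the valuation pipeline: `N` windows of `W`
#' timesteps over `C` channels, an integer class label per window (0-based,
#' values in `0..K-1`), a split tag per window (`train`, `validation`,
#' `test`), and the per-channel normalisation statistics (training-split
#' mean/sd) once [normalizeDataset()] has been applied.
#'
#' @slot signals numeric array `N x W x C`.
#' @slot labels integer vector of length `N`, 0-based class codes.
#' @slot split character vector of length `N` with values in
#'   `c("train", "validation", "test")`.
#' @slot nClasses integer, the number of classes `K`.
#' @slot channelStats data.frame with columns `mean` and `sd` (one row per
#'   channel) or an empty data.frame before normalisation.
#'
#' @seealso [generateDataset()], [corruptLabels()], [normalizeDataset()]
#' @export
setClass("WindowedDataset",
  representation(
    signals = "array",
    labels = "integer",
    split = "character",
    nClasses = "integer",
    channelStats = "data.frame"
  ),
  prototype(channelStats = data.frame())
)

setValidity("WindowedDataset", function(object) {
  d <- dim(object@signals)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "signals must be an N x W x C array")
  else {
    if (length(object@labels) != d[1L]) {
      msg <- c(msg, "labels length must equal the number of windows")
    }
    if (length(object@split) != d[1L]) {
      msg <- c(msg, "split length must equal the number of windows")
    }
  }
  if (any(!object@split %in% c("train", "validation", "test"))) {
    msg <- c(msg, "split tags must be train/validation/test")
  }
  if (length(object@labels) &&
      (min(object@labels) < 0L || max(object@labels) >= object@nClasses)) {
    msg <- c(msg, "labels must lie in 0..nClasses-1")
  }
  if (anyNA(object@signals)) msg <- c(msg, "signals contain NA/NaN")
  if (length(msg)) msg else TRUE
})

#' CorruptionRecord: ground truth of injected label noise
#'
#' Which training-split windows had their label flipped by [corruptLabels()],
#' together with the original labels — the ground truth that corrupted-sample
#' discovery (CSD) is scored against.
#'
#' @slot indices integer vector of corrupted window indices (into the dataset).
#' @slot originalLabels integer vector aligned with `indices`.
#' @slot rate numeric corruption rate in `[0, 1]`.
#' @slot seed integer seed used for the corruption draw.
#' @export
setClass("CorruptionRecord",
  representation(
    indices = "integer",
    originalLabels = "integer",
    rate = "numeric",
    seed = "integer"
  )
)

setValidity("CorruptionRecord", function(object) {
  msg <- character()
  if (length(object@indices) != length(object@originalLabels)) {
    msg <- c(msg, "indices and originalLabels must be aligned")
  }
  if (object@rate < 0 || object@rate > 1) msg <- c(msg, "rate must be in [0,1]")
  if (anyDuplicated(object@indices)) msg <- c(msg, "indices must be unique")
  if (length(msg)) msg else TRUE
})

#' ValueTable: per-training-sample selection probabilities
#'
#' The output of the valuation algorithm: the data value estimator's selection
#' probability for every training-split window, clipped strictly inside
#' (0, 1). Higher values mark more valuable samples.
#'
#' @slot probs numeric vector in (0, 1).
#' @slot sampleIndex integer vector of dataset indices (training split) the
#'   probabilities refer to.
#' @export
setClass("ValueTable",
  representation(probs = "numeric", sampleIndex = "integer")
)

setValidity("ValueTable", function(object) {
  msg <- character()
  if (length(object@probs) != length(object@sampleIndex)) {
    msg <- c(msg, "probs and sampleIndex must be aligned")
  }
  if (length(object@probs) && (min(object@probs) <= 0 || max(object@probs) >= 1)) {
    msg <- c(msg, "probs must lie strictly inside (0,1)")
  }
  if (length(msg)) msg else TRUE
})

#' CSDCurve: corrupted sample discovery curve
#'
#' Fraction of injected label corruptions found among the lowest-valued
#' `5% * r` of training windows, for `r = 0..10`, together with the ideal
#' (optimal) curve `min(v*r/o, 1)`.
#'
#' @slot removalFractions numeric vector (length 11 by default).
#' @slot discovery numeric vector in `[0,1]`, same length.
#' @slot optimal numeric vector, the ideal curve.
#' @export
setClass("CSDCurve",
  representation(
    removalFractions = "numeric",
    discovery = "numeric",
    optimal = "numeric"
  )
)

setValidity("CSDCurve", function(object) {
  msg <- character()
  n <- length(object@removalFractions)
  if (length(object@discovery) != n || length(object@optimal) != n) {
    msg <- c(msg, "curve components must share a length")
  }
  if (n && object@discovery[1L] != 0) msg <- c(msg, "discovery at r=0 must be 0")
  if (n > 1L && any(diff(object@discovery) < 0)) {
    msg <- c(msg, "discovery must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' RHLVSCurve: remove high/low value samples accuracy curves
#'
#' Test accuracy of a reference classifier retrained after removing the
#' top (resp. bottom) `5% * r` of training windows by value, `r = 0..10`.
#'
#' @slot removalFractions numeric vector.
#' @slot removeHighAcc numeric accuracies after removing highest-value data.
#' @slot removeLowAcc numeric accuracies after removing lowest-value data.
#' @slot classifier character, the reference classifier variant used.
#' @export
setClass("RHLVSCurve",
  representation(
    removalFractions = "numeric",
    removeHighAcc = "numeric",
    removeLowAcc = "numeric",
    classifier = "character"
  )
)

setValidity("RHLVSCurve", function(object) {
  msg <- character()
  if (length(object@removeHighAcc) != length(object@removalFractions) ||
      length(object@removeLowAcc) != length(object@removalFractions)) {
    msg <- c(msg, "curve components must share a length")
  }
  accs <- c(object@removeHighAcc, object@removeLowAcc)
  if (length(accs) && (min(accs) < 0 || max(accs) > 1)) {
    msg <- c(msg, "accuracies must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})
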
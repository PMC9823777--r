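#' Predictor (task model) configuration
#'
#' The task classifier is a double-head 1D-CNN stacking ensemble: two parallel
#' 1D convolutions with distinct kernel sizes (1 and 3) and ReLU activations
#' extract different temporal features, each head is globally max-pooled over
#' time, the pooled features are concatenated, and a dense softmax classifier
#' follows. Trained by Adam on a value-weighted cross-entropy.
#'
#' @param filters integer, convolution filters per head.
#' @param headKernels integer pair of distinct kernel sizes.
#' @param denseUnits integer; 0 means the classifier is a single dense softmax
#'   layer, a positive value inserts a hidden ReLU layer of that width.
#' @param lr numeric Adam learning rate.
#' @param batch integer mini-batch size.
#' @param iterations integer training iterations (gradient steps).
#' @return a validated list of class `"predictorConfig"`.
#' @export
predictorConfig <- function(filters = 64L, headKernels = c(1L, 3L),
                            denseUnits = 0L, lr = 0.01, batch = 64L,
                            iterations = 200L) {
  headKernels <- as.integer(headKernels)
  if (length(headKernels) != 2L || headKernels[1L] == headKernels[2L]) {
    stop("headKernels must be two distinct kernel sizes")
  }
  if (!is.finite(lr) || lr <= 0) stop("lr must be positive")
  structure(
    list(
      filters = as.integer(filters), headKernels = headKernels,
      denseUnits = as.integer(denseUnits), lr = lr,
      batch = as.integer(batch), iterations = as.integer(iterations)
    ),
    class = "predictorConfig"
  )
}

#' Construct an untrained double-head 1D-CNN predictor
#'
#' @param nChannels integer, input channels.
#' @param nClasses integer, output classes.
#' @param cfg a [predictorConfig()].
#' @param seed optional integer seed for weight initialisation.
#' @return an object of class `"predictorModel"`.
#' @export
predictorModel <- function(nChannels, nClasses, cfg = predictorConfig(),
                           seed = NULL) {
  stopifnot(inherits(cfg, "predictorConfig"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  Fc <- cfg$filters
  p <- list()
  for (h in 1:2) {
    k <- cfg$headKernels[h]
    p[[paste0("head", h, ".W")]] <- glorot(k * nChannels, Fc,
      paste0("pred.head", h, ".W"))
    p[[paste0("head", h, ".b")]] <- zeros(1L, Fc, paste0("pred.head", h, ".b"))
  }
  inDim <- 2L * Fc
  if (cfg$denseUnits > 0L) {
    p$hidW <- glorot(inDim, cfg$denseUnits, "pred.hidW")
    p$hidB <- zeros(1L, cfg$denseUnits, "pred.hidB")
    inDim <- cfg$denseUnits
  }
  p$outW <- glorot(inDim, as.integer(nClasses), "pred.outW")
  p$outB <- zeros(1L, as.integer(nClasses), "pred.outB")
  structure(
    list(
      params = p, cfg = cfg, nChannels = as.integer(nChannels),
      nClasses = as.integer(nClasses)
    ),
    class = "predictorModel"
  )
}

# constant conv inputs (stacked im2col per head) for a signal array
predictorCache <- function(model, signalsArray) {
  d <- dim(signalsArray)
  x <- stackSignals(signalsArray)
  list(
    heads = lapply(model$cfg$headKernels, function(k) {
      im2colNumeric(x, d[1L], d[2L], k)
    }),
    N = d[1L], W = d[2L]
  )
}

# logits node for the samples in `idx`
predictorLogitsNode <- function(tape, model, cache, idx) {
  W <- cache$W
  rows <- as.vector(vapply(idx, function(i) ((i - 1L) * W + 1L):(i * W),
    integer(W)))
  pooled <- lapply(1:2, function(h) {
    Xc <- adConst(tape, cache$heads[[h]][rows, , drop = FALSE])
    A <- adRelu(tape, adAdd(
      tape,
      adMatmul(tape, Xc, adLeaf(tape, model$params[[paste0("head", h, ".W")]])),
      adLeaf(tape, model$params[[paste0("head", h, ".b")]])
    ))
    adMaxGroups(tape, A, W)
  })
  z <- adConcatCols(tape, pooled)
  if (model$cfg$denseUnits > 0L) {
    z <- adRelu(tape, adAdd(
      tape,
      adMatmul(tape, z, adLeaf(tape, model$params$hidW)),
      adLeaf(tape, model$params$hidB)
    ))
  }
  adAdd(
    tape,
    adMatmul(tape, z, adLeaf(tape, model$params$outW)),
    adLeaf(tape, model$params$outB)
  )
}

#' Class-probability forward pass of the predictor
#'
#' @param model a [predictorModel()].
#' @param signalsArray numeric array `n x W x C`.
#' @return numeric matrix `n x K` of softmax probabilities (rows sum to 1).
#' @export
predictProba <- function(model, signalsArray) {
  stopifnot(inherits(model, "predictorModel"))
  if (length(dim(signalsArray)) == 2L) {
    signalsArray <- array(signalsArray, c(1L, dim(signalsArray)))
  }
  if (dim(signalsArray)[3L] != model$nChannels) stop("channel count mismatch")
  cache <- predictorCache(model, signalsArray)
  tape <- adTape(training = FALSE)
  z <- predictorLogitsNode(tape, model, cache, seq_len(cache$N))$value
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Mean (optionally weighted) cross-entropy of the predictor on a sample set
#'
#' @param model a [predictorModel()].
#' @param signalsArray numeric array `n x W x C`.
#' @param labels integer vector (0-based).
#' @param weights optional non-negative weights (mean is over n, not sum(w)).
#' @return scalar loss.
#' @export
predictorLoss <- function(model, signalsArray, labels, weights = NULL) {
  p <- predictProba(model, signalsArray)
  py <- pmax(p[cbind(seq_along(labels), labels + 1L)], 1e-12)
  if (is.null(weights)) mean(-log(py)) else sum(weights * -log(py)) / length(py)
}

#' Train the predictor with per-sample weights
#'
#' Minimises the value-weighted cross-entropy
#' `(1/N) * sum_i w_i * CE(f(x_i), y_i)` by Adam: each iteration draws a
#' mini-batch (seeded, without replacement) and applies one gradient step.
#' With `weights = NULL` the ordinary unweighted cross-entropy is minimised;
#' samples with weight 0 contribute exactly zero gradient.
#'
#' @param model a [predictorModel()]; updated parameters are modified in
#'   place (parameters are reference objects) and the model is also returned.
#' @param signalsArray numeric array `n x W x C` of training windows.
#' @param labels integer vector (0-based) of length `n`.
#' @param weights optional numeric vector of length `n`, non-negative.
#' @param iterations,batch,lr override the corresponding [predictorConfig()]
#'   entries when non-NULL.
#' @param seed optional integer seed controlling batch draws.
#' @return the trained model (invisibly the same object), with a numeric
#'   `lossHistory` attribute of per-iteration batch losses.
#' @export
fitWeighted <- function(model, signalsArray, labels, weights = NULL,
                        iterations = NULL, batch = NULL, lr = NULL,
                        seed = NULL) {
  stopifnot(inherits(model, "predictorModel"))
  n <- dim(signalsArray)[1L]
  if (!is.null(weights)) {
    if (length(weights) != n) stop("weights must have one entry per sample")
    if (any(weights < 0)) stop("weights must be non-negative")
    if (all(weights == 0)) stop("empty effective training set: all weights zero")
  }
  iterations <- iterations %||% model$cfg$iterations
  batch <- min(batch %||% model$cfg$batch, n)
  lr <- lr %||% model$cfg$lr
  if (!is.null(seed)) set.seed(as.integer(seed))
  cache <- predictorCache(model, signalsArray)
  y1 <- labels + 1L
  hist <- numeric(iterations)
  for (it in seq_len(iterations)) {
    idx <- if (batch < n) sample.int(n, batch) else seq_len(n)
    tape <- adTape(training = TRUE)
    logits <- predictorLogitsNode(tape, model, cache, idx)
    loss <- adSoftmaxCrossEntropy(
      tape, logits, y1[idx],
      if (is.null(weights)) NULL else weights[idx]
    )
    adBackward(tape, loss)
    adamStep(model$params, lr)
    hist[it] <- loss$value[1L]
  }
  attr(model, "lossHistory") <- hist
  invisible(model)
}

#' Pretrain the validation predictor f_v
#'
#' Trains a fresh predictor of the same architecture on the validation split
#' only. The resulting model is used solely to compute marginal information
#' `m(x, y) = |onehot(y) - f_v(x)|` and is never updated afterwards.
#'
#' @param ds a [WindowedDataset-class] with a non-empty validation split.
#' @param cfg a [predictorConfig()].
#' @param seed optional integer seed (initialisation + batch draws).
#' @return a trained `"predictorModel"`.
#' @export
pretrainValidationPredictor <- function(ds, cfg = predictorConfig(),
                                        seed = NULL) {
  stopifnot(is(ds, "WindowedDataset"))
  vIdx <- which(ds@split == "validation")
  if (!length(vIdx)) stop("validation split is empty")
  C <- dim(ds@signals)[3L]
  fv <- predictorModel(C, ds@nClasses, cfg, seed = seed)
  fitWeighted(
    fv, ds@signals[vIdx, , , drop = FALSE], ds@labels[vIdx],
    seed = if (is.null(seed)) NULL else childSeed(seed, 1L)
  )
}

#' Marginal information of labelled windows
#'
#' The elementwise absolute difference between the one-hot label and the
#' validation-pretrained predictor's class probabilities,
#' `m(x, y) = |onehot(y) - f_v(x)|`. Every component lies in `[0, 1]`; for a
#' correctly labelled, confidently classified window the vector is near zero,
#' for a mislabelled one the components at the true and claimed class are
#' near one — a per-class contamination signal.
#'
#' @param fv the validation-pretrained predictor.
#' @param signalsArray numeric array `n x W x C`.
#' @param labels integer vector (0-based).
#' @return numeric `n x K` matrix.
#' @export
marginalInfo <- function(fv, signalsArray, labels) {
  abs(oneHot(labels, fv$nClasses) - predictProba(fv, signalsArray))
}
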
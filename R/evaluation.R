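#' Corrupted sample discovery (CSD) curve
#'
#' Sorts the training samples ascending by value (stable, index tie-break)
#' and, for `r = 0..nSteps`, accumulates the lowest `v * r` samples where
#' `v = round(stepFraction * N)`. The discovery at step `r` is the fraction
#' of the injected corruptions found in that accumulated low-value set,
#' `|accumulated intersect corrupted| / o`. The ideal (optimal) curve is
#' `min(v * r / o, 1)`: every accumulated sample a corruption until all `o`
#' are found.
#'
#' @param valueTable a [ValueTable-class].
#' @param record a [CorruptionRecord-class] with at least one corruption.
#' @param stepFraction numeric step of the removal grid (default 0.05).
#' @param nSteps integer number of steps beyond zero (default 10).
#' @return a [CSDCurve-class].
#' @export
csd <- function(valueTable, record, stepFraction = 0.05, nSteps = 10L) {
  stopifnot(is(valueTable, "ValueTable"), is(record, "CorruptionRecord"))
  o <- length(record@indices)
  if (o == 0L) stop("no corruption record: CSD is undefined")
  vals <- valueTable@probs
  idx <- valueTable@sampleIndex
  N <- length(vals)
  v <- round(stepFraction * N)
  ordAsc <- order(vals, seq_len(N)) # stable ascending, index tie-break
  sortedIdx <- idx[ordAsc]
  corrupted <- record@indices
  disc <- vapply(0:nSteps, function(r) {
    take <- min(v * r, N)
    if (take == 0L) return(0)
    sum(sortedIdx[seq_len(take)] %in% corrupted) / o
  }, numeric(1))
  methods::new("CSDCurve",
    removalFractions = (0:nSteps) * stepFraction,
    discovery = disc,
    optimal = pmin(v * (0:nSteps) / o, 1)
  )
}

#' Reference classifier specification
#'
#' The three classifier variants used to score RHLVS curves. All share
#' 1D-conv layers with 64 filters, kernel 3, ReLU and temporal max-pooling of
#' size 2 (two conv/pool blocks), and a 100-unit dense layer before the
#' softmax. `bbs_model` and `public_complex` insert a GRU with 8 units after
#' the conv stack, followed by 50% and 70% dropout respectively;
#' `public_baseline` flattens the conv features directly.
#'
#' @param variant one of `"bbs_model"`, `"public_baseline"`,
#'   `"public_complex"`.
#' @return a validated list of class `"classifierSpec"`.
#' @export
classifierSpec <- function(variant = c("public_baseline", "bbs_model",
                                       "public_complex")) {
  variant <- match.arg(variant)
  structure(
    list(
      variant = variant,
      convFilters = 64L, convKernel = 3L, poolSize = 2L, nConvBlocks = 2L,
      gruUnits = if (variant == "public_baseline") 0L else 8L,
      dropout = switch(variant,
        public_baseline = 0,
        bbs_model = 0.5,
        public_complex = 0.7
      ),
      denseUnits = 100L
    ),
    class = "classifierSpec"
  )
}

#' Build a reference classifier
#'
#' @param spec a [classifierSpec()].
#' @param nClasses integer, output classes.
#' @param nChannels integer, input channels.
#' @param windowLen integer, window length (fixes the flatten width of the
#'   baseline variant).
#' @param seed optional integer seed for weight initialisation.
#' @return an object of class `"classifierModel"`.
#' @export
buildClassifier <- function(spec, nClasses, nChannels, windowLen,
                            seed = NULL) {
  stopifnot(inherits(spec, "classifierSpec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  Fc <- spec$convFilters
  p <- list(
    conv1W = glorot(spec$convKernel * nChannels, Fc, "clf.conv1W"),
    conv1B = zeros(1L, Fc, "clf.conv1B"),
    conv2W = glorot(spec$convKernel * Fc, Fc, "clf.conv2W"),
    conv2B = zeros(1L, Fc, "clf.conv2B")
  )
  wOut <- windowLen
  for (b in seq_len(spec$nConvBlocks)) wOut <- (wOut %/% 2L)
  if (wOut < 1L) stop("window too short for two pooling stages")
  if (spec$gruUnits > 0L) {
    u <- spec$gruUnits
    for (gate in c("z", "r", "n")) {
      p[[paste0("gruW", gate)]] <- glorot(Fc, u, paste0("clf.gruW", gate))
      p[[paste0("gruU", gate)]] <- glorot(u, u, paste0("clf.gruU", gate))
      p[[paste0("gruB", gate)]] <- zeros(1L, u, paste0("clf.gruB", gate))
    }
    denseIn <- u
  } else {
    denseIn <- wOut * Fc
  }
  p$denseW <- glorot(denseIn, spec$denseUnits, "clf.denseW")
  p$denseB <- zeros(1L, spec$denseUnits, "clf.denseB")
  p$outW <- glorot(spec$denseUnits, as.integer(nClasses), "clf.outW")
  p$outB <- zeros(1L, as.integer(nClasses), "clf.outB")
  structure(
    list(
      params = p, spec = spec, nChannels = as.integer(nChannels),
      nClasses = as.integer(nClasses), windowLen = as.integer(windowLen)
    ),
    class = "classifierModel"
  )
}

classifierCache <- function(model, signalsArray) {
  d <- dim(signalsArray)
  x <- stackSignals(signalsArray)
  list(
    im2col = im2colNumeric(x, d[1L], d[2L], model$spec$convKernel),
    N = d[1L], W = d[2L]
  )
}

# drop the last timestep of every sample in a stacked node if W is odd
adEvenRows <- function(tape, a, B, W) {
  if (W %% 2L == 0L) return(list(node = a, W = W))
  keep <- as.vector(vapply(seq_len(B), function(b) {
    ((b - 1L) * W + 1L):((b - 1L) * W + W - 1L)
  }, integer(W - 1L)))
  list(node = adGatherRows(tape, a, keep), W = W - 1L)
}

classifierLogitsNode <- function(tape, model, cache, idx) {
  spec <- model$spec
  p <- model$params
  B <- length(idx)
  W <- cache$W
  rows <- as.vector(vapply(idx, function(i) ((i - 1L) * W + 1L):(i * W),
    integer(W)))
  Xc <- adConst(tape, cache$im2col[rows, , drop = FALSE])
  h <- adRelu(tape, adAdd(
    tape, adMatmul(tape, Xc, adLeaf(tape, p$conv1W)), adLeaf(tape, p$conv1B)
  ))
  ev <- adEvenRows(tape, h, B, W)
  h <- adPoolPairs(tape, ev$node)
  W1 <- ev$W %/% 2L
  h <- adRelu(tape, adAdd(
    tape,
    adMatmul(tape, adIm2col(tape, h, B, W1, spec$convKernel),
      adLeaf(tape, p$conv2W)),
    adLeaf(tape, p$conv2B)
  ))
  ev <- adEvenRows(tape, h, B, W1)
  h <- adPoolPairs(tape, ev$node)
  W2 <- ev$W %/% 2L
  if (spec$gruUnits > 0L) {
    u <- spec$gruUnits
    hid <- adConst(tape, matrix(0, B, u))
    for (t in seq_len(W2)) {
      xt <- adGatherRows(tape, h, (seq_len(B) - 1L) * W2 + t)
      z <- adSigmoid(tape, adAdd(tape, adAdd(
        tape, adMatmul(tape, xt, adLeaf(tape, p$gruWz)),
        adMatmul(tape, hid, adLeaf(tape, p$gruUz))
      ), adLeaf(tape, p$gruBz)))
      r <- adSigmoid(tape, adAdd(tape, adAdd(
        tape, adMatmul(tape, xt, adLeaf(tape, p$gruWr)),
        adMatmul(tape, hid, adLeaf(tape, p$gruUr))
      ), adLeaf(tape, p$gruBr)))
      nn <- adTanh(tape, adAdd(tape, adAdd(
        tape, adMatmul(tape, xt, adLeaf(tape, p$gruWn)),
        adMul(tape, r, adMatmul(tape, hid, adLeaf(tape, p$gruUn)))
      ), adLeaf(tape, p$gruBn)))
      oneMinusZ <- adAffine(tape, z, -1, 1)
      hid <- adAdd(tape, adMul(tape, oneMinusZ, nn), adMul(tape, z, hid))
    }
    feat <- adDropout(tape, hid, spec$dropout)
  } else {
    feat <- adFlattenStack(tape, h, B)
  }
  d1 <- adRelu(tape, adAdd(
    tape, adMatmul(tape, feat, adLeaf(tape, p$denseW)), adLeaf(tape, p$denseB)
  ))
  adAdd(
    tape, adMatmul(tape, d1, adLeaf(tape, p$outW)), adLeaf(tape, p$outB)
  )
}

#' Class probabilities from a reference classifier
#'
#' @param model a [buildClassifier()] model.
#' @param signalsArray numeric array `n x W x C`.
#' @return numeric `n x K` softmax matrix.
#' @export
predictClassifier <- function(model, signalsArray) {
  stopifnot(inherits(model, "classifierModel"))
  cache <- classifierCache(model, signalsArray)
  tape <- adTape(training = FALSE)
  z <- classifierLogitsNode(tape, model, cache, seq_len(cache$N))$value
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a reference classifier with optional per-sample weights
#'
#' @param model a `"classifierModel"` (updated in place and returned).
#' @param signalsArray numeric array `n x W x C`.
#' @param labels integer (0-based) labels.
#' @param weights optional non-negative weights.
#' @param iterations,batch,lr Adam training settings.
#' @param seed optional integer seed for batch draws and dropout.
#' @return the trained model.
#' @export
trainClassifier <- function(model, signalsArray, labels, weights = NULL,
                            iterations = 60L, batch = 32L, lr = 0.01,
                            seed = NULL) {
  stopifnot(inherits(model, "classifierModel"))
  n <- dim(signalsArray)[1L]
  if (!is.null(weights) && all(weights == 0)) {
    stop("empty effective training set: all weights zero")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  cache <- classifierCache(model, signalsArray)
  y1 <- labels + 1L
  batch <- min(batch, n)
  for (it in seq_len(iterations)) {
    idx <- if (batch < n) sample.int(n, batch) else seq_len(n)
    tape <- adTape(training = TRUE)
    logits <- classifierLogitsNode(tape, model, cache, idx)
    loss <- adSoftmaxCrossEntropy(
      tape, logits, y1[idx],
      if (is.null(weights)) NULL else weights[idx]
    )
    adBackward(tape, loss)
    adamStep(model$params, lr)
  }
  model
}

#' Remove high/low-value samples (RHLVS) curves
#'
#' For each removal step `r = 0..nSteps`, retrains the reference classifier
#' from scratch (fresh seeded initialisation, one shared seed per curve) on
#' the training split minus the top (resp. bottom) `v * r` samples by value,
#' weighting the remaining samples by their selection probabilities, and
#' records the test-split accuracy. A well-performing valuation yields a
#' `removeLowAcc` curve that stays flat or improves while `removeHighAcc`
#' drops.
#'
#' @param ds the (corrupted) [WindowedDataset-class] used for valuation.
#' @param valueTable the [ValueTable-class] from [trainValuation()].
#' @param spec a [classifierSpec()].
#' @param stepFraction numeric removal-grid step (default 0.05).
#' @param nSteps integer steps beyond zero (default 10).
#' @param seed integer seed shared by every retraining in the curve.
#' @param weighted logical; weight remaining samples by their values (the
#'   printed objective) or train unweighted.
#' @param iterations,batch,lr classifier training settings.
#' @return an [RHLVSCurve-class].
#' @export
rhlvs <- function(ds, valueTable, spec = classifierSpec("public_baseline"),
                  stepFraction = 0.05, nSteps = 10L, seed = 1L,
                  weighted = TRUE, iterations = 60L, batch = 32L, lr = 0.01) {
  stopifnot(is(ds, "WindowedDataset"), is(valueTable, "ValueTable"))
  testIdx <- which(ds@split == "test")
  if (!length(testIdx)) stop("test split is empty")
  vals <- valueTable@probs
  idx <- valueTable@sampleIndex
  N <- length(vals)
  v <- round(stepFraction * N)
  ordAsc <- order(vals, seq_len(N)) # ascending, stable index tie-break
  xTest <- ds@signals[testIdx, , , drop = FALSE]
  yTest <- ds@labels[testIdx]
  W <- dim(ds@signals)[2L]
  C <- dim(ds@signals)[3L]

  fitAccuracy <- function(keepPos) {
    dsIdx <- idx[keepPos]
    clf <- buildClassifier(spec, ds@nClasses, C, W, seed = childSeed(seed, 1L))
    trainClassifier(
      clf, ds@signals[dsIdx, , , drop = FALSE], ds@labels[dsIdx],
      weights = if (weighted) vals[keepPos] else NULL,
      iterations = iterations, batch = batch, lr = lr,
      seed = childSeed(seed, 2L)
    )
    mean(max.col(predictClassifier(clf, xTest)) == yTest + 1L)
  }

  accHigh <- accLow <- rep(NA_real_, nSteps + 1L)
  acc0 <- fitAccuracy(ordAsc) # r = 0: identical for both directions
  accHigh[1L] <- accLow[1L] <- acc0
  lastStep <- nSteps
  for (r in seq_len(nSteps)) {
    m <- v * r
    if (m >= N) {
      warning(sprintf("removal of %d samples would empty the training set; ",
        m), "curve truncated at r = ", r - 1L)
      lastStep <- r - 1L
      break
    }
    accHigh[r + 1L] <- fitAccuracy(ordAsc[seq_len(N - m)]) # drop highest m
    accLow[r + 1L] <- fitAccuracy(ordAsc[(m + 1L):N]) # drop lowest m
  }
  keep <- seq_len(lastStep + 1L)
  methods::new("RHLVSCurve",
    removalFractions = ((0:nSteps) * stepFraction)[keep],
    removeHighAcc = accHigh[keep],
    removeLowAcc = accLow[keep],
    classifier = spec$variant
  )
}
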
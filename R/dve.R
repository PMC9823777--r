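#' Data value estimator configuration
#'
#' Architecture hyperparameters of the data value estimator (DVE): a 1D
#' convolution (64 filters, kernel 3, GeLU) followed by transformer encoder
#' blocks (2 self-attention heads, 256-unit feed-forward layer, dropout 0.1,
#' GeLU), global average pooling over time, then a 5-layer MLP of 100 ReLU
#' units on the embedding concatenated with the one-hot label; marginal
#' information joins before the final dense layer, whose sigmoid output is
#' the selection probability.
#'
#' @param convFilters integer, 1D-CNN filters (embedding width).
#' @param convKernel integer, 1D-CNN kernel size.
#' @param nTransformerBlocks integer, structurally identical encoder blocks.
#' @param nHeads integer, self-attention heads (must divide `convFilters`).
#' @param ffnUnits integer, feed-forward layer width.
#' @param dropout numeric in `[0, 1)`, dropout rate used during training.
#' @param mlpLayers integer, dense layers in the label-conditioned MLP.
#' @param mlpUnits integer, units per MLP layer.
#' @return a validated list of class `"dveConfig"`.
#' @export
dveConfig <- function(convFilters = 64L, convKernel = 3L,
                      nTransformerBlocks = 2L, nHeads = 2L,
                      ffnUnits = 256L, dropout = 0.1,
                      mlpLayers = 5L, mlpUnits = 100L) {
  cfg <- list(
    convFilters = as.integer(convFilters), convKernel = as.integer(convKernel),
    nTransformerBlocks = as.integer(nTransformerBlocks),
    nHeads = as.integer(nHeads), ffnUnits = as.integer(ffnUnits),
    dropout = dropout, mlpLayers = as.integer(mlpLayers),
    mlpUnits = as.integer(mlpUnits)
  )
  ints <- cfg[setdiff(names(cfg), "dropout")]
  if (any(vapply(ints, function(x) is.na(x) || x < 1L, logical(1)))) {
    stop("all dveConfig sizes must be positive integers")
  }
  if (!is.finite(dropout) || dropout < 0 || dropout >= 1) {
    stop("dropout must be in [0,1)")
  }
  if (cfg$convFilters %% cfg$nHeads != 0L) {
    stop("convFilters must be divisible by nHeads")
  }
  structure(cfg, class = "dveConfig")
}

# sinusoidal positional encoding, W x d (no learned parameters)
posEncoding <- function(W, d) {
  pos <- seq_len(W) - 1L
  i <- seq_len(d %/% 2) - 1L
  ang <- outer(pos, 1 / 10000^(2 * i / d))
  pe <- matrix(0, W, d)
  pe[, seq(1L, d, 2L)] <- sin(ang)
  pe[, seq(2L, d, 2L)] <- cos(ang[, seq_len(d - d %/% 2)])
  pe
}

#' Construct an untrained data value estimator
#'
#' @param nChannels integer, input signal channels.
#' @param nClasses integer, number of classes (one-hot label width).
#' @param cfg a [dveConfig()].
#' @param seed optional integer seed for weight initialisation.
#' @return an object of class `"dveModel"`.
#' @export
dveModel <- function(nChannels, nClasses, cfg = dveConfig(), seed = NULL) {
  stopifnot(inherits(cfg, "dveConfig"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- cfg$convFilters
  K <- as.integer(nClasses)
  p <- list(
    convW = glorot(cfg$convKernel * nChannels, d, "dve.convW"),
    convB = zeros(1L, d, "dve.convB")
  )
  for (b in seq_len(cfg$nTransformerBlocks)) {
    pf <- paste0("dve.t", b, ".")
    p[[paste0("t", b, ".Wq")]] <- glorot(d, d, paste0(pf, "Wq"))
    p[[paste0("t", b, ".bq")]] <- zeros(1L, d, paste0(pf, "bq"))
    p[[paste0("t", b, ".Wk")]] <- glorot(d, d, paste0(pf, "Wk"))
    p[[paste0("t", b, ".bk")]] <- zeros(1L, d, paste0(pf, "bk"))
    p[[paste0("t", b, ".Wv")]] <- glorot(d, d, paste0(pf, "Wv"))
    p[[paste0("t", b, ".bv")]] <- zeros(1L, d, paste0(pf, "bv"))
    p[[paste0("t", b, ".Wo")]] <- glorot(d, d, paste0(pf, "Wo"))
    p[[paste0("t", b, ".bo")]] <- zeros(1L, d, paste0(pf, "bo"))
    p[[paste0("t", b, ".ln1g")]] <- ones(1L, d, paste0(pf, "ln1g"))
    p[[paste0("t", b, ".ln1b")]] <- zeros(1L, d, paste0(pf, "ln1b"))
    p[[paste0("t", b, ".W1")]] <- glorot(d, cfg$ffnUnits, paste0(pf, "W1"))
    p[[paste0("t", b, ".b1")]] <- zeros(1L, cfg$ffnUnits, paste0(pf, "b1"))
    p[[paste0("t", b, ".W2")]] <- glorot(cfg$ffnUnits, d, paste0(pf, "W2"))
    p[[paste0("t", b, ".b2")]] <- zeros(1L, d, paste0(pf, "b2"))
    p[[paste0("t", b, ".ln2g")]] <- ones(1L, d, paste0(pf, "ln2g"))
    p[[paste0("t", b, ".ln2b")]] <- zeros(1L, d, paste0(pf, "ln2b"))
  }
  inDim <- d + K
  for (l in seq_len(cfg$mlpLayers)) {
    p[[paste0("mlp", l, ".W")]] <- glorot(inDim, cfg$mlpUnits,
      paste0("dve.mlp", l, ".W"))
    p[[paste0("mlp", l, ".b")]] <- zeros(1L, cfg$mlpUnits,
      paste0("dve.mlp", l, ".b"))
    inDim <- cfg$mlpUnits
  }
  # The output layer starts at zero so the initial selection probability is
  # exactly 0.5 for every sample: the policy head is neutral at the start and
  # the policy gradient alone decides the sign of each feature's influence
  # (including the marginal-information block).
  p$outW <- zeros(cfg$mlpUnits + K, 1L, "dve.outW")
  p$outB <- zeros(1L, 1L, "dve.outB")
  structure(
    list(params = p, cfg = cfg, nChannels = as.integer(nChannels), nClasses = K),
    class = "dveModel"
  )
}

# one transformer encoder block on a single sample's W x d node
dveTransformerBlock <- function(tape, model, h, b) {
  p <- model$params
  cfg <- model$cfg
  g <- function(nm) adLeaf(tape, p[[paste0("t", b, ".", nm)]])
  d <- cfg$convFilters
  hd <- d %/% cfg$nHeads
  Q <- adAdd(tape, adMatmul(tape, h, g("Wq")), g("bq"))
  K_ <- adAdd(tape, adMatmul(tape, h, g("Wk")), g("bk"))
  V <- adAdd(tape, adMatmul(tape, h, g("Wv")), g("bv"))
  heads <- lapply(seq_len(cfg$nHeads), function(j) {
    idx <- ((j - 1L) * hd + 1L):(j * hd)
    Qh <- adSliceCols(tape, Q, idx)
    Kh <- adSliceCols(tape, K_, idx)
    Vh <- adSliceCols(tape, V, idx)
    S <- adAffine(tape, adMatmul(tape, Qh, adTranspose(tape, Kh)), 1 / sqrt(hd))
    adMatmul(tape, adSoftmaxRows(tape, S), Vh)
  })
  O <- adAdd(tape, adMatmul(tape, adConcatCols(tape, heads), g("Wo")), g("bo"))
  O <- adDropout(tape, O, cfg$dropout)
  h1 <- adLayerNorm(tape, adAdd(tape, h, O), g("ln1g"), g("ln1b"))
  F1 <- adGelu(tape, adAdd(tape, adMatmul(tape, h1, g("W1")), g("b1")))
  F2 <- adAdd(tape, adMatmul(tape, F1, g("W2")), g("b2"))
  F2 <- adDropout(tape, F2, cfg$dropout)
  adLayerNorm(tape, adAdd(tape, h1, F2), g("ln2g"), g("ln2b"))
}

# Precompute the constant part of the DVE forward pass for a signal array:
# the stacked im2col of every window (the first conv layer's input).
dveInputCache <- function(model, signalsArray) {
  d <- dim(signalsArray)
  x <- stackSignals(signalsArray)
  list(
    im2col = im2colNumeric(x, d[1L], d[2L], model$cfg$convKernel),
    N = d[1L], W = d[2L]
  )
}

# Embedding node(s) for the samples in `idx` (rows of the cache), N x filters
dveEmbeddingNode <- function(tape, model, cache, idx) {
  cfg <- model$cfg
  W <- cache$W
  rows <- as.vector(vapply(idx, function(i) ((i - 1L) * W + 1L):(i * W),
    integer(W)))
  Xc <- adConst(tape, cache$im2col[rows, , drop = FALSE])
  H <- adGelu(tape, adAdd(
    tape,
    adMatmul(tape, Xc, adLeaf(tape, model$params$convW)),
    adLeaf(tape, model$params$convB)
  ))
  pe <- posEncoding(W, cfg$convFilters)
  peStack <- adConst(tape, pe[rep(seq_len(W), length(idx)), , drop = FALSE])
  H <- adAdd(tape, H, peStack)
  embs <- lapply(seq_along(idx), function(i) {
    hi <- adGatherRows(tape, H, ((i - 1L) * W + 1L):(i * W))
    for (b in seq_len(cfg$nTransformerBlocks)) {
      hi <- dveTransformerBlock(tape, model, hi, b)
    }
    adMeanRows(tape, hi)
  })
  adConcatRows(tape, embs)
}

# Full DVE forward: selection-probability node (n x 1) for the given samples.
# yOnehot and marginal are n x K numeric matrices.
dveProbsNode <- function(tape, model, cache, idx, yOnehot, marginal) {
  cfg <- model$cfg
  h <- adConcatCols(tape, list(
    dveEmbeddingNode(tape, model, cache, idx),
    adConst(tape, yOnehot)
  ))
  for (l in seq_len(cfg$mlpLayers)) {
    h <- adRelu(tape, adAdd(
      tape,
      adMatmul(tape, h, adLeaf(tape, model$params[[paste0("mlp", l, ".W")]])),
      adLeaf(tape, model$params[[paste0("mlp", l, ".b")]])
    ))
  }
  h <- adConcatCols(tape, list(h, adConst(tape, marginal)))
  logit <- adAdd(
    tape,
    adMatmul(tape, h, adLeaf(tape, model$params$outW)),
    adLeaf(tape, model$params$outB)
  )
  adSigmoid(tape, logit)
}

#' Extract the DVE feature embedding of one window
#'
#' Runs the 1D-conv + transformer-encoder feature extractor in evaluation
#' mode (dropout off) and returns the temporally average-pooled embedding.
#'
#' @param model a [dveModel()].
#' @param x numeric matrix `W x C`.
#' @return numeric vector of length `convFilters`.
#' @export
extractFeatures <- function(model, x) {
  stopifnot(inherits(model, "dveModel"), is.matrix(x))
  if (ncol(x) != model$nChannels) stop("channel count mismatch")
  if (nrow(x) < model$cfg$convKernel) stop("window shorter than the kernel")
  cache <- dveInputCache(model, array(x, c(1L, nrow(x), ncol(x))))
  tape <- adTape(training = FALSE)
  as.vector(dveEmbeddingNode(tape, model, cache, 1L)$value)
}

#' Selection probabilities for a batch of labelled windows
#'
#' Evaluation-mode forward pass of the full DVE: embeds each window,
#' conditions on its one-hot label, mixes in marginal information before the
#' final layer, and returns the sigmoid selection probability, clipped
#' strictly inside (0, 1).
#'
#' @param model a [dveModel()].
#' @param signalsArray numeric array `n x W x C`.
#' @param labels integer vector (0-based) of length `n`.
#' @param marginal numeric `n x K` marginal-information matrix
#'   (see [marginalInfo()]); zeros if not yet available.
#' @return numeric vector of `n` probabilities in (0, 1).
#' @export
dveValues <- function(model, signalsArray, labels, marginal = NULL) {
  stopifnot(inherits(model, "dveModel"))
  n <- dim(signalsArray)[1L]
  K <- model$nClasses
  if (is.null(marginal)) marginal <- matrix(0, n, K)
  yOnehot <- oneHot(labels, K)
  cache <- dveInputCache(model, signalsArray)
  tape <- adTape(training = FALSE)
  p <- dveProbsNode(tape, model, cache, seq_len(n), yOnehot, marginal)
  clipProb(as.vector(p$value))
}

#' Selection probability of a single window
#'
#' @param model a [dveModel()].
#' @param x numeric matrix `W x C`.
#' @param y one-hot numeric vector of length `K` (exactly one 1).
#' @param m numeric vector of length `K`, the marginal information.
#' @return a probability strictly inside (0, 1).
#' @export
selectionProbability <- function(model, x, y, m = NULL) {
  K <- model$nClasses
  if (length(y) != K || any(!y %in% c(0, 1)) || sum(y) != 1) {
    stop("y must be a one-hot vector over the model's classes")
  }
  if (is.null(m)) m <- rep(0, K)
  if (length(m) != K) stop("m must have one component per class")
  lab <- which(y == 1) - 1L
  dveValues(
    model, array(x, c(1L, nrow(x), ncol(x))), lab,
    matrix(m, 1L)
  )
}

#' Log-probability of a Bernoulli selection vector
#'
#' `log pi(s) = sum_i [s_i log p_i + (1 - s_i) log(1 - p_i)]`, the log of the
#' product-form probability of drawing the binary selection vector `s` from
#' independent Bernoulli draws with parameters `p`.
#'
#' @param probs numeric vector strictly inside (0, 1).
#' @param s binary vector (0/1) of the same length.
#' @return the scalar log-probability.
#' @examples
#' exp(selectionLogProb(c(0.9, 0.2, 0.7), c(1, 0, 1))) # 0.9 * 0.8 * 0.7
#' @export
selectionLogProb <- function(probs, s) {
  if (length(probs) != length(s)) stop("probs and s must be aligned")
  if (any(probs <= 0 | probs >= 1)) {
    stop("probs must be strictly inside (0,1); clip upstream")
  }
  if (any(!s %in% c(0, 1))) stop("s must be binary")
  sum(s * log(probs) + (1 - s) * log(1 - probs))
}

# analytic d/dp of a * selectionLogProb(p, s); used by the REINFORCE check
selectionLogProbGrad <- function(probs, s, advantage = 1) {
  advantage * (s / probs - (1 - s) / (1 - probs))
}
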
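#' Valuation-training configuration
#'
#' Hyperparameters of the REINFORCE valuation loop: predictor learning rate
#' `alpha`, DVE learning rate `beta`, predictor mini-batch `Bp`, selection
#' batch `Bs`, inner predictor iterations `NI`, moving-average window `T`
#' and the number of outer DVE iterations. Defaults follow the reference
#' settings: Adam at 0.01 for both networks, 200 inner iterations, 30 outer
#' iterations, predictor batch 64 (small-data profile; 1024 for large public
#' datasets), `T = 20`.
#'
#' @param alpha numeric > 0, predictor learning rate.
#' @param beta numeric > 0, DVE learning rate.
#' @param Bp integer > 0, predictor mini-batch size.
#' @param Bs integer or NULL; selection batch size. NULL resolves at run time
#'   to `min(N_train, 4 * Bp)`.
#' @param NI integer > 0, inner predictor iterations per outer iteration.
#' @param T integer > 0, moving-average baseline window.
#' @param outerIters integer >= 0, outer DVE iterations.
#' @param explorationWeight numeric >= 0; weight of the exploration
#'   regulariser that penalises the mean selection probability leaving
#'   `explorationRange`. The Bernoulli policy has two absorbing flat regions
#'   (select everything / select nothing) where the REINFORCE gradient
#'   vanishes; the penalty keeps the policy in its responsive region. Set to
#'   0 for the bare policy-gradient update.
#' @param explorationRange numeric length-2 vector, the tolerated band for
#'   the mean selection probability.
#' @param seed integer master seed; every stochastic stage derives from it.
#' @return a validated list of class `"trainerConfig"`.
#' @export
trainerConfig <- function(alpha = 0.01, beta = 0.01, Bp = 64L, Bs = NULL,
                          NI = 200L, T = 20L, outerIters = 30L,
                          explorationWeight = 1000, explorationRange = c(0.1, 0.9),
                          seed = 1L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive")
  Bp <- as.integer(Bp)
  NI <- as.integer(NI)
  T <- as.integer(T)
  outerIters <- as.integer(outerIters)
  if (Bp < 1L || NI < 1L || T < 1L) stop("Bp, NI and T must be positive")
  if (outerIters < 0L) stop("outerIters must be >= 0")
  if (!is.null(Bs)) {
    Bs <- as.integer(Bs)
    if (Bs < Bp) stop("Bs must be at least Bp")
  }
  if (!is.finite(explorationWeight) || explorationWeight < 0) {
    stop("explorationWeight must be >= 0")
  }
  if (length(explorationRange) != 2L || explorationRange[1L] >= explorationRange[2L]) {
    stop("explorationRange must be an increasing pair")
  }
  structure(
    list(
      alpha = alpha, beta = beta, Bp = Bp, Bs = Bs, NI = NI, T = T,
      outerIters = outerIters, explorationWeight = explorationWeight,
      explorationRange = explorationRange, seed = as.integer(seed)
    ),
    class = "trainerConfig"
  )
}

#' Moving-average baseline state
#'
#' Holds the exponential moving average `delta` of the validation-loss reward
#' (initialised at 0) together with the number of updates it has absorbed.
#' Because the average starts at 0, its early values are biased towards 0 by
#' the factor `1 - ((T-1)/T)^k`; [debiasedBaseline()] removes that start-up
#' bias (the same correction Adam applies to its moment estimates) so the
#' advantage is centred from the first iterations rather than after ~T of
#' them.
#'
#' @param delta numeric initial baseline (0 at the start of training).
#' @param count integer number of baseline updates already applied.
#' @return a list of class `"rewardState"`.
#' @export
rewardState <- function(delta = 0, count = 0L) {
  stopifnot(is.finite(delta), count >= 0L)
  structure(list(delta = delta, count = as.integer(count)), class = "rewardState")
}

#' @rdname rewardState
#' @param state a `"rewardState"`.
#' @param T integer moving-average window.
#' @return `debiasedBaseline`: the bias-corrected baseline, or `NA` before
#'   the first update.
#' @export
debiasedBaseline <- function(state, T) {
  if (state$count == 0L) return(NA_real_)
  state$delta / (1 - ((T - 1) / T)^state$count)
}

#' Moving-average baseline recursion
#'
#' `delta <- ((T - 1) / T) * delta + Lbar / T`. After `k` updates with a
#' constant reward `Lbar` from `delta = 0`, the baseline equals
#' `Lbar * (1 - ((T - 1) / T)^k)` — geometric convergence to `Lbar`.
#'
#' @param delta numeric current baseline.
#' @param Lbar numeric mean validation loss of the current outer iteration.
#' @param T integer moving-average window.
#' @return the updated baseline.
#' @export
baselineUpdate <- function(delta, Lbar, T) {
  if (!is.finite(Lbar)) stop("non-finite validation loss")
  (T - 1) / T * delta + Lbar / T
}

#' Sample a Bernoulli selection vector
#'
#' Draws `s_j ~ Bernoulli(p_j)` independently. If every coordinate comes out
#' zero (which would make the weighted predictor objective undefined), the
#' draw is repeated up to 10 times and finally the maximum-probability sample
#' is force-selected.
#'
#' @param probs numeric vector strictly inside (0, 1).
#' @param seed optional integer seed.
#' @return an integer 0/1 vector of the same length.
#' @export
sampleSelection <- function(probs, seed = NULL) {
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie strictly inside (0,1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (tryi in seq_len(11L)) {
    s <- as.integer(stats::runif(length(probs)) < probs)
    if (any(s == 1L)) return(s)
    if (tryi == 11L) break
  }
  s <- integer(length(probs))
  s[which.max(probs)] <- 1L
  s
}

# REINFORCE surrogate: advantage * log pi(s), plus the exploration penalty
# keeping mean selection probability inside the responsive band.
dveSurrogateNode <- function(tape, probsNode, s, advantage, cfg) {
  sg <- adAffine(tape, adBernoulliLogProb(tape, probsNode, s), advantage)
  if (cfg$explorationWeight > 0) {
    mp <- adMeanRows(tape, probsNode)
    hi <- adRelu(tape, adAffine(tape, mp, 1, -cfg$explorationRange[2L]))
    lo <- adRelu(tape, adAffine(tape, mp, -1, cfg$explorationRange[1L]))
    pen <- adAffine(tape, adAdd(tape, hi, lo), cfg$explorationWeight)
    sg <- adAdd(tape, sg, pen)
  }
  sg
}

# TRUE when neither the advantage nor the exploration penalty contributes a
# gradient (so the DVE update can be skipped exactly)
dveUpdateIsNoop <- function(probs, advantage, cfg) {
  mp <- mean(probs)
  advantage == 0 &&
    (cfg$explorationWeight == 0 ||
       (mp >= cfg$explorationRange[1L] && mp <= cfg$explorationRange[2L]))
}

#' Selection-masked inner training of the predictor
#'
#' Runs `NI` masked gradient steps: each step draws `Bp` of the `Bs`
#' selection-batch samples and applies one Adam step on
#' `(1/Bp) * sum_m s_m * CE(f(x_m), y_m)`. Samples with `s_m = 0` contribute
#' zero gradient; a step whose draw is entirely unselected leaves the
#' parameters untouched.
#'
#' @param model a [predictorModel()] (updated in place and returned).
#' @param signalsArray numeric array `Bs x W x C`, the selection batch.
#' @param labels integer vector (0-based) of length `Bs`.
#' @param selection integer 0/1 vector of length `Bs`.
#' @param cfg a [trainerConfig()] (uses `alpha`, `Bp`, `NI`).
#' @param cache optional precomputed [predictorCache()] of `signalsArray`.
#' @return the updated model.
#' @export
innerUpdate <- function(model, signalsArray, labels, selection, cfg,
                        cache = NULL) {
  stopifnot(inherits(model, "predictorModel"), inherits(cfg, "trainerConfig"))
  Bs <- length(labels)
  if (!any(selection == 1L)) stop("empty selection; guard upstream")
  if (is.null(cache)) cache <- predictorCache(model, signalsArray)
  y1 <- labels + 1L
  Bp <- min(cfg$Bp, Bs)
  for (t in seq_len(cfg$NI)) {
    idx <- if (Bp < Bs) sample.int(Bs, Bp) else seq_len(Bs)
    w <- selection[idx]
    if (!any(w == 1L)) next # fully masked draw: parameters unchanged
    tape <- adTape(training = TRUE)
    logits <- predictorLogitsNode(tape, model, cache, idx)
    loss <- adSoftmaxCrossEntropy(tape, logits, y1[idx], as.numeric(w))
    adBackward(tape, loss)
    adamStep(model$params, cfg$alpha)
  }
  model
}

#' REINFORCE update of the data value estimator
#'
#' Given the selection batch, the drawn selection vector `s` and the mean
#' validation loss `Lbar` of the updated predictor, applies one Adam step on
#' the surrogate `(Lbar - delta) * log pi(s)`. Minimising this surrogate
#' raises the selection probability of draws whose validation loss beat the
#' moving-average baseline and lowers it otherwise; the baseline is then
#' advanced by [baselineUpdate()].
#'
#' @param model a [dveModel()] (updated in place and returned).
#' @param signalsArray numeric array `Bs x W x C`, the selection batch.
#' @param labels integer vector (0-based) of length `Bs`.
#' @param marginal numeric `Bs x K` marginal-information matrix.
#' @param s integer 0/1 selection vector of length `Bs`.
#' @param Lbar numeric finite mean validation loss.
#' @param state a [rewardState()].
#' @param cfg a [trainerConfig()] (uses `beta`, `T`).
#' @param cache optional precomputed DVE input cache of `signalsArray`.
#' @return a list with the updated `model` and `state`.
#' @export
reinforceUpdate <- function(model, signalsArray, labels, marginal, s, Lbar,
                            state, cfg, cache = NULL) {
  stopifnot(
    inherits(model, "dveModel"), inherits(state, "rewardState"),
    inherits(cfg, "trainerConfig")
  )
  if (!is.finite(Lbar)) stop("non-finite validation loss; aborting DVE update")
  base <- debiasedBaseline(state, cfg$T)
  advantage <- if (is.na(base)) 0 else Lbar - base
  if (is.null(cache)) cache <- dveInputCache(model, signalsArray)
  n <- length(labels)
  tape <- adTape(training = TRUE)
  probs <- dveProbsNode(
    tape, model, cache, seq_len(n),
    oneHot(labels, model$nClasses), marginal
  )
  if (!dveUpdateIsNoop(as.vector(probs$value), advantage, cfg)) {
    surrogate <- dveSurrogateNode(tape, probs, s, advantage, cfg)
    adBackward(tape, surrogate)
    adamStep(model$params, cfg$beta)
  }
  state$delta <- baselineUpdate(state$delta, Lbar, cfg$T)
  state$count <- state$count + 1L
  list(model = model, state = state)
}

#' Train the data valuation algorithm
#'
#' Full valuation training: pretrain the validation predictor `f_v`, compute
#' marginal information once, warm-start the task predictor on the training
#' split, then run the outer REINFORCE loop — sample a selection batch, draw
#' a Bernoulli selection from the DVE's probabilities, run `NI` masked inner
#' predictor steps, measure the mean validation loss, update the DVE against
#' the moving-average baseline, and advance the baseline. The full run is
#' reproducible from `cfg$seed`.
#'
#' @param ds a [WindowedDataset-class] with non-empty train and validation
#'   splits (training labels possibly corrupted; validation must be clean).
#' @param cfg a [trainerConfig()].
#' @param dveCfg a [dveConfig()].
#' @param predCfg a [predictorConfig()].
#' @param rewardType `"loss"` (mean validation cross-entropy, the default) or
#'   `"accuracy"` (uses `1 - accuracy` as the loss signal).
#' @param verbose logical; print per-outer-iteration reward/baseline lines.
#' @return a [ValueTable-class] with the evaluation-mode selection
#'   probability of every training window; the per-iteration history
#'   (reward, baseline, mean value) is attached as attribute `"history"`,
#'   and the trained models as attributes `"dve"`, `"predictor"` and `"fv"`.
#' @export
trainValuation <- function(ds, cfg = trainerConfig(), dveCfg = dveConfig(),
                           predCfg = predictorConfig(),
                           rewardType = c("loss", "accuracy"),
                           verbose = FALSE) {
  stopifnot(is(ds, "WindowedDataset"), inherits(cfg, "trainerConfig"))
  rewardType <- match.arg(rewardType)
  trainIdx <- which(ds@split == "train")
  valIdx <- which(ds@split == "validation")
  if (length(trainIdx) < 2L || !length(valIdx)) {
    stop("degenerate splits: need a training and a validation split")
  }
  C <- dim(ds@signals)[3L]
  K <- ds@nClasses
  Ntrain <- length(trainIdx)
  Bs <- cfg$Bs %||% min(Ntrain, 4L * cfg$Bp)
  Bs <- min(Bs, Ntrain)

  xTrain <- ds@signals[trainIdx, , , drop = FALSE]
  yTrain <- ds@labels[trainIdx]
  xVal <- ds@signals[valIdx, , , drop = FALSE]
  yVal <- ds@labels[valIdx]

  # frozen validation predictor and the marginal information it defines
  fv <- pretrainValidationPredictor(ds, predCfg, seed = childSeed(cfg$seed, 11L))
  M <- marginalInfo(fv, xTrain, yTrain)

  dve <- dveModel(C, K, dveCfg, seed = childSeed(cfg$seed, 12L))
  pred <- predictorModel(C, K, predCfg, seed = childSeed(cfg$seed, 13L))
  # warm start: the predictor pretrains once on the full training split.
  # Each outer iteration then starts the inner loop from this snapshot, so
  # the validation loss reflects the current selection only and not the
  # accumulated training of earlier iterations.
  fitWeighted(pred, xTrain, yTrain, seed = childSeed(cfg$seed, 14L))
  warmStart <- lapply(pred$params, function(p) {
    list(value = p$value, m = p$m, v = p$v, t = p$t)
  })
  restoreWarmStart <- function() {
    for (nm in names(warmStart)) {
      p <- pred$params[[nm]]
      p$value <- warmStart[[nm]]$value
      p$m <- warmStart[[nm]]$m
      p$v <- warmStart[[nm]]$v
      p$t <- warmStart[[nm]]$t
      p$grad <- NULL
    }
  }

  dveCache <- dveInputCache(dve, xTrain)
  predCache <- predictorCache(pred, xTrain)
  valCache <- predictorCache(pred, xVal)
  yOnehot <- oneHot(yTrain, K)

  valLoss <- function() {
    tape <- adTape(training = FALSE)
    z <- predictorLogitsNode(tape, pred, valCache, seq_along(valIdx))$value
    if (rewardType == "accuracy") {
      return(1 - mean(max.col(z) == yVal + 1L))
    }
    z <- z - apply(z, 1L, max)
    p <- exp(z) / rowSums(exp(z))
    mean(-log(pmax(p[cbind(seq_along(yVal), yVal + 1L)], 1e-12)))
  }

  state <- rewardState()
  hist <- matrix(NA_real_, cfg$outerIters, 3L,
    dimnames = list(NULL, c("reward", "baseline", "meanValue")))
  for (it in seq_len(cfg$outerIters)) {
    set.seed(childSeed(cfg$seed, 100L + it))
    bIdx <- if (Bs < Ntrain) sample.int(Ntrain, Bs) else sample.int(Ntrain)
    tape <- adTape(training = TRUE)
    probsNode <- dveProbsNode(
      tape, dve, dveCache, bIdx,
      yOnehot[bIdx, , drop = FALSE], M[bIdx, , drop = FALSE]
    )
    p <- clipProb(as.vector(probsNode$value))
    s <- sampleSelection(p)
    restoreWarmStart()
    # common random numbers: the inner loop draws the same mini-batch
    # sequence in every outer iteration, so differences in the validation
    # loss are driven by the selection rather than by batch noise
    set.seed(childSeed(cfg$seed, 77L))
    innerUpdate(
      pred, NULL, yTrain[bIdx], s, cfg,
      cache = subsetStackedCache(predCache, bIdx)
    )
    set.seed(childSeed(cfg$seed, 500L + it))
    Lbar <- valLoss()
    base <- debiasedBaseline(state, cfg$T)
    advantage <- if (is.na(base)) 0 else Lbar - base
    if (!dveUpdateIsNoop(p, advantage, cfg)) {
      surrogate <- dveSurrogateNode(tape, probsNode, s, advantage, cfg)
      adBackward(tape, surrogate)
      adamStep(dve$params, cfg$beta)
    }
    state$delta <- baselineUpdate(state$delta, Lbar, cfg$T)
    state$count <- state$count + 1L
    hist[it, ] <- c(Lbar, state$delta, mean(p))
    if (verbose) {
      message(sprintf(
        "outer %3d | reward %.4f | baseline %.4f | mean value %.4f",
        it, Lbar, state$delta, mean(p)
      ))
    }
  }

  finalTape <- adTape(training = FALSE)
  probs <- clipProb(as.vector(
    dveProbsNode(finalTape, dve, dveCache, seq_len(Ntrain), yOnehot, M)$value
  ))
  vt <- methods::new("ValueTable",
    probs = probs, sampleIndex = as.integer(trainIdx))
  attr(vt, "history") <- hist
  attr(vt, "dve") <- dve
  attr(vt, "predictor") <- pred
  attr(vt, "fv") <- fv
  vt
}

# restrict a stacked predictor cache to a subset of samples (keeps row order)
subsetStackedCache <- function(cache, idx) {
  W <- cache$W
  rows <- as.vector(vapply(idx, function(i) ((i - 1L) * W + 1L):(i * W),
    integer(W)))
  list(
    heads = lapply(cache$heads, function(h) h[rows, , drop = FALSE]),
    N = length(idx), W = W
  )
}
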
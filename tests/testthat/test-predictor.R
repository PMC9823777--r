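test_that("predictor probabilities are rows of a simplex", {
  set.seed(31)
  m <- predictorModel(3, 4, seed = 1)
  x <- array(rnorm(5 * 20 * 3), c(5, 20, 3))
  p <- predictProba(m, x)
  expect_equal(dim(p), c(5L, 4L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
})

test_that("the kernel-1 head is strictly local, the kernel-3 head spans 3 steps", {
  set.seed(32)
  m <- predictorModel(2, 3, seed = 2)
  W <- 12L
  x <- matrix(rnorm(W * 2), W, 2)
  convAct <- function(xm, head) {
    cache <- harvalue:::predictorCache(m, array(xm, c(1L, W, 2L)))
    pmax(cache$heads[[head]] %*% m$params[[paste0("head", head, ".W")]]$value +
      rep(m$params[[paste0("head", head, ".b")]]$value, each = W), 0)
  }
  x2 <- x
  x2[6L, ] <- x2[6L, ] + 1
  d1 <- rowSums(abs(convAct(x2, 1L) - convAct(x, 1L)))
  d3 <- rowSums(abs(convAct(x2, 2L) - convAct(x, 2L)))
  expect_true(all(d1[-6L] == 0) && d1[6L] > 0)
  expect_true(all(d3[-(5:7)] == 0) && any(d3[5:7] > 0))
})

test_that("uniform weights reproduce unweighted training exactly", {
  set.seed(33)
  n <- 12L
  x <- array(rnorm(n * 10 * 2), c(n, 10, 2))
  y <- sample(0:2, n, replace = TRUE)
  a <- predictorModel(2, 3, predictorConfig(batch = n, iterations = 3L),
    seed = 4)
  b <- predictorModel(2, 3, predictorConfig(batch = n, iterations = 3L),
    seed = 4)
  fitWeighted(a, x, y, weights = rep(1, n), seed = 5)
  fitWeighted(b, x, y, weights = NULL, seed = 5)
  for (nm in names(a$params)) {
    expect_equal(a$params[[nm]]$value, b$params[[nm]]$value,
      tolerance = 1e-10)
  }
})

test_that("a single positively weighted sample drives the first step", {
  set.seed(34)
  n <- 6L
  x <- array(rnorm(n * 10 * 2), c(n, 10, 2))
  y <- c(0L, 1L, 2L, 0L, 1L, 2L)
  w <- c(1, 0, 0, 0, 0, 0)
  a <- predictorModel(2, 3, predictorConfig(batch = n, iterations = 1L),
    seed = 6)
  b <- predictorModel(2, 3, predictorConfig(batch = 1L, iterations = 1L),
    seed = 6)
  fitWeighted(a, x, y, weights = w, seed = 7)
  fitWeighted(b, x[1L, , , drop = FALSE], y[1L], seed = 7)
  # the gradients differ by the scalar 1/n, which Adam's first step absorbs
  for (nm in names(a$params)) {
    expect_equal(a$params[[nm]]$value, b$params[[nm]]$value,
      tolerance = 1e-4)
  }
  expect_error(fitWeighted(a, x, y, weights = rep(0, n)), "empty effective")
})

test_that("weight 2 equals a duplicated sample for the first step", {
  set.seed(35)
  x1 <- array(rnorm(10 * 2), c(1, 10, 2))
  xdup <- array(0, c(2, 10, 2))
  xdup[1, , ] <- x1[1, , ]
  xdup[2, , ] <- x1[1, , ]
  a <- predictorModel(2, 3, predictorConfig(batch = 1L, iterations = 1L),
    seed = 8)
  b <- predictorModel(2, 3, predictorConfig(batch = 2L, iterations = 1L),
    seed = 8)
  fitWeighted(a, x1, 0L, weights = 2, seed = 9)
  fitWeighted(b, xdup, c(0L, 0L), weights = c(1, 1), seed = 9)
  for (nm in names(a$params)) {
    expect_equal(a$params[[nm]]$value, b$params[[nm]]$value,
      tolerance = 1e-4)
  }
})

test_that("training loss trends down on separable data", {
  drops <- vapply(1:3, function(sd) {
    ds <- tinyDataset(seed = sd, nPerClass = 10, noiseSd = 0.2)
    tr <- splits(ds) == "train"
    m <- predictorModel(3, 3,
      predictorConfig(batch = sum(tr), iterations = 10L), seed = sd)
    fitted <- fitWeighted(m, signals(ds)[tr, , ], windowLabels(ds)[tr],
      seed = sd)
    h <- attr(fitted, "lossHistory")
    h[10L] - h[1L]
  }, numeric(1))
  expect_lt(mean(drops), 0)
})

test_that("the validation predictor flags corrupted labels via marginal info", {
  ds <- normalizeDataset(generateDataset(syntheticSpec(
    nClasses = 3, nPerClass = 20, windowLen = 24, nChannels = 3,
    noiseSd = 0.1, seed = 36
  )))
  out <- corruptLabels(ds, 0.2, seed = 37)
  dsc <- out$dataset
  fv <- pretrainValidationPredictor(dsc,
    predictorConfig(iterations = 60L, batch = 16L), seed = 38)
  tr <- which(splits(dsc) == "train")
  M <- marginalInfo(fv, signals(dsc)[tr, , ], windowLabels(dsc)[tr])
  expect_true(all(M >= 0 & M <= 1))
  isC <- tr %in% corruptedIndices(out$record)
  expect_gt(mean(rowSums(M)[isC]), mean(rowSums(M)[!isC]))
  # frozen model: repeated calls agree exactly
  expect_identical(
    predictProba(fv, signals(dsc)[tr[1:3], , ]),
    predictProba(fv, signals(dsc)[tr[1:3], , ])
  )
  expect_error(
    pretrainValidationPredictor(methods::new("WindowedDataset",
      signals = signals(dsc), labels = windowLabels(dsc),
      split = rep("train", length(windowLabels(dsc))),
      nClasses = 3L, channelStats = data.frame()
    )),
    "validation split"
  )
})
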
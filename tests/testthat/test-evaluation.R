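# independent CSD oracle: build the ascending-value order by repeated
# minimum extraction (selection sort with index tie-break), then count
# corrupted members in each prefix
csdOracle <- function(vals, idx, corrupted, stepFraction, nSteps) {
  remaining <- seq_along(vals)
  ord <- integer(0)
  while (length(remaining)) {
    best <- remaining[which.min(vals[remaining])]
    ord <- c(ord, best)
    remaining <- setdiff(remaining, best)
  }
  v <- round(stepFraction * length(vals))
  vapply(0:nSteps, function(r) {
    take <- min(v * r, length(vals))
    sum(idx[ord[seq_len(take)]] %in% corrupted) / length(corrupted)
  }, numeric(1))
}

test_that("CSD matches hand enumeration when corrupted samples rank lowest", {
  N <- 20L
  vals <- seq(0.1, 0.9, length.out = N)
  idx <- seq_len(N)
  corrupted <- 1:4 # the four smallest values
  vt <- methods::new("ValueTable", probs = vals, sampleIndex = idx)
  rec <- methods::new("CorruptionRecord", indices = corrupted,
    originalLabels = rep(0L, 4L), rate = 0.2, seed = 1L)
  cur <- csd(vt, rec) # v = round(0.05 * 20) = 1
  expect_equal(discovery(cur), c(0, 0.25, 0.5, 0.75, 1, 1, 1, 1, 1, 1, 1))
  expect_equal(removalFractions(cur), seq(0, 0.5, by = 0.05))
  expect_equal(cur@optimal, pmin((0:10) * 1 / 4, 1))
})

test_that("CSD agrees exactly with a brute-force oracle on random configs", {
  set.seed(61)
  for (i in 1:200) {
    N <- sample(10:40, 1)
    o <- sample(2:max(2, N %/% 4), 1)
    vals <- round(runif(N), 2) # coarse grid forces ties
    idx <- sample(1000L, N) # arbitrary dataset indices
    corrupted <- sample(idx, o)
    vt <- methods::new("ValueTable",
      probs = pmin(pmax(vals, 0.01), 0.99), sampleIndex = idx)
    rec <- methods::new("CorruptionRecord", indices = corrupted,
      originalLabels = integer(o), rate = o / N, seed = 1L)
    cur <- csd(vt, rec, stepFraction = 0.1, nSteps = 10L)
    expect_identical(
      discovery(cur),
      csdOracle(pmin(pmax(vals, 0.01), 0.99), idx, corrupted, 0.1, 10L)
    )
  }
})

test_that("CSD is a rank statistic: invariant to monotone value transforms", {
  set.seed(62)
  N <- 30L
  vals <- runif(N, 0.05, 0.95)
  idx <- seq_len(N)
  rec <- methods::new("CorruptionRecord", indices = sample(N, 6L),
    originalLabels = integer(6L), rate = 0.2, seed = 1L)
  vt1 <- methods::new("ValueTable", probs = vals, sampleIndex = idx)
  vt2 <- methods::new("ValueTable", probs = vals^3, sampleIndex = idx)
  vt3 <- methods::new("ValueTable", probs = plogis(5 * (vals - 0.5)),
    sampleIndex = idx)
  expect_identical(discovery(csd(vt1, rec)), discovery(csd(vt2, rec)))
  expect_identical(discovery(csd(vt1, rec)), discovery(csd(vt3, rec)))
})

test_that("the optimal curve saturates once v*r reaches the corruption count", {
  N <- 100L
  o <- 20L # corruption rate 0.2
  vt <- methods::new("ValueTable", probs = runif(N, 0.1, 0.9),
    sampleIndex = seq_len(N))
  rec <- methods::new("CorruptionRecord", indices = sample(N, o),
    originalLabels = integer(o), rate = 0.2, seed = 1L)
  cur <- csd(vt, rec)
  expect_equal(cur@optimal, pmin(5 * (0:10) / 20, 1))
  expect_equal(cur@optimal[5L], 1) # r = 4: v*r = 20 = o
  expect_true(all(discovery(cur) <= cur@optimal + 1e-12))
  # and an error when there is nothing to discover
  empty <- methods::new("CorruptionRecord", indices = integer(),
    originalLabels = integer(), rate = 0, seed = 1L)
  expect_error(csd(vt, empty), "no corruption")
})

test_that("classifier variants carry their documented hyperparameters", {
  bbs <- classifierSpec("bbs_model")
  base <- classifierSpec("public_baseline")
  cplx <- classifierSpec("public_complex")
  expect_equal(bbs$dropout, 0.5)
  expect_equal(cplx$dropout, 0.7)
  expect_equal(base$gruUnits, 0L)
  expect_equal(bbs$gruUnits, 8L)
  expect_equal(cplx$gruUnits, 8L)
  for (sp in list(bbs, base, cplx)) {
    expect_equal(sp$convFilters, 64L)
    expect_equal(sp$convKernel, 3L)
    expect_equal(sp$poolSize, 2L)
    expect_equal(sp$denseUnits, 100L)
  }
  expect_error(classifierSpec("lstm_model"))
  set.seed(63)
  x <- array(rnorm(3 * 16 * 2), c(3, 16, 2))
  for (v in c("bbs_model", "public_baseline", "public_complex")) {
    cl <- buildClassifier(classifierSpec(v), 3, 2, 16, seed = 1)
    p <- predictClassifier(cl, x)
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("RHLVS starts both curves at the same point and is deterministic", {
  ds <- tinyDataset(seed = 64, nPerClass = 10)
  tr <- which(splits(ds) == "train")
  set.seed(65)
  vt <- methods::new("ValueTable",
    probs = runif(length(tr), 0.2, 0.8), sampleIndex = tr)
  cur1 <- rhlvs(ds, vt, classifierSpec("public_baseline"),
    nSteps = 3L, seed = 66, iterations = 8L, batch = 8L)
  cur2 <- rhlvs(ds, vt, classifierSpec("public_baseline"),
    nSteps = 3L, seed = 66, iterations = 8L, batch = 8L)
  expect_equal(cur1@removeHighAcc[1L], cur1@removeLowAcc[1L])
  expect_identical(cur1@removeHighAcc, cur2@removeHighAcc)
  expect_identical(cur1@removeLowAcc, cur2@removeLowAcc)
  expect_true(all(cur1@removeHighAcc >= 0 & cur1@removeHighAcc <= 1))
})

test_that("RHLVS truncates with a warning when removal would empty the split", {
  ds <- tinyDataset(seed = 67)
  tr <- which(splits(ds) == "train")
  vt <- methods::new("ValueTable",
    probs = seq(0.2, 0.8, length.out = length(tr)), sampleIndex = tr)
  expect_warning(
    cur <- rhlvs(ds, vt, classifierSpec("public_baseline"),
      stepFraction = 0.4, nSteps = 5L, seed = 68, iterations = 4L,
      batch = 8L),
    "empty"
  )
  expect_lt(length(removalFractions(cur)), 6L)
})
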
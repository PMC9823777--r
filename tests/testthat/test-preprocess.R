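test_that("sliding-window count and starts match the closed form", {
  set.seed(11)
  x <- matrix(rnorm(256 * 3), 256, 3)
  lab <- rep(0L, 256)
  out <- slideWindows(x, lab, windowingConfig(128, 0.5))
  expect_equal(dim(out$windows)[1L], 3L) # floor((256-128)/64)+1
  expect_equal(out$starts, c(0L, 64L, 128L))
  expect_equal(out$windows[2L, , ], x[65:192, ])

  # L == W gives exactly one window
  one <- slideWindows(x[1:128, ], lab[1:128], windowingConfig(128, 0.5))
  expect_equal(dim(one$windows)[1L], 1L)

  # the 20 Hz accelerometer configuration: window 80, 50% overlap, stride 40
  cfg80 <- windowingConfig(80, 0.5)
  expect_equal(cfg80$stride, 40L)

  # property sweep of the count formula
  for (i in 1:20) {
    L <- sample(64:400, 1)
    Wl <- sample(16:64, 1)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    cfg <- windowingConfig(Wl, ov)
    n <- dim(slideWindows(matrix(0, L, 1), rep(0L, L), cfg)$windows)[1L]
    expect_equal(n, (L - Wl) %/% cfg$stride + 1L)
  }
})

test_that("window labels use majority vote with midpoint tie-break", {
  x <- matrix(0, 8, 1)
  lab <- c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L) # 4 vs 4 tie, midpoint (t=4) is 1
  out <- slideWindows(x, lab, windowingConfig(8, 0))
  expect_equal(out$labels, 1L)
  lab2 <- c(0L, 0L, 0L, 0L, 1L, 0L, 1L, 1L) # clear majority 0
  expect_equal(slideWindows(x, lab2, windowingConfig(8, 0))$labels, 0L)
})

test_that("short recordings error unless padTo is set, then zero-pad first", {
  x <- matrix(1, 10, 2)
  expect_error(slideWindows(x, rep(0L, 10), windowingConfig(16, 0.5)),
    "padTo")
  out <- slideWindows(x, rep(0L, 10), windowingConfig(16, 0.5, padTo = 16))
  expect_equal(dim(out$windows), c(1L, 16L, 2L))
  expect_equal(out$windows[1L, 11:16, ], matrix(0, 6, 2))
})

test_that("zero padding appends zeros, preserves content, refuses truncation", {
  set.seed(12)
  w <- matrix(rnorm(50 * 3), 50, 3)
  p <- zeroPad(w, 100)
  expect_equal(dim(p), c(100L, 3L))
  expect_equal(p[51:100, ], matrix(0, 50, 3))
  expect_equal(sum(p), sum(w)) # conservation
  expect_identical(zeroPad(w, 50), w)
  expect_error(zeroPad(w, 40), "truncate")
})

test_that("normalisation uses training statistics only and is idempotent", {
  ds <- generateDataset(tinySpec(seed = 13))
  nds <- normalizeDataset(ds)
  tr <- splits(ds) == "train"
  for (c0 in seq_len(dim(signals(ds))[3L])) {
    expect_lt(abs(mean(signals(nds)[tr, , c0])), 1e-6)
    expect_lt(abs(stats::sd(as.vector(signals(nds)[tr, , c0])) - 1), 1e-6)
  }
  # held-out data transformed with the stored statistics equals the manual
  # z-score, checked on a 3-sample fixture
  st <- channelStats(nds)
  hold <- signals(ds)[1:3, , , drop = FALSE]
  man <- hold
  for (c0 in seq_len(dim(hold)[3L])) {
    man[, , c0] <- (hold[, , c0] - st$mean[c0]) / st$sd[c0]
  }
  expect_equal(applyChannelStats(hold, st), man)
  # re-applying the stored stats to already-normalised data changes nothing
  renorm <- applyChannelStats(signals(nds),
    data.frame(mean = rep(0, nrow(st)), sd = rep(1, nrow(st))))
  expect_equal(renorm, signals(nds), tolerance = 1e-6)
})

test_that("a constant channel normalises to zeros with a warning", {
  ds <- generateDataset(tinySpec(seed = 14))
  sig <- signals(ds)
  sig[, , 2L] <- 3.14
  flat <- methods::new("WindowedDataset",
    signals = sig, labels = windowLabels(ds), split = splits(ds),
    nClasses = nClasses(ds), channelStats = data.frame()
  )
  expect_warning(nds <- normalizeDataset(flat), "zero variance")
  expect_true(all(signals(nds)[, , 2L] == 0))
})

test_that("oversampling equalises training class counts; jitter 0 copies", {
  ds <- tinyDataset(seed = 15, nPerClass = 12)
  # unbalance the training split by relabelling a few training windows
  tr <- which(splits(ds) == "train")
  lab <- windowLabels(ds)
  lab[tr[lab[tr] == 2L][1:3]] <- 0L
  ub <- methods::new("WindowedDataset",
    signals = signals(ds), labels = lab, split = splits(ds),
    nClasses = nClasses(ds), channelStats = channelStats(ds)
  )
  target <- max(table(lab[tr])) + 2L
  aug <- oversampleAugment(ub, target, jitterSd = 0.1, seed = 16)
  newTr <- splits(aug) == "train"
  expect_true(all(table(windowLabels(aug)[newTr]) == target))
  # validation/test untouched
  expect_identical(
    windowLabels(aug)[splits(aug) != "train"],
    lab[splits(ub) != "train"]
  )
  # jitter 0 duplicates exactly: every added window equals some original
  aug0 <- oversampleAugment(ub, target, jitterSd = 0, seed = 16)
  added <- which(seq_along(windowLabels(aug0)) > length(lab))
  orig <- matrix(signals(ub), dim(signals(ub))[1L])
  for (i in added[1:2]) {
    expect_true(any(apply(orig, 1L, function(r) {
      isTRUE(all.equal(r, as.vector(signals(aug0)[i, , ])))
    })))
  }
  expect_warning(oversampleAugment(ub, 1L), "no-op")
})

test_that("decimation keeps every k-th timestep", {
  x <- matrix(seq_len(20), 10, 2)
  expect_equal(decimateSeries(x, 2), x[c(1, 3, 5, 7, 9), ])
  expect_identical(decimateSeries(x, 1), x)
})
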
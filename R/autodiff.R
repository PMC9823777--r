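# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape records each operation as a node (an environment holding the forward
# value, an accumulated gradient slot, and a backward closure). adBackward()
# walks the tape in reverse creation order, so gradients reach every trainable
# parameter that participated in the forward pass. The engine is deliberately
# small: only the primitives the valuation networks need are implemented, and
# each backward rule is exercised against central finite differences in the
# test suite.

.adCounter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

#' @noRd
adTape <- function(training = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp$leaves <- new.env(parent = emptyenv())
  tp$training <- isTRUE(training)
  tp
}

adPush <- function(tape, value, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$bw <- bw
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

adAccum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' @noRd
adBackward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  # deposit gradients on the parameter objects behind the leaf nodes
  for (id in ls(tape$leaves)) {
    lf <- get(id, envir = tape$leaves)
    g <- lf$grad
    if (is.null(g)) g <- matrix(0, nrow(lf$value), ncol(lf$value))
    p <- lf$param
    if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  }
  invisible(NULL)
}

# ---- leaves -----------------------------------------------------------------

#' Trainable parameter: a matrix plus Adam state.
#' @noRd
newParam <- function(value, name = "p") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- matrix(0, nrow(value), ncol(value))
  p$v <- matrix(0, nrow(value), ncol(value))
  p$t <- 0L
  p$id <- paste0(name, "#", .adCounter())
  p
}

adLeaf <- function(tape, p) {
  cached <- tape$leaves[[p$id]]
  if (!is.null(cached)) return(cached)
  nd <- adPush(tape, p$value)
  nd$param <- p
  assign(p$id, nd, envir = tape$leaves)
  nd
}

adConst <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  adPush(tape, x)
}

# ---- arithmetic -------------------------------------------------------------

adMatmul <- function(tape, a, b) {
  adPush(tape, a$value %*% b$value, bw = function(g) {
    adAccum(a, g %*% t(b$value))
    adAccum(b, crossprod(a$value, g))
  })
}

# a + b with row-vector broadcasting in either argument (bias addition)
adAdd <- function(tape, a, b) {
  av <- a$value
  bv <- b$value
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    v <- av + rep(bv, each = nrow(av))
    adPush(tape, v, bw = function(g) {
      adAccum(a, g)
      adAccum(b, matrix(colSums(g), 1L))
    })
  } else if (nrow(av) == 1L && nrow(bv) > 1L) {
    v <- bv + rep(av, each = nrow(bv))
    adPush(tape, v, bw = function(g) {
      adAccum(b, g)
      adAccum(a, matrix(colSums(g), 1L))
    })
  } else {
    adPush(tape, av + bv, bw = function(g) {
      adAccum(a, g)
      adAccum(b, g)
    })
  }
}

# elementwise product, equal shapes
adMul <- function(tape, a, b) {
  adPush(tape, a$value * b$value, bw = function(g) {
    adAccum(a, g * b$value)
    adAccum(b, g * a$value)
  })
}

# a * mult + shift with scalar constants
adAffine <- function(tape, a, mult = 1, shift = 0) {
  adPush(tape, a$value * mult + shift, bw = function(g) adAccum(a, g * mult))
}

adSum <- function(tape, a) {
  nr <- nrow(a$value)
  nc <- ncol(a$value)
  adPush(tape, matrix(sum(a$value), 1L, 1L), bw = function(g) {
    adAccum(a, matrix(g[1L], nr, nc))
  })
}

adTranspose <- function(tape, a) {
  adPush(tape, t(a$value), bw = function(g) adAccum(a, t(g)))
}

# ---- activations ------------------------------------------------------------

adRelu <- function(tape, a) {
  x <- a$value
  adPush(tape, pmax(x, 0), bw = function(g) adAccum(a, g * (x > 0)))
}

# exact GeLU: x * Phi(x)
adGelu <- function(tape, a) {
  x <- a$value
  px <- stats::pnorm(x)
  adPush(tape, x * px, bw = function(g) {
    adAccum(a, g * (px + x * stats::dnorm(x)))
  })
}

adSigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  adPush(tape, s, bw = function(g) adAccum(a, g * s * (1 - s)))
}

adTanh <- function(tape, a) {
  v <- tanh(a$value)
  adPush(tape, v, bw = function(g) adAccum(a, g * (1 - v * v)))
}

adSoftmaxRows <- function(tape, a) {
  x <- a$value
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  s <- e / rowSums(e)
  adPush(tape, s, bw = function(g) {
    adAccum(a, s * (g - rowSums(g * s)))
  })
}

# ---- normalisation & dropout ------------------------------------------------

# per-row layer normalisation with learned gain/bias (1 x d parameters)
adLayerNorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- gamma$value
  v <- xhat * rep(gv, each = nrow(x)) + rep(beta$value, each = nrow(x))
  adPush(tape, v, bw = function(g) {
    dxhat <- g * rep(gv, each = nrow(g))
    # standard layernorm backward, vectorised over rows
    t1 <- rowSums(dxhat)
    t2 <- rowSums(dxhat * xhat)
    dx <- (dxhat - (t1 + xhat * t2) / d) * istd
    adAccum(a, dx)
    adAccum(gamma, matrix(colSums(g * xhat), 1L))
    adAccum(beta, matrix(colSums(g), 1L))
  })
}

# inverted dropout; identity when the tape is in evaluation mode
adDropout <- function(tape, a, rate) {
  if (!tape$training || rate <= 0) return(a)
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) < keep) / keep
  adPush(tape, a$value * mask, bw = function(g) adAccum(a, g * mask))
}

# ---- shape ops --------------------------------------------------------------

adConcatCols <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  adPush(tape, do.call(cbind, vals), bw = function(g) {
    for (i in seq_along(nodes)) {
      adAccum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

adConcatRows <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  hs <- vapply(vals, nrow, 1L)
  ends <- cumsum(hs)
  starts <- ends - hs + 1L
  adPush(tape, do.call(rbind, vals), bw = function(g) {
    for (i in seq_along(nodes)) {
      adAccum(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

adSliceCols <- function(tape, a, idx) {
  nr <- nrow(a$value)
  nc <- ncol(a$value)
  adPush(tape, a$value[, idx, drop = FALSE], bw = function(g) {
    gm <- matrix(0, nr, nc)
    gm[, idx] <- g
    adAccum(a, gm)
  })
}

# row gather; idx may repeat (backward scatter-adds)
adGatherRows <- function(tape, a, idx) {
  nr <- nrow(a$value)
  nc <- ncol(a$value)
  adPush(tape, a$value[idx, , drop = FALSE], bw = function(g) {
    gm <- matrix(0, nr, nc)
    agg <- rowsum(g, group = idx, reorder = TRUE)
    gm[as.integer(rownames(agg)), ] <- agg
    adAccum(a, gm)
  })
}

# mean over rows -> 1 x d (global average pooling over time)
adMeanRows <- function(tape, a) {
  nr <- nrow(a$value)
  adPush(tape, matrix(colMeans(a$value), 1L), bw = function(g) {
    adAccum(a, matrix(g / nr, nr, ncol(g), byrow = TRUE))
  })
}

# column-wise max within consecutive groups of `groupLen` rows:
# (B*W) x F stacked sample-major -> B x F (global max pooling per sample)
adMaxGroups <- function(tape, a, groupLen) {
  x <- a$value
  nr <- nrow(x)
  nc <- ncol(x)
  B <- nr %/% groupLen
  arr <- array(x, c(groupLen, B, nc))
  v <- apply(arr, c(2L, 3L), max)
  am <- apply(arr, c(2L, 3L), which.max) # local row of the max
  adPush(tape, v, bw = function(g) {
    gm <- matrix(0, nr, nc)
    rows <- (rep(seq_len(B), nc) - 1L) * groupLen + as.vector(am)
    cols <- rep(seq_len(nc), each = B)
    gm[cbind(rows, cols)] <- as.vector(g)
    adAccum(a, gm)
  })
}

# pairwise temporal max-pool (pool size 2) on a sample-stacked matrix;
# requires an even number of rows per sample
adPoolPairs <- function(tape, a) {
  x <- a$value
  nr <- nrow(x)
  stopifnot(nr %% 2L == 0L)
  o <- x[seq(1L, nr, 2L), , drop = FALSE]
  e <- x[seq(2L, nr, 2L), , drop = FALSE]
  takeOdd <- o >= e
  adPush(tape, pmax(o, e), bw = function(g) {
    gm <- matrix(0, nr, ncol(x))
    gm[seq(1L, nr, 2L), ] <- g * takeOdd
    gm[seq(2L, nr, 2L), ] <- g * !takeOdd
    adAccum(a, gm)
  })
}

# ---- convolution helpers ----------------------------------------------------

# Row-index plan for a 'same'-padded kernel-k 1D convolution over a matrix of
# B stacked samples, each W rows. Column block o of the im2col output holds the
# input shifted by (o - pad - 1) timesteps, zero outside each sample.
im2colPlan <- function(B, W, k) {
  pad <- (k - 1L) %/% 2L
  zeroRow <- B * W + 1L # index of an all-zero guard row
  lapply(seq_len(k), function(o) {
    d <- o - pad - 1L
    w <- seq_len(W) + d
    bad <- w < 1L | w > W
    w[bad] <- 1L
    idx <- rep((seq_len(B) - 1L) * W, each = W) + rep(w, times = B)
    idx[rep(bad, times = B)] <- zeroRow
    idx
  })
}

# numeric (non-tape) im2col of a stacked matrix, for constant inputs
im2colNumeric <- function(x, B, W, k) {
  plan <- im2colPlan(B, W, k)
  xp <- rbind(x, 0)
  do.call(cbind, lapply(plan, function(idx) xp[idx, , drop = FALSE]))
}

# tape version for hidden layers
adIm2col <- function(tape, a, B, W, k) {
  plan <- im2colPlan(B, W, k)
  nc <- ncol(a$value)
  nr <- nrow(a$value)
  xp <- rbind(a$value, 0)
  v <- do.call(cbind, lapply(plan, function(idx) xp[idx, , drop = FALSE]))
  adPush(tape, v, bw = function(g) {
    gm <- matrix(0, nr + 1L, nc)
    for (o in seq_along(plan)) {
      blk <- g[, ((o - 1L) * nc + 1L):(o * nc), drop = FALSE]
      agg <- rowsum(blk, group = plan[[o]], reorder = TRUE)
      rws <- as.integer(rownames(agg))
      gm[rws, ] <- gm[rws, ] + agg
    }
    adAccum(a, gm[seq_len(nr), , drop = FALSE])
  })
}

# flatten a sample-stacked (B*W) x F matrix into B x (W*F)
adFlattenStack <- function(tape, a, B) {
  x <- a$value
  W <- nrow(x) %/% B
  Fc <- ncol(x)
  srcIdx <- matrix(
    aperm(array(seq_along(x), c(W, B, Fc)), c(2L, 1L, 3L)),
    B, W * Fc
  )
  adPush(tape, matrix(x[srcIdx], B, W * Fc), bw = function(g) {
    gm <- numeric(length(x))
    gm[as.vector(srcIdx)] <- as.vector(g)
    adAccum(a, matrix(gm, nrow(x), Fc))
  })
}

# ---- fused losses -----------------------------------------------------------

# mean weighted softmax cross-entropy over a batch of logits.
# y is a 1-based integer class vector; w a non-negative weight per row.
# Value = (1/B) * sum_i w_i * CE_i  (normalisation by batch size, not sum(w)).
adSoftmaxCrossEntropy <- function(tape, logits, y, w = NULL) {
  x <- logits$value
  B <- nrow(x)
  if (is.null(w)) w <- rep(1, B)
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  p <- e / rowSums(e)
  py <- pmax(p[cbind(seq_len(B), y)], 1e-12)
  v <- sum(w * -log(py)) / B
  adPush(tape, matrix(v, 1L, 1L), bw = function(g) {
    d <- p
    d[cbind(seq_len(B), y)] <- d[cbind(seq_len(B), y)] - 1
    adAccum(logits, g[1L] * d * (w / B))
  })
}

# Bernoulli selection log-likelihood sum_i [s_i log p_i + (1-s_i) log(1-p_i)]
# with the package-wide probability clipping applied to the forward value.
adBernoulliLogProb <- function(tape, pnode, s) {
  p <- clipProb(pnode$value)
  s <- as.numeric(s)
  v <- sum(s * log(p) + (1 - s) * log(1 - p))
  adPush(tape, matrix(v, 1L, 1L), bw = function(g) {
    adAccum(pnode, matrix(g[1L] * (s / p - (1 - s) / (1 - p)), nrow(pnode$value)))
  })
}

# ---- optimiser --------------------------------------------------------------

#' One Adam update over a list of parameters, consuming their gradients.
#' @noRd
adamStep <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    p$t <- p$t + 1L
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^p$t)
    vhat <- p$v / (1 - beta2^p$t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

zeroGrads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Glorot-uniform initialisation
glorot <- function(fanIn, fanOut, name = "w") {
  l <- sqrt(6 / (fanIn + fanOut))
  newParam(matrix(stats::runif(fanIn * fanOut, -l, l), fanIn, fanOut), name)
}

zeros <- function(nr, nc, name = "b") newParam(matrix(0, nr, nc), name)
ones <- function(nr, nc, name = "g") newParam(matrix(1, nr, nc), name)
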
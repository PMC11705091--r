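gatFixture <- function(n = 12, dIn = 6, seed = 9) {
  set.seed(seed)
  x <- matrix(rnorm(n * dIn), n)
  g <- buildCellGraph(x, kNeighbors = 3, t = 2)
  edges <- zigacl:::graphEdges(g)
  cfg <- gatConfig(dims = c(dIn, 5, 4, 3), lambda = 0.4, k = 3)
  set.seed(seed + 1)
  w <- zigacl:::gatInitWeights(cfg)
  hList <- list(matrix(rnorm(n * 5), n), matrix(rnorm(n * 4), n),
                matrix(rnorm(n * 3), n))
  list(x = x, g = g, edges = edges, cfg = cfg, w = w, hList = hList, n = n)
}

test_that("attention scores follow a^T [W x_i || W x_j]", {
  # hand-computed 2-node toy
  x <- rbind(c(1, 2), c(3, -1))
  W <- rbind(c(1, 0), c(1, 1))
  a1 <- c(0.5, -1); a2 <- c(2, 0.25)
  edges <- list(ei = c(1L, 1L, 2L, 2L), ej = c(1L, 2L, 1L, 2L),
                R = rep(1, 4), n = 2L)
  f <- zigacl:::gatLayerForward(x, W, a1, a2, edges, slope = 0.2)
  # P = x W^T: P1 = (1, 3), P2 = (3, 2)
  # c_12 = a1.P1 + a2.P2 = (0.5 - 3) + (6 + 0.5) = 4
  expect_equal(f$cEdge[2], 0.5 * 1 - 1 * 3 + 2 * 3 + 0.25 * 2)
  # zero attention vector kills every score
  f0 <- zigacl:::gatLayerForward(x, W, a1 * 0, a2 * 0, edges, slope = 0.2)
  expect_true(all(f0$cEdge == 0))
  # identical inputs make scores symmetric
  fx <- gatFixture()
  xSame <- matrix(rep(fx$x[1, ], each = fx$n), fx$n)
  fs <- zigacl:::gatLayerForward(xSame, diag(6)[1:5, ],
                                 runif(5), runif(5), fx$edges, 0.2)
  ij <- paste(fx$edges$ei, fx$edges$ej)
  ji <- paste(fx$edges$ej, fx$edges$ei)
  expect_equal(fs$cEdge, fs$cEdge[match(ij, ji)])
})

test_that("attention coefficients are a topology-weighted neighbour softmax", {
  # single neighbour => coefficient 1
  expect_equal(zigacl:::edgeSoftmax(c(1.7), c(1L), 1L), 1)
  # equal scores => uniform over the neighbourhood
  expect_equal(zigacl:::edgeSoftmax(rep(2, 3), rep(1L, 3), 1L), rep(1/3, 3))
  # derived 3-neighbour case: e = R * LeakyReLU(c)
  R <- c(0.5, 0.25, 0.25); lc <- c(1, 1, -2)
  e <- R * lc
  expected <- exp(e) / sum(exp(e))
  expect_equal(zigacl:::edgeSoftmax(e, rep(1L, 3), 1L), expected)
  # rows sum to one on a real graph forward pass
  fx <- gatFixture()
  f <- zigacl:::gatLayerForward(fx$x, fx$w$W1, fx$w$a1_1, fx$w$a2_1,
                                fx$edges, 0.2)
  sums <- tapply(f$alpha, fx$edges$ei, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(f$alpha >= 0))
})

test_that("layer aggregation equals a brute-force triple loop", {
  fx <- gatFixture(n = 25)
  f <- zigacl:::gatLayerForward(fx$x, fx$w$W1, fx$w$a1_1, fx$w$a2_1,
                                fx$edges, 0.2)
  n <- fx$n; dOut <- nrow(fx$w$W1)
  out <- matrix(0, 25, dOut)
  for (i in 1:25) {
    acc <- numeric(dOut)
    for (e in which(fx$edges$ei == i)) {
      j <- fx$edges$ej[e]
      wz <- as.numeric(fx$w$W1 %*% fx$x[j, ])
      acc <- acc + f$alpha[e] * wz
    }
    out[i, ] <- ifelse(acc > 0, acc, 0.2 * acc)
  }
  expect_equal(unname(f$out), out, tolerance = 1e-6)
})

test_that("fusion interpolates and respects its endpoints", {
  z <- matrix(rnorm(12), 4)
  h <- matrix(rnorm(12), 4)
  expect_identical(fuseRepresentations(z, h, 0), z)
  expect_identical(fuseRepresentations(z, h, 1), h)
  expect_equal(fuseRepresentations(matrix(0, 2, 2), matrix(1, 2, 2), 0.4),
               matrix(0.4, 2, 2))
  fz <- fuseRepresentations(z, h, 0.3)
  expect_true(all(fz >= pmin(z, h) - 1e-12 & fz <= pmax(z, h) + 1e-12))
  expect_error(fuseRepresentations(z, h[1:2, ], 0.5), "shape")
  expect_error(fuseRepresentations(z, h, 1.2), "lambda")
})

test_that("the k-way head is a row softmax with the expected limits", {
  fx <- gatFixture()
  w <- fx$w
  w$Wh <- w$Wh * 0; w$bh <- w$bh * 0
  f <- zigacl:::gatForwardFull(w, fx$x, fx$hList, fx$edges, fx$cfg)
  expect_equal(unname(f$z), matrix(1/3, fx$n, 3))
  # saturated logits approach one-hot rows
  logits <- matrix(0, 4, 3); logits[cbind(1:4, c(1, 3, 2, 1))] <- 100
  sm <- zigacl:::rowSoftmax(logits)
  expect_equal(sm[cbind(1:4, c(1, 3, 2, 1))], rep(1, 4), tolerance = 1e-6)
  f2 <- zigacl:::gatForwardFull(fx$w, fx$x, fx$hList, fx$edges, fx$cfg)
  expect_true(all(abs(rowSums(f2$z) - 1) < 1e-6))
})

test_that("lambda = 1 short-circuits the GAT to the encoder path", {
  fx <- gatFixture()
  cfg1 <- fx$cfg; cfg1$lambda <- 1
  f <- zigacl:::gatForwardFull(fx$w, fx$x, fx$hList, fx$edges, cfg1)
  expect_identical(f$headIn, fx$hList[[3]])
})

test_that("GAT backprop matches finite differences end to end", {
  fx <- gatFixture()
  p <- t(apply(matrix(runif(fx$n * 3), fx$n), 1, function(r) r / sum(r)))
  lossFn <- function(w) {
    f <- zigacl:::gatForwardFull(w, fx$x, fx$hList, fx$edges, fx$cfg)
    klDivergence(p, f$z)
  }
  f <- zigacl:::gatForwardFull(fx$w, fx$x, fx$hList, fx$edges, fx$cfg)
  bk <- zigacl:::gatBackwardFull(fx$w, f, fx$edges, fx$cfg,
                                 (f$z - p) / fx$n)
  for (nm in names(fx$w)) {
    gn <- numGrad(function(pp) { w2 <- fx$w; w2[[nm]] <- pp; lossFn(w2) },
                  fx$w[[nm]], 1e-6)
    expect_lt(relErr(bk$grads[[nm]], gn), 1e-4)
  }
  for (l in 1:3) {
    gn <- numGrad(function(hp) {
      h2 <- fx$hList; h2[[l]] <- hp
      f <- zigacl:::gatForwardFull(fx$w, fx$x, h2, fx$edges, fx$cfg)
      klDivergence(p, f$z)
    }, fx$hList[[l]], 1e-6)
    expect_lt(relErr(bk$dH[[l]], gn), 1e-4)
  }
})
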
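aeFixture <- function(seed = 3) {
  n <- 7; d <- 5; m <- 5
  cfg <- encoderConfig(inputDim = d, hiddenDims = c(4, 3), latentDim = 2,
                       noiseSigma = 0, batchNorm = TRUE)
  set.seed(seed)
  w <- zigacl:::aeInitWeights(cfg, m)
  # lift biases off the ReLU kinks so finite differences are clean
  w <- lapply(w, function(p) if (is.matrix(p)) p else p + 0.05)
  bn <- zigacl:::aeInitBnStats(cfg)
  list(cfg = cfg, w = w, bn = bn, x = matrix(rnorm(n * d), n),
       counts = matrix(rpois(n * m, 2), n), sf = runif(n, .5, 2))
}

test_that("eval mode ignores the noise layer; training noise is seeded", {
  fx <- aeFixture()
  cfgNoisy <- fx$cfg; cfgNoisy$noiseSigma <- 2
  e1 <- zigacl:::aeForward(fx$w, fx$bn, fx$x, fx$sf, fx$cfg, training = FALSE)
  e2 <- zigacl:::aeForward(fx$w, fx$bn, fx$x, fx$sf, cfgNoisy, training = FALSE)
  expect_identical(e1$h, e2$h)
  set.seed(9)
  t1 <- zigacl:::aeForward(fx$w, fx$bn, fx$x, fx$sf, cfgNoisy, training = TRUE)
  set.seed(9)
  t2 <- zigacl:::aeForward(fx$w, fx$bn, fx$x, fx$sf, cfgNoisy, training = TRUE)
  expect_identical(t1$h, t2$h)
  expect_false(identical(t1$h, e1$h))
})

test_that("zeroed decoder heads give pi = 1/2, mu = size factor, theta = 1", {
  fx <- aeFixture()
  w0 <- lapply(fx$w, function(p) p * 0)
  f <- zigacl:::aeForward(w0, fx$bn, fx$x, fx$sf, fx$cfg, training = FALSE)
  expect_true(all(abs(f$pi - 0.5) < 1e-12))
  expect_equal(unname(f$mu), matrix(fx$sf, nrow(fx$x), 5))
  expect_true(all(f$theta == 1))
})

test_that("extreme dispersion pre-activations hit the upper clamp", {
  fx <- aeFixture()
  w <- lapply(fx$w, function(p) p * 0)
  w$bth[] <- 100
  f <- zigacl:::aeForward(w, fx$bn, fx$x, fx$sf, fx$cfg, training = FALSE)
  expect_true(all(f$theta == 1e4))
  expect_true(all(f$thMask == 0))   # clamped entries carry no gradient
})

test_that("analytic backprop matches finite differences, including the
           gradient injections used by the joint objective", {
  fx <- aeFixture()
  lossFn <- function(w) {
    f <- zigacl:::aeForward(w, fx$bn, fx$x, fx$sf, fx$cfg, training = TRUE)
    zinbNLL(fx$counts, f$pi, f$mu, f$theta)
  }
  f <- zigacl:::aeForward(fx$w, fx$bn, fx$x, fx$sf, fx$cfg, training = TRUE)
  zg <- zigacl:::zinbNLLGrad(fx$counts, f$pi, f$mu, f$theta)
  g <- zigacl:::aeBackward(fx$w, f, fx$cfg, gPi = zg$dpi, gMu = zg$dmu,
                           gTheta = zg$dtheta)
  for (nm in names(fx$w)) {
    gn <- numGrad(function(p) { w2 <- fx$w; w2[[nm]] <- p; lossFn(w2) },
                  fx$w[[nm]])
    expect_lt(relErr(g[[nm]], gn), 1e-5)
  }

  set.seed(1)
  dhE <- matrix(rnorm(7 * 2), 7)
  dh1E <- matrix(rnorm(7 * 4), 7)
  dh2E <- matrix(rnorm(7 * 3), 7)
  lossFn2 <- function(w) {
    f <- zigacl:::aeForward(w, fx$bn, fx$x, fx$sf, fx$cfg, training = TRUE)
    zinbNLL(fx$counts, f$pi, f$mu, f$theta) +
      sum(f$h * dhE) + sum(f$h1 * dh1E) + sum(f$h2 * dh2E)
  }
  g2 <- zigacl:::aeBackward(fx$w, f, fx$cfg, gPi = zg$dpi, gMu = zg$dmu,
                            gTheta = zg$dtheta, dhExtra = dhE,
                            dh1Extra = dh1E, dh2Extra = dh2E)
  for (nm in names(fx$w)) {
    gn <- numGrad(function(p) { w2 <- fx$w; w2[[nm]] <- p; lossFn2(w2) },
                  fx$w[[nm]])
    expect_lt(relErr(g2[[nm]], gn), 1e-5)
  }
})

test_that("global L2 clipping rescales exactly to the threshold", {
  set.seed(6)
  g <- list(a = matrix(rnorm(20, 0, 5), 4), b = rnorm(7, 0, 5))
  pre <- sqrt(sum(unlist(g)^2))
  cl <- zigacl:::clipGradsL2(g, 3)
  expect_equal(sqrt(sum(unlist(cl$grads)^2)), min(pre, 3), tolerance = 1e-12)
  # direction preserved
  expect_equal(cl$grads$a / g$a, matrix((min(pre, 3) / pre), 4, 5),
               tolerance = 1e-12)
  small <- list(a = matrix(1e-3, 2, 2))
  expect_identical(zigacl:::clipGradsL2(small, 3)$grads, small)
})

test_that("pretraining reduces the ZINB loss, clips gradients and is
           reproducible", {
  sce <- tinySim(nCells = 60, nGenes = 80, seed = 5)
  prep <- preprocessCounts(sce, nTop = 40)
  m1 <- pretrainAutoencoder(prep, tinyEncoder(), epochs = 30, seed = 2)
  expect_lt(tail(m1@history$loss, 1), m1@history$loss[1])
  expect_true(all(m1@history$gradNorm <= 3 + 1e-6))
  m2 <- pretrainAutoencoder(prep, tinyEncoder(), epochs = 30, seed = 2)
  expect_equal(tail(m1@history$loss, 1), tail(m2@history$loss, 1),
               tolerance = 1e-6)
  expect_identical(m1@latent, m2@latent)
  expect_error(zigacl:::aeForward(m1@weights, m1@bnStats,
                                  prep@xZscore * NA, prep@sizeFactors,
                                  m1@config), "NaN")
})
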
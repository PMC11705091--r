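# Denoising autoencoder with a ZINB decoder. Architecture (defaults):
#   encoder: input -> 256 -> 64 (each FC + batch norm + ReLU) -> 16 (linear)
#   decoder: 16 -> 64 -> 256 (FC + ReLU)
#   heads:   pi = sigmoid(W_pi D), mu = sizeFactor * exp(W_mu D),
#            theta = exp(W_theta D)
# Training mode adds Gaussian noise (sd = noiseSigma) to the z-scored input.
# All gradients are derived analytically and checked against finite
# differences in the test suite.

#' Encoder/decoder configuration
#'
#' @param inputDim number of input genes (set automatically by
#'   [pretrainAutoencoder()]).
#' @param hiddenDims widths of the two hidden layers.
#' @param latentDim latent dimension.
#' @param noiseSigma sd of the Gaussian noise added to the input in training
#'   mode (denoising regularisation).
#' @param batchNorm apply batch normalisation after each encoder hidden
#'   layer.
#' @return a named list understood by the training functions.
#' @export
encoderConfig <- function(inputDim = NULL, hiddenDims = c(256, 64),
                          latentDim = 16, noiseSigma = 1.0,
                          batchNorm = TRUE) {
  stopifnot(all(hiddenDims > 0), latentDim > 0, noiseSigma >= 0,
            latentDim < hiddenDims[length(hiddenDims)] * 16) # sanity only
  list(inputDim = inputDim, hiddenDims = hiddenDims, latentDim = latentDim,
       noiseSigma = noiseSigma, batchNorm = batchNorm)
}

aeInitWeights <- function(cfg, nGenes) {
  d <- cfg$inputDim; h1 <- cfg$hiddenDims[1]; h2 <- cfg$hiddenDims[2]
  z <- cfg$latentDim
  list(
    W1 = glorotMatrix(h1, d),  b1 = numeric(h1),
    g1 = rep(1, h1),           be1 = numeric(h1),
    W2 = glorotMatrix(h2, h1), b2 = numeric(h2),
    g2 = rep(1, h2),           be2 = numeric(h2),
    W3 = glorotMatrix(z, h2),  b3 = numeric(z),
    W4 = glorotMatrix(h2, z),  b4 = numeric(h2),
    W5 = glorotMatrix(h1, h2), b5 = numeric(h1),
    Wpi = glorotMatrix(nGenes, h1), bpi = numeric(nGenes),
    Wmu = glorotMatrix(nGenes, h1), bmu = numeric(nGenes),
    Wth = glorotMatrix(nGenes, h1), bth = numeric(nGenes)
  )
}

aeInitBnStats <- function(cfg) {
  list(bn1 = list(mean = numeric(cfg$hiddenDims[1]),
                  var = rep(1, cfg$hiddenDims[1])),
       bn2 = list(mean = numeric(cfg$hiddenDims[2]),
                  var = rep(1, cfg$hiddenDims[2])))
}

# Forward pass. `training` toggles input noise and batch statistics; the
# noise draw uses the current RNG state.
aeForward <- function(w, bn, x, sizeFactors, cfg, training = TRUE,
                      withHeads = TRUE) {
  if (anyNA(x)) stop("NaN in autoencoder input")
  n <- nrow(x)
  xn <- if (training && cfg$noiseSigma > 0)
    x + matrix(rnorm(length(x), 0, cfg$noiseSigma), n) else x

  a1 <- addBias(xn %*% t(w$W1), w$b1)
  if (cfg$batchNorm) {
    f1 <- bnForward(a1, w$g1, w$be1, bn$bn1, training)
    bn$bn1 <- f1$running; r1 <- f1$out
  } else { f1 <- NULL; r1 <- a1 }
  h1 <- pmax(r1, 0)

  a2 <- addBias(h1 %*% t(w$W2), w$b2)
  if (cfg$batchNorm) {
    f2 <- bnForward(a2, w$g2, w$be2, bn$bn2, training)
    bn$bn2 <- f2$running; r2 <- f2$out
  } else { f2 <- NULL; r2 <- a2 }
  h2 <- pmax(r2, 0)

  h <- addBias(h2 %*% t(w$W3), w$b3)

  a4 <- addBias(h %*% t(w$W4), w$b4)
  d1 <- pmax(a4, 0)
  a5 <- addBias(d1 %*% t(w$W5), w$b5)
  dd <- pmax(a5, 0)

  out <- list(xn = xn, a1 = a1, f1 = f1, r1 = r1, h1 = h1,
              a2 = a2, f2 = f2, r2 = r2, h2 = h2, h = h,
              a4 = a4, d1 = d1, a5 = a5, dd = dd, bn = bn)
  if (withHeads) {
    if (any(sizeFactors <= 0)) stop("size factors must be positive")
    spi <- addBias(dd %*% t(w$Wpi), w$bpi)
    smu <- addBias(dd %*% t(w$Wmu), w$bmu)
    sth <- addBias(dd %*% t(w$Wth), w$bth)
    heads <- .zinbHeadsCpp(spi, smu, sth, as.numeric(sizeFactors))
    out$pi <- heads$pi; out$mu <- heads$mu; out$theta <- heads$theta
    out$muMask <- heads$muMask
    out$thMask <- heads$thMask
  }
  out
}

# Backward pass. `gPi`, `gMu`, `gTheta` are dL/d(pi, mu, theta); `dhExtra`,
# `dh1Extra`, `dh2Extra` inject gradients flowing into the latent code and
# the encoder hidden activations from the clustering and GAT branches.
aeBackward <- function(w, cache, cfg, gPi = NULL, gMu = NULL, gTheta = NULL,
                       dhExtra = NULL, dh1Extra = NULL, dh2Extra = NULL) {
  g <- lapply(w, function(p) p * 0)
  dDd <- NULL
  if (!is.null(gPi)) {
    gSpi <- gPi * cache$pi * (1 - cache$pi)
    gSmu <- gMu * cache$mu * cache$muMask
    gSth <- gTheta * cache$theta * cache$thMask
    g$Wpi <- crossprod(gSpi, cache$dd); g$bpi <- colSums(gSpi)
    g$Wmu <- crossprod(gSmu, cache$dd); g$bmu <- colSums(gSmu)
    g$Wth <- crossprod(gSth, cache$dd); g$bth <- colSums(gSth)
    dDd <- gSpi %*% w$Wpi + gSmu %*% w$Wmu + gSth %*% w$Wth
  }

  dh <- if (is.null(dhExtra)) matrix(0, nrow(cache$h), ncol(cache$h)) else dhExtra
  if (!is.null(dDd)) {
    dA5 <- dDd * (cache$a5 > 0)
    g$W5 <- crossprod(dA5, cache$d1); g$b5 <- colSums(dA5)
    dD1 <- dA5 %*% w$W5
    dA4 <- dD1 * (cache$a4 > 0)
    g$W4 <- crossprod(dA4, cache$h); g$b4 <- colSums(dA4)
    dh <- dh + dA4 %*% w$W4
  }

  g$W3 <- crossprod(dh, cache$h2); g$b3 <- colSums(dh)
  dh2 <- dh %*% w$W3
  if (!is.null(dh2Extra)) dh2 <- dh2 + dh2Extra
  dr2 <- dh2 * (cache$r2 > 0)
  if (cfg$batchNorm) {
    bb2 <- bnBackward(dr2, cache$f2$cache)
    g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
    dA2 <- bb2$dx
  } else dA2 <- dr2
  g$W2 <- crossprod(dA2, cache$h1); g$b2 <- colSums(dA2)
  dh1 <- dA2 %*% w$W2
  if (!is.null(dh1Extra)) dh1 <- dh1 + dh1Extra
  dr1 <- dh1 * (cache$r1 > 0)
  if (cfg$batchNorm) {
    bb1 <- bnBackward(dr1, cache$f1$cache)
    g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
    dA1 <- bb1$dx
  } else dA1 <- dr1
  g$W1 <- crossprod(dA1, cache$xn); g$b1 <- colSums(dA1)
  g
}

#' Pretrain the ZINB denoising autoencoder
#'
#' Full-batch Adam optimisation of the mean-per-entry ZINB negative
#' log-likelihood of the raw counts of the selected genes, with global L2
#' gradient clipping. All randomness (weight init, input noise) derives from
#' `seed`.
#'
#' @param prep a [PreprocessedCounts-class] object.
#' @param config an [encoderConfig()] list; `inputDim` is filled in from the
#'   data.
#' @param epochs number of full-batch epochs (default 200).
#' @param lr Adam learning rate.
#' @param gradClip maximum global L2 gradient norm.
#' @param seed integer seed.
#' @param verbose print the loss every 25 epochs.
#' @return a [ZinbModel-class] with trained weights, eval-mode latent
#'   representation and the per-epoch loss history.
#' @examples
#' sce <- simulateCounts(nCells = 60, nGenes = 80, nGroups = 2, seed = 1)
#' prep <- preprocessCounts(sce, nTop = 50)
#' mod <- pretrainAutoencoder(prep, encoderConfig(hiddenDims = c(16, 8),
#'   latentDim = 4), epochs = 10, seed = 1)
#' @export
pretrainAutoencoder <- function(prep, config = encoderConfig(),
                                epochs = 200, lr = 1e-3, gradClip = 3,
                                seed = 1L, verbose = FALSE) {
  x <- prep@xZscore
  counts <- prep@counts
  sf <- prep@sizeFactors
  config$inputDim <- ncol(x)
  set.seed(substreamSeed(seed, "init"))
  w <- aeInitWeights(config, ncol(counts))
  bn <- aeInitBnStats(config)
  opt <- adamInit(w)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     gradNorm = numeric())
  set.seed(substreamSeed(seed, "noise"))
  for (ep in seq_len(epochs)) {
    fwd <- aeForward(w, bn, x, sf, config, training = TRUE)
    bn <- fwd$bn
    gr <- zinbNLLGrad(counts, fwd$pi, fwd$mu, fwd$theta)
    if (!is.finite(gr$loss))
      stop(sprintf("ZINB pretraining diverged (loss %s) at epoch %d",
                   gr$loss, ep))
    grads <- aeBackward(w, fwd, config, gPi = gr$dpi, gMu = gr$dmu,
                        gTheta = gr$dtheta)
    cl <- clipGradsL2(grads, gradClip)
    st <- adamStep(w, cl$grads, opt, lr = lr)
    w <- st$params; opt <- st$state
    hist <- rbind(hist, data.frame(epoch = ep, loss = gr$loss,
                                   gradNorm = cl$clippedNorm))
    if (verbose && ep %% 25 == 0)
      message(sprintf("pretrain epoch %d: L_ZINB = %.5f", ep, gr$loss))
  }
  lat <- aeForward(w, bn, x, sf, config, training = FALSE,
                   withHeads = FALSE)$h
  rownames(lat) <- prep@cellIds
  methods::new("ZinbModel", weights = w, bnStats = bn, config = config,
               latent = lat, history = hist, seed = as.integer(seed))
}
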
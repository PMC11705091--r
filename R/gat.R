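# Graph attention network with higher-order topological weighting and
# lambda-fusion of encoder representations at every layer.
#
# Layer l: P = Zbar %*% t(W)          (linear transform of the fused input)
#          c_ij = a1 . P_i + a2 . P_j  (attention score on each edge)
#          e_ij = R_ij * LeakyReLU(c_ij)
#          alpha_i. = softmax over the neighbour set of e_i.
#          out = LeakyReLU(Aalpha %*% P)
# Fusion: the input of layer l is (1 - lambda) * z^(l-1) + lambda * H_e^(l-1),
# pairing each GAT layer width with the corresponding encoder layer; the
# k-way head applies the same fusion to the latent pair before a row softmax.

#' GAT configuration
#'
#' @param dims layer widths from input to embedding; must match the encoder
#'   widths (input, hidden1, hidden2, latent) so fusion is well-formed.
#' @param lambda fusion weight in `[0, 1]`; 0 = pure GAT, 1 = pure
#'   autoencoder.
#' @param slope LeakyReLU negative slope.
#' @param k number of clusters for the head distribution Z.
#' @return named list consumed by the GAT forward/backward routines.
#' @export
gatConfig <- function(dims, lambda = 0.4, slope = 0.2, k = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (slope <= 0) stop("LeakyReLU slope must be positive")
  list(dims = dims, lambda = lambda, slope = slope, k = k)
}

gatInitWeights <- function(cfg) {
  L <- length(cfg$dims) - 1
  w <- list()
  for (l in seq_len(L)) {
    dIn <- cfg$dims[l]; dOut <- cfg$dims[l + 1]
    w[[paste0("W", l)]] <- glorotMatrix(dOut, dIn)
    w[[paste0("a1_", l)]] <- runif(dOut, -0.1, 0.1)
    w[[paste0("a2_", l)]] <- runif(dOut, -0.1, 0.1)
  }
  if (is.null(cfg$k)) stop("k must be set before initialising the GAT head")
  w$Wh <- glorotMatrix(cfg$k, cfg$dims[L + 1])
  w$bh <- numeric(cfg$k)
  w
}

# Edge softmax of e grouped by source node; numerically stabilised.
edgeSoftmax <- function(e, ei, n) {
  mx <- rep(-Inf, n)
  mxAgg <- tapply(e, ei, max)
  mx[as.integer(names(mxAgg))] <- mxAgg
  ex <- exp(e - mx[ei])
  den <- rep(0, n)
  dAgg <- rowsum(ex, ei)
  den[as.integer(rownames(dAgg))] <- dAgg
  ex / den[ei]
}

# Single attention layer forward on a fused input.
gatLayerForward <- function(zbar, W, a1, a2, edges, slope) {
  P <- zbar %*% t(W)
  u <- as.vector(P %*% a1)
  v <- as.vector(P %*% a2)
  cEdge <- u[edges$ei] + v[edges$ej]
  e <- edges$R * leakyRelu(cEdge, slope)
  alpha <- edgeSoftmax(e, edges$ei, edges$n)
  Aalpha <- Matrix::sparseMatrix(i = edges$ei, j = edges$ej, x = alpha,
                                 dims = c(edges$n, edges$n))
  S <- as.matrix(Aalpha %*% P)
  list(out = leakyRelu(S, slope), P = P, cEdge = cEdge, alpha = alpha,
       Aalpha = Aalpha, S = S, zbar = zbar)
}

# Backward through one attention layer. `dOut` is dL/d(layer output).
# Returns gradients for W, a1, a2 and dL/d(zbar).
gatLayerBackward <- function(cache, W, a1, a2, edges, slope, dOut) {
  ei <- edges$ei; ej <- edges$ej; n <- edges$n
  dS <- dOut * leakyReluGrad(cache$S, slope)
  dP <- as.matrix(Matrix::t(cache$Aalpha) %*% dS)
  dAlpha <- rowSums(dS[ei, , drop = FALSE] * cache$P[ej, , drop = FALSE])
  # softmax backward per source group
  s <- rep(0, n)
  sAgg <- rowsum(dAlpha * cache$alpha, ei)
  s[as.integer(rownames(sAgg))] <- sAgg
  de <- cache$alpha * (dAlpha - s[ei])
  dc <- de * edges$R * leakyReluGrad(cache$cEdge, slope)
  du <- rep(0, n); dv <- rep(0, n)
  duA <- rowsum(dc, ei); du[as.integer(rownames(duA))] <- duA
  dvA <- rowsum(dc, ej); dv[as.integer(rownames(dvA))] <- dvA
  dP <- dP + outer(du, a1) + outer(dv, a2)
  da1 <- as.vector(crossprod(cache$P, du))
  da2 <- as.vector(crossprod(cache$P, dv))
  dW <- crossprod(dP, cache$zbar)
  dZbar <- dP %*% W
  list(dW = dW, da1 = da1, da2 = da2, dZbar = dZbar)
}

#' Convex fusion of GAT and encoder representations
#'
#' `(1 - lambda) * z + lambda * h`, elementwise; the layer-wise blending of
#' the structural (GAT) and denoised (autoencoder) views.
#'
#' @param z GAT layer output.
#' @param h matching encoder layer output.
#' @param lambda fusion weight in `[0, 1]`.
#' @return matrix of the same shape.
#' @export
fuseRepresentations <- function(z, h, lambda) {
  if (!all(dim(z) == dim(h)))
    stop("fusion requires matching shapes")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  (1 - lambda) * z + lambda * h
}

# Full multi-layer forward. `hList` holds the encoder layer outputs
# (h1, h2, latent) aligned with cfg$dims[-1].
gatForwardFull <- function(w, x, hList, edges, cfg) {
  L <- length(cfg$dims) - 1
  lam <- cfg$lambda
  caches <- vector("list", L)
  zbar <- x
  for (l in seq_len(L)) {
    caches[[l]] <- gatLayerForward(zbar, w[[paste0("W", l)]],
                                   w[[paste0("a1_", l)]],
                                   w[[paste0("a2_", l)]], edges, cfg$slope)
    zout <- caches[[l]]$out
    zbar <- if (l < L) fuseRepresentations(zout, hList[[l]], lam) else zout
  }
  headIn <- fuseRepresentations(zbar, hList[[L]], lam)
  logits <- addBias(headIn %*% t(w$Wh), w$bh)
  z <- rowSoftmax(logits)
  list(caches = caches, headIn = headIn, logits = logits, z = z)
}

# Full backward from dL/d(logits). Returns GAT weight gradients plus the
# lambda-weighted gradients flowing into the encoder outputs (same order as
# hList) and into the input features.
gatBackwardFull <- function(w, fwd, edges, cfg, dLogits) {
  L <- length(cfg$dims) - 1
  lam <- cfg$lambda
  g <- lapply(w, function(p) p * 0)
  dH <- vector("list", L)
  g$Wh <- crossprod(dLogits, fwd$headIn)
  g$bh <- colSums(dLogits)
  dHeadIn <- dLogits %*% w$Wh
  dH[[L]] <- lam * dHeadIn
  dZ <- (1 - lam) * dHeadIn
  for (l in rev(seq_len(L))) {
    bk <- gatLayerBackward(fwd$caches[[l]], w[[paste0("W", l)]],
                           w[[paste0("a1_", l)]], w[[paste0("a2_", l)]],
                           edges, cfg$slope, dZ)
    g[[paste0("W", l)]] <- bk$dW
    g[[paste0("a1_", l)]] <- bk$da1
    g[[paste0("a2_", l)]] <- bk$da2
    if (l > 1) {
      dH[[l - 1]] <- lam * bk$dZbar
      dZ <- (1 - lam) * bk$dZbar
    } else {
      dX <- bk$dZbar
    }
  }
  list(grads = g, dH = dH, dX = dX)
}
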
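# Internal numerical helpers shared across modules.

# Derive a reproducible sub-stream seed from a root seed and a stage name,
# so the simulator, k-means, noise draws etc. are independently replayable.
substreamSeed <- function(seed, stage) {
  offsets <- c(simulate = 11L, preprocess = 23L, noise = 37L, kmeans = 53L,
               init = 71L, dropout = 89L, finetune = 101L)
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 7919 + off * 104729) %% 2147483647)
}

addBias <- function(m, b) {
  m + rep(b, each = nrow(m))
}

clampVal <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(x) 1 / (1 + exp(-x))

leakyRelu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)

leakyReluGrad <- function(x, slope = 0.2) slope + (1 - slope) * (x > 0)

rowSoftmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Glorot/Xavier uniform initialisation; rows = fan-out, cols = fan-in so that
# layers compute x %*% t(W).
glorotMatrix <- function(nOut, nIn, gain = 1) {
  lim <- gain * sqrt(6 / (nIn + nOut))
  matrix(runif(nOut * nIn, -lim, lim), nrow = nOut, ncol = nIn)
}

# ---- Adam optimiser over a named list of arrays ---------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Global L2 gradient clipping across every tensor in the list. Returns the
# rescaled gradients together with the pre- and post-clip norms.
clipGradsL2 <- function(grads, maxNorm = 3) {
  sq <- sum(vapply(grads, function(g) sum(g * g), numeric(1)))
  nrm <- sqrt(sq)
  if (is.finite(nrm) && nrm > maxNorm) {
    scale <- maxNorm / nrm
    grads <- lapply(grads, function(g) g * scale)
  }
  list(grads = grads, norm = nrm, clippedNorm = min(nrm, maxNorm))
}

# ---- Batch normalisation ---------------------------------------------------

bnForward <- function(x, gamma, beta, running, training, momentum = 0.9,
                      eps = 1e-5) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, inv, "*")
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v * n / max(n - 1, 1)
    cache <- list(xc = xc, inv = inv, xhat = xhat, gamma = gamma)
  } else {
    xhat <- sweep(sweep(x, 2, running$mean), 2,
                  1 / sqrt(running$var + eps), "*")
    cache <- NULL
  }
  out <- addBias(sweep(xhat, 2, gamma, "*"), beta)
  list(out = out, cache = cache, running = running)
}

bnBackward <- function(dout, cache) {
  n <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, cache$gamma, "*")
  # dx for batch statistics (biased variance)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2, cache$inv, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}
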
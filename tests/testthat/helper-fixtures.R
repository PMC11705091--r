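# Shared helpers: central-difference gradients, small model configs and a
# quick simulation wrapper used across the unit tests.

numGrad <- function(f, p, eps = 1e-5) {
  g <- p * 0
  for (i in seq_along(p)) {
    p1 <- p; p2 <- p
    p1[i] <- p1[i] + eps
    p2[i] <- p2[i] - eps
    g[i] <- (f(p1) - f(p2)) / (2 * eps)
  }
  g
}

relErr <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(a) + abs(b), floor))
}

tinyEncoder <- function(inputDim = NULL) {
  encoderConfig(inputDim = inputDim, hiddenDims = c(16, 8), latentDim = 4,
                noiseSigma = 0.5)
}

tinySim <- function(nCells = 80, nGenes = 120, nGroups = 2, seed = 7, ...) {
  simulateCounts(nCells = nCells, nGenes = nGenes, nGroups = nGroups,
                 seed = seed, ...)
}

simTruth <- function(sce) SummarizedExperiment::colData(sce)$Group

# strongly separated 2-group simulation: k-means on PCA must solve it
blobSim <- function(nCells = 200, seed = 11) {
  simulateCounts(nCells = nCells, nGenes = 150, nGroups = 2,
                 groupProps = c(0.5, 0.5), deProb = 0.4, deFactorLoc = 1,
                 deFactorScale = 0.2, seed = seed)
}
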
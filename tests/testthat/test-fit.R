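fitTinyConfig <- function(maxEpochs = 25, ...) {
  trainConfig(maxEpochs = maxEpochs, pUpdateInterval = 5, ...)
}

test_that("two well-separated groups are recovered perfectly", {
  sce <- blobSim()
  truth <- simTruth(sce)
  prep <- preprocessCounts(sce, nTop = 100)
  # precondition of the fixture: plain k-means on PCA already solves it
  pc <- prcomp(prep@xZscore, rank. = 20)
  set.seed(1)
  km <- kmeans(pc$x, 2, nstart = 10)
  expect_equal(adjustedRandIndex(truth, km$cluster), 1)

  fit <- zigacl(sce, k = 2, nTop = 100, kNeighbors = 10,
                encoder = tinyEncoder(), train = fitTinyConfig(),
                pretrainEpochs = 30, labelsTrue = truth, seed = 2)
  expect_equal(fit@metrics$ari, 1)
})

test_that("training histories respect the clipping and KL invariants", {
  sce <- blobSim(nCells = 120, seed = 3)
  prep <- preprocessCounts(sce, nTop = 80)
  mod <- pretrainAutoencoder(prep, tinyEncoder(), epochs = 20, seed = 1)
  graph <- buildCellGraph(prep@xZscore, kNeighbors = 8, t = 2)
  fit <- fitZigacl(prep, graph, mod, k = 2, config = fitTinyConfig(20))
  expect_true(all(fit@history$gradNorm <= 3 + 1e-6))
  expect_true(all(fit@history$lClu >= 0))
  expect_true(all(fit@history$lGat >= 0))
  expect_true(all(abs(rowSums(fit@q) - 1) < 1e-6))
  expect_true(all(abs(rowSums(fit@p) - 1) < 1e-6))
  expect_true(all(abs(rowSums(fit@z) - 1) < 1e-6))
  # attention rows still sum to one after training
  gCfg <- gatConfig(dims = c(ncol(prep@xZscore), 16, 8, 4),
                    lambda = fit@config$lambda, k = 2)
  edges <- zigacl:::graphEdges(graph)
  # recompute the attention of the first layer with the final latent inputs
  hF <- zigacl:::aeForward(mod@weights, mod@bnStats, prep@xZscore,
                           prep@sizeFactors, mod@config, training = FALSE)
  set.seed(1)
  w <- zigacl:::gatInitWeights(gCfg)
  f <- zigacl:::gatForwardFull(w, prep@xZscore,
                               list(hF$h1, hF$h2, hF$h), edges, gCfg)
  for (cache in f$caches) {
    sums <- tapply(cache$alpha, edges$ei, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
})

test_that("the clustering loss trends down within target-update windows", {
  sce <- blobSim(nCells = 150, seed = 9)
  prep <- preprocessCounts(sce, nTop = 100)
  mod <- pretrainAutoencoder(prep, tinyEncoder(), epochs = 25, seed = 2)
  graph <- buildCellGraph(prep@xZscore, kNeighbors = 8, t = 2)
  fit <- fitZigacl(prep, graph, mod, k = 2,
                   config = trainConfig(maxEpochs = 20, pUpdateInterval = 5,
                                        labelChangeTol = 1e-9))
  h <- fit@history
  # compare consecutive epochs that share the same target P
  sameWindow <- ((h$epoch[-1] - 1) %% 5) != 0
  dec <- diff(h$lClu)[sameWindow] < 1e-8
  expect_gte(mean(dec), 0.8)
})

test_that("the label-change criterion halts fine-tuning", {
  sce <- blobSim(nCells = 120, seed = 5)
  prep <- preprocessCounts(sce, nTop = 80)
  mod <- pretrainAutoencoder(prep, tinyEncoder(), epochs = 25, seed = 1)
  graph <- buildCellGraph(prep@xZscore, kNeighbors = 8, t = 2)
  fit <- fitZigacl(prep, graph, mod, k = 2,
                   config = trainConfig(maxEpochs = 150, pUpdateInterval = 1))
  expect_true(fit@config$halted)
  expect_lt(nrow(fit@history), 150)
  expect_lt(fit@config$haltLabelChange, 0.001)
})

test_that("fitting is deterministic under a fixed seed", {
  sce <- blobSim(nCells = 100, seed = 8)
  truth <- simTruth(sce)
  f1 <- zigacl(sce, k = 2, nTop = 60, kNeighbors = 8,
               encoder = tinyEncoder(), train = fitTinyConfig(10),
               pretrainEpochs = 10, seed = 5)
  f2 <- zigacl(sce, k = 2, nTop = 60, kNeighbors = 8,
               encoder = tinyEncoder(), train = fitTinyConfig(10),
               pretrainEpochs = 10, seed = 5)
  expect_identical(f1@labels, f2@labels)
  expect_equal(f1@latent, f2@latent, tolerance = 1e-12)
})

test_that("invalid clustering requests fail fast", {
  sce <- tinySim(nCells = 20, nGenes = 30)
  prep <- preprocessCounts(sce, nTop = 20)
  mod <- pretrainAutoencoder(prep, tinyEncoder(), epochs = 2, seed = 1)
  graph <- buildCellGraph(prep@xZscore, kNeighbors = 5, t = 1)
  expect_error(fitZigacl(prep, graph, mod, k = 1), "k must be")
  expect_error(fitZigacl(prep, graph, mod, k = 21), "cannot exceed")
})
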
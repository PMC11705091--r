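# Scripted experiments: robustness to injected dropout and the lambda sweep.

runOnce <- function(sce, k, rate, seed, lambda, opts) {
  data <- if (rate > 0) injectDropout(sce, rate, seed = seed)$counts else sce
  truth <- SummarizedExperiment::colData(sce)$Group
  train <- opts$train
  train$lambda <- lambda
  fit <- zigacl(data, k = k, nTop = opts$nTop,
                kNeighbors = opts$kNeighbors, encoder = opts$encoder,
                train = train, pretrainEpochs = opts$pretrainEpochs,
                labelsTrue = truth, seed = seed)
  data.frame(rate = rate, lambda = lambda, seed = seed,
             ari = fit@metrics$ari, nmi = fit@metrics$nmi,
             asw = fit@metrics$asw)
}

expOpts <- function(nTop, kNeighbors, encoder, train, pretrainEpochs) {
  list(nTop = nTop, kNeighbors = kNeighbors, encoder = encoder,
       train = train, pretrainEpochs = pretrainEpochs)
}

#' Dropout-robustness experiment
#'
#' For each dropout rate and seed, injects dropout into the counts of `sce`,
#' reruns the full pipeline and records ARI, NMI and the average silhouette
#' width, mirroring the robustness protocol of masking observed expression
#' at increasing rates with several random seeds.
#'
#' @param sce a labelled `SingleCellExperiment` (colData column `Group`),
#'   e.g. from [simulateCounts()].
#' @param k number of clusters.
#' @param rates dropout rates in `[0, 1)`.
#' @param seeds integer vector of seeds (one pipeline run per rate x seed).
#' @param nTop,kNeighbors,encoder,train,pretrainEpochs pipeline settings
#'   forwarded to [zigacl()].
#' @return list with `runs` (one row per rate x seed) and `summary`
#'   (per-rate means).
#' @export
experimentDropout <- function(sce, k, rates = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                              seeds = 1:5, nTop = 2500, kNeighbors = 15,
                              encoder = encoderConfig(),
                              train = trainConfig(),
                              pretrainEpochs = 200) {
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  opts <- expOpts(nTop, kNeighbors, encoder, train, pretrainEpochs)
  runs <- do.call(rbind, lapply(rates, function(r)
    do.call(rbind, lapply(seeds, function(s)
      runOnce(sce, k, r, s, train$lambda, opts)))))
  summary <- do.call(rbind, lapply(split(runs, runs$rate), function(d)
    data.frame(rate = d$rate[1], ari = mean(d$ari), nmi = mean(d$nmi),
               asw = mean(d$asw))))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}

#' Fusion-weight (lambda) sweep
#'
#' Reruns the pipeline over a grid of fusion weights lambda (0 = pure GAT,
#' 1 = pure autoencoder) and records the clustering metrics per seed.
#'
#' @inheritParams experimentDropout
#' @param lambdas grid of fusion weights in `[0, 1]`.
#' @return list with `runs` and per-lambda `summary`.
#' @export
experimentLambda <- function(sce, k, lambdas = seq(0, 1, by = 0.1),
                             seeds = 1:3, nTop = 2500, kNeighbors = 15,
                             encoder = encoderConfig(),
                             train = trainConfig(),
                             pretrainEpochs = 200) {
  if (any(lambdas < 0 | lambdas > 1)) stop("lambdas must lie in [0, 1]")
  opts <- expOpts(nTop, kNeighbors, encoder, train, pretrainEpochs)
  runs <- do.call(rbind, lapply(lambdas, function(l)
    do.call(rbind, lapply(seeds, function(s)
      runOnce(sce, k, 0, s, l, opts)))))
  summary <- do.call(rbind, lapply(split(runs, runs$lambda), function(d)
    data.frame(lambda = d$lambda[1], ari = mean(d$ari), nmi = mean(d$nmi),
               asw = mean(d$asw))))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}
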
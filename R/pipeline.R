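# End-to-end pipeline: preprocess -> graph -> ZINB pretraining ->
# co-supervised fine-tuning -> metrics.

#' Cluster single cells with the full pipeline
#'
#' Runs gene filtering, depth normalisation and HVG selection, builds the
#' Gaussian-kernel cell graph, pretrains the ZINB denoising autoencoder and
#' fine-tunes the co-supervised clustering model.
#'
#' @param x counts: a `SingleCellExperiment` (genes x cells) or a
#'   cells x genes matrix.
#' @param k number of clusters.
#' @param nTop number of high-variability genes to keep.
#' @param kNeighbors graph neighbourhood size.
#' @param bandwidth Gaussian kernel bandwidth, `"auto"` for the median
#'   pairwise cosine distance.
#' @param topoOrder order t of the topological correlation matrix.
#' @param encoder an [encoderConfig()] list.
#' @param train a [trainConfig()] list; its `seed` is overridden by `seed`.
#' @param pretrainEpochs pretraining epochs (default 200).
#' @param labelsTrue optional ground-truth labels; when given, ARI/NMI are
#'   added to the returned metrics.
#' @param seed root seed for every stochastic stage.
#' @param verbose progress messages.
#' @return a [ZigaclFit-class]; its `metrics` slot holds the average
#'   silhouette width of the latent embedding under the predicted labels
#'   and, when `labelsTrue` is given, ARI and NMI.
#'
#' @examples
#' sce <- simulateCounts(nCells = 80, nGenes = 120, nGroups = 2, seed = 7)
#' fit <- zigacl(sce, k = 2, nTop = 60, kNeighbors = 5,
#'   encoder = encoderConfig(hiddenDims = c(16, 8), latentDim = 4),
#'   train = trainConfig(maxEpochs = 15), pretrainEpochs = 15, seed = 7,
#'   labelsTrue = SummarizedExperiment::colData(sce)$Group)
#' fit
#' @export
zigacl <- function(x, k, nTop = 2500, kNeighbors = 15, bandwidth = "auto",
                   topoOrder = 2, encoder = encoderConfig(),
                   train = trainConfig(), pretrainEpochs = 200,
                   labelsTrue = NULL, seed = 1L, verbose = FALSE) {
  train$seed <- as.integer(seed)
  if (verbose) message("preprocessing ...")
  prep <- preprocessCounts(x, nTop = nTop)
  if (verbose) message("building cell graph ...")
  graph <- buildCellGraph(prep@xZscore, r = bandwidth,
                          kNeighbors = kNeighbors, t = topoOrder)
  if (verbose) message("pretraining ZINB autoencoder ...")
  model <- pretrainAutoencoder(prep, encoder, epochs = pretrainEpochs,
                               seed = seed, verbose = verbose)
  if (verbose) message("co-supervised fine-tuning ...")
  fit <- fitZigacl(prep, graph, model, k, config = train, verbose = verbose)
  fit@metrics <- clusterMetrics(fit, labelsTrue = labelsTrue)
  fit
}

#' Export the artefacts of a fitted model
#'
#' Writes `labels.csv` (cell_id, cluster), `embedding.csv`, `history.csv`,
#' `metrics.json` and a `manifest.json` recording configuration, seed and
#' package version — enough to reproduce the run.
#'
#' @param fit a [ZigaclFit-class] object.
#' @param dir output directory.
#' @param extra named list merged into the manifest (e.g. input paths).
#' @return `dir`, invisibly.
#' @export
exportFit <- function(fit, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(data.frame(cell_id = fit@cellIds, cluster = fit@labels),
              file.path(dir, "labels.csv"), sep = ",", row.names = FALSE,
              quote = FALSE)
  emb <- data.frame(cell_id = fit@cellIds, unname(fit@latent))
  names(emb) <- c("cell_id", sprintf("dim%d", seq_len(ncol(fit@latent))))
  write.table(emb, file.path(dir, "embedding.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  write.table(fit@history, file.path(dir, "history.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(fit@metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(list(package = "zigacl",
                     version = as.character(packageVersion("zigacl")),
                     k = ncol(fit@q),
                     clusterSizes = as.list(table(fit@labels)),
                     config = fit@config), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
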
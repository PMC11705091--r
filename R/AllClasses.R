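#' Preprocessed count data
#'
#' Container produced by [preprocessCounts()]. Cells are rows throughout.
#' `counts` holds the *raw* integer counts of the selected high-variability
#' genes (the observation matrix of the ZINB likelihood); `xZscore` is the
#' per-gene z-score of log1p(depth-normalised) expression of the same genes
#' (the model input).
#'
#' @slot counts raw counts of selected genes, cells x genes.
#' @slot xZscore z-scored log-normalised expression, cells x genes.
#' @slot sizeFactors per-cell library size over median library size.
#' @slot hvgIndex integer index of the kept genes into the filtered gene axis.
#' @slot dispersion variance-to-mean dispersion of every filtered gene on the
#'   scale used for ranking.
#' @slot cellIds,geneIds identifiers; `geneIds` refers to the kept genes.
#'
#' @aliases PreprocessedCounts-class
#' @exportClass PreprocessedCounts
setClass("PreprocessedCounts",
  representation(
    counts      = "matrix",
    xZscore     = "matrix",
    sizeFactors = "numeric",
    hvgIndex    = "integer",
    dispersion  = "numeric",
    cellIds     = "character",
    geneIds     = "character"
  )
)

setValidity("PreprocessedCounts", function(object) {
  msg <- character()
  n <- nrow(object@counts)
  m <- ncol(object@counts)
  if (any(object@counts < 0) || anyNA(object@counts))
    msg <- c(msg, "counts must be non-negative and finite")
  if (!all(dim(object@xZscore) == c(n, m)))
    msg <- c(msg, "xZscore dimensions must match counts")
  if (length(object@sizeFactors) != n || any(object@sizeFactors <= 0))
    msg <- c(msg, "sizeFactors must be positive, one per cell")
  if (length(object@cellIds) != n || anyDuplicated(object@cellIds))
    msg <- c(msg, "cellIds must be unique, one per cell")
  if (length(object@geneIds) != m)
    msg <- c(msg, "geneIds must match the kept gene axis")
  if (length(msg)) msg else TRUE
})

#' Cell-cell similarity graph
#'
#' Gaussian-kernel adjacency over cosine distances, k-nearest-neighbour
#' sparsified (union symmetrisation), with the row-stochastic transition
#' matrix B and the higher-order topological correlation
#' R = (B + B^2 + ... + B^t) / t.
#'
#' @slot adjacency dense kernel matrix A (n x n), entries in (0, 1].
#' @slot neighbors per-cell integer neighbour sets (excluding self).
#' @slot bandwidth Gaussian kernel bandwidth r.
#' @slot transition transition matrix B, B_ij = 1/m_i on retained edges.
#' @slot topoCorr topological correlation matrix R.
#' @slot order averaging order t.
#' @slot kNeighbors neighbourhood size used for sparsification.
#'
#' @aliases CellGraph-class
#' @exportClass CellGraph
setClass("CellGraph",
  representation(
    adjacency  = "matrix",
    neighbors  = "list",
    bandwidth  = "numeric",
    transition = "matrix",
    topoCorr   = "matrix",
    order      = "integer",
    kNeighbors = "integer"
  )
)

setValidity("CellGraph", function(object) {
  msg <- character()
  n <- nrow(object@adjacency)
  if (ncol(object@adjacency) != n)
    msg <- c(msg, "adjacency must be square")
  if (length(object@neighbors) != n)
    msg <- c(msg, "one neighbour set per cell required")
  if (object@order < 1L)
    msg <- c(msg, "order t must be >= 1")
  if (object@bandwidth <= 0)
    msg <- c(msg, "bandwidth must be positive")
  deg <- vapply(object@neighbors, length, integer(1))
  rs <- rowSums(object@transition)
  if (any(abs(rs[deg > 0] - 1) > 1e-8))
    msg <- c(msg, "transition rows must sum to 1 for connected cells")
  if (length(msg)) msg else TRUE
})

#' Pretrained ZINB denoising autoencoder
#'
#' Weights and configuration of the autoencoder after ZINB pretraining,
#' together with the latent representation of the training cells.
#'
#' @slot weights named list of weight matrices / bias vectors.
#' @slot bnStats running batch-normalisation statistics for eval mode.
#' @slot config encoder configuration (layer widths, latent dim, noise sd).
#' @slot latent cells x latentDim representation (eval mode).
#' @slot history per-epoch pretraining loss.
#' @slot seed integer seed that reproduces the pretraining run.
#'
#' @aliases ZinbModel-class
#' @exportClass ZinbModel
setClass("ZinbModel",
  representation(
    weights = "list",
    bnStats = "list",
    config  = "list",
    latent  = "matrix",
    history = "data.frame",
    seed    = "integer"
  )
)

#' Fitted co-supervised clustering model
#'
#' Result of [fitZigacl()] / [zigacl()]: hard labels (argmax of the soft
#' assignment Q, ties broken toward the lowest cluster index), the three
#' row-stochastic distributions, the latent embedding and training history.
#'
#' @slot labels integer cluster labels, one per cell (1-based).
#' @slot q,p,z soft assignment, sharpened target and GAT head distributions
#'   (cells x k, row-stochastic).
#' @slot centers cluster centres in the latent space (k x latentDim).
#' @slot latent final latent embedding (cells x latentDim).
#' @slot history per-epoch loss components and label-change fraction.
#' @slot metrics named list of evaluation metrics (may be empty).
#' @slot config training configuration actually used.
#' @slot cellIds cell identifiers.
#'
#' @aliases ZigaclFit-class
#' @exportClass ZigaclFit
setClass("ZigaclFit",
  representation(
    labels  = "integer",
    q       = "matrix",
    p       = "matrix",
    z       = "matrix",
    centers = "matrix",
    latent  = "matrix",
    history = "data.frame",
    metrics = "list",
    config  = "list",
    cellIds = "character"
  )
)

setValidity("ZigaclFit", function(object) {
  msg <- character()
  n <- length(object@labels)
  for (nm in c("q", "p", "z")) {
    mat <- slot(object, nm)
    if (nrow(mat) != n) msg <- c(msg, sprintf("%s must have one row per cell", nm))
    if (any(mat < 0) || any(abs(rowSums(mat) - 1) > 1e-5))
      msg <- c(msg, sprintf("%s rows must be non-negative and sum to 1", nm))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PreprocessedCounts", function(object) {
  cat("PreprocessedCounts:", nrow(object@counts), "cells x",
      ncol(object@counts), "selected genes\n")
  cat("  size factors: [", signif(min(object@sizeFactors), 3), ",",
      signif(max(object@sizeFactors), 3), "]\n")
})

setMethod("show", "CellGraph", function(object) {
  deg <- vapply(object@neighbors, length, integer(1))
  cat("CellGraph:", nrow(object@adjacency), "cells, mean degree",
      signif(mean(deg), 3), "\n")
  cat("  kernel bandwidth r =", signif(object@bandwidth, 4),
      "; topological order t =", object@order, "\n")
})

setMethod("show", "ZinbModel", function(object) {
  cat("ZinbModel: input", object@config$inputDim, "->",
      paste(object@config$hiddenDims, collapse = " -> "), "->",
      object@config$latentDim, "\n")
  if (nrow(object@history))
    cat("  pretraining loss:", signif(object@history$loss[1], 4), "->",
        signif(object@history$loss[nrow(object@history)], 4), "\n")
})

setMethod("show", "ZigaclFit", function(object) {
  k <- ncol(object@q)
  cat("ZigaclFit:", length(object@labels), "cells in", k, "clusters\n")
  print(table(cluster = object@labels))
  if (length(object@metrics))
    cat("  metrics:", paste(names(object@metrics),
        signif(unlist(object@metrics), 3), sep = "=", collapse = ", "), "\n")
})

#' Accessors for fitted objects
#'
#' @param object a [ZigaclFit-class] or [ZinbModel-class] object.
#' @return `clusterLabels` returns the integer label vector;
#'   `latentEmbedding` the cells x latentDim matrix; `softAssignment` the
#'   row-stochastic Q matrix.
#' @export
#' @rdname accessors
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @export
#' @rdname accessors
setGeneric("latentEmbedding", function(object) standardGeneric("latentEmbedding"))

#' @export
#' @rdname accessors
setGeneric("softAssignment", function(object) standardGeneric("softAssignment"))

#' @rdname accessors
setMethod("clusterLabels", "ZigaclFit", function(object) object@labels)

#' @rdname accessors
setMethod("latentEmbedding", "ZigaclFit", function(object) object@latent)

#' @rdname accessors
setMethod("latentEmbedding", "ZinbModel", function(object) object@latent)

#' @rdname accessors
setMethod("softAssignment", "ZigaclFit", function(object) object@q)
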
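# Gene filtering, depth normalisation, dispersion-based HVG selection and
# z-scoring. Cells are rows internally; SingleCellExperiment inputs (genes x
# cells, the Bioconductor convention) are transposed on entry.

asCellMatrix <- function(x) {
  if (methods::is(x, "SingleCellExperiment") ||
      methods::is(x, "SummarizedExperiment")) {
    m <- t(as.matrix(SummarizedExperiment::assay(x, "counts")))
  } else {
    m <- as.matrix(x)
  }
  if (anyNA(m) || any(m < 0))
    stop("counts must be non-negative and free of NA")
  if (is.null(rownames(m))) rownames(m) <- sprintf("cell%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("gene%d", seq_len(ncol(m)))
  m
}

#' Remove genes with no expression in any cell
#'
#' @param x counts as a cells x genes matrix or a SingleCellExperiment
#'   (genes x cells).
#' @return a cells x genes matrix restricted to genes with at least one
#'   non-zero count, columns in their original order.
#' @examples
#' m <- cbind(a = c(0, 1), b = c(0, 0), c = c(2, 3))
#' filterGenes(m)
#' @export
filterGenes <- function(x) {
  m <- asCellMatrix(x)
  keep <- colSums(m != 0) > 0
  if (!any(keep))
    stop("no expressed genes: every gene is zero in all cells")
  m[, keep, drop = FALSE]
}

#' Normalise counts and select high-variability genes
#'
#' Depth normalisation uses median-library-size factors
#' (`libSize / median(libSize)`). The per-gene dispersion is the
#' variance-to-mean ratio of the depth-normalised expression; genes are
#' ranked by dispersion (ties broken by original gene order) and the top
#' `nTop` kept. The returned model input is the per-gene z-score of
#' `log1p` normalised expression of the kept genes, while their raw counts
#' are carried along unchanged for the ZINB likelihood.
#'
#' @param x counts (cells x genes matrix or SingleCellExperiment); genes
#'   should already be expression-filtered (done here defensively).
#' @param nTop number of high-variability genes to keep (default 2500).
#' @param dispersionOn scale on which the variance/mean dispersion is
#'   computed: `"normalized"` (default) or `"raw"` counts.
#' @return a [PreprocessedCounts-class] object.
#' @examples
#' sce <- simulateCounts(nCells = 50, nGenes = 200, nGroups = 2, seed = 1)
#' prep <- preprocessCounts(sce, nTop = 100)
#' prep
#' @export
preprocessCounts <- function(x, nTop = 2500,
                             dispersionOn = c("normalized", "raw")) {
  dispersionOn <- match.arg(dispersionOn)
  if (nTop < 1) stop("nTop must be >= 1")
  m <- filterGenes(x)
  n <- nrow(m)
  libSize <- rowSums(m)
  if (any(libSize == 0))
    stop("cells with zero library size cannot be normalised")
  sizeFactors <- libSize / median(libSize)
  norm <- m / sizeFactors

  base <- if (dispersionOn == "normalized") norm else m
  mu <- colMeans(base)
  v <- apply(base, 2, var)
  dispersion <- ifelse(mu > 0, v / mu, 0)

  nKeep <- min(nTop, ncol(m))
  if (nKeep < nTop)
    warning(sprintf("only %d genes survive filtering; keeping all of them",
                    ncol(m)))
  ord <- order(-dispersion)        # stable: ties keep original gene order
  hvg <- sort(ord[seq_len(nKeep)]) # preserve original gene order in output

  logNorm <- log1p(norm[, hvg, drop = FALSE])
  mus <- colMeans(logNorm)
  sds <- apply(logNorm, 2, sd)
  xz <- sweep(logNorm, 2, mus)
  pos <- sds > 0
  xz[, pos] <- sweep(xz[, pos, drop = FALSE], 2, sds[pos], "/")
  xz[, !pos] <- 0

  methods::new("PreprocessedCounts",
    counts = m[, hvg, drop = FALSE],
    xZscore = xz,
    sizeFactors = as.numeric(sizeFactors),
    hvgIndex = as.integer(hvg),
    dispersion = as.numeric(dispersion),
    cellIds = rownames(m),
    geneIds = colnames(m)[hvg])
}
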
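# Readers for dense CSV/TSV and MatrixMarket (CellRanger layout) count
# matrices, and a plain-text directory bundle that persists preprocessing
# and graph results so training can be resumed or inspected.

#' Read a dense delimited count matrix
#'
#' @param path CSV or TSV file with row and column headers; the delimiter is
#'   inferred from the extension unless given.
#' @param cellsAsRows orientation of the file (default TRUE: rows are cells).
#' @param sep field separator; default `","` for `.csv`, tab otherwise.
#' @return a `SingleCellExperiment` with a genes x cells `counts` assay.
#' @export
readCountsCSV <- function(path, cellsAsRows = TRUE, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  nf <- count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1)
    stop(sprintf("malformed delimited file %s: ragged row at line %d",
                 path, which(nf != nf[1])[1]))
  df <- read.table(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("count matrix must be numeric")
  if (cellsAsRows) m <- t(m)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Read a MatrixMarket count matrix with name sidecar files
#'
#' Expects the CellRanger text layout: `matrix.mtx` (genes x cells triplets),
#' `features.tsv` or `genes.tsv` (gene ids in column 1) and `barcodes.tsv`.
#'
#' @param dir directory containing the three files (uncompressed).
#' @return a `SingleCellExperiment` with a genes x cells `counts` assay.
#' @export
readCountsMTX <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("matrix.mtx not found in ", dir)
  feat <- file.path(dir, "features.tsv")
  if (!file.exists(feat)) feat <- file.path(dir, "genes.tsv")
  bc <- file.path(dir, "barcodes.tsv")
  if (!file.exists(feat) || !file.exists(bc))
    stop("features/genes.tsv and barcodes.tsv are required beside matrix.mtx")
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- read.table(feat, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[, 1]
  cells <- read.table(bc, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[, 1]
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("matrix dimensions do not match features/barcodes files")
  dimnames(m) <- list(genes, cells)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write a counts SingleCellExperiment as MTX + sidecar files
#'
#' @param sce a SingleCellExperiment with a `counts` assay (genes x cells).
#' @param dir output directory (created if needed).
#' @param labels optional label vector written as `labels.csv`.
#' @return `dir`, invisibly.
#' @export
writeCountsMTX <- function(sce, dir, labels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(methods::as(m, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (!is.null(labels))
    write.table(data.frame(cell_id = colnames(m), label = labels),
                file.path(dir, "labels.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Persist / restore a preprocessed bundle
#'
#' Writes the preprocessing result (raw selected counts, z-scored input,
#' size factors, gene index) and optionally the cell graph as a plain-text
#' directory bundle (MTX + CSV + JSON), sufficient to resume training
#' deterministically.
#'
#' @param prep a [PreprocessedCounts-class] object.
#' @param graph optional [CellGraph-class] object.
#' @param dir bundle directory.
#' @return `dir`, invisibly (for `writeBundle`); for `readBundle`, a list
#'   with elements `prep` and (if present) `graph`.
#' @export
writeBundle <- function(prep, dir, graph = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(prep@counts, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  write.table(prep@xZscore, file.path(dir, "x_zscore.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  meta <- list(cellIds = prep@cellIds, geneIds = prep@geneIds,
               sizeFactors = prep@sizeFactors,
               hvgIndex = prep@hvgIndex, dispersion = prep@dispersion)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  if (!is.null(graph)) {
    write.table(graph@adjacency, file.path(dir, "adjacency.csv"), sep = ",",
                row.names = FALSE, col.names = FALSE)
    write.table(graph@transition, file.path(dir, "transition.csv"),
                sep = ",", row.names = FALSE, col.names = FALSE)
    write.table(graph@topoCorr, file.path(dir, "topo_corr.csv"), sep = ",",
                row.names = FALSE, col.names = FALSE)
    ginfo <- list(bandwidth = graph@bandwidth, order = graph@order,
                  kNeighbors = graph@kNeighbors,
                  neighbors = graph@neighbors)
    jsonlite::write_json(ginfo, file.path(dir, "graph.json"), digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  xz <- as.matrix(read.table(file.path(dir, "x_zscore.csv"), sep = ","))
  dimnames(counts) <- list(meta$cellIds, meta$geneIds)
  dimnames(xz) <- NULL
  rownames(xz) <- meta$cellIds
  prep <- methods::new("PreprocessedCounts", counts = counts, xZscore = xz,
                       sizeFactors = meta$sizeFactors,
                       hvgIndex = as.integer(meta$hvgIndex),
                       dispersion = meta$dispersion,
                       cellIds = meta$cellIds, geneIds = meta$geneIds)
  out <- list(prep = prep)
  gj <- file.path(dir, "graph.json")
  if (file.exists(gj)) {
    ginfo <- jsonlite::read_json(gj, simplifyVector = TRUE,
                                 simplifyMatrix = FALSE)
    nbr <- lapply(ginfo$neighbors, as.integer)
    out$graph <- methods::new("CellGraph",
      adjacency = unname(as.matrix(read.table(file.path(dir, "adjacency.csv"),
                                       sep = ","))),
      transition = unname(as.matrix(read.table(file.path(dir, "transition.csv"),
                                        sep = ","))),
      topoCorr = unname(as.matrix(read.table(file.path(dir, "topo_corr.csv"),
                                      sep = ","))),
      neighbors = nbr, bandwidth = ginfo$bandwidth,
      order = as.integer(ginfo$order),
      kNeighbors = as.integer(ginfo$kNeighbors))
  }
  out
}
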
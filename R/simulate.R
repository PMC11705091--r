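#' Splat-style scRNA-seq count simulation
#'
#' Generates a groups-mode gamma-Poisson (negative binomial) count matrix in
#' the style of the splat model: gene means drawn from a gamma distribution,
#' per-group differential-expression factors from a (possibly inverted)
#' log-normal, log-normal library sizes, a biological-coefficient-of-variation
#' layer producing overdispersion, and optional logistic dropout. The default
#' configuration emulates the published splat defaults: 5 groups whose cell
#' proportions are drawn uniformly at random from the simplex.
#'
#' @param nCells,nGenes,nGroups dimensions of the simulation.
#' @param groupProps either `"uniform-random"` (a symmetric Dirichlet(1) draw)
#'   or a probability vector of length `nGroups`.
#' @param meanShape,meanRate gamma hyperparameters of the gene mean.
#' @param deProb probability that a gene is differentially expressed in a
#'   group.
#' @param deFactorLoc,deFactorScale log-normal hyperparameters of the DE
#'   factor magnitude.
#' @param deDownProb probability that a DE factor is a down-regulation
#'   (reciprocal factor).
#' @param libsizeLoc,libsizeScale log-normal hyperparameters of the expected
#'   library size.
#' @param bcv biological coefficient of variation; counts are
#'   gamma-Poisson with gamma shape `1/bcv^2`, giving per-entry variance
#'   `mu + bcv^2 * mu^2`.
#' @param dropoutMid,dropoutShape logistic zero-inflation parameters applied
#'   when `dropout = TRUE` (probability of a technical zero as a decreasing
#'   function of log mean expression).
#' @param dropout logical; apply logistic dropout inside the simulator.
#'   Off by default: experiment-style dropout is injected afterwards with
#'   [injectDropout()], which operates on observed non-zero entries.
#' @param seed integer seed; the simulation is fully reproducible.
#'
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (genes x cells), `colData` column `Group` (factor of generating
#'   labels), and the full parameter list in `metadata(sce)$simulation`.
#'
#' @examples
#' sce <- simulateCounts(nCells = 60, nGenes = 100, nGroups = 3, seed = 1)
#' table(SummarizedExperiment::colData(sce)$Group)
#' @export
simulateCounts <- function(nCells = 5000, nGenes = 10000, nGroups = 5,
                           groupProps = "uniform-random",
                           meanShape = 0.6, meanRate = 0.3,
                           deProb = 0.1, deFactorLoc = 0.1,
                           deFactorScale = 0.4, deDownProb = 0.5,
                           libsizeLoc = 11, libsizeScale = 0.2,
                           bcv = 0.18,
                           dropoutMid = 0, dropoutShape = -1,
                           dropout = FALSE, seed = 1L) {
  if (nGroups > nCells)
    stop("nGroups must not exceed nCells")
  set.seed(substreamSeed(seed, "simulate"))

  if (identical(groupProps, "uniform-random")) {
    g <- rgamma(nGroups, shape = 1)   # symmetric Dirichlet(1)
    props <- g / sum(g)
  } else {
    if (length(groupProps) != nGroups || abs(sum(groupProps) - 1) > 1e-8)
      stop("groupProps must be a probability vector of length nGroups")
    props <- groupProps
  }
  labels <- sample.int(nGroups, nCells, replace = TRUE, prob = props)
  # guard: every group must appear at least once
  missing <- setdiff(seq_len(nGroups), unique(labels))
  if (length(missing))
    labels[sample.int(nCells, length(missing))] <- missing

  geneMean <- rgamma(nGenes, shape = meanShape, rate = meanRate)

  # per-group DE factors (1 for non-DE genes)
  deFac <- matrix(1, nGenes, nGroups)
  for (k in seq_len(nGroups)) {
    isDE <- runif(nGenes) < deProb
    fac <- exp(rnorm(nGenes, deFactorLoc, deFactorScale))
    down <- runif(nGenes) < deDownProb
    fac[down] <- 1 / fac[down]
    deFac[isDE, k] <- fac[isDE]
  }

  libSize <- rlnorm(nCells, libsizeLoc, libsizeScale)

  groupMean <- geneMean * deFac                     # genes x groups
  groupNorm <- sweep(groupMean, 2, colSums(groupMean), "/")

  # cells x genes expected expression scaled to each cell's library size
  mu <- t(groupNorm[, labels, drop = FALSE]) * libSize
  shape <- 1 / bcv^2
  lambda <- matrix(rgamma(length(mu), shape = shape, rate = shape / pmax(mu, 1e-300)),
                   nrow = nCells)
  counts <- matrix(rpois(length(lambda), lambda), nrow = nCells)

  if (dropout) {
    pDrop <- sigmoid(dropoutShape * (log(pmax(lambda, 1e-300)) - dropoutMid))
    keep <- matrix(runif(length(counts)) >= pDrop, nrow = nCells)
    counts <- counts * keep
  }

  cellIds <- sprintf("cell%0*d", nchar(nCells), seq_len(nCells))
  geneIds <- sprintf("gene%0*d", nchar(nGenes), seq_len(nGenes))
  dimnames(counts) <- list(cellIds, geneIds)

  spec <- list(nCells = nCells, nGenes = nGenes, nGroups = nGroups,
               groupProps = props, meanShape = meanShape, meanRate = meanRate,
               deProb = deProb, deFactorLoc = deFactorLoc,
               deFactorScale = deFactorScale, deDownProb = deDownProb,
               libsizeLoc = libsizeLoc, libsizeScale = libsizeScale,
               bcv = bcv, dropoutMid = dropoutMid,
               dropoutShape = dropoutShape, dropout = dropout, seed = seed)

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = t(counts)),
    colData = S4Vectors::DataFrame(Group = factor(labels),
                                   row.names = cellIds)
  )
  S4Vectors::metadata(sce)$simulation <- spec
  sce
}

#' Inject dropout by masking observed non-zero entries
#'
#' Samples `round(rate * nnz)` of the currently non-zero entries uniformly at
#' random and sets them to zero, emulating increasing technical dropout on
#' top of an observed count matrix. The input is not modified.
#'
#' @param x a counts matrix or a SingleCellExperiment with a `counts` assay.
#' @param rate fraction of non-zero entries to zero out, in `[0, 1)`.
#' @param seed integer seed for the mask draw.
#' @return a list with `counts` (same class as the input) and `mask`, an
#'   integer matrix of the zeroed (row, col) index pairs in the input's
#'   orientation.
#' @examples
#' m <- matrix(rpois(40, 3), 5, 8)
#' out <- injectDropout(m, rate = 0.25, seed = 1)
#' sum(out$counts == 0) - sum(m == 0)  # == nrow(out$mask)
#' @export
injectDropout <- function(x, rate, seed = 1L) {
  if (rate < 0 || rate >= 1)
    stop("rate must be in [0, 1)")
  isSCE <- methods::is(x, "SingleCellExperiment")
  m <- if (isSCE) as.matrix(SummarizedExperiment::assay(x, "counts")) else x
  nz <- which(m != 0)
  nDrop <- round(rate * length(nz))
  set.seed(substreamSeed(seed, "dropout"))
  drop <- if (nDrop > 0) sample(nz, nDrop) else integer(0)
  if (nDrop > 0) m[drop] <- 0
  mask <- cbind(row = ((drop - 1) %% nrow(m)) + 1,
                col = ((drop - 1) %/% nrow(m)) + 1)
  if (isSCE) {
    out <- x
    SummarizedExperiment::assay(out, "counts") <- m
  } else out <- m
  list(counts = out, mask = mask)
}
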
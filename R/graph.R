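# Cell-cell graph: Gaussian kernel on cosine distances, kNN sparsification
# (union symmetrisation), row-stochastic transition matrix B and the
# higher-order topological correlation R = (B + B^2 + ... + B^t) / t.

cosineDistance <- function(x) {
  nrm <- sqrt(rowSums(x * x))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero feature rows; cosine distance set to 2",
                    sum(zero)))
    nrm[zero] <- 1
  }
  xs <- x / nrm
  d <- 1 - tcrossprod(xs)
  d <- clampVal(d, 0, 2)
  if (any(zero)) {
    d[zero, ] <- 2
    d[, zero] <- 2
  }
  diag(d) <- 0
  d
}

#' Topological correlation of averaged transition-matrix powers
#'
#' `R = (B + B^2 + ... + B^t) / t` for a row-stochastic transition matrix B,
#' quantifying multi-hop proximity between cells up to order `t`.
#'
#' @param B square transition matrix.
#' @param t averaging order, integer >= 1.
#' @return dense matrix R of the same dimension.
#' @examples
#' B <- matrix(c(0, 1, 0, .5, 0, .5, 0, 1, 0), 3, byrow = TRUE)
#' topoCorrelation(B, 2)[1, 3]   # 0.25 on the 3-node path
#' @export
topoCorrelation <- function(B, t) {
  if (t < 1) stop("order t must be >= 1")
  acc <- B
  pow <- B
  if (t >= 2) for (s in 2:t) {
    pow <- pow %*% B
    acc <- acc + pow
  }
  acc / t
}

#' Build the cell-cell similarity graph
#'
#' Computes pairwise cosine distances on the preprocessed feature matrix,
#' applies the Gaussian kernel `A_ij = exp(-d_ij^2 / (2 r^2))`, sparsifies to
#' the `kNeighbors` highest-kernel neighbours per cell (symmetrised by
#' union), and derives the transition matrix B (`B_ij = 1/m_i` on retained
#' edges, `m_i` the degree) and the topological correlation R of order `t`.
#'
#' @param x feature matrix, cells x features (typically
#'   `prep@xZscore`).
#' @param r kernel bandwidth; `"auto"` (default) uses the median pairwise
#'   cosine distance.
#' @param kNeighbors neighbours kept per cell before symmetrisation.
#' @param t topological order for R.
#' @return a [CellGraph-class] object.
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' g <- buildCellGraph(x, kNeighbors = 3, t = 2)
#' g
#' @export
buildCellGraph <- function(x, r = "auto", kNeighbors = 15, t = 2) {
  n <- nrow(x)
  if (kNeighbors >= n) stop("kNeighbors must be smaller than the cell count")
  t <- as.integer(t)
  if (t < 1L) stop("order t must be >= 1")
  d <- cosineDistance(x)
  dimnames(d) <- NULL
  if (identical(r, "auto"))
    r <- median(d[upper.tri(d)])
  if (!is.numeric(r) || r <= 0) stop("bandwidth r must be positive")
  A <- exp(-d^2 / (2 * r^2))

  # k highest-kernel neighbours per cell (self excluded), union symmetrised
  nbr <- vector("list", n)
  Ax <- A
  diag(Ax) <- -Inf
  ord <- apply(Ax, 1, function(row) order(row, decreasing = TRUE)[seq_len(kNeighbors)])
  adj <- matrix(FALSE, n, n)
  adj[cbind(rep(seq_len(n), each = kNeighbors), as.vector(ord))] <- TRUE
  adj <- adj | t(adj)
  for (i in seq_len(n)) nbr[[i]] <- which(adj[i, ])

  deg <- rowSums(adj)
  B <- matrix(0, n, n)
  B[adj] <- 1
  B[deg > 0, ] <- B[deg > 0, , drop = FALSE] / deg[deg > 0]
  R <- topoCorrelation(B, t)

  methods::new("CellGraph",
    adjacency = A, neighbors = nbr, bandwidth = as.numeric(r),
    transition = B, topoCorr = R, order = t,
    kNeighbors = as.integer(kNeighbors))
}

# Edge list used by the attention layers: kNN-union edges plus self-loops,
# with the corresponding entries of R.
graphEdges <- function(graph) {
  n <- length(graph@neighbors)
  js <- lapply(seq_len(n), function(i) c(i, graph@neighbors[[i]]))
  ei <- rep.int(seq_len(n), lengths(js))
  ej <- unlist(js, use.names = FALSE)
  list(ei = ei, ej = ej, R = graph@topoCorr[cbind(ei, ej)], n = n)
}
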
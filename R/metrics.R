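# Clustering evaluation implemented from first principles: adjusted Rand
# index on the contingency table, NMI with geometric-mean normalisation
# (natural log), and the average silhouette width with Euclidean distances.

contingencyTable <- function(labelsTrue, labelsPred) {
  if (length(labelsTrue) != length(labelsPred))
    stop("label vectors must have equal length")
  table(true = labelsTrue, pred = labelsPred)
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions,
#' evaluated exactly on the contingency table with binomial coefficients.
#' Invariant to label renaming; 1 for identical partitions, about 0 for
#' independent ones.
#'
#' @param labelsTrue,labelsPred label vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @examples
#' adjustedRandIndex(c(0, 0, 0, 1, 1, 1), c(0, 0, 1, 1, 1, 1))
#' @export
adjustedRandIndex <- function(labelsTrue, labelsPred) {
  tab <- contingencyTable(labelsTrue, labelsPred)
  n <- sum(tab)
  if (n < 2) stop("at least two observations required")
  sumIj <- sum(choose(tab, 2))
  a <- rowSums(tab); b <- colSums(tab)
  sumA <- sum(choose(a, 2)); sumB <- sum(choose(b, 2))
  expected <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) {
    # both partitions trivial (single cluster each): identical by definition
    return(1)
  }
  (sumIj - expected) / (maxIdx - expected)
}

#' Normalised mutual information
#'
#' Mutual information between the two label distributions normalised by the
#' geometric mean of their entropies (natural log; the value is
#' base-invariant under this normalisation). A zero-entropy partition yields
#' 1 if the partitions are identical and 0 otherwise.
#'
#' @inheritParams adjustedRandIndex
#' @return scalar in `[0, 1]`.
#' @export
normalizedMutualInfo <- function(labelsTrue, labelsPred) {
  tab <- contingencyTable(labelsTrue, labelsPred)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj); pb <- colSums(pj)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha == 0 || hb == 0) {
    ident <- adjustedRandIndex(labelsTrue, labelsPred) == 1
    return(if (ident) 1 else 0)
  }
  mi <- sum(ifelse(pj > 0, pj * log(pj / outer(pa, pb)), 0))
  mi / sqrt(ha * hb)
}

#' Average silhouette width
#'
#' Per-cell silhouette `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the
#' mean Euclidean distance to the cell's own cluster and `b_i` the smallest
#' mean distance to another cluster, averaged over cells. Cells in singleton
#' clusters score 0 (convention); if all pairwise distances in a comparison
#' are zero the cell also scores 0.
#'
#' @param embedding numeric matrix, cells x dimensions.
#' @param labels cluster labels, one per row of `embedding`; at least two
#'   distinct clusters required.
#' @return scalar in `[-1, 1]`.
#' @export
silhouetteWidth <- function(embedding, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette requires at least two clusters")
  n <- nrow(embedding)
  d <- as.matrix(dist(embedding))
  sizes <- tabulate(labels, k)
  # mean distance from each cell to each cluster
  byCluster <- t(rowsum(t(d), labels)) / rep(sizes, each = n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- byCluster[i, ci] * sizes[ci] / (sizes[ci] - 1)  # exclude self
    b <- min(byCluster[i, -ci])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Evaluate a clustering against ground truth and/or by cohesion
#'
#' @param fit a [ZigaclFit-class] object, or an integer label vector (then
#'   `embedding` must be supplied for the silhouette).
#' @param labelsTrue optional ground-truth labels for ARI/NMI.
#' @param embedding optional embedding overriding the fit's latent space.
#' @return named list with `asw` and, when truth is given, `ari` and `nmi`.
#' @export
clusterMetrics <- function(fit, labelsTrue = NULL, embedding = NULL) {
  if (methods::is(fit, "ZigaclFit")) {
    labels <- fit@labels
    if (is.null(embedding)) embedding <- fit@latent
  } else {
    labels <- fit
    if (is.null(embedding)) stop("an embedding is required for the silhouette")
  }
  out <- list(asw = silhouetteWidth(embedding, labels))
  if (!is.null(labelsTrue)) {
    out$ari <- adjustedRandIndex(labelsTrue, labels)
    out$nmi <- normalizedMutualInfo(labelsTrue, labels)
  }
  out
}
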
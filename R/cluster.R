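# Student-t soft assignment, sharpened target distribution and KL losses —
# the co-supervision machinery of deep embedded clustering.

#' Student-t soft cluster assignment
#'
#' `q_ik` proportional to `(1 + ||h_i - u_k||^2 / v)^(-(v+1)/2)`, normalised
#' over clusters: the probability of assigning cell i to centre k under a
#' Student-t kernel on latent distances.
#'
#' @param h latent representation, cells x latentDim.
#' @param centers cluster centres, k x latentDim.
#' @param v Student-t degrees of freedom (default 1, the standard
#'   deep-embedded-clustering choice).
#' @return row-stochastic cells x k matrix Q.
#' @examples
#' softAssign(matrix(0, 1, 1), matrix(c(0, 2), 2, 1))  # c(5/6, 1/6)
#' @export
softAssign <- function(h, centers, v = 1) {
  if (nrow(centers) < 1) stop("at least one cluster centre required")
  d2 <- outer(rowSums(h * h), rowSums(centers * centers), "+") -
    2 * tcrossprod(h, centers)
  d2 <- pmax(d2, 0)
  num <- (1 + d2 / v)^(-(v + 1) / 2)
  num / rowSums(num)
}

#' Sharpened target distribution
#'
#' `p_ik = (q_ik^2 / F_k) / sum_k' (q_ik'^2 / F_k')` with soft label
#' frequency `F_k = sum_i q_ik`: squaring emphasises confident assignments
#' while the frequency normalisation counteracts large-cluster dominance.
#' Empty clusters (`F_k = 0`) are dropped from the normalisation with a
#' warning.
#'
#' @param q row-stochastic soft assignment matrix.
#' @return row-stochastic target matrix P of the same shape.
#' @export
targetDistribution <- function(q) {
  f <- colSums(q)
  w <- q * q
  if (any(f == 0)) {
    warning(sprintf("%d empty cluster(s) dropped from target normalisation",
                    sum(f == 0)))
    w[, f == 0] <- 0
    f[f == 0] <- 1
  }
  w <- sweep(w, 2, f, "/")
  w / rowSums(w)
}

#' KL divergence between row-stochastic matrices
#'
#' `KL(p || s) = sum_ik p_ik log(p_ik / s_ik)`, with `s` clipped away from
#' zero; reduced to a per-cell mean by default so the loss is comparable
#' across dataset sizes.
#'
#' @param p,s row-stochastic matrices of identical shape.
#' @param reduce `"mean"` (per-row mean, default) or `"sum"`.
#' @param eps clipping floor for `s` (and `p` inside the log).
#' @return non-negative scalar; 0 iff `p == s` up to clipping.
#' @export
klDivergence <- function(p, s, reduce = c("mean", "sum"), eps = 1e-12) {
  reduce <- match.arg(reduce)
  if (!all(dim(p) == dim(s))) stop("shape mismatch")
  s <- pmax(s, eps)
  term <- ifelse(p > 0, p * (log(pmax(p, eps)) - log(s)), 0)
  tot <- sum(term)
  if (reduce == "mean") tot / nrow(p) else tot
}

#' Weighted total training loss
#'
#' `L = L_ZINB + alpha * L_clu + beta * L_GAT`.
#'
#' @param lZinb,lClu,lGat component losses.
#' @param alpha clustering-loss weight (default 0.1).
#' @param beta GAT-loss weight (default 0.01).
#' @return scalar total loss.
#' @export
totalLoss <- function(lZinb, lClu, lGat, alpha = 0.1, beta = 0.01) {
  stopifnot(is.finite(lZinb), is.finite(lClu), is.finite(lGat))
  lZinb + alpha * lClu + beta * lGat
}

# Gradient of KL(P || Q)/n with respect to the latent h and the centres,
# treating P as a constant target. Returns dL/dh and dL/dcenters.
softAssignGrad <- function(h, centers, q, p, v = 1) {
  n <- nrow(h)
  d2 <- outer(rowSums(h * h), rowSums(centers * centers), "+") -
    2 * tcrossprod(h, centers)
  d2 <- pmax(d2, 0)
  base <- 1 + d2 / v
  num <- base^(-(v + 1) / 2)
  S <- rowSums(num)
  dLdq <- -(p / pmax(q, 1e-12)) / n
  # q = num / S: dL/dnum_ik = (dLdq_ik - sum_j dLdq_ij q_ij) / S_i
  rowDot <- rowSums(dLdq * q)
  dNum <- (dLdq - rowDot) / S
  dD2 <- dNum * (-(v + 1) / (2 * v)) * num / base
  dh <- 2 * (h * rowSums(dD2) - dD2 %*% centers)
  dCenters <- 2 * (centers * colSums(dD2) - crossprod(dD2, h))
  list(dh = dh, dCenters = dCenters)
}
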
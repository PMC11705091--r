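# Zero-inflated negative binomial likelihood, computed in log space.
#
# ZINB(x | pi, mu, theta) = pi * I[x = 0] + (1 - pi) * NB(x | mu, theta)
# NB log pmf: lgamma(x + theta) - lgamma(theta) - lgamma(x + 1)
#             + theta * (log theta - log(theta + mu))
#             + x * (log mu - log(theta + mu))
# Numerical guards: pi in [1e-8, 1 - 1e-8]; mu, theta in [1e-4, 1e4].

PI_EPS <- 1e-8
PAR_LO <- 1e-4
PAR_HI <- 1e4

nbLogPmf <- function(x, mu, theta) {
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(mu) - log(theta + mu))
}

#' Negative log-likelihood of counts under a ZINB model
#'
#' Evaluates `-log ZINB(x | pi, mu, theta)` entrywise in log space (log-gamma
#' for the NB pmf, log-sum-exp for the zero branch) and reduces it.
#'
#' @param x observed counts (non-negative; same shape as the parameters).
#' @param pi dropout probability, in (0, 1).
#' @param mu NB mean, positive.
#' @param theta NB dispersion, positive.
#' @param reduce `"mean"` (per-entry mean, default), `"sum"`, or `"none"`
#'   for the entrywise matrix.
#' @return non-negative scalar (or matrix for `reduce = "none"`).
#' @examples
#' zinbNLL(0, pi = 1 - 1e-12, mu = 5, theta = 2)  # dropout explains a zero
#' zinbNLL(3, pi = 1e-12, mu = 2, theta = 5)      # plain NB branch
#' @export
zinbNLL <- function(x, pi, mu, theta, reduce = c("mean", "sum", "none")) {
  reduce <- match.arg(reduce)
  if (any(x < 0)) stop("counts must be non-negative")
  if (length(pi) != length(x) && length(pi) != 1)
    stop("parameter shapes must match the counts")
  pi <- clampVal(pi, PI_EPS, 1 - PI_EPS)
  mu <- clampVal(mu, PAR_LO, PAR_HI)
  theta <- clampVal(theta, PAR_LO, PAR_HI)
  ll <- log1p(-pi) + nbLogPmf(x, mu, theta)
  zero <- x == 0
  if (any(zero)) {
    # log(pi + (1 - pi) * NB(0)) via log-sum-exp
    a <- log(pi)[if (length(pi) == 1) TRUE else zero]
    b <- ll[zero]
    mx <- pmax(a, b)
    ll[zero] <- mx + log(exp(a - mx) + exp(b - mx))
  }
  nll <- -ll
  switch(reduce, mean = mean(nll), sum = sum(nll), none = nll)
}

# Entrywise gradients of the per-entry mean NLL with respect to pi, mu and
# theta. The compiled single-pass implementation is used on matrices (one
# call per training step); the R fallback below doubles as its reference in
# the gradient-check tests. Returns dL/dpi, dL/dmu, dL/dtheta (already
# divided by the entry count) plus the scalar loss.
zinbNLLGrad <- function(x, pi, mu, theta) {
  out <- .zinbLossGradCpp(as.matrix(x), as.matrix(pi), as.matrix(mu),
                          as.matrix(theta))
  out
}

zinbNLLGradR <- function(x, pi, mu, theta) {
  pi <- clampVal(pi, PI_EPS, 1 - PI_EPS)
  mu <- clampVal(mu, PAR_LO, PAR_HI)
  theta <- clampVal(theta, PAR_LO, PAR_HI)
  n <- length(x)
  zero <- x == 0

  tm <- theta + mu
  lth <- log(theta)
  ltm <- log(tm)
  lratio0 <- theta * (lth - ltm)          # NB log pmf at x = 0
  # positive branch everywhere, then overwrite the zero entries
  ratio <- (theta + x) / tm
  dpi <- 1 / (1 - pi)
  dmu <- -(x / mu - ratio)
  dth <- -(digamma(x + theta) - digamma(theta) + lth + 1 - ltm - ratio)
  llPos <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    lratio0 + x * (log(mu) - ltm)
  ll <- log1p(-pi) + llPos

  a <- exp(lratio0)                       # NB(0)
  lik0 <- pi + (1 - pi) * a
  dLda <- -(1 - pi) / lik0
  zTerm <- lth + 1 - ltm - theta / tm
  dpi0 <- -(1 - a) / lik0
  dmu0 <- dLda * (-a * theta / tm)
  dth0 <- dLda * a * zTerm
  dpi[zero] <- dpi0[zero]
  dmu[zero] <- dmu0[zero]
  dth[zero] <- dth0[zero]
  ll[zero] <- log(lik0[zero])

  list(loss = -sum(ll) / n, dpi = dpi / n, dmu = dmu / n, dtheta = dth / n)
}
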
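# Joint fine-tuning of the autoencoder and GAT under the co-supervised
# objective L = L_ZINB + alpha * KL(P || Q) + beta * KL(P || Z).

#' Training configuration for the co-supervised phase
#'
#' @param alpha clustering-loss weight (default 0.1).
#' @param beta GAT-loss weight (default 0.01).
#' @param lr Adam learning rate (default 0.001).
#' @param gradClip maximum global L2 gradient norm (default 3).
#' @param labelChangeTol early-stopping threshold on the fraction of cells
#'   changing label between target updates (default 0.001, i.e. 0.1%).
#' @param pUpdateInterval epochs between recomputations of the target
#'   distribution P (default 5).
#' @param maxEpochs fine-tuning epoch cap (default 300).
#' @param lambda fusion weight of the GAT branch (default 0.4).
#' @param v Student-t degrees of freedom (default 1).
#' @param kmeansRestarts restarts of the k-means initialisation (default 20).
#' @param seed integer seed controlling every stochastic stage.
#' @return named list of training settings.
#' @export
trainConfig <- function(alpha = 0.1, beta = 0.01, lr = 1e-3, gradClip = 3,
                        labelChangeTol = 0.001, pUpdateInterval = 5,
                        maxEpochs = 300, lambda = 0.4, v = 1,
                        kmeansRestarts = 20, seed = 1L) {
  stopifnot(alpha >= 0, beta >= 0, lr > 0, gradClip > 0,
            labelChangeTol > 0, pUpdateInterval >= 1, maxEpochs >= 1)
  list(alpha = alpha, beta = beta, lr = lr, gradClip = gradClip,
       labelChangeTol = labelChangeTol, pUpdateInterval = pUpdateInterval,
       maxEpochs = maxEpochs, lambda = lambda, v = v,
       kmeansRestarts = kmeansRestarts, seed = as.integer(seed))
}

hardLabels <- function(q) max.col(q, ties.method = "first")

#' Fit the co-supervised clustering model
#'
#' Initialises cluster centres by seeded k-means on the pretrained latent
#' representation, then jointly optimises the autoencoder (ZINB
#' reconstruction), the Student-t clustering head and the GAT head with
#' Adam and global gradient clipping. The target distribution P is
#' recomputed every `pUpdateInterval` epochs from the current Q; training
#' halts early once fewer than `labelChangeTol` of the cells change their
#' argmax-Q label between consecutive target updates.
#'
#' @param prep a [PreprocessedCounts-class] object.
#' @param graph a [CellGraph-class] built on `prep@xZscore`.
#' @param model a pretrained [ZinbModel-class].
#' @param k number of clusters.
#' @param config a [trainConfig()] list.
#' @param verbose print loss components every 10 epochs.
#' @return a [ZigaclFit-class] object.
#' @export
fitZigacl <- function(prep, graph, model, k, config = trainConfig(),
                      verbose = FALSE) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(prep@counts)) stop("k cannot exceed the number of cells")
  x <- prep@xZscore
  counts <- prep@counts
  sf <- prep@sizeFactors
  n <- nrow(x)
  aeCfg <- model@config
  w <- model@weights
  bn <- model@bnStats

  # centre initialisation: k-means on the pretrained latent space
  set.seed(substreamSeed(config$seed, "kmeans"))
  km <- kmeans(model@latent, centers = k, nstart = config$kmeansRestarts,
               iter.max = 100)
  centers <- km$centers
  dimnames(centers) <- NULL

  gCfg <- gatConfig(dims = c(ncol(x), aeCfg$hiddenDims, aeCfg$latentDim),
                    lambda = config$lambda, slope = 0.2, k = k)
  set.seed(substreamSeed(config$seed, "init"))
  gw <- gatInitWeights(gCfg)
  edges <- graphEdges(graph)

  params <- c(w, list(centers = centers), gw)
  nAe <- length(w)
  opt <- adamInit(params)
  hist <- data.frame()
  p <- NULL
  prevLabels <- NULL
  halted <- FALSE

  set.seed(substreamSeed(config$seed, "finetune"))
  for (ep in seq_len(config$maxEpochs)) {
    w <- params[seq_len(nAe)]
    centers <- params$centers
    gw <- params[(nAe + 2):length(params)]

    # deterministic eval-mode latent for the target, labels and early stop
    hEval <- aeForward(w, bn, x, sf, aeCfg, training = FALSE,
                       withHeads = FALSE)$h
    qEval <- softAssign(hEval, centers, config$v)
    labels <- hardLabels(qEval)
    labelChange <- if (is.null(prevLabels)) NA_real_
                   else mean(labels != prevLabels)
    if ((ep - 1) %% config$pUpdateInterval == 0) {
      if (!is.null(prevLabels) && labelChange < config$labelChangeTol) {
        halted <- TRUE
        config$haltLabelChange <- labelChange
        break
      }
      p <- targetDistribution(qEval)
      prevLabels <- labels
    }

    # shared noisy forward for all three loss branches
    fwd <- aeForward(w, bn, x, sf, aeCfg, training = TRUE)
    bn <- fwd$bn
    zgr <- zinbNLLGrad(counts, fwd$pi, fwd$mu, fwd$theta)
    q <- softAssign(fwd$h, centers, config$v)
    lClu <- klDivergence(p, q)
    gFwd <- gatForwardFull(gw, x, list(fwd$h1, fwd$h2, fwd$h), edges, gCfg)
    lGat <- klDivergence(p, gFwd$z)
    loss <- totalLoss(zgr$loss, lClu, lGat, config$alpha, config$beta)
    if (!is.finite(loss))
      stop(sprintf("fine-tuning diverged (loss %s) at epoch %d", loss, ep))

    cluGr <- softAssignGrad(fwd$h, centers, q, p, config$v)
    dLogits <- config$beta * (gFwd$z - p) / n
    gBk <- gatBackwardFull(gw, gFwd, edges, gCfg, dLogits)
    aeGr <- aeBackward(w, fwd, aeCfg, gPi = zgr$dpi, gMu = zgr$dmu,
                       gTheta = zgr$dtheta,
                       dhExtra = config$alpha * cluGr$dh + gBk$dH[[3]],
                       dh1Extra = gBk$dH[[1]], dh2Extra = gBk$dH[[2]])
    grads <- c(aeGr, list(centers = config$alpha * cluGr$dCenters),
               gBk$grads)
    cl <- clipGradsL2(grads, config$gradClip)
    st <- adamStep(params, cl$grads, opt, lr = config$lr)
    params <- st$params; opt <- st$state

    hist <- rbind(hist, data.frame(epoch = ep, lZinb = zgr$loss,
                                   lClu = lClu, lGat = lGat, loss = loss,
                                   gradNorm = cl$clippedNorm,
                                   labelChange = labelChange))
    if (verbose && ep %% 10 == 0)
      message(sprintf(
        "epoch %d: L=%.4f (zinb %.4f, clu %.4f, gat %.4f) dlabel=%.4f",
        ep, loss, zgr$loss, lClu, lGat, labelChange))
  }

  w <- params[seq_len(nAe)]
  centers <- params$centers
  gw <- params[(nAe + 2):length(params)]
  hFinal <- aeForward(w, bn, x, sf, aeCfg, training = FALSE,
                      withHeads = FALSE)
  qFinal <- softAssign(hFinal$h, centers, config$v)
  pFinal <- targetDistribution(qFinal)
  zFinal <- gatForwardFull(gw, x, list(hFinal$h1, hFinal$h2, hFinal$h),
                           edges, gCfg)$z
  lab <- hardLabels(qFinal)
  lat <- hFinal$h
  rownames(lat) <- prep@cellIds
  config$halted <- halted
  methods::new("ZigaclFit",
    labels = as.integer(lab), q = qFinal, p = pFinal, z = zFinal,
    centers = centers, latent = lat, history = hist, metrics = list(),
    config = config, cellIds = prep@cellIds)
}
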
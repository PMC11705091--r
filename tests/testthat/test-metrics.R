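# Brute-force pair-counting ARI oracle: classify every pair of points by
# whether the two partitions agree on it.
ariPairsOracle <- function(lt, lp) {
  n <- length(lt)
  a <- b <- cc <- d <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    st <- lt[i] == lt[j]; sp <- lp[i] == lp[j]
    if (st && sp) a <- a + 1
    else if (st && !sp) b <- b + 1
    else if (!st && sp) cc <- cc + 1
    else d <- d + 1
  }
  2 * (a * d - b * cc) / ((a + b) * (b + d) + (a + cc) * (cc + d))
}

test_that("ARI agrees with hand arithmetic and pair-counting oracles", {
  lt <- c(0, 0, 0, 1, 1, 1)
  lp <- c(0, 0, 1, 1, 1, 1)
  # contingency (2,1;0,3): sum nij C2 = 4; a=(3,3) -> 6; b=(2,4) -> 7
  # expected = 6*7/15 = 2.8; max = 6.5; ARI = 1.2/3.7
  expect_equal(adjustedRandIndex(lt, lp), 1.2 / 3.7)
  expect_equal(adjustedRandIndex(lt, lp), ariPairsOracle(lt, lp))

  expect_equal(adjustedRandIndex(lt, lt), 1)
  expect_equal(adjustedRandIndex(lt, c(7, 7, 7, 2, 2, 2)), 1)

  set.seed(8)
  for (rep in 1:6) {
    n <- sample(10:50, 1)
    l1 <- sample(1:4, n, replace = TRUE)
    l2 <- sample(1:3, n, replace = TRUE)
    expect_equal(adjustedRandIndex(l1, l2), ariPairsOracle(l1, l2),
                 tolerance = 1e-12)
    expect_equal(adjustedRandIndex(l1, l2),
                 mclust::adjustedRandIndex(l1, l2), tolerance = 1e-12)
    # invariance under renaming and joint permutation
    perm <- sample(n)
    expect_equal(adjustedRandIndex(l1[perm], l2[perm]),
                 adjustedRandIndex(l1, l2))
    expect_equal(adjustedRandIndex(l1, 5 - l2), adjustedRandIndex(l1, l2))
  }
})

test_that("NMI matches an explicit entropy oracle and its limits", {
  lt <- c(1, 1, 2, 2)
  lp <- c(1, 2, 2, 2)
  pj <- table(lt, lp) / 4
  pa <- rowSums(pj); pb <- colSums(pj)
  mi <- 0
  for (i in 1:2) for (j in 1:2) if (pj[i, j] > 0)
    mi <- mi + pj[i, j] * log(pj[i, j] / (pa[i] * pb[j]))
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(normalizedMutualInfo(lt, lp),
               unname(mi / sqrt(h(pa) * h(pb))))

  expect_equal(normalizedMutualInfo(lt, lt), 1)
  expect_equal(normalizedMutualInfo(lt, c(9, 9, 1, 1)), 1)
  # independent labelings at large n are near zero
  set.seed(10)
  l1 <- sample(1:5, 10000, replace = TRUE)
  l2 <- sample(1:5, 10000, replace = TRUE)
  expect_lt(normalizedMutualInfo(l1, l2), 0.05)
  # degenerate single-cluster partitions
  expect_equal(normalizedMutualInfo(rep(1, 5), rep(2, 5)), 1)
  expect_equal(normalizedMutualInfo(rep(1, 5), c(1, 1, 2, 2, 2)), 0)
})

test_that("silhouette matches hand arithmetic and a per-point loop", {
  # 1-D points (0, 1 | 10, 11): outer points score 9.5/10.5 (a = 1,
  # b = (10+11)/2), inner points 8.5/9.5 (a = 1, b = (9+10)/2)
  emb <- matrix(c(0, 1, 10, 11), 4, 1)
  expect_equal(silhouetteWidth(emb, c(0, 0, 1, 1)),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)))

  # tight, far-apart blobs approach 1
  set.seed(2)
  blob <- rbind(matrix(rnorm(40, 0, .1), 20), matrix(rnorm(40, 20, .1), 20))
  expect_gt(silhouetteWidth(blob, rep(1:2, each = 20)), 0.95)

  # all points identical: a = b = 0 scores 0 by convention
  expect_equal(silhouetteWidth(matrix(1, 6, 2), rep(1:2, 3)), 0)

  # per-point scalar-loop oracle on random data, including vs cluster::
  set.seed(3)
  emb <- matrix(rnorm(30 * 4), 30)
  lab <- sample(1:3, 30, replace = TRUE)
  d <- as.matrix(dist(emb))
  sOracle <- numeric(30)
  for (i in 1:30) {
    own <- which(lab == lab[i] & seq_len(30) != i)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(1:3, lab[i]),
                    function(k) mean(d[i, lab == k]), numeric(1)))
    sOracle[i] <- (b - a) / max(a, b)
  }
  expect_equal(silhouetteWidth(emb, lab), mean(sOracle), tolerance = 1e-12)
  expect_equal(silhouetteWidth(emb, lab),
               mean(cluster::silhouette(lab, dist(emb))[, "sil_width"]),
               tolerance = 1e-12)
  expect_error(silhouetteWidth(emb, rep(1, 30)), "two clusters")
})

test_that("metric inputs are validated", {
  expect_error(adjustedRandIndex(1:3, 1:4), "equal length")
  expect_error(adjustedRandIndex(1, 1), "at least two")
})
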
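test_that("squared Euclidean distance counts differing markers", {
  m <- rbind(a = c(1, 0, 1), b = c(0, 0, 1), c = c(0, 1, 0))
  colnames(m) <- paste0("L", 1:3)
  d <- squaredEuclideanDistances(BinaryMarkerMatrix(m))
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 3)  # complementary rows of length 3
  expect_true(isSymmetric(d))
})

test_that("the 2-group, 10-population, 160-individual design gives dfs 1/8/150", {
  set.seed(2)
  des <- balancedDesign(2, 5, 16)
  x <- randomMarkerMatrix(160, 12)
  d <- squaredEuclideanDistances(x)
  rownames(d) <- colnames(d) <- des$samples
  res <- amovaTwoLevel(d, des$populations, des$groups, nPermutations = 0)
  expect_equal(amovaTable(res)$df, c(1L, 8L, 150L))
  # coefficient closed forms for the balanced design
  core <- epiclover:::.amovaCore(d, unname(des$populations[rownames(d)]),
                                 des$groups)
  expect_equal(unname(core$coef), c(16, 16, 80))
})

test_that("the three sums of squares add to the total sum of squares", {
  set.seed(8)
  for (k in 1:5) {
    des <- balancedDesign(2, 3, sample(2:5, 1))
    n <- length(des$samples)
    x <- randomMarkerMatrix(n, 20)
    d <- squaredEuclideanDistances(x)
    rownames(d) <- colnames(d) <- des$samples
    res <- amovaTwoLevel(d, des$populations, des$groups, nPermutations = 0)
    ssTotal <- sum(d[upper.tri(d)]) / n
    expect_equal(sum(amovaTable(res)$SS), ssTotal, tolerance = 1e-9)
  }
})

test_that("variance components equal a direct-sum oracle on small data", {
  set.seed(14)
  for (k in 1:6) {
    nPerPop <- 2
    des <- balancedDesign(2, 2, nPerPop)  # 2 groups x 2 pops x 2 inds
    n <- length(des$samples)
    x <- randomMarkerMatrix(n, 4)
    # inject visible group structure so components are non-trivial
    v <- markerValues(x); v[1:(n / 2), 1:2] <- 1; v[(n / 2 + 1):n, 1:2] <- 0
    d <- squaredEuclideanDistances(BinaryMarkerMatrix(v))
    rownames(d) <- colnames(d) <- des$samples
    res <- amovaTwoLevel(d, des$populations, des$groups, nPermutations = 0)

    # oracle: the defining sums written out directly
    pop <- unname(des$populations[rownames(d)])
    grp <- unname(des$groups[pop])
    ssT <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) ssT <- ssT + d[i, j]
    ssT <- ssT / n
    ssW <- 0
    for (p in unique(pop)) {
      idx <- which(pop == p); s <- 0
      for (i in idx) for (j in idx) s <- s + d[i, j]
      ssW <- ssW + s / 2 / length(idx)
    }
    ssG <- 0
    for (g in unique(grp)) {
      idx <- which(grp == g); s <- 0
      for (i in idx) for (j in idx) s <- s + d[i, j]
      ssG <- ssG + s / 2 / length(idx)
    }
    ssAP <- ssG - ssW; ssAG <- ssT - ssG
    K <- 4; G <- 2
    msAG <- ssAG / (G - 1); msAP <- ssAP / (K - G); msW <- ssW / (n - K)
    # balanced coefficients: n' = n'' = nPerPop, n''' = n/2
    vc <- msW
    vb <- (msAP - vc) / nPerPop
    va <- (msAG - vc - nPerPop * vb) / (n / 2)
    est <- pmax(c(va, vb, vc), 0)
    expect_equal(amovaTable(res)$estVar, unname(est), tolerance = 1e-10)
    phiPT <- if (sum(est) > 0) (est[1] + est[2]) / sum(est) else 0
    expect_equal(phiStatistics(res)[["phi_PT"]], phiPT, tolerance = 1e-10)
  }
})

test_that("identical individuals give zero variance and Phi = 0 with a warning", {
  n <- 8
  v <- matrix(1, n, 5, dimnames = list(paste0("i", 1:n), paste0("L", 1:5)))
  d <- squaredEuclideanDistances(BinaryMarkerMatrix(v))
  pops <- setNames(rep(c("p1", "p2", "p3", "p4"), each = 2), paste0("i", 1:n))
  grps <- c(p1 = "A", p2 = "A", p3 = "B", p4 = "B")
  expect_warning(res <- amovaTwoLevel(d, pops, grps, nPermutations = 9),
                 "no molecular variance")
  expect_true(all(amovaTable(res)$SS == 0))
  expect_equal(unname(phiStatistics(res)), c(0, 0, 0))
  expect_length(amovaPValues(res), 0)
})

test_that("misassigned hierarchies and singleton populations are rejected", {
  d <- squaredEuclideanDistances(randomMarkerMatrix(6, 5))
  pops <- setNames(c("p1", "p1", "p2", "p2", "p3", "p3"), rownames(d))
  expect_error(
    amovaTwoLevel(d, pops, c(p1 = "A", p1 = "B", p2 = "A", p3 = "B")),
    "two groups")
  pops2 <- setNames(c("p1", "p1", "p1", "p2", "p2", "p3"), rownames(d))
  expect_error(
    amovaTwoLevel(d, pops2, c(p1 = "A", p2 = "B", p3 = "B")),
    "fewer than 2 individuals")
})

test_that("permutation p-values respect the (b+1)/(m+1) bounds and row-order invariance", {
  set.seed(77)
  des <- balancedDesign(2, 3, 4)
  x <- randomMarkerMatrix(24, 30)
  d <- squaredEuclideanDistances(x)
  rownames(d) <- colnames(d) <- des$samples
  res <- amovaPermutationTest(d, des$populations, des$groups, "phi_PT",
                              nPermutations = 99, seed = 5)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
  expect_error(amovaPermutationTest(d, des$populations, des$groups, "phi_PT",
                                    nPermutations = 0), "nPermutations")
  # reordering the rows leaves the observed statistic identical and the
  # p-value equal up to Monte Carlo error
  perm <- sample(24)
  d2 <- d[perm, perm]
  res2 <- amovaPermutationTest(d2, des$populations, des$groups, "phi_PT",
                               nPermutations = 499, seed = 6)
  res1 <- amovaPermutationTest(d, des$populations, des$groups, "phi_PT",
                               nPermutations = 499, seed = 6)
  expect_equal(res1$observed, res2$observed, tolerance = 1e-12)
  expect_lt(abs(res1$p - res2$p), 0.1)
})

test_that("pairwise PhiPT spans its 0 and 1 extremes and fills all pairs", {
  # two identical populations -> 0
  v <- matrix(rep(c(1, 0, 1, 0, 1), 4), 4, byrow = TRUE,
              dimnames = list(paste0("i", 1:4), paste0("L", 1:5)))
  d <- squaredEuclideanDistances(BinaryMarkerMatrix(v))
  pops <- setNames(c("p1", "p1", "p2", "p2"), paste0("i", 1:4))
  pw <- pairwisePhiPT(d, pops, nPermutations = 0)
  expect_equal(pw$phi["p1", "p2"], 0)
  # two populations fixed for complementary bands -> 1
  v2 <- rbind(i1 = c(1, 1, 1), i2 = c(1, 1, 1),
              i3 = c(0, 0, 0), i4 = c(0, 0, 0))
  colnames(v2) <- paste0("L", 1:3)
  d2 <- squaredEuclideanDistances(BinaryMarkerMatrix(v2))
  pw2 <- pairwisePhiPT(d2, pops, nPermutations = 19, seed = 1)
  expect_equal(pw2$phi["p1", "p2"], 1)
  # 10 populations -> 45 unique off-diagonal entries
  set.seed(99)
  des <- balancedDesign(2, 5, 3)
  x <- randomMarkerMatrix(30, 15)
  d3 <- squaredEuclideanDistances(x)
  rownames(d3) <- colnames(d3) <- des$samples
  pw3 <- pairwisePhiPT(d3, des$populations, nPermutations = 0)
  expect_equal(dim(pw3$phi), c(10L, 10L))
  expect_equal(sum(upper.tri(pw3$phi)), 45L)
  expect_true(all(pw3$phi >= 0))
  expect_true(isSymmetric(pw3$phi))
})

test_that("one-level and two-level analyses agree on the total SS partition", {
  set.seed(55)
  des <- balancedDesign(2, 4, 4)
  x <- randomMarkerMatrix(32, 25)
  d <- squaredEuclideanDistances(x)
  rownames(d) <- colnames(d) <- des$samples
  one <- amovaOneLevel(d, des$populations, nPermutations = 0)
  two <- amovaTwoLevel(d, des$populations, des$groups, nPermutations = 0)
  expect_equal(sum(amovaTable(one)$SS), sum(amovaTable(two)$SS),
               tolerance = 1e-9)
  # within-population SS identical across parameterizations
  expect_equal(amovaTable(one)$SS[2], amovaTable(two)$SS[3], tolerance = 1e-9)
})
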
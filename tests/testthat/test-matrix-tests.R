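test_that("geographic distances follow the haversine closed form", {
  sites <- data.frame(population_id = c("a", "b", "c"),
                      habitat = "CG",
                      latitude = c(48, 49, 48), longitude = c(9, 9, 9))
  d <- geographicDistanceMatrix(sites)
  expect_equal(d["a", "c"], 0)
  expect_equal(round(d["a", "b"], 3), 111.195)  # one degree of latitude
  sites$latitude[2] <- NA
  expect_error(geographicDistanceMatrix(sites), "missing coordinate")
})

test_that("geographic distances are symmetric and satisfy the triangle inequality", {
  set.seed(4)
  for (k in 1:4) {
    n <- sample(4:8, 1)
    sites <- data.frame(population_id = paste0("p", 1:n), habitat = "CG",
                        latitude = runif(n, 45, 50),
                        longitude = runif(n, 5, 12))
    d <- geographicDistanceMatrix(sites)
    expect_true(isSymmetric(d))
    for (i in 1:n) for (j in 1:n) for (l in 1:n)
      expect_lte(d[i, j], d[i, l] + d[l, j] + 1e-9)
  }
})

test_that("habitat dissimilarity codes unequal pairs 1 and equal pairs 0", {
  sites <- data.frame(population_id = paste0("p", 1:10),
                      habitat = rep(c("CG", "OM"), each = 5))
  h <- habitatDissimilarityMatrix(sites)
  expect_equal(h["p1", "p6"], 1)  # CG vs OM
  expect_equal(h["p1", "p2"], 0)  # CG vs CG
  expect_equal(sum(h[upper.tri(h)]), 25)  # 5x5 cross pairs of 45
})

test_that("Mantel r is the upper-triangle Pearson correlation", {
  set.seed(10)
  a <- randomDistanceMatrix(8)
  expect_equal(mantelTest(a, a, nPermutations = 9, seed = 1)$r, 1)
  b <- randomDistanceMatrix(8)
  expect_equal(mantelTest(a, b, nPermutations = 9, seed = 1)$r,
               cor(a[upper.tri(a)], b[upper.tri(b)]))
  expect_equal(mantelTest(a, b, nPermutations = 99, seed = 1)$r,
               mantelTest(b, a, nPermutations = 99, seed = 1)$r)
  const <- matrix(0, 8, 8, dimnames = dimnames(a))
  expect_error(mantelTest(const, b), "first matrix is constant")
})

test_that("exhaustive Mantel p equals brute-force enumeration at n = 4", {
  set.seed(20)
  for (k in 1:4) {
    a <- randomDistanceMatrix(4); b <- randomDistanceMatrix(4)
    res <- mantelTest(a, b, exhaustive = TRUE)
    # oracle: enumerate the 24 relabelings literally
    perms <- expand.grid(i = 1:4, j = 1:4, k = 1:4, l = 1:4)
    perms <- as.matrix(perms[apply(perms, 1, function(r)
      length(unique(r)) == 4), ])
    rObs <- cor(a[upper.tri(a)], b[upper.tri(b)])
    rs <- apply(perms, 1, function(pp) {
      ap <- a[pp, pp]
      cor(ap[upper.tri(ap)], b[upper.tri(b)])
    })
    expect_equal(nrow(perms), 24)
    expect_equal(res$p, mean(rs >= rObs - 1e-12))
    expect_equal(res$nPermutations, 24)
  }
  # generic self-comparison: only the identity attains r = 1
  a <- randomDistanceMatrix(4)
  expect_equal(mantelTest(a, a, exhaustive = TRUE)$p, 1 / 24)
})

test_that("Mantel agrees with an independent implementation on r and p", {
  set.seed(30)
  sites <- data.frame(population_id = paste0("p", 1:10), habitat = "CG",
                      latitude = runif(10, 48, 49),
                      longitude = runif(10, 9, 10))
  a <- geographicDistanceMatrix(sites)
  b <- randomDistanceMatrix(10, labels = sites$population_id)
  ours <- mantelTest(a, b, nPermutations = 999, seed = 3)
  theirs <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(ours$r, unname(theirs$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - theirs$signif), 0.12)
})

test_that("partial Mantel reduces to the first-order partial correlation", {
  set.seed(40)
  a <- randomDistanceMatrix(7); b <- randomDistanceMatrix(7)
  cc <- randomDistanceMatrix(7)
  res <- partialMantelTest(a, b, cc, nPermutations = 49, seed = 2)
  va <- a[upper.tri(a)]; vb <- b[upper.tri(b)]; vc <- cc[upper.tri(cc)]
  rab <- cor(va, vb); rac <- cor(va, vc); rbc <- cor(vb, vc)
  expect_equal(res$r, (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2)))
  # conditioning on itself is degenerate
  expect_error(partialMantelTest(a, b, a, nPermutations = 9),
               "degenerate conditioning")
  # identical matrices correlate perfectly whatever the conditioning
  expect_equal(partialMantelTest(a, a, cc, nPermutations = 9, seed = 1)$r, 1)
})

test_that("exhaustive partial Mantel matches enumeration at n = 4", {
  set.seed(50)
  a <- randomDistanceMatrix(4); b <- randomDistanceMatrix(4)
  cc <- randomDistanceMatrix(4)
  res <- partialMantelTest(a, b, cc, exhaustive = TRUE)
  perms <- expand.grid(i = 1:4, j = 1:4, k = 1:4, l = 1:4)
  perms <- as.matrix(perms[apply(perms, 1, function(r)
    length(unique(r)) == 4), ])
  vb <- b[upper.tri(b)]; vc <- cc[upper.tri(cc)]
  rbc <- cor(vb, vc)
  pr <- function(va) {
    rab <- cor(va, vb); rac <- cor(va, vc)
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  }
  rs <- apply(perms, 1, function(pp) {
    ap <- a[pp, pp]; pr(ap[upper.tri(ap)])
  })
  expect_equal(res$p, mean(rs >= pr(a[upper.tri(a)]) - 1e-12))
})

test_that("MMRR recovers exact fits and reduces to Mantel r with one predictor", {
  set.seed(60)
  y <- randomDistanceMatrix(8)
  res <- mmrr(y, list(self = y), nPermutations = 49, seed = 1)
  expect_equal(res$coefficients$coefficient, 1)
  expect_equal(res$R2, 1)
  x <- randomDistanceMatrix(8)
  single <- mmrr(y, list(x = x), nPermutations = 49, seed = 1)
  expect_equal(single$coefficients$coefficient,
               mantelTest(y, x, nPermutations = 9, seed = 1)$r,
               tolerance = 1e-12)
})

test_that("MMRR rejects collinear predictors naming the offending pair", {
  set.seed(70)
  x1 <- randomDistanceMatrix(8)
  x2 <- 2 * x1
  dimnames(x2) <- dimnames(x1)
  y <- randomDistanceMatrix(8)
  expect_error(mmrr(y, list(first = x1, second = x2), nPermutations = 9),
               "collinear predictors '(first|second)' and '(first|second)'")
})

test_that("matrix tests are invariant under simultaneous relabeling", {
  set.seed(80)
  a <- randomDistanceMatrix(8); b <- randomDistanceMatrix(8)
  cc <- randomDistanceMatrix(8)
  perm <- sample(8)
  ap <- a[perm, perm]; bp <- b[perm, perm]; cp <- cc[perm, perm]
  expect_equal(mantelTest(ap, bp, nPermutations = 9, seed = 1)$r,
               mantelTest(a, b, nPermutations = 9, seed = 1)$r)
  expect_equal(partialMantelTest(ap, bp, cp, nPermutations = 9, seed = 1)$r,
               partialMantelTest(a, b, cc, nPermutations = 9, seed = 1)$r)
  expect_equal(mmrr(ap, list(x = bp), nPermutations = 9, seed = 1)$coefficients$coefficient,
               mmrr(a, list(x = b), nPermutations = 9, seed = 1)$coefficients$coefficient)
})
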
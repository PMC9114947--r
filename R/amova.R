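#' Pairwise squared Euclidean distances between individuals
#'
#' For binary band data the squared Euclidean distance between two
#' individuals is the number of markers at which they differ, the metric
#' underlying band-based AMOVA.
#'
#' @param x a [BinaryMarkerMatrix-class].
#' @return symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
squaredEuclideanDistances <- function(x) {
  v <- markerValues(x)
  storage.mode(v) <- "double"
  r <- rowSums(v)
  d <- outer(r, r, "+") - 2 * tcrossprod(v)
  d[d < 0] <- 0  # guard tiny negatives from floating arithmetic
  diag(d) <- 0
  dimnames(d) <- list(rownames(v), rownames(v))
  d
}

.checkDistanceMatrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  invisible(d)
}

# Sum of within-block pairwise distances for each level of f: the workhorse
# of the AMOVA sums of squares. Returns named vector of pair sums per block.
.blockPairSums <- function(d, f) {
  b <- rowsum(t(rowsum(d, f, reorder = FALSE)), f, reorder = FALSE)
  diag(b) / 2
}

# SS partition, variance components and Phi-statistics; group = NULL gives
# the one-level (among/within populations) analysis. Returns plain vectors
# (no table) because the permutation loops call this tens of thousands of
# times; amovaTwoLevel()/amovaOneLevel() wrap it into an AmovaResult.
.amovaCore <- function(d, pop, group = NULL) {
  n <- nrow(d)
  popSizes <- table(pop)
  K <- length(popSizes)
  ssTotal <- sum(d) / 2 / n
  ps <- .blockPairSums(d, pop)
  ssWithin <- sum(ps / as.vector(popSizes[names(ps)]))
  if (is.null(group)) {
    dfA <- K - 1L; dfW <- n - K
    msA <- (ssTotal - ssWithin) / dfA
    msW <- ssWithin / dfW
    nPrime <- (n - sum(popSizes^2) / n) / dfA
    vc <- msW
    vb <- (msA - msW) / nPrime
    est <- pmax(c(among = vb, within = vc), 0)
    tot <- sum(est)
    return(list(source = c("among populations", "within populations"),
                df = c(dfA, dfW), SS = c(ssTotal - ssWithin, ssWithin),
                MS = c(msA, msW), est = est,
                phi = c(phi_PT = if (tot > 0) est[["among"]] / tot else 0),
                degenerate = tot == 0, coef = c(nPrime = nPrime)))
  }
  grpOfInd <- group[match(pop, names(group))]
  grpSizes <- table(grpOfInd)
  G <- length(grpSizes)
  gs <- .blockPairSums(d, grpOfInd)
  ssGroupsTotal <- sum(gs / as.vector(grpSizes[names(gs)]))
  ssAP <- ssGroupsTotal - ssWithin
  ssAG <- ssTotal - ssGroupsTotal
  dfAG <- G - 1L; dfAP <- K - G; dfW <- n - K
  msAG <- ssAG / dfAG; msAP <- ssAP / dfAP; msW <- ssWithin / dfW
  # unequal-sample-size coefficients
  NgOfPop <- grpSizes[group[match(names(popSizes), names(group))]]
  s1 <- sum(popSizes^2 / as.vector(NgOfPop))
  s2 <- sum(popSizes^2) / n
  s3 <- sum(grpSizes^2) / n
  n1 <- (n - s1) / dfAP
  n2 <- (s1 - s2) / dfAG
  n3 <- (n - s3) / dfAG
  vc <- msW
  vb <- (msAP - vc) / n1
  va <- (msAG - vc - n2 * vb) / n3
  est <- pmax(c(among_groups = va, among_pops = vb, within = vc), 0)
  tot <- sum(est)
  phi <- c(
    phi_RT = if (tot > 0) est[["among_groups"]] / tot else 0,
    phi_PR = if (est[["among_pops"]] + est[["within"]] > 0)
      est[["among_pops"]] / (est[["among_pops"]] + est[["within"]]) else 0,
    phi_PT = if (tot > 0)
      (est[["among_groups"]] + est[["among_pops"]]) / tot else 0)
  list(source = c("among groups", "among populations", "within populations"),
       df = c(dfAG, dfAP, dfW), SS = c(ssAG, ssAP, ssWithin),
       MS = c(msAG, msAP, msW), est = est, phi = phi,
       degenerate = tot == 0,
       coef = c(nPrime = n1, nDoublePrime = n2, nTriplePrime = n3))
}

.coreTable <- function(core) {
  tot <- sum(core$est)
  data.frame(source = core$source, df = core$df, SS = core$SS, MS = core$MS,
             estVar = unname(core$est),
             pct = if (tot > 0) 100 * unname(core$est) / tot
                   else rep(0, length(core$est)),
             stringsAsFactors = FALSE)
}

.resolveAssignments <- function(d, populations, groups) {
  labels <- rownames(d)
  if (!is.null(names(populations))) {
    missing <- setdiff(labels, names(populations))
    if (length(missing)) stop("no population for sample '", missing[1], "'")
    populations <- populations[labels]
  } else if (length(populations) != nrow(d))
    stop("populations must be named by sample or aligned with the matrix")
  populations <- as.character(populations)
  if (!is.null(groups)) {
    if (is.null(names(groups))) stop("groups must be named by population")
    if (anyDuplicated(names(groups))) {
      perPop <- tapply(as.character(groups), names(groups),
                       function(v) length(unique(v)))
      if (any(perPop > 1))
        stop("population '", names(perPop)[perPop > 1][1],
             "' is assigned to two groups")
      groups <- groups[!duplicated(names(groups))]
    }
    missing <- setdiff(unique(populations), names(groups))
    if (length(missing)) stop("no group for population '", missing[1], "'")
    pops <- unique(populations)
    groups <- setNames(as.character(groups[pops]), pops)
  }
  sizes <- table(populations)
  if (any(sizes < 2L))
    stop("population '", names(sizes)[sizes < 2][1],
         "' has fewer than 2 individuals (singleton populations unsupported)")
  list(pop = populations, group = groups)
}

#' Two-level hierarchical AMOVA on a squared Euclidean distance matrix
#'
#' Partitions molecular variance among groups (e.g. habitat types), among
#' populations within groups, and within populations, following the
#' sums-of-squares decomposition for pairwise distances with
#' unequal-sample-size coefficients. Negative variance component estimates
#' are truncated to zero before percentages and Phi-statistics are formed.
#' Phi-statistics: `phi_RT` (among groups / total), `phi_PR` (among
#' populations / within-group total), `phi_PT` (among populations plus
#' groups / total). Permutation p-values use scheme-specific shuffles (see
#' [amovaPermutationTest()]) and the `(b + 1) / (m + 1)` estimator.
#'
#' @param d labelled symmetric distance matrix (zero diagonal), e.g. from
#'   [squaredEuclideanDistances()].
#' @param populations population of each sample: named by sample id, or in
#'   matrix order.
#' @param groups group of each population, named by population id.
#' @param nPermutations permutations per Phi-statistic (0 skips testing).
#' @param seed optional integer seed for the permutation streams.
#' @return an [AmovaResult-class].
#' @examples
#' set.seed(1)
#' x <- BinaryMarkerMatrix(matrix(rbinom(80, 1, 0.5), 8,
#'   dimnames = list(paste0("i", 1:8), paste0("L", 1:10))))
#' pops <- setNames(rep(c("p1", "p2", "p3", "p4"), each = 2), paste0("i", 1:8))
#' grps <- c(p1 = "A", p2 = "A", p3 = "B", p4 = "B")
#' amovaTwoLevel(squaredEuclideanDistances(x), pops, grps, nPermutations = 99)
#' @export
amovaTwoLevel <- function(d, populations, groups, nPermutations = 999,
                          seed = NULL) {
  .checkDistanceMatrix(d)
  a <- .resolveAssignments(d, populations, groups)
  if (length(unique(a$group)) < 2L) stop("need at least 2 groups")
  core <- .amovaCore(d, a$pop, a$group)
  if (core$degenerate)
    warning("no molecular variance in the data; Phi-statistics reported as 0")
  pvals <- numeric(0)
  if (nPermutations > 0 && !core$degenerate) {
    if (!is.null(seed)) set.seed(seed)
    pvals <- vapply(c("phi_PT", "phi_RT", "phi_PR"), function(s)
      .permutePhi(d, a$pop, a$group, s, nPermutations, core$phi[[s]]),
      numeric(1))
  }
  new("AmovaResult", tbl = .coreTable(core), phi = core$phi, pValues = pvals,
      nPermutations = as.integer(nPermutations))
}

#' One-level AMOVA (among and within populations)
#'
#' The non-hierarchical variance partition: among populations vs within
#' populations, with its PhiPT (the global differentiation estimate when no
#' grouping level is modelled). Permutation shuffles individuals across
#' populations.
#'
#' @inheritParams amovaTwoLevel
#' @return an [AmovaResult-class] with `phi_PT` only.
#' @export
amovaOneLevel <- function(d, populations, nPermutations = 999, seed = NULL) {
  .checkDistanceMatrix(d)
  a <- .resolveAssignments(d, populations, groups = NULL)
  if (length(unique(a$pop)) < 2L) stop("need at least 2 populations")
  core <- .amovaCore(d, a$pop)
  if (core$degenerate)
    warning("no molecular variance in the data; Phi-statistics reported as 0")
  pvals <- numeric(0)
  if (nPermutations > 0 && !core$degenerate) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(nPermutations)) {
      val <- .amovaCore(d, sample(a$pop))$phi[["phi_PT"]]
      if (val >= core$phi[["phi_PT"]] - 1e-12) hits <- hits + 1L
    }
    pvals <- c(phi_PT = (hits + 1) / (nPermutations + 1))
  }
  new("AmovaResult", tbl = .coreTable(core), phi = core$phi, pValues = pvals,
      nPermutations = as.integer(nPermutations))
}

# one permuted phi value under the scheme appropriate for the statistic
.permutedAssignment <- function(pop, group, statistic) {
  switch(statistic,
    phi_PT = list(pop = sample(pop), group = group),
    phi_RT = list(pop = pop,
                  group = setNames(sample(unname(group)), names(group))),
    phi_PR = {
      newPop <- pop
      grpOfInd <- group[match(pop, names(group))]
      for (g in unique(grpOfInd)) {
        idx <- which(grpOfInd == g)
        newPop[idx] <- sample(pop[idx])
      }
      list(pop = newPop, group = group)
    },
    stop("unknown statistic '", statistic, "'"))
}

.permutePhi <- function(d, pop, group, statistic, nPerm, observed) {
  hits <- 0L
  for (b in seq_len(nPerm)) {
    pa <- .permutedAssignment(pop, group, statistic)
    phi <- .amovaCore(d, pa$pop, pa$group)$phi[[statistic]]
    if (phi >= observed - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (nPerm + 1)
}

#' Permutation test for one AMOVA Phi-statistic
#'
#' Scheme per statistic: `phi_PT` shuffles individuals across all
#' populations; `phi_RT` shuffles whole populations among groups; `phi_PR`
#' shuffles individuals among populations within their group. The p-value is
#' `(count[phi_perm >= phi_obs] + 1) / (nPermutations + 1)`, so it never
#' returns zero.
#'
#' @inheritParams amovaTwoLevel
#' @param statistic one of "phi_PT", "phi_RT", "phi_PR".
#' @return list with `statistic` name, `observed` value and `p`.
#' @export
amovaPermutationTest <- function(d, populations, groups,
                                 statistic = c("phi_PT", "phi_RT", "phi_PR"),
                                 nPermutations = 999, seed = NULL) {
  statistic <- match.arg(statistic)
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  .checkDistanceMatrix(d)
  a <- .resolveAssignments(d, populations, groups)
  observed <- .amovaCore(d, a$pop, a$group)$phi[[statistic]]
  if (!is.null(seed)) set.seed(seed)
  p <- .permutePhi(d, a$pop, a$group, statistic, nPermutations, observed)
  list(statistic = statistic, observed = observed, p = p,
       nPermutations = nPermutations)
}

#' Pairwise population PhiPT matrix
#'
#' For every population pair, a one-level AMOVA restricted to that pair
#' yields its PhiPT (negative estimates truncated to zero); p-values come
#' from shuffling individuals between the two populations. The PhiPT matrix
#' is the population-level distance matrix used by the isolation-by-distance
#' and isolation-by-habitat tests.
#'
#' @inheritParams amovaTwoLevel
#' @param nPermutations permutations per pair (0 skips p-values).
#' @return list with symmetric matrices `phi` and (if requested) `p`.
#' @export
pairwisePhiPT <- function(d, populations, nPermutations = 999, seed = NULL) {
  .checkDistanceMatrix(d)
  a <- .resolveAssignments(d, populations, groups = NULL)
  pops <- unique(a$pop)
  K <- length(pops)
  if (K < 2L) stop("need at least 2 populations")
  phi <- p <- matrix(0, K, K, dimnames = list(pops, pops))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    idx <- a$pop %in% c(pops[i], pops[j])
    dd <- d[idx, idx, drop = FALSE]
    subPop <- a$pop[idx]
    core <- .amovaCore(dd, subPop)
    phi[i, j] <- phi[j, i] <- core$phi[["phi_PT"]]
    if (nPermutations > 0) {
      hits <- 0L
      for (b in seq_len(nPermutations)) {
        val <- .amovaCore(dd, sample(subPop))$phi[["phi_PT"]]
        if (val >= core$phi[["phi_PT"]] - 1e-12) hits <- hits + 1L
      }
      p[i, j] <- p[j, i] <- (hits + 1) / (nPermutations + 1)
    }
  }
  out <- list(phi = phi)
  if (nPermutations > 0) out$p <- p
  out
}
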
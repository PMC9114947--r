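# fixtures shared across test files; everything is generated in code

randomMarkerMatrix <- function(n, p, prob = 0.5, label = "markers") {
  BinaryMarkerMatrix(
    matrix(rbinom(n * p, 1, prob), n,
           dimnames = list(sprintf("s%02d", seq_len(n)),
                           sprintf("m%02d", seq_len(p)))),
    markerSet = label)
}

randomProfilePair <- function(n, nf) {
  ids <- list(sprintf("s%02d", seq_len(n)), sprintf("f%02d", seq_len(nf)))
  hpa <- matrix(rbinom(n * nf, 1, 0.5), n, dimnames = ids)
  msp <- matrix(rbinom(n * nf, 1, 0.5), n, dimnames = ids)
  MsapProfilePair(BinaryMarkerMatrix(hpa, "HpaII"),
                  BinaryMarkerMatrix(msp, "MspI"))
}

# distance matrix from random points in the plane (euclidean, generic)
randomDistanceMatrix <- function(n, labels = sprintf("p%02d", seq_len(n))) {
  pts <- matrix(runif(2 * n), n)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(labels, labels)
  d
}

# population / group assignments for a balanced two-level design
balancedDesign <- function(nGroups, popsPerGroup, nPerPop) {
  K <- nGroups * popsPerGroup
  pops <- sprintf("p%02d", seq_len(K))
  samples <- sprintf("i%03d", seq_len(K * nPerPop))
  list(populations = setNames(rep(pops, each = nPerPop), samples),
       groups = setNames(rep(LETTERS[seq_len(nGroups)], each = popsPerGroup),
                         pops),
       samples = samples, pops = pops)
}

tinySites <- function() {
  data.frame(population_id = paste0("p", 1:4),
             habitat = c("CG", "OM", "CG", "OM"),
             latitude = c(48.3, 48.4, 48.5, 48.6),
             longitude = c(9.1, 9.4, 9.2, 9.6),
             stringsAsFactors = FALSE)
}
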
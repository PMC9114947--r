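#' Classify the methylation state of one fragment call pair
#'
#' A CCGG site assayed with the isoschizomers HpaII and MspI yields one of
#' four informative patterns: a band in both profiles means the site is
#' unmethylated (`u`); a band only in the EcoRI/MspI profile means internal
#' cytosine methylation (`m`); a band only in the EcoRI/HpaII profile means
#' hemimethylation of the external cytosine (`h`); absence from both
#' profiles is uninformative (missing site or methylation type invisible to
#' either enzyme).
#'
#' @param hpa 0/1 call(s) from the EcoRI/HpaII profile.
#' @param msp 0/1 call(s) from the EcoRI/MspI profile, same length.
#' @return character vector over {"u","m","h","uninformative"}; vectorized.
#' @examples
#' classifyFragmentState(c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
classifyFragmentState <- function(hpa, msp) {
  stopifnot(length(hpa) == length(msp),
            all(hpa %in% c(0, 1)), all(msp %in% c(0, 1)))
  state <- character(length(hpa))
  state[hpa == 1 & msp == 1] <- "u"
  state[hpa == 0 & msp == 1] <- "m"
  state[hpa == 1 & msp == 0] <- "h"
  state[hpa == 0 & msp == 0] <- "uninformative"
  state
}

#' Mixed scoring 2: expand paired MSAP profiles into u/m/h subepiloci
#'
#' Each MSAP fragment is expanded into three candidate binary subepilocus
#' columns, one per methylation class. An individual scores 1 in exactly the
#' column matching its state at that fragment and 0 in the other two;
#' individuals with the uninformative (0,0) pattern score 0 in all three.
#' Candidate columns that are all-zero across every individual are dropped;
#' monomorphic present (all-one) columns are retained. Column ids are
#' `<fragment>.<class>`.
#'
#' @param profiles an [MsapProfilePair-class].
#' @return list with elements `subepiloci` (a [SubepilocusMatrix-class]) and
#'   `report` (a [ScoringReport-class]).
#' @export
mixedScoring2 <- function(profiles) {
  stopifnot(is(profiles, "MsapProfilePair"))
  validObject(profiles)
  hpa <- markerValues(hpaProfile(profiles))
  msp <- markerValues(mspProfile(profiles))
  n <- nrow(hpa); p <- ncol(hpa)
  classes <- c("u", "m", "h")
  # candidate indicator blocks, one per class, fragments side by side
  cand <- cbind(hpa * msp,                 # u: band in both
                (1 - hpa) * msp,           # m: MspI only
                hpa * (1 - msp))           # h: HpaII only
  fragment <- rep(colnames(hpa), times = 3)
  cls <- rep(classes, each = p)
  colnames(cand) <- paste(fragment, cls, sep = ".")
  # interleave by fragment so u/m/h of a fragment sit together
  ord <- order(rep(seq_len(p), times = 3), rep(seq_len(3), each = p))
  cand <- cand[, ord, drop = FALSE]
  fragment <- fragment[ord]; cls <- cls[ord]
  keep <- colSums(cand) > 0
  sub <- SubepilocusMatrix(cand[, keep, drop = FALSE], cls[keep],
                           fragment[keep], markerSet = "MSAP-all")
  tab <- table(factor(cls[keep], levels = classes))
  report <- new("ScoringReport", nFragments = as.integer(p),
                nSubepiloci = as.integer(sum(keep)),
                nU = as.integer(tab[["u"]]), nM = as.integer(tab[["m"]]),
                nH = as.integer(tab[["h"]]),
                nDropped = as.integer(sum(!keep)))
  validObject(sub); validObject(report)
  list(subepiloci = sub, report = report)
}

#' Reconstruct HpaII/MspI profiles from a subepilocus matrix
#'
#' Inverse of [mixedScoring2()] for the retained columns: an individual's
#' state at a fragment is read off the indicator columns and re-emitted as
#' the (hpa, msp) call pair. Fragments whose columns were all dropped are
#' reconstructed as all-absent.
#'
#' @param x a [SubepilocusMatrix-class].
#' @param fragmentIDs fragment ids to emit (default: those present in `x`).
#' @return an [MsapProfilePair-class].
#' @export
profilesFromSubepiloci <- function(x, fragmentIDs = unique(sourceFragments(x))) {
  n <- nrow(markerValues(x))
  hpa <- msp <- matrix(0L, n, length(fragmentIDs),
                       dimnames = list(sampleIDs(x), fragmentIDs))
  vals <- markerValues(x)
  for (k in seq_len(ncol(vals))) {
    frag <- sourceFragments(x)[k]
    on <- vals[, k] == 1
    switch(subepilocusClasses(x)[k],
           u = { hpa[on, frag] <- 1L; msp[on, frag] <- 1L },
           m = { msp[on, frag] <- 1L },
           h = { hpa[on, frag] <- 1L })
  }
  MsapProfilePair(BinaryMarkerMatrix(hpa, "HpaII"),
                  BinaryMarkerMatrix(msp, "MspI"))
}

#' Genotyping error rate between original and replicate profiles
#'
#' Reproducibility check: a subset of individuals is fingerprinted twice and
#' the percentage of differing fragment calls over all compared cells
#' (fragments x replicated individuals) is reported.
#'
#' @param original [BinaryMarkerMatrix-class] with all individuals.
#' @param replicate [BinaryMarkerMatrix-class] whose sample ids are a subset
#'   of the originals (same marker ids).
#' @return error rate as a percentage in \[0, 100\].
#' @export
genotypingErrorRate <- function(original, replicate) {
  if (!identical(markerIDs(original), markerIDs(replicate)))
    stop("original and replicate must score the same markers")
  shared <- intersect(sampleIDs(replicate), sampleIDs(original))
  if (length(shared) == 0L)
    stop("no overlapping samples between original and replicate")
  a <- markerValues(original)[shared, , drop = FALSE]
  b <- markerValues(replicate)[shared, , drop = FALSE]
  100 * sum(a != b) / length(a)
}
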
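#' @import methods
NULL

#' BinaryMarkerMatrix: individuals x dominant markers, scored 0/1
#'
#' The universal data container of the package: a complete (no missing cells)
#' binary matrix of band presence/absence calls, one row per individual and
#' one column per marker, plus a label naming the marker set (e.g. "AFLP",
#' "MSAP-all", or a methylation class "u"/"m"/"h"). Row and column names are
#' the sample and marker identifiers and must be unique.
#'
#' @slot values integer matrix over {0,1} with unique dimnames.
#' @slot markerSet single character label for the marker set.
#'
#' @seealso [BinaryMarkerMatrix()] for the constructor,
#'   [markerValues()], [sampleIDs()], [markerIDs()] for accessors.
#' @export
setClass("BinaryMarkerMatrix",
  representation(values = "matrix", markerSet = "character"))

setValidity("BinaryMarkerMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v))
    msg <- c(msg, "values must be a numeric matrix")
  if (anyNA(v))
    msg <- c(msg, "missing cells are not representable; filter upstream")
  else if (is.numeric(v) && !all(v %in% c(0, 1))) {
    bad <- which(matrix(!(v %in% c(0, 1)), nrow(v)), arr.ind = TRUE)[1, ]
    msg <- c(msg, sprintf("non-binary value at row '%s', column '%s'",
                          rownames(v)[bad[1]] %||% bad[1],
                          colnames(v)[bad[2]] %||% bad[2]))
  }
  if ((nrow(v) > 0 && is.null(rownames(v))) ||
      (ncol(v) > 0 && is.null(colnames(v))))
    msg <- c(msg, "values must carry sample (row) and marker (column) names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, sprintf("duplicated sample id '%s'",
                            rownames(v)[duplicated(rownames(v))][1]))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, sprintf("duplicated marker id '%s'",
                            colnames(v)[duplicated(colnames(v))][1]))
  }
  if (length(object@markerSet) != 1L)
    msg <- c(msg, "markerSet must be a single label")
  if (length(msg)) msg else TRUE
})

#' SubepilocusMatrix: MSAP subepiloci with methylation-class annotation
#'
#' A [BinaryMarkerMatrix-class] whose columns additionally carry a
#' methylation class (`u` unmethylated, `m` internal-cytosine methylated,
#' `h` external-cytosine hemimethylated) and the id of the MSAP fragment each
#' subepilocus was derived from. A fragment contributes at most one column
#' per class.
#'
#' @slot subepilocusClass character vector, one of "u","m","h" per column.
#' @slot sourceFragment character vector of fragment ids, one per column.
#' @export
setClass("SubepilocusMatrix",
  contains = "BinaryMarkerMatrix",
  representation(subepilocusClass = "character", sourceFragment = "character"))

setValidity("SubepilocusMatrix", function(object) {
  p <- ncol(object@values)
  msg <- character()
  if (length(object@subepilocusClass) != p || length(object@sourceFragment) != p)
    msg <- c(msg, "class and source-fragment annotations must have one entry per column")
  if (!all(object@subepilocusClass %in% c("u", "m", "h")))
    msg <- c(msg, "subepilocus classes must be 'u', 'm' or 'h'")
  key <- paste(object@sourceFragment, object@subepilocusClass)
  if (anyDuplicated(key))
    msg <- c(msg, "a source fragment contributes at most one column per class")
  if (length(msg)) msg else TRUE
})

#' MsapProfilePair: paired EcoRI/HpaII and EcoRI/MspI fragment profiles
#'
#' The two presence/absence profiles produced by MSAP fingerprinting of the
#' same individuals with the isoschizomers HpaII and MspI. Both matrices must
#' have identical samples and fragments in identical order.
#'
#' @slot hpa [BinaryMarkerMatrix-class] of EcoRI/HpaII calls.
#' @slot msp [BinaryMarkerMatrix-class] of EcoRI/MspI calls.
#' @export
setClass("MsapProfilePair",
  representation(hpa = "BinaryMarkerMatrix", msp = "BinaryMarkerMatrix"))

setValidity("MsapProfilePair", function(object) {
  msg <- character()
  if (!identical(dim(object@hpa@values), dim(object@msp@values)))
    msg <- c(msg, "HpaII and MspI profiles must have the same shape")
  else {
    if (!identical(rownames(object@hpa@values), rownames(object@msp@values)))
      msg <- c(msg, "HpaII and MspI profiles must list the same samples in the same order")
    if (!identical(colnames(object@hpa@values), colnames(object@msp@values)))
      msg <- c(msg, "HpaII and MspI profiles must list the same fragments in the same order")
  }
  if (length(msg)) msg else TRUE
})

#' ScoringReport: bookkeeping from mixed scoring 2
#'
#' Counts of fragments, retained subepiloci per methylation class, and
#' dropped (all-zero) candidate columns from one [mixedScoring2()] run.
#'
#' @slot nFragments number of input MSAP fragments.
#' @slot nSubepiloci total retained subepilocus columns.
#' @slot nU,nM,nH retained columns per methylation class.
#' @slot nDropped all-zero candidate columns removed.
#' @export
setClass("ScoringReport",
  representation(nFragments = "integer", nSubepiloci = "integer",
                 nU = "integer", nM = "integer", nH = "integer",
                 nDropped = "integer"))

setValidity("ScoringReport", function(object) {
  msg <- character()
  if (object@nU + object@nM + object@nH != object@nSubepiloci)
    msg <- c(msg, "class counts must sum to the total subepilocus count")
  if (object@nSubepiloci > 3L * object@nFragments)
    msg <- c(msg, "at most three subepiloci per fragment")
  if (length(msg)) msg else TRUE
})

#' AmovaResult: hierarchical analysis of molecular variance
#'
#' Variance partition of squared Euclidean marker distances into hierarchy
#' levels, with Phi-statistics and (optionally) permutation p-values.
#' The `tbl` slot mirrors the conventional AMOVA table: one row per level
#' with degrees of freedom, sums of squares, mean squares, estimated variance
#' component (negative estimates truncated to zero) and percentage of total.
#'
#' @slot tbl data.frame with columns source, df, SS, MS, estVar, pct.
#' @slot phi named numeric: phi_RT, phi_PR, phi_PT (two-level) or phi_PT only.
#' @slot pValues named numeric permutation p-values (may be empty).
#' @slot nPermutations integer number of permutations used (0 if none).
#' @export
setClass("AmovaResult",
  representation(tbl = "data.frame", phi = "numeric",
                 pValues = "numeric", nPermutations = "integer"))

setValidity("AmovaResult", function(object) {
  msg <- character()
  need <- c("source", "df", "SS", "MS", "estVar", "pct")
  if (!all(need %in% names(object@tbl)))
    msg <- c(msg, "tbl must have columns source, df, SS, MS, estVar, pct")
  else if (any(object@tbl$estVar < 0))
    msg <- c(msg, "variance components must be truncated at zero")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
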
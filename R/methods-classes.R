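#' Construct a BinaryMarkerMatrix
#'
#' @param values matrix (numeric or logical) of 0/1 calls, individuals in
#'   rows; must carry row (sample) and column (marker) names, or names are
#'   generated as `S1..Sn` / `M1..Mp`.
#' @param markerSet label for the marker set.
#' @return a validated [BinaryMarkerMatrix-class].
#' @examples
#' m <- BinaryMarkerMatrix(matrix(c(1, 0, 0, 1), 2,
#'   dimnames = list(c("a", "b"), c("L1", "L2"))), "AFLP")
#' markerValues(m)
#' @export
BinaryMarkerMatrix <- function(values, markerSet = "markers") {
  values <- as.matrix(values)
  if (is.logical(values)) storage.mode(values) <- "integer"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%d", seq_len(ncol(values)))
  if (is.double(values) && !anyNA(values) && all(values %in% c(0, 1)))
    storage.mode(values) <- "integer"
  new("BinaryMarkerMatrix", values = values, markerSet = as.character(markerSet))
}

#' Construct a SubepilocusMatrix
#'
#' @inheritParams BinaryMarkerMatrix
#' @param subepilocusClass methylation class ("u"/"m"/"h") per column.
#' @param sourceFragment source fragment id per column.
#' @return a validated [SubepilocusMatrix-class].
#' @export
SubepilocusMatrix <- function(values, subepilocusClass, sourceFragment,
                              markerSet = "MSAP-all") {
  base <- BinaryMarkerMatrix(values, markerSet)
  new("SubepilocusMatrix", base,
      subepilocusClass = as.character(subepilocusClass),
      sourceFragment = as.character(sourceFragment))
}

#' Construct an MsapProfilePair
#'
#' @param hpa EcoRI/HpaII calls: [BinaryMarkerMatrix-class] or coercible matrix.
#' @param msp EcoRI/MspI calls, same samples and fragments, same order.
#' @return a validated [MsapProfilePair-class].
#' @export
MsapProfilePair <- function(hpa, msp) {
  if (!is(hpa, "BinaryMarkerMatrix")) hpa <- BinaryMarkerMatrix(hpa, "HpaII")
  if (!is(msp, "BinaryMarkerMatrix")) msp <- BinaryMarkerMatrix(msp, "MspI")
  new("MsapProfilePair", hpa = hpa, msp = msp)
}

#' @rdname markerValues
#' @export
setMethod("markerValues", "BinaryMarkerMatrix", function(x) x@values)

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "BinaryMarkerMatrix", function(x) rownames(x@values))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "MsapProfilePair", function(x) rownames(x@hpa@values))

#' @rdname markerIDs
#' @export
setMethod("markerIDs", "BinaryMarkerMatrix", function(x) colnames(x@values))

#' @rdname markerIDs
#' @export
setMethod("markerIDs", "MsapProfilePair", function(x) colnames(x@hpa@values))

#' @rdname markerSetLabel
#' @export
setMethod("markerSetLabel", "BinaryMarkerMatrix", function(x) x@markerSet)

#' @rdname subepilocusClasses
#' @export
setMethod("subepilocusClasses", "SubepilocusMatrix", function(x) x@subepilocusClass)

#' @rdname sourceFragments
#' @export
setMethod("sourceFragments", "SubepilocusMatrix", function(x) x@sourceFragment)

#' @rdname subsetByClass
#' @export
setMethod("subsetByClass", "SubepilocusMatrix", function(x, class) {
  class <- match.arg(class, c("u", "m", "h"))
  keep <- x@subepilocusClass == class
  BinaryMarkerMatrix(x@values[, keep, drop = FALSE], markerSet = class)
})

#' HpaII profile of a pair
#' @param x an [MsapProfilePair-class].
#' @return the EcoRI/HpaII [BinaryMarkerMatrix-class].
#' @export
hpaProfile <- function(x) x@hpa

#' MspI profile of a pair
#' @param x an [MsapProfilePair-class].
#' @return the EcoRI/MspI [BinaryMarkerMatrix-class].
#' @export
mspProfile <- function(x) x@msp

#' @describeIn BinaryMarkerMatrix dimensions (samples, markers)
#' @param x a BinaryMarkerMatrix.
#' @export
setMethod("dim", "BinaryMarkerMatrix", function(x) dim(x@values))

#' Subset samples and/or markers
#'
#' Standard `[` subsetting; a SubepilocusMatrix keeps its per-column
#' annotations aligned.
#'
#' @param x a [BinaryMarkerMatrix-class].
#' @param i,j sample / marker indices (any standard form).
#' @param ... ignored.
#' @param drop ignored; objects are never dropped to vectors.
#' @export
setMethod("[", "BinaryMarkerMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  initialize(x, values = x@values[i, j, drop = FALSE])
})

#' @rdname sub-BinaryMarkerMatrix-ANY-ANY-ANY-method
#' @export
setMethod("[", "SubepilocusMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  jj <- setNames(seq_len(ncol(x@values)), colnames(x@values))[j]
  initialize(x, values = x@values[i, jj, drop = FALSE],
             subepilocusClass = x@subepilocusClass[jj],
             sourceFragment = x@sourceFragment[jj])
})

setMethod("show", "BinaryMarkerMatrix", function(object) {
  cat(sprintf("%s: %d samples x %d markers [%s]\n", class(object),
              nrow(object@values), ncol(object@values), object@markerSet))
  f <- colMeans(object@values)
  cat(sprintf("  band frequency: min %.3f / median %.3f / max %.3f\n",
              min(f), stats::median(f), max(f)))
})

setMethod("show", "SubepilocusMatrix", function(object) {
  callNextMethod()
  tab <- table(factor(object@subepilocusClass, levels = c("u", "m", "h")))
  cat(sprintf("  subepiloci: u %d / m %d / h %d (from %d fragments)\n",
              tab[["u"]], tab[["m"]], tab[["h"]],
              length(unique(object@sourceFragment))))
})

setMethod("show", "MsapProfilePair", function(object) {
  cat(sprintf("MsapProfilePair: %d samples x %d fragments (HpaII + MspI)\n",
              nrow(object@hpa@values), ncol(object@hpa@values)))
})

setMethod("show", "ScoringReport", function(object) {
  cat("Mixed scoring 2 report\n")
  cat(sprintf("  fragments analysed : %d\n", object@nFragments))
  cat(sprintf("  subepiloci retained: %d (u %d / m %d / h %d)\n",
              object@nSubepiloci, object@nU, object@nM, object@nH))
  cat(sprintf("  all-zero columns dropped: %d\n", object@nDropped))
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (squared Euclidean distances)\n")
  tbl <- object@tbl
  tbl$SS <- round(tbl$SS, 2); tbl$MS <- round(tbl$MS, 2)
  tbl$estVar <- round(tbl$estVar, 3); tbl$pct <- round(tbl$pct, 0)
  print(tbl, row.names = FALSE)
  phi <- paste(sprintf("%s = %.3f", names(object@phi), object@phi),
               collapse = ", ")
  cat(" ", phi, "\n")
  if (length(object@pValues))
    cat(sprintf("  p-values (%d permutations): %s\n", object@nPermutations,
                paste(sprintf("%s %.4g", names(object@pValues),
                              object@pValues), collapse = ", ")))
})

#' AMOVA table accessor
#' @param x an [AmovaResult-class].
#' @return data.frame with one row per hierarchy level.
#' @export
amovaTable <- function(x) x@tbl

#' Phi-statistics accessor
#' @param x an [AmovaResult-class].
#' @return named numeric vector of Phi-statistics.
#' @export
phiStatistics <- function(x) x@phi

#' Permutation p-values accessor
#' @param x an [AmovaResult-class].
#' @return named numeric vector of p-values (empty if no permutations ran).
#' @export
amovaPValues <- function(x) x@pValues
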
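#' Extract the binary call matrix
#' @param x a [BinaryMarkerMatrix-class] (or derived) object.
#' @return integer matrix of 0/1 calls, samples in rows.
#' @export
setGeneric("markerValues", function(x) standardGeneric("markerValues"))

#' Sample identifiers
#' @param x a container holding samples.
#' @return character vector of sample ids, in storage order.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Marker identifiers
#' @param x a container holding markers.
#' @return character vector of marker ids, in storage order.
#' @export
setGeneric("markerIDs", function(x) standardGeneric("markerIDs"))

#' Marker-set label
#' @param x a [BinaryMarkerMatrix-class] object.
#' @return single character label (e.g. "AFLP", "MSAP-all", "m").
#' @export
setGeneric("markerSetLabel", function(x) standardGeneric("markerSetLabel"))

#' Methylation class of each subepilocus column
#' @param x a [SubepilocusMatrix-class].
#' @return character vector over {"u","m","h"}, one per column.
#' @export
setGeneric("subepilocusClasses", function(x) standardGeneric("subepilocusClasses"))

#' Source MSAP fragment of each subepilocus column
#' @param x a [SubepilocusMatrix-class].
#' @return character vector of fragment ids, one per column.
#' @export
setGeneric("sourceFragments", function(x) standardGeneric("sourceFragments"))

#' Restrict a subepilocus matrix to one methylation class
#'
#' Returns the columns of the given class as a plain
#' [BinaryMarkerMatrix-class] labelled with the class name, the form used for
#' the per-class (u/m/h) diversity and AMOVA analyses.
#'
#' @param x a [SubepilocusMatrix-class].
#' @param class one of "u", "m", "h".
#' @return a [BinaryMarkerMatrix-class].
#' @export
setGeneric("subsetByClass", function(x, class) standardGeneric("subsetByClass"))
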
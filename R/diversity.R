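#' Shannon information index of one dominant marker
#'
#' Two-state entropy of the band frequency at a locus,
#' `SI = -(p log2 p + (1-p) log2 (1-p))`, with `0 log2 0 = 0`. Dominant
#' (presence/absence) markers carry two observable states, so the index is
#' bounded by 1 and is symmetric in `p` and `1-p`; monomorphic loci
#' contribute 0.
#'
#' @param p band ('1' score) frequency, in \[0, 1\]; vectorized.
#' @return SI value(s) in \[0, 1\].
#' @examples
#' shannonIndexLocus(c(0, 0.25, 0.5, 1))
#' @export
shannonIndexLocus <- function(p) {
  if (any(p < 0 | p > 1)) stop("band frequency must lie in [0, 1]")
  term <- function(q) ifelse(q == 0, 0, q * log2(q))
  -(term(p) + term(1 - p))
}

#' Per-population band diversity statistics
#'
#' For each population: percentage of total bands (markers with at least one
#' presence), percentage of private bands (markers present here and absent
#' from every other population), percentage of polymorphic markers (both
#' states observed, no minimum-frequency threshold), and the mean Shannon
#' information index over all markers. A grand mean row and a standard-error
#' row (sd across populations / sqrt(number of populations)) are appended.
#'
#' @param x a [BinaryMarkerMatrix-class].
#' @param samples sample metadata data.frame (sample_id, population_id, ...).
#' @return data.frame with columns population_id, n, pct_bands,
#'   pct_private_bands, pct_polymorphic, mean_SI; last two rows are the
#'   grand "mean" and "s.e." across populations.
#' @export
populationDiversity <- function(x, samples) {
  x <- alignToMetadata(x, samples)
  vals <- markerValues(x)
  pop <- samples$population_id
  pops <- unique(pop)
  sizes <- table(pop)[pops]
  if (any(sizes < 2L))
    stop("population '", names(sizes)[sizes < 2][1],
         "' has fewer than 2 individuals")
  nm <- ncol(vals)
  present <- rowsum(vals, pop)[pops, , drop = FALSE] > 0   # pop x marker
  freq <- rowsum(vals, pop)[pops, , drop = FALSE] / as.vector(sizes)
  private <- present & (colSums(present) == 1L)[col(present)]
  poly <- freq > 0 & freq < 1
  res <- data.frame(
    population_id = pops,
    n = as.vector(sizes),
    pct_bands = 100 * rowSums(present) / nm,
    pct_private_bands = 100 * rowSums(private) / nm,
    pct_polymorphic = 100 * rowSums(poly) / nm,
    mean_SI = rowMeans(matrix(shannonIndexLocus(freq), nrow(freq))),
    stringsAsFactors = FALSE, row.names = NULL)
  summarizeDiversity(res)
}

#' Append grand mean and standard error rows to a diversity table
#'
#' @param tbl per-population diversity data.frame (no summary rows).
#' @return `tbl` with "mean" and "s.e." rows appended; the s.e. is the
#'   sample standard deviation across populations divided by the square root
#'   of the number of populations.
#' @export
summarizeDiversity <- function(tbl) {
  num <- setdiff(names(tbl), c("population_id", "n"))
  k <- nrow(tbl)
  mn <- se <- tbl[1, ]
  mn$population_id <- "mean"; se$population_id <- "s.e."
  mn$n <- se$n <- NA_integer_
  for (col in num) {
    mn[[col]] <- mean(tbl[[col]])
    se[[col]] <- stats::sd(tbl[[col]]) / sqrt(k)
  }
  rbind(tbl, mn, se)
}

#' Diversity statistics per methylation class
#'
#' Repeats [populationDiversity()] on the full subepilocus matrix and on its
#' u/m/h column subsets, the per-class layout used when contrasting
#' methylation contexts.
#'
#' @param x a [SubepilocusMatrix-class].
#' @param samples sample metadata data.frame.
#' @return named list of diversity tables: `all`, `u`, `m`, `h`.
#' @export
diversityByClass <- function(x, samples) {
  out <- list(all = populationDiversity(x, samples))
  for (cl in c("u", "m", "h"))
    out[[cl]] <- populationDiversity(subsetByClass(x, cl), samples)
  out
}
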
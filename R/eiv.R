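#' Mean weighted Ellenberg indicator value per site
#'
#' Abundance-weighted mean of the species indicator values recorded at each
#' site: `sum(abundance_s * EIV_s) / sum(abundance_s)` over the species with
#' a numeric value for the chosen indicator. Species marked indifferent
#' ("x") or missing from the indicator table are excluded from both sums;
#' unmatched relevé species are reported via a "dropped" attribute so silent
#' losses are visible. Species names are matched exactly after whitespace
#' and case normalization. Abundances are used on whatever scale is supplied
#' (percent cover or a transformed ordinal scale); no internal
#' transformation is applied.
#'
#' @param releves data.frame: rows = sites (site id in column `site` or row
#'   names), remaining columns = species abundances (non-negative).
#' @param eivs data.frame: species name in column `species` (or row names),
#'   columns `L`, `M`, `R`, `N` holding integers 1-9 or "x" for indifferent.
#' @param indicator one of "L" (light), "M" (soil moisture), "R" (soil
#'   reaction/pH), "N" (soil nitrogen).
#' @return named numeric vector of per-site mean weighted values, with
#'   attribute `dropped` listing relevé species excluded for this indicator.
#' @examples
#' rel <- data.frame(site = "s1", "Poa pratensis" = 2, "Lotus corniculatus" = 2,
#'                   check.names = FALSE)
#' eiv <- data.frame(species = c("Poa pratensis", "Lotus corniculatus"),
#'                   L = c("6", "7"), M = c("4", "6"), R = c("x", "7"),
#'                   N = c("6", "3"))
#' meanWeightedEiv(rel, eiv, "M")
#' @export
meanWeightedEiv <- function(releves, eivs, indicator = c("L", "M", "R", "N")) {
  indicator <- match.arg(indicator)
  norm <- function(s) tolower(gsub("\\s+", " ", trimws(s)))
  if ("site" %in% names(releves)) {
    siteIDs <- as.character(releves$site)
    ab <- as.matrix(releves[, setdiff(names(releves), "site"), drop = FALSE])
  } else {
    siteIDs <- rownames(releves)
    ab <- as.matrix(releves)
  }
  if (any(ab < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  ab[is.na(ab)] <- 0
  spNames <- if ("species" %in% names(eivs)) as.character(eivs$species)
             else rownames(eivs)
  vals <- eivs[[indicator]]
  numeric_ok <- suppressWarnings(as.numeric(as.character(vals)))
  if (any(!is.na(numeric_ok) & (numeric_ok < 1 | numeric_ok > 9)))
    stop(indicator, " indicator values must lie in the Ellenberg range 1-9")
  lookup <- setNames(numeric_ok, norm(spNames))
  relSpecies <- norm(colnames(ab))
  score <- lookup[relSpecies]          # NA: unmatched or indifferent
  dropped <- colnames(ab)[is.na(score)]
  out <- setNames(numeric(length(siteIDs)), siteIDs)
  for (i in seq_along(siteIDs)) {
    use <- !is.na(score) & ab[i, ] > 0
    if (!any(use))
      stop("site '", siteIDs[i], "' has no scorable species for indicator ",
           indicator)
    out[i] <- sum(ab[i, use] * score[use]) / sum(ab[i, use])
  }
  if (length(dropped))
    message("excluded species without a numeric ", indicator, " value: ",
            paste(dropped, collapse = ", "))
  attr(out, "dropped") <- dropped
  out
}

#' Attach mean weighted EIVs to a site table
#'
#' Convenience wrapper computing all four indicators and appending them as
#' `eiv_L`, `eiv_M`, `eiv_R`, `eiv_N` columns.
#'
#' @param sites site data.frame with population_id matching the relevé site
#'   ids.
#' @param releves,eivs as in [meanWeightedEiv()].
#' @return `sites` with the four EIV columns added.
#' @export
addSiteEivs <- function(sites, releves, eivs) {
  for (ind in c("L", "M", "R", "N")) {
    v <- suppressMessages(meanWeightedEiv(releves, eivs, ind))
    sites[[paste0("eiv_", ind)]] <- unname(v[sites$population_id])
  }
  sites
}
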
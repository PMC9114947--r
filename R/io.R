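#' Read a binary marker matrix from CSV
#'
#' Canonical layout: header row `sample_id,<marker ids...>`, then one row per
#' individual with 0/1 calls. The comma/"." dialect is canonical; `dialect`
#' accepts ";" or tab-separated files.
#'
#' @param path CSV file.
#' @param markerSet label attached to the resulting matrix.
#' @param dialect field separator: "," (default), ";" or "\t".
#' @return a [BinaryMarkerMatrix-class]; row and column order preserved from
#'   the file.
#' @export
readMarkerMatrix <- function(path, markerSet = "markers", dialect = ",") {
  dialect <- match.arg(dialect, c(",", ";", "\t"))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("marker matrix needs a sample_id column and >=1 marker: ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated sample id '", ids[duplicated(ids)][1], "' in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-binary cell '%s' at sample '%s', marker '%s' in %s",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]], path))
  }
  dimnames(num) <- list(ids, colnames(vals))
  BinaryMarkerMatrix(num, markerSet)
}

#' Write a binary marker matrix to CSV
#'
#' Inverse of [readMarkerMatrix()]; round-trips bit-identically.
#'
#' @param x a [BinaryMarkerMatrix-class].
#' @param path output file.
#' @param dialect field separator, as in [readMarkerMatrix()].
#' @return `path`, invisibly.
#' @export
writeMarkerMatrix <- function(x, path, dialect = ",") {
  dialect <- match.arg(dialect, c(",", ";", "\t"))
  df <- data.frame(sample_id = sampleIDs(x), markerValues(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = dialect, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a subepilocus matrix with its class annotation
#'
#' Layout is the marker-matrix CSV preceded by one extra header row carrying
#' the methylation class of each column (`class,<u|m|h ...>`). Column ids are
#' `<fragment>.<class>`, so the source fragment is recoverable on read.
#'
#' @param x a [SubepilocusMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSubepilocusMatrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("class", subepilocusClasses(x)), collapse = ","), con)
  writeLines(paste(c("sample_id", markerIDs(x)), collapse = ","), con)
  vals <- markerValues(x)
  writeLines(paste(sampleIDs(x), apply(vals, 1, paste, collapse = ","),
                   sep = ","), con)
  invisible(path)
}

#' Read a subepilocus matrix written by [writeSubepilocusMatrix()]
#'
#' @param path CSV file with the two-row (class, marker id) header.
#' @return a [SubepilocusMatrix-class].
#' @export
readSubepilocusMatrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("not a subepilocus CSV: ", path)
  classes <- strsplit(lines[1], ",", fixed = TRUE)[[1]][-1]
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  writeLines(lines[-1], tmp)
  base <- readMarkerMatrix(tmp, markerSet = "MSAP-all")
  SubepilocusMatrix(markerValues(base), classes,
                    sub("\\.[umh]$", "", markerIDs(base)))
}

.checkHabitats <- function(habitat, freeLabels, what) {
  if (!freeLabels && !all(habitat %in% c("CG", "OM")))
    stop("unknown habitat label '", setdiff(habitat, c("CG", "OM"))[1],
         "' in ", what, " (use freeLabels = TRUE for arbitrary groups)")
}

#' Read sample and site metadata
#'
#' The sample table maps individuals to populations
#' (`sample_id,population_id,habitat`); the site table carries one row per
#' population (`population_id,habitat,latitude,longitude` plus optional
#' `eiv_L,eiv_M,eiv_R,eiv_N` columns). Consistency is enforced: each
#' population has exactly one habitat, every sample's population exists in
#' the site table, coordinates are valid, and EIVs (when present) lie in the
#' Ellenberg ordinal range 1-9.
#'
#' @param samplesPath sample metadata CSV.
#' @param sitesPath site table CSV.
#' @param freeLabels allow habitat labels other than CG/OM.
#' @return list with data.frames `samples` and `sites`.
#' @export
readMetadata <- function(samplesPath, sitesPath, freeLabels = FALSE) {
  samples <- utils::read.csv(samplesPath, stringsAsFactors = FALSE,
                             colClasses = "character")
  sites <- utils::read.csv(sitesPath, stringsAsFactors = FALSE)
  if (nrow(samples) == 0L || nrow(sites) == 0L)
    warning("empty metadata: ", nrow(samples), " samples, ",
            nrow(sites), " sites")
  validateMetadata(samples, sites, freeLabels = freeLabels)
}

#' Validate (and return) sample/site metadata given as data.frames
#'
#' @param samples data.frame with sample_id, population_id, habitat.
#' @param sites data.frame with population_id, habitat, latitude, longitude
#'   and optional eiv_* columns.
#' @param freeLabels allow habitat labels other than CG/OM.
#' @return list(samples, sites) after validation.
#' @export
validateMetadata <- function(samples, sites, freeLabels = FALSE) {
  need <- c("sample_id", "population_id", "habitat")
  if (!all(need %in% names(samples)))
    stop("sample metadata must have columns ", paste(need, collapse = ", "))
  need <- c("population_id", "habitat", "latitude", "longitude")
  if (!all(need %in% names(sites)))
    stop("site table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id '",
         samples$sample_id[duplicated(samples$sample_id)][1], "'")
  if (anyDuplicated(sites$population_id))
    stop("duplicated population_id in site table")
  hab <- unique(rbind(samples[c("population_id", "habitat")],
                      sites[c("population_id", "habitat")]))
  if (anyDuplicated(hab$population_id))
    stop("population '", hab$population_id[duplicated(hab$population_id)][1],
         "' is assigned two habitats")
  .checkHabitats(unique(hab$habitat), freeLabels, "metadata")
  unknown <- setdiff(samples$population_id, sites$population_id)
  if (length(unknown))
    stop("samples reference unknown population '", unknown[1], "'")
  if (any(abs(sites$latitude) > 90) || any(abs(sites$longitude) > 180))
    stop("coordinates out of range in site table")
  for (col in intersect(c("eiv_L", "eiv_M", "eiv_R", "eiv_N"), names(sites))) {
    v <- sites[[col]]
    if (any(!is.na(v) & (v < 1 | v > 9)))
      stop(col, " outside the Ellenberg range [1, 9]")
  }
  list(samples = samples, sites = sites)
}

#' Re-index a marker matrix to the metadata sample order
#'
#' Sample order in the metadata is authoritative, so that distance matrices
#' align across AFLP and MSAP datasets.
#'
#' @param x a [BinaryMarkerMatrix-class] (or [SubepilocusMatrix-class]).
#' @param samples sample metadata data.frame.
#' @return `x` with rows reordered to `samples$sample_id`.
#' @export
alignToMetadata <- function(x, samples) {
  missing <- setdiff(samples$sample_id, sampleIDs(x))
  if (length(missing))
    stop("marker matrix lacks sample '", missing[1], "'")
  x[samples$sample_id, ]
}
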
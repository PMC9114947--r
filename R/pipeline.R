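#' Run the full genetic/epigenetic analysis chain
#'
#' End-to-end orchestration on one study: MSAP mixed scoring 2; diversity
#' tables for AFLP and the full/u/m/h subepilocus sets; two-level AMOVA with
#' permutation tests on each of the five marker sets; pairwise population
#' PhiPT matrices; geographic and habitat dissimilarity matrices; simple and
#' partial Mantel tests plus MMRR of each PhiPT matrix against geography and
#' habitat; habitat comparisons of diversity; genetic-epigenetic
#' interdependence (paired t plus Pearson and Spearman correlations); and,
#' when the site table carries EIV columns, diversity-environment
#' correlations. All permutation streams derive from `seed`.
#'
#' @param study list with elements `sites`, `samples`, `aflp` (a
#'   [BinaryMarkerMatrix-class]) and `msap` (an [MsapProfilePair-class]):
#'   either from [readStudy()] or built from [simulateStudy()] output via
#'   `runFullStudy(simulateStudy(cfg), ...)` (the simulated layout is
#'   accepted directly).
#' @param amovaPermutations permutations per AMOVA statistic.
#' @param mantelPermutations permutations for Mantel and MMRR tests.
#' @param pairwisePermutations permutations per pairwise PhiPT entry (0
#'   skips their p-values; the PhiPT values themselves are always computed).
#' @param seed integer seed controlling every stochastic step.
#' @param outdir optional directory; when given, one CSV per result table
#'   plus a JSON run summary are written.
#' @return nested list of results: `scoring`, `diversity`, `amova`,
#'   `pairwisePhi`, `matrices`, `mantel`, `mmrr`, `habitatComparisons`,
#'   `interdependence`, `environment` (NULL without EIVs), `seed`.
#' @export
runFullStudy <- function(study, amovaPermutations = 999,
                         mantelPermutations = 9999,
                         pairwisePermutations = 0, seed = 17,
                         outdir = NULL) {
  # accept the simulateStudy() layout directly
  if (!is.null(study$aflp$matrix)) {
    study <- list(sites = study$sites, samples = study$samples,
                  aflp = study$aflp$matrix, msap = study$msap$profiles)
  }
  sites <- study$sites; samples <- study$samples
  stopifnot(identical(sampleIDs(study$aflp), samples$sample_id),
            identical(sampleIDs(study$msap), samples$sample_id))
  groups <- setNames(sites$habitat, sites$population_id)
  pops <- setNames(samples$population_id, samples$sample_id)

  scored <- mixedScoring2(study$msap)
  markerSets <- c(list(AFLP = study$aflp, `MSAP-all` = scored$subepiloci),
                  lapply(setNames(c("u", "m", "h"), c("u", "m", "h")),
                         function(cl) subsetByClass(scored$subepiloci, cl)))

  diversity <- lapply(markerSets, populationDiversity, samples = samples)

  amova <- list(); pairwisePhi <- list()
  for (i in seq_along(markerSets)) {
    d <- squaredEuclideanDistances(markerSets[[i]])
    amova[[names(markerSets)[i]]] <-
      amovaTwoLevel(d, pops, groups, nPermutations = amovaPermutations,
                    seed = seed + i)
    pairwisePhi[[names(markerSets)[i]]] <-
      pairwisePhiPT(d, pops, nPermutations = pairwisePermutations,
                    seed = seed + 100 + i)
  }

  geo <- geographicDistanceMatrix(sites)
  hab <- habitatDissimilarityMatrix(sites)
  mantel <- list(); mmrrRes <- list()
  for (set in names(markerSets)) {
    phi <- pairwisePhi[[set]]$phi[sites$population_id, sites$population_id]
    mantel[[set]] <- list(
      ibd = mantelTest(phi, geo, mantelPermutations, seed = seed + 201),
      ibd_partial_habitat = partialMantelTest(phi, geo, hab,
                                              mantelPermutations,
                                              seed = seed + 202),
      ibh = mantelTest(phi, hab, mantelPermutations, seed = seed + 203),
      ibh_partial_geo = partialMantelTest(phi, hab, geo, mantelPermutations,
                                          seed = seed + 204))
    mmrrRes[[set]] <- mmrr(phi, list(geographic = geo, habitat = hab),
                           mantelPermutations, seed = seed + 205)
  }
  # cross-matrix correlations: genetic vs epigenetic, geography vs habitat
  crossTests <- list(
    genetic_vs_epigenetic = mantelTest(
      pairwisePhi$AFLP$phi[sites$population_id, sites$population_id],
      pairwisePhi$`MSAP-all`$phi[sites$population_id, sites$population_id],
      mantelPermutations, seed = seed + 206),
    geo_vs_habitat = mantelTest(geo, hab, mantelPermutations,
                                seed = seed + 207))

  perPopSI <- function(set) {
    tbl <- diversity[[set]]
    tbl$mean_SI[!(tbl$population_id %in% c("mean", "s.e."))]
  }
  habOfPop <- groups[diversity$AFLP$population_id[
    !(diversity$AFLP$population_id %in% c("mean", "s.e."))]]
  habLevels <- unique(sites$habitat)
  habitatComparisons <- NULL
  if (length(habLevels) == 2) {
    habitatComparisons <- lapply(names(markerSets), function(set) {
      si <- perPopSI(set)
      twoSampleTest(si[habOfPop == habLevels[1]],
                    si[habOfPop == habLevels[2]], force = "t")
    })
    names(habitatComparisons) <- names(markerSets)
  }

  interdependence <- list(
    paired_t = pairedTTest(perPopSI("AFLP"), perPopSI("MSAP-all")),
    pearson = correlationTest(perPopSI("AFLP"), perPopSI("MSAP-all"),
                              "pearson"),
    spearman = correlationTest(perPopSI("AFLP"), perPopSI("MSAP-all"),
                               "spearman"))

  envAssoc <- NULL
  eivCols <- intersect(c("eiv_L", "eiv_M", "eiv_R", "eiv_N"), names(sites))
  if (length(eivCols)) {
    envAssoc <- list()
    for (set in names(markerSets)) {
      si <- perPopSI(set)
      envAssoc[[set]] <- lapply(setNames(eivCols, eivCols), function(cl)
        correlationTest(sites[[cl]][match(
          diversity[[set]]$population_id[seq_along(si)],
          sites$population_id)], si, "pearson"))
    }
  } else message("no EIV columns in the site table; environment stage skipped")

  results <- list(scoring = scored$report, diversity = diversity,
                  amova = amova, pairwisePhi = pairwisePhi,
                  matrices = list(geographic = geo, habitat = hab),
                  mantel = mantel, crossTests = crossTests, mmrr = mmrrRes,
                  habitatComparisons = habitatComparisons,
                  interdependence = interdependence,
                  environment = envAssoc, seed = seed)
  if (!is.null(outdir)) .writeReportBundle(results, outdir)
  results
}

.writeReportBundle <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(outdir, f),
                                          row.names = FALSE, quote = FALSE)
  # AMOVA tables, one file mirroring the conventional layout
  amovaRows <- do.call(rbind, lapply(names(results$amova), function(set) {
    r <- results$amova[[set]]
    tbl <- amovaTable(r)
    tbl <- cbind(marker_set = set, tbl)
    tbl$phi <- NA_real_; tbl$p <- NA_real_
    tbl$phi[1] <- phiStatistics(r)[["phi_PT"]]
    if (length(amovaPValues(r))) tbl$p[1] <- amovaPValues(r)[["phi_PT"]]
    tbl
  }))
  wcsv(amovaRows, "amova.csv")
  divRows <- do.call(rbind, lapply(names(results$diversity), function(set)
    cbind(marker_set = set, results$diversity[[set]])))
  wcsv(divRows, "diversity.csv")
  mantelRows <- do.call(rbind, lapply(names(results$mantel), function(set) {
    tests <- results$mantel[[set]]
    data.frame(marker_set = set, test = names(tests),
               r = vapply(tests, `[[`, numeric(1), "r"),
               p = vapply(tests, `[[`, numeric(1), "p"),
               stringsAsFactors = FALSE)
  }))
  wcsv(mantelRows, "mantel.csv")
  mmrrRows <- do.call(rbind, lapply(names(results$mmrr), function(set) {
    r <- results$mmrr[[set]]
    cbind(marker_set = set, r$coefficients,
          F = r$F, F_p = r$F_p, R2 = r$R2)
  }))
  wcsv(mmrrRows, "mmrr.csv")
  for (set in names(results$pairwisePhi)) {
    phi <- results$pairwisePhi[[set]]$phi
    utils::write.csv(data.frame(population_id = rownames(phi), phi,
                                check.names = FALSE),
                     file.path(outdir, paste0("phipt_",
                                              gsub("[^A-Za-z0-9]", "_", set),
                                              ".csv")), row.names = FALSE)
  }
  summary <- list(
    seed = results$seed,
    package_version = as.character(utils::packageVersion("epiclover")),
    r_version = R.version.string,
    scoring = list(fragments = results$scoring@nFragments,
                   subepiloci = results$scoring@nSubepiloci,
                   u = results$scoring@nU, m = results$scoring@nM,
                   h = results$scoring@nH),
    phi_PT = lapply(results$amova, function(r) unname(phiStatistics(r)["phi_PT"])))
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Check computed results against an expectations table
#'
#' Machine-readable acceptance harness: each expectation names a numeric
#' quantity in a flattened result list, a comparator and a tolerance, and is
#' evaluated to pass/fail.
#'
#' @param values named list or vector of computed numbers.
#' @param expectations data.frame with columns `target` (name in `values`),
#'   `value` (expected number), `cmp` (one of "eq", "le", "ge") and
#'   `tol` (absolute tolerance, used by "eq"); or a path to such a CSV.
#' @return data.frame with one row per expectation and a logical `pass`
#'   column; attribute `ok` is TRUE when all pass.
#' @export
checkExpectations <- function(values, expectations) {
  if (is.character(expectations))
    expectations <- utils::read.csv(expectations, stringsAsFactors = FALSE)
  need <- c("target", "value", "cmp")
  if (!all(need %in% names(expectations)))
    stop("expectations need columns ", paste(need, collapse = ", "))
  if (is.null(expectations$tol))
    expectations$tol <- rep(0, nrow(expectations))
  values <- unlist(values)
  out <- expectations
  out$computed <- rep(NA_real_, nrow(out))
  out$pass <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))) {
    tgt <- out$target[i]
    if (!tgt %in% names(values)) {
      warning("no computed value named '", tgt, "'")
      next
    }
    v <- values[[tgt]]
    out$computed[i] <- v
    out$pass[i] <- switch(out$cmp[i],
      eq = abs(v - out$value[i]) <= out$tol[i],
      le = v <= out$value[i],
      ge = v >= out$value[i],
      stop("unknown comparator '", out$cmp[i], "'"))
  }
  attr(out, "ok") <- all(out$pass)
  out
}
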
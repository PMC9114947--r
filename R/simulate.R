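#' Configuration for a synthetic two-habitat fragment study
#'
#' Defaults mirror a regional two-habitat grassland design: 2 habitat groups
#' of 5 populations with 16 individuals each, 124 AFLP loci and 159 MSAP
#' fragments, weak hierarchical differentiation (theta_pop 0.04 among
#' populations within groups plus theta_group 0.03 between habitats, i.e. a
#' global PhiPT around 0.07), a mild habitat shift in the
#' internal-methylation state, and a moisture effect on epiallele evenness.
#'
#' Differentiation follows a Balding-Nichols-style Beta model: the
#' population band frequency at a locus is Beta-distributed around the group
#' frequency with variance `theta_pop * p * (1 - p)`, which makes the
#' simulated `theta` the quantitative target that band-based AMOVA PhiPT
#' estimates.
#'
#' @param n_groups number of habitat groups (2 gives labels CG/OM).
#' @param pops_per_group populations per group.
#' @param n_per_pop individuals sampled per population.
#' @param n_aflp_loci AFLP loci.
#' @param n_msap_fragments MSAP fragments.
#' @param theta_pop target among-population differentiation in \[0, 1).
#' @param theta_group added among-group differentiation in \[0, 1).
#' @param habitat_methylation_shift log-odds increase of the m state in the
#'   second habitat.
#' @param env_effect slope linking standardized site moisture to methylation
#'   state evenness (positive: wetter sites have more even u/m/h states and
#'   hence higher epigenetic diversity).
#' @param ibd_strength distance-decay coefficient (per km) of the Gaussian
#'   copula correlating population frequencies; 0 disables isolation by
#'   distance.
#' @param seed integer seed; the configuration plus seed fully determines
#'   the dataset.
#' @return validated list of class `simulationConfig`.
#' @export
simulationConfig <- function(n_groups = 2L, pops_per_group = 5L,
                             n_per_pop = 16L, n_aflp_loci = 124L,
                             n_msap_fragments = 159L, theta_pop = 0.04,
                             theta_group = 0.03,
                             habitat_methylation_shift = 0.3,
                             env_effect = 0.3, ibd_strength = 0,
                             seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups),
              pops_per_group = as.integer(pops_per_group),
              n_per_pop = as.integer(n_per_pop),
              n_aflp_loci = as.integer(n_aflp_loci),
              n_msap_fragments = as.integer(n_msap_fragments),
              theta_pop = theta_pop, theta_group = theta_group,
              habitat_methylation_shift = habitat_methylation_shift,
              env_effect = env_effect, ibd_strength = ibd_strength,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_groups", "pops_per_group", "n_per_pop",
                         "n_aflp_loci", "n_msap_fragments")])
  if (any(counts < 1)) stop("all design counts must be positive")
  if (theta_pop < 0 || theta_pop >= 1 || theta_group < 0 || theta_group >= 1)
    stop("theta values must lie in [0, 1)")
  if (ibd_strength < 0) stop("ibd_strength must be non-negative")
  structure(cfg, class = "simulationConfig")
}

# Beta draw with mean p and variance theta * p * (1 - p); theta = 0 passes
# the frequency through unchanged (degenerate Beta limit).
.driftFreq <- function(p, theta) {
  if (theta <= 0) return(p)
  stats::rbeta(length(p), p * (1 - theta) / theta,
               (1 - p) * (1 - theta) / theta)
}

# copula-correlated uniforms for IBD: exponential spatial correlation on
# population coordinates, Beta marginals preserved exactly
.ibdUniforms <- function(nLoci, distKm, decay) {
  K <- nrow(distKm)
  R <- exp(-decay * distKm)
  L <- chol(R + diag(1e-10, K))
  z <- matrix(stats::rnorm(nLoci * K), K, nLoci)
  stats::pnorm(t(L) %*% z)
}

.driftFreqSpatial <- function(p, theta, u) {
  if (theta <= 0) return(rep(p, length(u)))
  stats::qbeta(u, p * (1 - theta) / theta, (1 - p) * (1 - theta) / theta)
}

#' Simulate study sites with habitat-structured environments
#'
#' Sites are placed uniformly in a ~100 x 60 km box with alternating habitat
#' labels; the four environmental indicator means are drawn from
#' habitat-specific normal distributions (the meadow habitat wetter and more
#' nitrogen-rich, the calcareous habitat more alkaline and lighter), clamped
#' to the Ellenberg range.
#'
#' @param config a [simulationConfig()].
#' @return site data.frame: population_id, habitat, latitude, longitude,
#'   eiv_L, eiv_M, eiv_R, eiv_N.
#' @export
simulateSites <- function(config) {
  set.seed(config$seed)
  K <- config$n_groups * config$pops_per_group
  habitats <- if (config$n_groups == 2) c("CG", "OM")
              else paste0("G", seq_len(config$n_groups))
  habitat <- rep(habitats, length.out = K)
  # habitat-specific environmental means (CG dry/alkaline, OM moist/fertile)
  envMean <- list(CG = c(L = 7.45, M = 3.4, R = 7.6, N = 2.7),
                  OM = c(L = 7.05, M = 4.9, R = 6.9, N = 5.3))
  envSd <- c(L = 0.2, M = 0.35, R = 0.3, N = 0.5)
  pick <- function(h, ind) {
    m <- if (h %in% names(envMean)) envMean[[h]][[ind]] else 5
    pmin(9, pmax(1, stats::rnorm(1, m, envSd[[ind]])))
  }
  sites <- data.frame(
    population_id = sprintf("pop%02d", seq_len(K)),
    habitat = habitat,
    latitude = stats::runif(K, 48.20, 48.74),
    longitude = stats::runif(K, 9.00, 10.34),
    stringsAsFactors = FALSE)
  for (ind in c("L", "M", "R", "N"))
    sites[[paste0("eiv_", ind)]] <-
      vapply(habitat, pick, numeric(1), ind = ind, USE.NAMES = FALSE)
  sites
}

#' Sample metadata for simulated sites
#'
#' @param config a [simulationConfig()].
#' @param sites site table from [simulateSites()].
#' @return sample data.frame: sample_id, population_id, habitat.
#' @export
simulateSamples <- function(config, sites) {
  data.frame(
    sample_id = paste0(rep(sites$population_id, each = config$n_per_pop), "_",
                       sprintf("i%02d", seq_len(config$n_per_pop))),
    population_id = rep(sites$population_id, each = config$n_per_pop),
    habitat = rep(sites$habitat, each = config$n_per_pop),
    stringsAsFactors = FALSE)
}

# hierarchical band-frequency model shared by the AFLP and MSAP generators:
# ancestral -> group (theta_group) -> population (theta_pop), optional
# spatial copula at the population level
.popFrequencies <- function(config, sites, nLoci, ancestralRange) {
  K <- nrow(sites)
  p0 <- stats::runif(nLoci, ancestralRange[1], ancestralRange[2])
  groupIdx <- match(sites$habitat, unique(sites$habitat))
  G <- max(groupIdx)
  pGroup <- matrix(0, G, nLoci)
  for (g in seq_len(G)) pGroup[g, ] <- .driftFreq(p0, config$theta_group)
  pPop <- matrix(0, K, nLoci,
                 dimnames = list(sites$population_id, NULL))
  u <- if (config$ibd_strength > 0 && config$theta_pop > 0)
    .ibdUniforms(nLoci, geographicDistanceMatrix(sites), config$ibd_strength)
  for (l in seq_len(nLoci)) {
    base <- pGroup[groupIdx, l]
    pPop[, l] <- if (is.null(u)) .driftFreq(base, config$theta_pop)
                 else mapply(.driftFreqSpatial, base, config$theta_pop, u[, l])
  }
  list(ancestral = p0, group = pGroup, pop = pPop, groupIdx = groupIdx)
}

#' Simulate an AFLP band matrix with known differentiation
#'
#' Individuals' band calls are Bernoulli draws from hierarchically drifted
#' population band frequencies (see [simulationConfig()]); the returned
#' truth record stores every frequency so downstream estimates can be
#' compared with their generating values.
#'
#' @param config a [simulationConfig()].
#' @param sites site table from [simulateSites()].
#' @return list: `matrix` (a [BinaryMarkerMatrix-class]), `samples`
#'   (metadata), `truth` (ancestral/group/population frequencies and thetas).
#' @export
simulateAflp <- function(config, sites) {
  set.seed(config$seed + 1L)
  samples <- simulateSamples(config, sites)
  fr <- .popFrequencies(config, sites, config$n_aflp_loci, c(0.1, 0.9))
  n <- nrow(samples)
  probs <- fr$pop[samples$population_id, , drop = FALSE]
  calls <- matrix(stats::rbinom(length(probs), 1, probs), n,
                  dimnames = list(samples$sample_id,
                                  sprintf("aflp%03d", seq_len(config$n_aflp_loci))))
  list(matrix = BinaryMarkerMatrix(calls, "AFLP"), samples = samples,
       truth = list(theta_pop = config$theta_pop,
                    theta_group = config$theta_group,
                    ancestral = fr$ancestral, group_freq = fr$group,
                    pop_freq = fr$pop))
}

#' Simulate paired MSAP profiles with habitat-linked methylation
#'
#' Fragment presence follows the same hierarchical frequency model as the
#' AFLP generator. Each present fragment copy is assigned a methylation
#' state from fragment-specific (u, m, h) weights: the m-state log-weight is
#' shifted by `habitat_methylation_shift` in the second habitat, and site
#' moisture flattens or sharpens the state distribution through
#' `env_effect` (softmax temperature), linking moisture to epiallele
#' evenness. States are emitted as call pairs u -> (1,1), m -> (0,1),
#' h -> (1,0), absent -> (0,0).
#'
#' @param config a [simulationConfig()].
#' @param sites site table from [simulateSites()].
#' @return list: `profiles` (an [MsapProfilePair-class]), `samples`,
#'   `truth` (presence frequencies, state weights, per-site temperatures).
#' @export
simulateMsap <- function(config, sites) {
  set.seed(config$seed + 2L)
  samples <- simulateSamples(config, sites)
  nf <- config$n_msap_fragments
  fr <- .popFrequencies(config, sites, nf, c(0.2, 0.95))
  # fragment-wise baseline state weights (u, m, h), Dirichlet-distributed
  w <- matrix(stats::rgamma(3 * nf, shape = rep(c(3, 3, 2), each = nf)), nf)
  w <- w / rowSums(w)
  zM <- as.numeric(scale(sites$eiv_M))
  if (anyNA(zM)) zM <- rep(0, nrow(sites))   # constant moisture degenerate
  tau <- exp(config$env_effect * zM)          # per-site softmax temperature
  habitats <- unique(sites$habitat)
  shiftOfSite <- ifelse(sites$habitat == habitats[min(2, length(habitats))],
                        config$habitat_methylation_shift, 0)
  n <- nrow(samples)
  hpa <- msp <- matrix(0L, n, nf,
                       dimnames = list(samples$sample_id,
                                       sprintf("frag%03d", seq_len(nf))))
  states <- matrix("uninformative", n, nf, dimnames = dimnames(hpa))
  siteOfSample <- match(samples$population_id, sites$population_id)
  stateProbs <- function(siteIdx, frag) {
    lw <- log(w[frag, ])
    lw[2] <- lw[2] + shiftOfSite[siteIdx]
    pr <- exp(lw / tau[siteIdx])
    s <- sum(pr)
    if (!is.finite(s) || s <= 0) stop("internal error: state weights failed to normalize")
    pr / s
  }
  for (f in seq_len(nf)) {
    present <- stats::rbinom(n, 1, fr$pop[samples$population_id, f])
    for (i in which(present == 1L)) {
      st <- sample(c("u", "m", "h"), 1, prob = stateProbs(siteOfSample[i], f))
      states[i, f] <- st
      if (st == "u") { hpa[i, f] <- 1L; msp[i, f] <- 1L }
      else if (st == "m") msp[i, f] <- 1L
      else hpa[i, f] <- 1L
    }
  }
  list(profiles = MsapProfilePair(BinaryMarkerMatrix(hpa, "HpaII"),
                                  BinaryMarkerMatrix(msp, "MspI")),
       samples = samples,
       truth = list(theta_pop = config$theta_pop,
                    theta_group = config$theta_group,
                    habitat_methylation_shift = config$habitat_methylation_shift,
                    env_effect = config$env_effect,
                    presence_pop_freq = fr$pop, state_weights = w,
                    site_temperature = tau, states = states))
}

#' Simulate a complete study
#'
#' Sites, sample metadata, AFLP matrix and MSAP profile pair from one
#' configuration; rerunning with the same configuration reproduces the
#' dataset exactly.
#'
#' @param config a [simulationConfig()].
#' @return list: config, sites, samples, aflp, msap (each generator's output).
#' @export
simulateStudy <- function(config = simulationConfig()) {
  sites <- simulateSites(config)
  aflp <- simulateAflp(config, sites)
  msap <- simulateMsap(config, sites)
  list(config = config, sites = sites, samples = aflp$samples,
       aflp = aflp, msap = msap)
}

#' Write a simulated study to disk
#'
#' Emits samples.csv, sites.csv, aflp.csv, msap_hpa.csv, msap_msp.csv in the
#' package's canonical CSV formats plus truth.json (generating frequencies,
#' effect parameters and the seed), so every pipeline stage can be run from
#' files alone.
#'
#' @param study result of [simulateStudy()], or a [simulationConfig()] to
#'   simulate first.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeStudy <- function(study, outdir) {
  if (inherits(study, "simulationConfig")) study <- simulateStudy(study)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$samples, file.path(outdir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$sites, file.path(outdir, "sites.csv"),
                   row.names = FALSE, quote = FALSE)
  writeMarkerMatrix(study$aflp$matrix, file.path(outdir, "aflp.csv"))
  writeMarkerMatrix(hpaProfile(study$msap$profiles),
                    file.path(outdir, "msap_hpa.csv"))
  writeMarkerMatrix(mspProfile(study$msap$profiles),
                    file.path(outdir, "msap_msp.csv"))
  truth <- list(config = unclass(study$config),
                aflp = study$aflp$truth[c("theta_pop", "theta_group")],
                msap = study$msap$truth[c("theta_pop", "theta_group",
                                          "habitat_methylation_shift",
                                          "env_effect")])
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read a study written by [writeStudy()]
#'
#' @param dir directory holding the study CSVs.
#' @return list: sites, samples, aflp ([BinaryMarkerMatrix-class]), msap
#'   ([MsapProfilePair-class]).
#' @export
readStudy <- function(dir) {
  meta <- readMetadata(file.path(dir, "samples.csv"),
                       file.path(dir, "sites.csv"), freeLabels = TRUE)
  aflp <- alignToMetadata(readMarkerMatrix(file.path(dir, "aflp.csv"), "AFLP"),
                          meta$samples)
  hpa <- alignToMetadata(readMarkerMatrix(file.path(dir, "msap_hpa.csv"), "HpaII"),
                         meta$samples)
  msp <- alignToMetadata(readMarkerMatrix(file.path(dir, "msap_msp.csv"), "MspI"),
                         meta$samples)
  list(sites = meta$sites, samples = meta$samples, aflp = aflp,
       msap = MsapProfilePair(hpa, msp))
}
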
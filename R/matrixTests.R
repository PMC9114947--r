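#' Great-circle distance matrix between study sites
#'
#' Haversine distances on unprojected coordinates with the mean Earth radius
#' 6371.0088 km; adequate at the ~100 km extent of regional population
#' studies, where the difference to a projected planar distance is
#' negligible.
#'
#' @param sites site data.frame with population_id, latitude, longitude.
#' @return symmetric matrix of distances in km, labelled by population.
#' @export
geographicDistanceMatrix <- function(sites) {
  if (anyNA(sites$latitude) || anyNA(sites$longitude))
    stop("missing coordinate for site '",
         sites$population_id[is.na(sites$latitude) | is.na(sites$longitude)][1], "'")
  xy <- cbind(sites$longitude, sites$latitude)
  d <- geosphere::distm(xy, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371008.8)) / 1000
  dimnames(d) <- list(sites$population_id, sites$population_id)
  diag(d) <- 0
  d
}

#' Habitat dissimilarity matrix
#'
#' Binary model matrix for isolation by habitat: pairs of sites from
#' different habitat types are coded 1, pairs from the same habitat 0.
#'
#' @param sites site data.frame with population_id and habitat.
#' @return symmetric 0/1 matrix labelled by population.
#' @export
habitatDissimilarityMatrix <- function(sites) {
  if (anyNA(sites$habitat)) stop("every site needs a habitat label")
  d <- outer(sites$habitat, sites$habitat, "!=") * 1
  dimnames(d) <- list(sites$population_id, sites$population_id)
  d
}

.upperVec <- function(m) m[upper.tri(m)]

.checkAligned <- function(...) {
  ms <- list(...)
  lab <- rownames(ms[[1]])
  for (m in ms) {
    .checkDistanceMatrix2(m)
    if (!identical(rownames(m), lab))
      stop("distance matrices must share labels in the same order")
  }
  invisible(lab)
}

# habitat matrices have a 0/1 structure but still zero diagonal/symmetric
.checkDistanceMatrix2 <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  invisible(d)
}

# all permutations of 1..n (used for exhaustive Mantel tests at tiny n)
.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Simple Mantel test
#'
#' Pearson correlation between the upper-triangle entries of two aligned
#' distance matrices, with significance from joint row/column permutation of
#' the first matrix. The default tail is upper (positive association), the
#' convention of the ecology packages this test comes from; `tail =
#' "two_sided"` uses `|r|`. With `exhaustive = TRUE` all `n!` relabelings
#' are enumerated and the p-value is exact.
#'
#' @param a,b aligned labelled distance matrices.
#' @param nPermutations random permutations (ignored if `exhaustive`).
#' @param tail "upper" or "two_sided".
#' @param seed optional integer seed.
#' @param exhaustive enumerate all permutations (feasible for n <= 7).
#' @return list of class `mantelResult`: r, p, nPermutations, tail.
#' @export
mantelTest <- function(a, b, nPermutations = 9999, tail = c("upper", "two_sided"),
                       seed = NULL, exhaustive = FALSE) {
  tail <- match.arg(tail)
  .checkAligned(a, b)
  n <- nrow(a)
  if (n < 4L) stop("need at least 4 sites for a Mantel test")
  va <- .upperVec(a); vb <- .upperVec(b)
  if (stats::sd(va) == 0) stop("first matrix is constant; r undefined")
  if (stats::sd(vb) == 0) stop("second matrix is constant; r undefined")
  r <- stats::cor(va, vb)
  stat <- function(x) if (tail == "upper") x else abs(x)
  if (exhaustive) {
    perms <- .allPermutations(n)
    rs <- apply(perms, 1, function(p) stats::cor(.upperVec(a[p, p]), vb))
    p <- mean(stat(rs) >= stat(r) - 1e-12)
    nPermutations <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (k in seq_len(nPermutations)) {
      idx <- sample(n)
      rp <- stats::cor(.upperVec(a[idx, idx]), vb)
      if (stat(rp) >= stat(r) - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (nPermutations + 1)
  }
  structure(list(r = r, p = p, nPermutations = nPermutations, tail = tail,
                 conditionedOn = NULL), class = "mantelResult")
}

#' Partial Mantel test
#'
#' First-order partial correlation of `a` and `b` given `c`,
#' `r_ab.c = (r_ab - r_ac r_bc) / sqrt((1 - r_ac^2)(1 - r_bc^2))`, with the
#' permutation scheme of the simple test applied to `a` and the partial
#' correlation recomputed under every relabeling.
#'
#' @param a,b,c aligned labelled distance matrices; `c` is conditioned on.
#' @inheritParams mantelTest
#' @return list of class `mantelResult`.
#' @export
partialMantelTest <- function(a, b, c, nPermutations = 9999,
                              tail = c("upper", "two_sided"), seed = NULL,
                              exhaustive = FALSE) {
  tail <- match.arg(tail)
  .checkAligned(a, b, c)
  n <- nrow(a)
  if (n < 4L) stop("need at least 4 sites for a Mantel test")
  va <- .upperVec(a); vb <- .upperVec(b); vc <- .upperVec(c)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0 || stats::sd(vc) == 0)
    stop("constant matrix; correlations undefined")
  partial <- function(xa) {
    rab <- stats::cor(xa, vb); rac <- stats::cor(xa, vc)
    rbc <- stats::cor(vb, vc)
    if (abs(rac) >= 1 - 1e-12 || abs(rbc) >= 1 - 1e-12)
      stop("degenerate conditioning: conditioning matrix is collinear with an input")
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  }
  r <- partial(va)
  stat <- function(x) if (tail == "upper") x else abs(x)
  if (exhaustive) {
    perms <- .allPermutations(n)
    rs <- apply(perms, 1, function(p) partial(.upperVec(a[p, p])))
    p <- mean(stat(rs) >= stat(r) - 1e-12)
    nPermutations <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (k in seq_len(nPermutations)) {
      idx <- sample(n)
      rp <- partial(.upperVec(a[idx, idx]))
      if (stat(rp) >= stat(r) - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (nPermutations + 1)
  }
  structure(list(r = r, p = p, nPermutations = nPermutations, tail = tail,
                 conditionedOn = deparse(substitute(c))), class = "mantelResult")
}

#' @export
print.mantelResult <- function(x, ...) {
  kind <- if (is.null(x$conditionedOn)) "Simple Mantel test"
          else paste0("Partial Mantel test (conditioned on ", x$conditionedOn, ")")
  cat(sprintf("%s: r = %.3f, p = %.4g (%s tail, %d permutations)\n",
              kind, x$r, x$p, x$tail, x$nPermutations))
  invisible(x)
}

#' Multiple matrix regression with randomization (MMRR)
#'
#' Regresses the unfolded (upper-triangle) response distance matrix on one
#' or more unfolded predictor matrices. All vectors are centred and scaled
#' to unit standard deviation, so coefficients are standardized. Ordinary
#' least squares supplies coefficients, t statistics, R-squared and the
#' overall F; significance comes from jointly permuting rows and columns of
#' the response and recomputing all statistics (two-tailed on |t| for
#' coefficients, upper-tail for F).
#'
#' @param y response distance matrix.
#' @param x named list of predictor distance matrices, aligned with `y`.
#' @param nPermutations number of permutations.
#' @param seed optional integer seed.
#' @param conditionThreshold condition-number limit above which the
#'   predictor set is rejected as collinear.
#' @return list of class `mmrrResult`: coefficients table (coefficient, t,
#'   p per predictor), `R2`, `F`, `F_p`, `nPermutations`.
#' @export
mmrr <- function(y, x, nPermutations = 9999, seed = NULL,
                 conditionThreshold = 1e6) {
  if (is.matrix(x)) x <- list(X1 = x)
  stopifnot(length(x) >= 1)
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- paste0("X", seq_along(x))
  do.call(.checkAligned, c(list(y), unname(x)))
  n <- nrow(y)
  if (n < 5L) stop("need at least 5 sites for MMRR")
  scaleVec <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("constant distance matrix; cannot standardize")
    (v - mean(v)) / s
  }
  xv <- vapply(x, function(m) scaleVec(.upperVec(m)), numeric(n * (n - 1) / 2))
  if (ncol(xv) > 1) {
    kap <- kappa(cbind(1, xv), exact = TRUE)
    if (kap > conditionThreshold) {
      cm <- stats::cor(xv)
      diag(cm) <- 0
      worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
      stop(sprintf("collinear predictors '%s' and '%s' (condition number %.3g)",
                   colnames(xv)[worst[1]], colnames(xv)[worst[2]], kap))
    }
  }
  fitStats <- function(yv) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xv), yv)
    res <- fit$residuals
    dfRes <- length(yv) - fit$rank
    sigma2 <- sum(res^2) / dfRes
    XtXinv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(diag(XtXinv) * sigma2)
    tval <- fit$coefficients / se
    ssTot <- sum((yv - mean(yv))^2)
    r2 <- 1 - sum(res^2) / ssTot
    k <- ncol(xv)
    fstat <- (r2 / k) / ((1 - r2) / dfRes)
    list(coef = fit$coefficients[-1], t = tval[-1], R2 = r2, F = fstat)
  }
  yv <- scaleVec(.upperVec(y))
  obs <- fitStats(yv)
  if (!is.null(seed)) set.seed(seed)
  hitsT <- numeric(length(obs$t)); hitsF <- 0L
  for (k in seq_len(nPermutations)) {
    idx <- sample(n)
    perm <- fitStats(scaleVec(.upperVec(y[idx, idx])))
    hitsT <- hitsT + (abs(perm$t) >= abs(obs$t) - 1e-12)
    if (perm$F >= obs$F - 1e-12) hitsF <- hitsF + 1L
  }
  coefTbl <- data.frame(predictor = names(x),
                        coefficient = unname(obs$coef),
                        t = unname(obs$t),
                        p = unname((hitsT + 1) / (nPermutations + 1)),
                        stringsAsFactors = FALSE)
  structure(list(coefficients = coefTbl, R2 = obs$R2, F = obs$F,
                 F_p = (hitsF + 1) / (nPermutations + 1),
                 nPermutations = nPermutations), class = "mmrrResult")
}

#' @export
print.mmrrResult <- function(x, ...) {
  cat(sprintf("MMRR: R2 = %.3f, F = %.2f, p(F) = %.4g (%d permutations)\n",
              x$R2, x$F, x$F_p, x$nPermutations))
  tbl <- x$coefficients
  tbl$coefficient <- round(tbl$coefficient, 4)
  tbl$t <- round(tbl$t, 3)
  print(tbl, row.names = FALSE)
  invisible(x)
}
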
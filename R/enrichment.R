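.knownPairs <- list(
  "A1/A0" = c(1L, 0L), "A2/A0" = c(2L, 0L), "A2/A1" = c(2L, 1L),
  "A3/A0" = c(3L, 0L), "A4/A0" = c(4L, 0L)
)

.pairIndices <- function(pair) {
  if (is.character(pair)) {
    if (!pair %in% names(.knownPairs))
      stop("unknown isotopomer pair '", pair, "'; use one of ",
           paste(names(.knownPairs), collapse = ", "))
    return(.knownPairs[[pair]])
  }
  stopifnot(is.numeric(pair), length(pair) == 2)
  p <- as.integer(pair)
  if (any(p < 0 | p > 5) || p[1] == p[2]) stop("invalid isotopomer pair")
  p
}

#' Theoretical isotopomer abundance ratio at a given enrichment
#'
#' The raw-abundance ratio A_i(t)/A_j(t) equals the RIA ratio
#' I_i(t)/I_j(t) because the normalization coefficient cancels. The RIAs
#' are evaluated with [labeledIsotopomerRias()].
#'
#' @param pair Pair label ("A1/A0", "A2/A0", "A2/A1", and the
#'   supplementary "A3/A0", "A4/A0") or an integer vector `c(i, j)`.
#' @param pX Deuterium enrichment.
#' @param natural Natural RIAs at t = 0.
#' @param nEH Number of exchangeable hydrogens.
#' @param pH Natural deuterium abundance.
#' @return The ratio I_i(pX)/I_j(pX).
#' @export
theoreticalRatio <- function(pair, pX, natural, nEH, pH = 0.000115) {
  ij <- .pairIndices(pair)
  ria <- isoValues(labeledIsotopomerRias(natural, pX, nEH, pH))
  denom <- ria[ij[2] + 1L]
  if (denom <= 0) stop("undefined ratio: I_", ij[2], "(pX) is zero")
  ria[ij[1] + 1L] / denom
}

#' Closed-form A2/A1 ratio
#'
#' The published closed form for the second-to-first heavy isotopomer
#' ratio, expressed through b_n coefficients and the
#' (N_EH + 1)/(N_EH - 1) factor. Provided as an independent cross-check
#' of the generic [theoreticalRatio()] path; requires N_EH != 1.
#'
#' @inheritParams theoreticalRatio
#' @return The ratio I_2(pX)/I_1(pX).
#' @export
closedFormRatioA2A1 <- function(pX, natural, nEH, pH = 0.000115) {
  stopifnot(abs(nEH - 1) > 1e-9)
  nat <- .isoNum(natural)
  i0z <- nat[1]
  b10 <- bCoefficient(1, nEH, 0, pH)
  b20 <- bCoefficient(2, nEH, 0, pH)
  b1t <- bCoefficient(1, nEH, pX, pH)
  b2t <- bCoefficient(2, nEH, pX, pH)
  i0t <- i0z * (1 - pX / (1 - pH))^nEH
  i1t <- (b1t - b10) * i0t + (i0t / i0z) * nat[2]
  if (i1t <= 0) stop("undefined ratio: I_1(pX) is zero")
  braced <- nat[3] / i0z - (nat[2] / i0z) * b10 +
    (nEH + 1) / (nEH - 1) * (b20 - b2t)
  braced * i0t / i1t + b1t
}

.invalidEstimate <- function(method, timePoint) {
  new("EnrichmentEstimate", pX = 0, method = method,
      objectiveResidual = 0, timePoint = as.numeric(timePoint),
      atBoundary = FALSE, valid = FALSE)
}

#' Estimate deuterium enrichment from one pair of mass isotopomers
#'
#' Finds pX in `[0, pW]` minimizing the absolute difference between the
#' theoretical ratio I_i(pX)/I_j(pX) and the experimental ratio
#' A_i/A_j. A coarse 50-point pre-scan brackets the minimum before
#' Brent refinement, guarding against any non-monotone objective. When
#' the experimental ratio is unreachable on `[0, pW]` the nearest
#' boundary is returned, flagged, with its residual.
#'
#' @param Ai,Aj Raw abundances of the i-th and j-th isotopomers.
#' @param pair Pair label or integer pair, see [theoreticalRatio()].
#' @param natural Natural RIAs at t = 0.
#' @param nEH Number of exchangeable hydrogens.
#' @param pH Natural deuterium abundance.
#' @param pW Body-water enrichment (upper bound for pX).
#' @param timePoint Labeling time in days, carried into the result.
#' @param tol Absolute solver tolerance (default 1e-9).
#' @return An [EnrichmentEstimate-class]; `valid` is FALSE when either
#'   abundance is non-positive.
#' @export
estimateEnrichmentFromPair <- function(Ai, Aj, pair, natural, nEH,
                                       pH = 0.000115, pW = 0.046,
                                       timePoint = NA_real_, tol = 1e-9) {
  method <- if (is.character(pair)) pair else
    paste0("A", pair[1], "/A", pair[2])
  if (!is.finite(Ai) || !is.finite(Aj) || Ai <= 0 || Aj <= 0)
    return(.invalidEstimate(method, timePoint))
  robs <- Ai / Aj
  obj <- function(p) abs(theoreticalRatio(pair, p, natural, nEH, pH) - robs)
  grid <- seq(0, pW, length.out = 50L)
  vals <- vapply(grid, obj, numeric(1))
  ibest <- which.min(vals)
  lo <- grid[max(1L, ibest - 1L)]
  hi <- grid[min(length(grid), ibest + 1L)]
  if (lo < hi) {
    opt <- stats::optimize(obj, lower = lo, upper = hi, tol = tol)
    pX <- opt$minimum
    res <- opt$objective
  } else {
    pX <- grid[ibest]
    res <- vals[ibest]
  }
  # endpoints can beat the interior optimum when the target is unreachable
  for (p in c(0, pW)) {
    v <- obj(p)
    if (v < res) { pX <- p; res <- v }
  }
  boundary <- (pX <= tol || pX >= pW - tol) && res > 10 * tol
  if (pX < 0) pX <- 0
  if (pX > pW) pX <- pW
  new("EnrichmentEstimate", pX = pX, method = method,
      objectiveResidual = res, timePoint = as.numeric(timePoint),
      atBoundary = boundary, valid = TRUE)
}

#' Estimate deuterium enrichment from the complete isotope profile
#'
#' The traditional route: the monoisotopic RIA is taken as the
#' normalized abundance A_0 / sum(A_0..A_5) and the enrichment follows
#' from the exact inversion
#' pX = (1 - pH) (1 - (I_0(t)/I_0(0))^(1/N_EH)), clipped to `[0, pW]`.
#' Because only six isotopomers are observed, the normalized abundance
#' overstates the true RIA by the inverse six-peak coverage of the
#' labeled distribution; a short fixed-point iteration rescales the
#' observation by the model's own six-peak sum at the current estimate,
#' so noiseless profiles invert exactly even when the heavy tail is
#' non-negligible. Set `truncationCorrection = FALSE` for the plain
#' one-shot inversion.
#'
#' @param abundances Raw abundances A_0..A_5 (numeric of length 6).
#' @param truncationCorrection Apply the six-peak coverage correction
#'   (default TRUE).
#' @inheritParams estimateEnrichmentFromPair
#' @return An [EnrichmentEstimate-class] with method "full_profile". A
#'   super-natural monoisotope (observed normalized abundance above the
#'   unlabeled value) yields pX = 0, flagged.
#' @export
estimateEnrichmentFullProfile <- function(abundances, natural, nEH,
                                          pH = 0.000115, pW = 0.046,
                                          timePoint = NA_real_,
                                          truncationCorrection = TRUE) {
  a <- .isoNum(abundances)
  if (any(!is.finite(a)) || sum(a) <= 0 || a[1] <= 0)
    return(.invalidEstimate("full_profile", timePoint))
  nat <- .isoNum(natural)
  i0z <- nat[1]
  obs <- a[1] / sum(a)                      # I_0(t) / S6(t)
  s6 <- function(p) sum(isoValues(labeledIsotopomerRias(nat, p, nEH, pH)))
  boundary <- FALSE
  if (obs > i0z / sum(nat) + 1e-12) {
    pX <- 0
    boundary <- TRUE
  } else {
    pX <- max(0, (1 - pH) * (1 - (pmin(obs, i0z) / i0z)^(1 / nEH)))
    if (truncationCorrection) {
      for (iter in 1:4) {
        i0t <- obs * s6(min(pX, pW))
        if (i0t > i0z) i0t <- i0z
        pX <- (1 - pH) * (1 - (i0t / i0z)^(1 / nEH))
      }
    }
    if (pX > pW) { pX <- pW; boundary <- TRUE }
    if (pX < 0) { pX <- 0; boundary <- TRUE }
  }
  res <- abs(reconstructMonoisotopicRia(pX, i0z, nEH, pH) / s6(pX) - obs)
  new("EnrichmentEstimate", pX = pX, method = "full_profile",
      objectiveResidual = res, timePoint = as.numeric(timePoint),
      atBoundary = boundary, valid = TRUE)
}

#' Reconstruct the monoisotopic RIA from an enrichment estimate
#'
#' I0_tilde(t) = I_0(0) (1 - pX/(1 - pH))^N_EH. This converts any pairwise
#' enrichment estimate back onto the monoisotopic-RIA scale used by the
#' exponential-decay turnover model.
#'
#' @param pX Deuterium enrichment.
#' @param i0Natural Monoisotopic RIA of the unlabeled peptide, I_0(0).
#' @param nEH Number of exchangeable hydrogens.
#' @param pH Natural deuterium abundance.
#' @return The reconstructed monoisotopic RIA.
#' @export
reconstructMonoisotopicRia <- function(pX, i0Natural, nEH, pH = 0.000115) {
  stopifnot(pX >= 0, pX / (1 - pH) < 1)
  i0Natural * (1 - pX / (1 - pH))^nEH
}
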
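#' @import methods
NULL

#' PeptideComposition: elemental composition of one peptide species
#'
#' Holds the elemental counts of a peptide together with the number of
#' hydrogens exchangeable with body-water deuterium (N_EH). The charge is
#' carried along for bookkeeping only; it shifts m/z, not the isotopomer
#' abundance pattern.
#'
#' @slot sequence Amino-acid sequence (one-letter codes).
#' @slot charge Positive integer charge state.
#' @slot elementCounts Named numeric vector of atom counts (at least
#'   C, H, N, O, S).
#' @slot nExchangeable N_EH, the number of deuterium-accessible hydrogens;
#'   may be non-integer because per-residue values are empirical averages.
#'
#' @seealso [peptideComposition()]
#' @export
setClass("PeptideComposition",
  representation(
    sequence = "character",
    charge = "integer",
    elementCounts = "numeric",
    nExchangeable = "numeric"
  )
)

setValidity("PeptideComposition", function(object) {
  msg <- character()
  ec <- object@elementCounts
  if (is.null(names(ec)) || any(!nzchar(names(ec))))
    msg <- c(msg, "elementCounts must be a named vector")
  if (any(ec < 0)) msg <- c(msg, "element counts must be non-negative")
  if (length(object@nExchangeable) != 1 || object@nExchangeable < 0)
    msg <- c(msg, "nExchangeable must be a single non-negative number")
  if ("H" %in% names(ec) && ec[["H"]] < object@nExchangeable - 1e-9)
    msg <- c(msg, "nExchangeable cannot exceed the hydrogen count")
  if (length(object@charge) != 1 || is.na(object@charge) || object@charge < 1)
    msg <- c(msg, "charge must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' IsotopomerVector: the first six mass-isotopomer abundances
#'
#' Relative isotope abundances (RIAs) or raw abundances of the aggregated
#' mass isotopomers +0..+5 of a peptide, monoisotope first. When
#' `normalized` is TRUE the entries are RIAs of the full isotope
#' distribution (so their sum is at most 1 up to truncation).
#'
#' @slot values Numeric vector of length 6, non-negative.
#' @slot normalized Logical; TRUE for RIAs, FALSE for raw abundances.
#'
#' @seealso [isotopomerVector()], [naturalIsotopeDistribution()]
#' @export
setClass("IsotopomerVector",
  representation(values = "numeric", normalized = "logical")
)

setValidity("IsotopomerVector", function(object) {
  msg <- character()
  if (length(object@values) != 6)
    msg <- c(msg, "values must have length 6 (isotopomers +0..+5)")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (isTRUE(object@normalized) && sum(object@values) > 1 + 1e-9)
    msg <- c(msg, "normalized values must sum to at most 1")
  if (length(msg)) msg else TRUE
})

#' LabelingParameters: heavy-water labeling experiment parameters
#'
#' @slot pH Natural deuterium abundance (fraction), default 0.000115.
#' @slot pW Body-water deuterium enrichment at plateau (fraction).
#' @slot timePoints Labeling durations in days, non-negative and strictly
#'   increasing; the first point is the unlabeled reference.
#'
#' @seealso [labelingParameters()]
#' @export
setClass("LabelingParameters",
  representation(pH = "numeric", pW = "numeric", timePoints = "numeric")
)

setValidity("LabelingParameters", function(object) {
  msg <- character()
  if (!(object@pH > 0 && object@pH < object@pW && object@pW < 1))
    msg <- c(msg, "require 0 < pH < pW < 1")
  tp <- object@timePoints
  if (length(tp) < 1 || any(tp < 0))
    msg <- c(msg, "timePoints must be non-negative")
  if (length(tp) > 1 && any(diff(tp) <= 0))
    msg <- c(msg, "timePoints must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' EnrichmentEstimate: deuterium enrichment at one time point
#'
#' @slot pX Estimated enrichment, constrained to [0, pW].
#' @slot method One of "A1/A0", "A2/A0", "A2/A1", "full_profile" (the
#'   supplementary "A3/A0"/"A4/A0" ratios are also recognised).
#' @slot objectiveResidual Achieved |theoretical - experimental| ratio
#'   difference (pair methods) or the post-clip monoisotopic-RIA residual
#'   (full profile).
#' @slot timePoint Labeling time in days (NA if not attached).
#' @slot atBoundary TRUE when the experimental ratio fell outside the range
#'   achievable on [0, pW] and the estimate was clipped to a bound.
#' @slot valid FALSE for unusable inputs (non-positive abundances); such
#'   estimates are excluded downstream.
#' @export
setClass("EnrichmentEstimate",
  representation(
    pX = "numeric", method = "character", objectiveResidual = "numeric",
    timePoint = "numeric", atBoundary = "logical", valid = "logical"
  )
)

setValidity("EnrichmentEstimate", function(object) {
  msg <- character()
  if (object@valid && (object@pX < 0 || object@pX > 1))
    msg <- c(msg, "pX must lie in [0, 1]")
  if (object@valid && object@objectiveResidual < 0)
    msg <- c(msg, "objectiveResidual must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TurnoverFit: exponential-decay fit for one peptide time course
#'
#' One-parameter fit of I0(t) = I0_asymp + (I0(0) - I0_asymp) exp(-k t),
#' with the anchors I0(0) and I0_asymp fixed at their theoretical values.
#'
#' @slot k Turnover (degradation) rate constant, day^-1.
#' @slot i0Zero Monoisotopic RIA of the unlabeled peptide.
#' @slot i0Asymp Monoisotopic RIA at the labeling plateau.
#' @slot rSquared Coefficient of determination (may be negative).
#' @slot pearson Pearson correlation between observed and fitted RIAs.
#' @slot rse Residual standard error of the fit.
#' @slot ciLow,ciHigh 95% confidence bounds for k.
#' @slot method RIA-construction method label.
#' @slot nPoints Number of time points used.
#' @slot flagged TRUE for degenerate or boundary fits.
#' @slot flagReason Short description when flagged.
#' @export
setClass("TurnoverFit",
  representation(
    k = "numeric", i0Zero = "numeric", i0Asymp = "numeric",
    rSquared = "numeric", pearson = "numeric", rse = "numeric",
    ciLow = "numeric", ciHigh = "numeric", method = "character",
    nPoints = "integer", flagged = "logical", flagReason = "character"
  )
)

setValidity("TurnoverFit", function(object) {
  msg <- character()
  if (object@k < 0) msg <- c(msg, "k must be non-negative")
  if (!is.na(object@pearson) &&
      (object@pearson < -1 - 1e-9 || object@pearson > 1 + 1e-9))
    msg <- c(msg, "pearson must lie in [-1, 1]")
  if (!is.na(object@rSquared) && object@rSquared > 1 + 1e-9)
    msg <- c(msg, "rSquared cannot exceed 1")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      (object@ciLow > object@k + 1e-9 || object@ciHigh < object@k - 1e-9))
    msg <- c(msg, "confidence interval must bracket k")
  if (length(msg)) msg else TRUE
})

#' CompositeFit: unlabeled/labeled mixture fit of one isotope profile
#'
#' @slot theta Unlabeled proportion in [0, 1].
#' @slot ssd Minimized sum of squared differences over the six isotopomers;
#'   the spectral-accuracy score of the observed profile.
#' @slot flagged TRUE when the unlabeled and labeled reference spectra
#'   coincide and theta is undefined.
#' @export
setClass("CompositeFit",
  representation(theta = "numeric", ssd = "numeric", flagged = "logical")
)

setValidity("CompositeFit", function(object) {
  msg <- character()
  if (object@theta < 0 || object@theta > 1)
    msg <- c(msg, "theta must lie in [0, 1]")
  if (object@ssd < 0) msg <- c(msg, "ssd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ProteinRate: protein-level turnover rate
#'
#' @slot protein Protein identifier.
#' @slot kProt Median of the peptide rate constants, day^-1.
#' @slot ciLow,ciHigh 95% confidence bounds from the standard deviation of
#'   the peptide rates (NA for single-peptide proteins).
#' @slot nPeptides Number of accepted peptides.
#' @slot peptideRates The accepted per-peptide rate constants.
#' @export
setClass("ProteinRate",
  representation(
    protein = "character", kProt = "numeric", ciLow = "numeric",
    ciHigh = "numeric", nPeptides = "integer", peptideRates = "numeric"
  )
)

setValidity("ProteinRate", function(object) {
  msg <- character()
  if (object@nPeptides < 1) msg <- c(msg, "need at least one peptide")
  if (length(object@peptideRates) != object@nPeptides)
    msg <- c(msg, "peptideRates length must equal nPeptides")
  if (abs(object@kProt - stats::median(object@peptideRates)) > 1e-9)
    msg <- c(msg, "kProt must equal the median of peptideRates")
  if (length(msg)) msg else TRUE
})
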
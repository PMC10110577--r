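#' Accessor generics
#'
#' Small accessor family for the S4 result objects: `isoValues()` returns
#' the six isotopomer abundances, `isNormalized()` the RIA flag,
#' `rateConstant()` the turnover rate of a [TurnoverFit-class] or
#' [ProteinRate-class], `enrichment()` the estimated deuterium enrichment,
#' `fitMethod()` the RIA-construction label, `goodnessOfFit()` the GOF
#' statistics of a fit, `nExchangeable()` N_EH, and `elementCounts()` the
#' atom counts of a [PeptideComposition-class].
#'
#' @param x An object of the documented class.
#' @return The slot value; `goodnessOfFit()` returns a named numeric vector
#'   with elements `r_squared`, `pearson`, `rse`.
#' @name accessors
#' @aliases isoValues isNormalized rateConstant enrichment fitMethod
#'   goodnessOfFit nExchangeable elementCounts
NULL

#' @rdname accessors
#' @export
setGeneric("isoValues", function(x) standardGeneric("isoValues"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("rateConstant", function(x) standardGeneric("rateConstant"))

#' @rdname accessors
#' @export
setGeneric("enrichment", function(x) standardGeneric("enrichment"))

#' @rdname accessors
#' @export
setGeneric("fitMethod", function(x) standardGeneric("fitMethod"))

#' @rdname accessors
#' @export
setGeneric("goodnessOfFit", function(x) standardGeneric("goodnessOfFit"))

#' @rdname accessors
#' @export
setGeneric("nExchangeable", function(x) standardGeneric("nExchangeable"))

#' @rdname accessors
#' @export
setGeneric("elementCounts", function(x) standardGeneric("elementCounts"))

#' @rdname accessors
#' @export
setMethod("isoValues", "IsotopomerVector", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("isNormalized", "IsotopomerVector", function(x) x@normalized)

#' @rdname accessors
#' @export
setMethod("rateConstant", "TurnoverFit", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("rateConstant", "ProteinRate", function(x) x@kProt)

#' @rdname accessors
#' @export
setMethod("enrichment", "EnrichmentEstimate", function(x) x@pX)

#' @rdname accessors
#' @export
setMethod("fitMethod", "TurnoverFit", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("fitMethod", "EnrichmentEstimate", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("goodnessOfFit", "TurnoverFit", function(x) {
  c(r_squared = x@rSquared, pearson = x@pearson, rse = x@rse)
})

#' @rdname accessors
#' @export
setMethod("nExchangeable", "PeptideComposition", function(x) x@nExchangeable)

#' @rdname accessors
#' @export
setMethod("elementCounts", "PeptideComposition", function(x) x@elementCounts)

#' Confidence interval of a turnover rate
#'
#' @param object A [TurnoverFit-class] or [ProteinRate-class].
#' @param parm Ignored; present for generic consistency.
#' @param level Ignored; intervals are computed at 95% when fitting.
#' @param ... Ignored.
#' @return Numeric vector `c(low, high)`.
#' @export
setMethod("confint", "TurnoverFit", function(object, parm, level = 0.95, ...) {
  c(low = object@ciLow, high = object@ciHigh)
})

#' @rdname confint-TurnoverFit-method
#' @export
setMethod("confint", "ProteinRate", function(object, parm, level = 0.95, ...) {
  c(low = object@ciLow, high = object@ciHigh)
})

setMethod("show", "PeptideComposition", function(object) {
  ec <- object@elementCounts
  formula <- paste0(names(ec)[ec > 0], ec[ec > 0], collapse = " ")
  cat("PeptideComposition:", object@sequence,
      sprintf("(z=%d)\n", object@charge))
  cat("  elements:", formula, "\n")
  cat(sprintf("  N_EH: %.3g\n", object@nExchangeable))
  invisible(object)
})

setMethod("show", "IsotopomerVector", function(object) {
  cat(sprintf("IsotopomerVector (%s)\n",
              if (object@normalized) "normalized RIAs" else "raw abundances"))
  v <- object@values
  names(v) <- paste0("I", 0:5)
  print(signif(v, 6))
  invisible(object)
})

setMethod("show", "LabelingParameters", function(object) {
  cat(sprintf("LabelingParameters: pH=%.6g, pW=%.4g\n", object@pH, object@pW))
  cat("  time points (days):", paste(object@timePoints, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "EnrichmentEstimate", function(object) {
  cat(sprintf("EnrichmentEstimate [%s]: pX = %.6g (residual %.3g)%s%s\n",
              object@method, object@pX, object@objectiveResidual,
              if (object@atBoundary) ", at boundary" else "",
              if (!object@valid) ", INVALID" else ""))
  invisible(object)
})

setMethod("show", "TurnoverFit", function(object) {
  cat(sprintf("TurnoverFit [%s]: k = %.5g /day (95%% CI %.4g-%.4g)\n",
              object@method, object@k, object@ciLow, object@ciHigh))
  cat(sprintf("  R2 = %.4g, r = %.4g, RSE = %.3g, n = %d%s\n",
              object@rSquared, object@pearson, object@rse, object@nPoints,
              if (object@flagged) paste0(" [", object@flagReason, "]") else ""))
  invisible(object)
})

setMethod("show", "CompositeFit", function(object) {
  cat(sprintf("CompositeFit: theta = %.5g, SSD = %.4g%s\n",
              object@theta, object@ssd,
              if (object@flagged) " [degenerate]" else ""))
  invisible(object)
})

setMethod("show", "ProteinRate", function(object) {
  cat(sprintf("ProteinRate %s: k = %.4g /day (95%% CI %.4g-%.4g), %d peptides\n",
              object@protein, object@kProt, object@ciLow, object@ciHigh,
              object@nPeptides))
  invisible(object)
})
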
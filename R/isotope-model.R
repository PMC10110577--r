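# Polynomial (distribution) convolution without FFT round-off surprises.
# Lengths here are small (a few hundred terms at most), so the direct
# O(n*m) product is both exact to machine precision and fast enough.
.convolveDist <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# n-fold self-convolution by binary exponentiation, dropping a negligible
# tail to keep lengths bounded for large atom counts.
.convolvePower <- function(p, n, tailTol = 1e-16) {
  out <- 1
  while (n > 0) {
    if (n %% 2 == 1) out <- .trimTail(.convolveDist(out, p), tailTol)
    n <- n %/% 2
    if (n > 0) p <- .trimTail(.convolveDist(p, p), tailTol)
  }
  out
}

.trimTail <- function(p, tol) {
  keep <- max(which(p > tol * max(p)), 1L)
  p[seq_len(keep)]
}

# Shift-indexed probability vector for one element (index 1 = shift 0).
.elementDist <- function(element, elementTable) {
  rows <- elementTable[elementTable$element == element, ]
  if (nrow(rows) == 0) stop("no isotope data for element ", element)
  d <- numeric(max(rows$shift) + 1L)
  d[rows$shift + 1L] <- rows$abundance
  d / sum(d)
}

# Full aggregated isotopomer distribution for a set of element counts.
.fullIsotopeDist <- function(counts, elementTable) {
  counts <- counts[counts > 0]
  dist <- 1
  for (el in names(counts))
    dist <- .convolveDist(dist,
                          .convolvePower(.elementDist(el, elementTable),
                                         counts[[el]]))
  dist / sum(dist)
}

#' Natural isotope distribution of a peptide
#'
#' Computes the aggregated mass-isotopomer distribution of a peptide at
#' natural isotope abundances by per-element multinomial expansion and
#' cross-element convolution, normalizes the full distribution to 1, and
#' truncates to the first `nPeaks` isotopomers. Fine structure within a
#' nominal mass shift is summed; charge does not change the pattern.
#'
#' @param composition A [PeptideComposition-class].
#' @param nPeaks Number of leading isotopomers to return (default 6).
#' @param elementTable Element isotope table, see [defaultElementTable()].
#' @return An [IsotopomerVector-class] of normalized RIAs (padded with
#'   zeros when the distribution has fewer than `nPeaks` terms).
#' @export
naturalIsotopeDistribution <- function(composition, nPeaks = 6,
                                       elementTable = defaultElementTable()) {
  stopifnot(is(composition, "PeptideComposition"))
  dist <- .fullIsotopeDist(composition@elementCounts, elementTable)
  isotopomerVector(.padTo(dist, nPeaks), normalized = TRUE)
}

.padTo <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
}

#' Labeling coefficient b_n
#'
#' The coefficient b_n = C(N_EH, n) ((pX + pH) / (1 - pH - pX))^n that
#' propagates the monoisotopic RIA into heavier isotopomers during
#' labeling. The binomial coefficient is generalized to non-integer N_EH
#' through the gamma function.
#'
#' @param n Isotopomer order, n >= 1.
#' @param nEH Number of exchangeable hydrogens, > 0 (may be non-integer).
#' @param pX Deuterium enrichment of the peptide.
#' @param pH Natural deuterium abundance.
#' @return The coefficient value.
#' @export
bCoefficient <- function(n, nEH, pX, pH) {
  stopifnot(n >= 1, nEH > 0, pX >= 0, pH >= 0)
  if (pH + pX >= 1) stop("require pH + pX < 1")
  choose(nEH, n) * ((pX + pH) / (1 - pH - pX))^n
}

#' Deconvolution coefficient c_n
#'
#' The coefficient c_n = C(N_EH + n - 1, n) (pH / (1 - pH))^n that strips
#' the natural-abundance contribution of the exchangeable hydrogens from
#' the unlabeled profile (the inverse series of the b_n(0) expansion).
#'
#' @inheritParams bCoefficient
#' @return The coefficient value.
#' @export
cCoefficient <- function(n, nEH, pH) {
  stopifnot(n >= 1, nEH > 0, pH >= 0)
  if (pH >= 1) stop("require pH < 1")
  choose(nEH + n - 1, n) * (pH / (1 - pH))^n
}

#' Analytic mass-isotopomer dynamics under deuterium labeling
#'
#' Evaluates the six labeled relative isotope abundances I_0(t)..I_5(t)
#' from the natural (t = 0) RIAs, the number of exchangeable hydrogens,
#' and the enrichment pX. The monoisotope follows
#' I_0(t) = I_0(0) (1 - pX/(1 - pH))^N_EH; the heavy isotopomers follow
#' the closed-form dynamics built from the b_n and c_n coefficients,
#' evaluated in index order: the natural profile is first deconvolved
#' from the exchangeable-hydrogen binomial at natural abundance
#' (alternating c_n series) and then reconvolved at the labeled
#' probability pH + pX (b_n series). This is algebraically identical to
#' the nested per-isotopomer expressions and remains valid for
#' non-integer N_EH.
#'
#' @param natural Natural RIAs at t = 0 ([IsotopomerVector-class] or
#'   numeric of length 6).
#' @param pX Deuterium enrichment in `[0, 1 - pH)`.
#' @param nEH Number of exchangeable hydrogens (> 0, may be non-integer).
#' @param pH Natural deuterium abundance.
#' @return An [IsotopomerVector-class] of the six labeled RIAs.
#' @export
labeledIsotopomerRias <- function(natural, pX, nEH, pH = 0.000115) {
  nat <- .isoNum(natural)
  if (pX < 0) stop("pX must be non-negative")
  if (pH + pX >= 1 || pX / (1 - pH) >= 1)
    stop("pX out of physical range (pH + pX must be < 1)")
  stopifnot(nEH > 0, nat[1] > 0)
  u0 <- pH / (1 - pH)
  u <- (pH + pX) / (1 - pH - pX)
  m <- 0:5
  b <- choose(nEH, m) * u^m
  cc <- choose(nEH + m - 1, m) * u0^m
  ratios0 <- nat / nat[1]
  # exchangeable-H-free residual profile, relative to its monoisotope
  r <- vapply(0:5, function(n) {
    k <- 0:n
    sum((-1)^k * cc[k + 1] * ratios0[n - k + 1])
  }, numeric(1))
  i0t <- nat[1] * (1 - pX / (1 - pH))^nEH
  out <- vapply(0:5, function(n) {
    k <- 0:n
    i0t * sum(b[k + 1] * r[n - k + 1])
  }, numeric(1))
  isotopomerVector(pmax(out, 0), normalized = TRUE)
}

#' First-principles labeled-distribution oracle
#'
#' Independent check of [labeledIsotopomerRias()]: builds the labeled
#' isotope distribution directly, by giving N_EH hydrogens the heavy
#' probability pH + pX while every other atom keeps its natural
#' abundances, then convolving across elements and truncating. Defined
#' only for integer N_EH, where the construction is exact.
#'
#' @param composition A [PeptideComposition-class] whose `nExchangeable`
#'   is a (near-)integer.
#' @param pX Deuterium enrichment.
#' @param pH Natural deuterium abundance.
#' @param nPeaks Number of leading isotopomers to return.
#' @param elementTable Element isotope table.
#' @return An [IsotopomerVector-class] of normalized labeled RIAs.
#' @export
oracleLabeledDistribution <- function(composition, pX, pH = 0.000115,
                                      nPeaks = 6,
                                      elementTable = defaultElementTable()) {
  stopifnot(is(composition, "PeptideComposition"), pX >= 0, pH + pX < 1)
  nEH <- composition@nExchangeable
  if (abs(nEH - round(nEH)) > 1e-9)
    stop("the convolution oracle is defined only for integer N_EH (got ",
         nEH, ")")
  nEH <- as.integer(round(nEH))
  counts <- composition@elementCounts
  if (counts[["H"]] < nEH) stop("N_EH exceeds the hydrogen count")
  counts[["H"]] <- counts[["H"]] - nEH
  rest <- .fullIsotopeDist(counts, elementTable)
  if (nEH > 0) {
    labeledH <- .convolvePower(c(1 - pH - pX, pH + pX), nEH)
    rest <- .convolveDist(rest, labeledH)
  }
  isotopomerVector(.padTo(rest / sum(rest), nPeaks), normalized = TRUE)
}
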
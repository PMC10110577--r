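# Residue elemental formulas (residue = amino acid minus water). Standard
# textbook values; a free peptide adds one H2O on top of the residue sum.
.residueFormulaTable <- function() {
  m <- rbind(
    G = c(2, 3, 1, 1, 0),
    A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),
    T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
}

#' Residue elemental formulas
#'
#' Elemental composition (C, H, N, O, S) of the 20 canonical amino-acid
#' residues, i.e. the amino acid minus one water.
#'
#' @return A matrix with one row per one-letter residue code.
#' @export
residueFormulas <- function() .residueFormulaTable()

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "TurnoverMI")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

#' Exchangeable-hydrogen table
#'
#' Per-residue numbers of hydrogens accessible to deuterium from body
#' water (N_EH). The shipped values are the Commerford-derived empirical
#' table used by the d2ome lineage of turnover tools; they are
#' configuration, not constants of nature, and can be replaced by any
#' two-column CSV (`residue`, `neh`).
#'
#' @param path Optional path to an alternative CSV.
#' @return Named numeric vector of N_EH values keyed by residue code.
#' @export
defaultNehTable <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("exchangeable_hydrogens.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "neh") %in% names(tab)))
    stop("NEH table must have columns 'residue' and 'neh'")
  stats::setNames(as.numeric(tab$neh), tab$residue)
}

#' Element isotope table
#'
#' Natural isotope abundances and masses per element, aggregated by
#' nominal mass shift. Shipped values follow the standard IUPAC reference
#' abundances; the table is an editable CSV with columns `element`,
#' `shift`, `mass`, `abundance`.
#'
#' @param path Optional path to an alternative CSV.
#' @return Data frame with columns element, shift, mass, abundance.
#' @export
defaultElementTable <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("element_isotopes.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "shift", "mass", "abundance")
  if (!all(need %in% names(tab)))
    stop("element table must have columns ", paste(need, collapse = ", "))
  tab
}

#' Build a PeptideComposition from an amino-acid sequence
#'
#' Sums the residue elemental formulas, adds one water for the free
#' peptide, and sums the per-residue exchangeable-hydrogen values to
#' obtain N_EH. Only the 20 canonical residues are supported.
#'
#' @param sequence Amino-acid sequence (one-letter codes).
#' @param charge Charge state (affects m/z only, never abundances).
#' @param nehTable Named numeric vector of per-residue N_EH values,
#'   see [defaultNehTable()].
#' @param residueTable Residue formula matrix, see [residueFormulas()].
#' @return A [PeptideComposition-class] object.
#' @examples
#' peptideComposition("GG")
#' @export
peptideComposition <- function(sequence, charge = 2L,
                               nehTable = defaultNehTable(),
                               residueTable = residueFormulas()) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  residues <- strsplit(sequence, "")[[1]]
  bad <- which(!(residues %in% rownames(residueTable)))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d in '%s'",
                 residues[bad[1]], bad[1], sequence))
  missingNeh <- setdiff(residues, names(nehTable))
  if (length(missingNeh))
    stop("NEH table has no entry for residue(s): ",
         paste(unique(missingNeh), collapse = ", "))
  counts <- colSums(residueTable[residues, , drop = FALSE])
  counts["H"] <- counts["H"] + 2  # terminal H2O
  counts["O"] <- counts["O"] + 1
  new("PeptideComposition",
      sequence = sequence, charge = as.integer(charge),
      elementCounts = counts,
      nExchangeable = sum(nehTable[residues]))
}

#' Monoisotopic mass of a peptide composition
#'
#' @param composition A [PeptideComposition-class].
#' @param elementTable Element isotope table, see [defaultElementTable()].
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopicMass <- function(composition, elementTable = defaultElementTable()) {
  stopifnot(is(composition, "PeptideComposition"))
  mono <- elementTable[elementTable$shift == 0, ]
  masses <- stats::setNames(mono$mass, mono$element)
  ec <- composition@elementCounts
  ec <- ec[ec > 0]
  if (!all(names(ec) %in% names(masses)))
    stop("element table lacks masses for: ",
         paste(setdiff(names(ec), names(masses)), collapse = ", "))
  sum(masses[names(ec)] * ec)
}

#' Construct an IsotopomerVector
#'
#' @param values Six non-negative abundances, monoisotope first.
#' @param normalized TRUE when the values are relative isotope abundances.
#' @return An [IsotopomerVector-class].
#' @export
isotopomerVector <- function(values, normalized = FALSE) {
  new("IsotopomerVector", values = as.numeric(values),
      normalized = isTRUE(normalized))
}

#' Construct LabelingParameters
#'
#' @param pH Natural deuterium abundance; default 0.000115.
#' @param pW Body-water deuterium enrichment; default 0.046 (a typical
#'   plateau reached with 5% heavy drinking water).
#' @param timePoints Labeling durations in days.
#' @return A [LabelingParameters-class].
#' @export
labelingParameters <- function(pH = 0.000115, pW = 0.046,
                               timePoints = c(0, 1, 3, 7, 14, 21)) {
  new("LabelingParameters", pH = pH, pW = pW,
      timePoints = as.numeric(timePoints))
}

# Coerce an IsotopomerVector or bare numeric(6) to numeric values.
.isoNum <- function(x) {
  if (is(x, "IsotopomerVector")) return(x@values)
  stopifnot(is.numeric(x), length(x) == 6)
  as.numeric(x)
}
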
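#' Aggregate peptide turnover rates to a protein rate
#'
#' The protein rate is the median of the accepted peptide rate
#' constants. The confidence interval is a 95% t-interval built from the
#' standard deviation of the peptide rates; single-peptide proteins get
#' NA bounds.
#'
#' @param peptideRates Numeric vector of accepted peptide k values
#'   (day^-1), one per peptide.
#' @param protein Protein identifier.
#' @return A [ProteinRate-class].
#' @export
aggregateProtein <- function(peptideRates, protein = NA_character_) {
  peptideRates <- peptideRates[is.finite(peptideRates)]
  n <- length(peptideRates)
  if (n < 1) stop("no accepted peptide rates for protein ", protein)
  kProt <- stats::median(peptideRates)
  if (n >= 2) {
    half <- stats::qt(0.975, n - 1) * stats::sd(peptideRates) / sqrt(n)
    ci <- c(kProt - half, kProt + half)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  new("ProteinRate", protein = as.character(protein), kProt = kProt,
      ciLow = ci[1], ciHigh = ci[2], nPeptides = as.integer(n),
      peptideRates = peptideRates)
}

#' Aggregate a table of peptide fits to protein rates
#'
#' Takes the filtered peptide fit table (one selected fit per peptide),
#' drops peptides shared between proteins (razor handling is out of
#' scope), enforces a minimum peptide count, and aggregates each protein
#' with [aggregateProtein()].
#'
#' @param fits Data frame with columns protein, peptide, k and logical
#'   `passed` (from [applyFilters()]); only passing rows are used.
#' @param minPeptides Minimum accepted peptides per protein (default 1;
#'   dataset-level accuracy analyses typically use 6, cross-study
#'   comparisons 3).
#' @param excludeShared Drop peptide sequences mapping to more than one
#'   protein (default TRUE).
#' @return Data frame with columns protein, k_prot, ci_low, ci_high,
#'   n_peptides.
#' @export
aggregateProteins <- function(fits, minPeptides = 1L,
                              excludeShared = TRUE) {
  stopifnot(all(c("protein", "peptide", "k") %in% names(fits)))
  if ("passed" %in% names(fits)) fits <- fits[fits$passed, ]
  if (nrow(fits) == 0)
    return(data.frame(protein = character(), k_prot = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      n_peptides = integer()))
  if (excludeShared) {
    map <- unique(fits[, c("protein", "peptide")])
    shared <- names(which(table(map$peptide) > 1))
    if (length(shared)) {
      message(length(shared), " shared peptide(s) excluded from rollup")
      fits <- fits[!(fits$peptide %in% shared), ]
    }
  }
  out <- lapply(split(fits, fits$protein), function(g) {
    if (length(g$k) < minPeptides) return(NULL)
    pr <- aggregateProtein(g$k, g$protein[1])
    data.frame(protein = pr@protein, k_prot = pr@kProt,
               ci_low = pr@ciLow, ci_high = pr@ciHigh,
               n_peptides = pr@nPeptides, stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(protein = character(), k_prot = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      n_peptides = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Normalized peptide-versus-protein rate difference
#'
#' The accuracy metric (k_pep - k_prot) / sqrt(k_pep^2 + k_prot^2),
#' bounded in (-1, 1) and zero exactly when the rates agree.
#'
#' @param kPep Peptide rate constant(s).
#' @param kProt Protein rate constant(s).
#' @return The normalized difference (vectorized).
#' @export
peptideProteinMetric <- function(kPep, kProt) {
  denom <- sqrt(kPep^2 + kProt^2)
  if (any(denom == 0))
    stop("metric undefined when both rates are zero")
  (kPep - kProt) / denom
}
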
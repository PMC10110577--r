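# Shared fixtures and independent oracles for the test suite.

# Build a bare composition without going through a sequence.
makeComposition <- function(counts, neh, sequence = "FIXTURE",
                            charge = 2L) {
  new("PeptideComposition", sequence = sequence, charge = charge,
      elementCounts = counts, nExchangeable = neh)
}

# Independent isotope-pattern oracle: walks the molecule atom by atom,
# accumulating the probability of every total nominal shift. No binomial
# shortcuts, no power-by-squaring, no tail trimming.
atomwiseDistribution <- function(counts, elementProbs) {
  dist <- 1
  for (el in names(counts)) {
    p <- elementProbs[[el]]
    n <- counts[[el]]
    if (is.null(p)) stop("no probabilities for ", el)
    for (a in seq_len(n)) {
      new <- numeric(length(dist) + length(p) - 1L)
      for (i in seq_along(dist))
        for (j in seq_along(p))
          new[i + j - 1L] <- new[i + j - 1L] + dist[i] * p[j]
      dist <- new
    }
  }
  dist / sum(dist)
}

naturalElementProbs <- function() {
  tab <- defaultElementTable()
  out <- list()
  for (el in unique(tab$element)) {
    rows <- tab[tab$element == el, ]
    p <- numeric(max(rows$shift) + 1L)
    p[rows$shift + 1L] <- rows$abundance
    out[[el]] <- p / sum(p)
  }
  out
}

# Atom-wise labeled oracle: nEH hydrogens at probability pH + pX.
atomwiseLabeled <- function(counts, neh, px, ph = 0.000115) {
  probs <- naturalElementProbs()
  counts[["H"]] <- counts[["H"]] - neh
  counts <- counts[counts > 0]
  dist <- atomwiseDistribution(counts, probs)
  if (neh > 0) {
    hprob <- c(1 - ph - px, ph + px)
    for (a in seq_len(neh)) {
      new <- numeric(length(dist) + 1L)
      for (i in seq_along(dist)) {
        new[i] <- new[i] + dist[i] * hprob[1]
        new[i + 1L] <- new[i + 1L] + dist[i] * hprob[2]
      }
      dist <- new
    }
  }
  dist / sum(dist)
}

pad6 <- function(x) if (length(x) >= 6) x[1:6] else c(x, numeric(6 - length(x)))

# Small fixture panel with integer N_EH for oracle comparisons.
oracleFixtures <- function() {
  list(
    makeComposition(c(C = 4, H = 8, N = 2, O = 3, S = 0), 4, "GG"),
    makeComposition(c(C = 10, H = 18, N = 3, O = 5, S = 0), 6),
    makeComposition(c(C = 20, H = 34, N = 5, O = 8, S = 1), 12),
    makeComposition(c(C = 40, H = 66, N = 10, O = 14, S = 0), 20),
    makeComposition(c(C = 53, H = 86, N = 12, O = 17, S = 0), 17)
  )
}

# Forward-simulate a noiseless labeled profile (analytic path).
forwardProfile <- function(comp, px, ph = 0.000115) {
  nat <- isoValues(naturalIsotopeDistribution(comp))
  isoValues(labeledIsotopomerRias(nat, px, comp@nExchangeable, ph))
}
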
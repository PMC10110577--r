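# Default simulated peptide panel: tryptic-like sequences spanning the
# rate range observable in a 1-21 day labeling design.
.defaultPeptidePanel <- function() {
  data.frame(
    protein = c("PROT1", "PROT1", "PROT2", "PROT2", "PROT3", "PROT3",
                "PROT4", "PROT4"),
    sequence = c("LVNELTEFAK", "HLVDEPQNLIK", "YLYEIAR", "AGLQFPVGR",
                 "AEFVEVTK", "DLGEEHFK", "TVMENFVAFVDK", "GITWGEETLMEYLENPK"),
    charge = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
    k = c(0.30, 0.20, 0.40, 0.135, 0.25, 0.35, 0.05, 0.10),
    base = rep(1e6, 8),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles everything the synthetic-data generator needs: the peptide
#' panel with true rate constants, the labeling design, the noise model,
#' and optional channel-specific contamination. Identical configurations
#' (including `seed`) produce identical output.
#'
#' @param peptides Data frame with columns protein, sequence, charge, k
#'   (true turnover rate, day^-1), base (abundance scale). Defaults to an
#'   8-peptide panel with rates spanning 0.05-0.4 day^-1.
#' @param params A [LabelingParameters-class]; its time points are the
#'   sampled labeling durations.
#' @param noiseCv Multiplicative coefficient of variation of the
#'   channel-wise abundance noise (default 0.03, typical LC-MS abundance
#'   fluctuation).
#' @param noiseModel "lognormal" (mean-one multiplicative, default) or
#'   "additive" (Gaussian with sd = noiseCv * value).
#' @param contamination NULL, or a data frame with columns `channel`
#'   (0..5), `amplitude` (additive abundance as a fraction of the
#'   peptide's base abundance), and optionally `peptide` and a
#'   comma-free list-column `times` restricting which peptides/time
#'   points are affected (defaults: all).
#' @param seed Integer RNG seed (NULL leaves the RNG state alone).
#' @return A validated list of class "SimulationConfig".
#' @export
simulationConfig <- function(peptides = NULL,
                             params = labelingParameters(),
                             noiseCv = 0.03,
                             noiseModel = c("lognormal", "additive"),
                             contamination = NULL, seed = NULL) {
  if (is.null(peptides)) peptides <- .defaultPeptidePanel()
  need <- c("protein", "sequence", "charge", "k", "base")
  stopifnot(all(need %in% names(peptides)))
  if (any(peptides$k < 0)) stop("true rates must be non-negative")
  if (any(peptides$base <= 0)) stop("base abundances must be positive")
  noiseModel <- match.arg(noiseModel)
  stopifnot(noiseCv >= 0)
  if (!is.null(contamination)) {
    stopifnot(all(c("channel", "amplitude") %in% names(contamination)),
              all(contamination$channel %in% 0:5),
              all(contamination$amplitude >= 0))
  }
  structure(list(peptides = peptides, params = params, noiseCv = noiseCv,
                 noiseModel = noiseModel, contamination = contamination,
                 seed = seed),
            class = "SimulationConfig")
}

.contaminationFor <- function(cfg, sequence, time) {
  cont <- cfg$contamination
  add <- numeric(6)
  if (is.null(cont)) return(add)
  for (i in seq_len(nrow(cont))) {
    if (!is.null(cont$peptide) && !is.na(cont$peptide[i]) &&
        cont$peptide[i] != sequence) next
    if (!is.null(cont$times) && !is.null(cont$times[[i]]) &&
        !any(is.na(cont$times[[i]])) && !(time %in% cont$times[[i]])) next
    add[cont$channel[i] + 1L] <- add[cont$channel[i] + 1L] +
      cont$amplitude[i]
  }
  add
}

#' Simulate isotopomer-abundance time courses with known ground truth
#'
#' Forward model per peptide and time point: the monoisotopic RIA
#' follows the one-compartment exponential decay between its natural
#' value and the labeling plateau; the implied enrichment
#' pX(t) = (1 - pH)(1 - (I_0(t)/I_0(0))^(1/N_EH)) then generates the
#' full six-isotopomer RIA vector via the analytic dynamics; RIAs are
#' scaled by the base abundance, multiplied by mean-one lognormal noise
#' (or additive Gaussian), and contamination is added on the configured
#' channels. Body-water enrichment is assumed at plateau from t = 0
#' (instantaneous one-compartment precursor).
#'
#' @param cfg A [simulationConfig()] object.
#' @param nehTable Per-residue exchangeable-hydrogen table.
#' @return List with `quant` (protein, peptide, charge, time,
#'   experiment, A0..A5) and `truth` (peptide, time, k, nEH, p_x, i0)
#'   data frames.
#' @export
simulateTimeCourse <- function(cfg, nehTable = defaultNehTable()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  params <- cfg$params
  pH <- params@pH; pW <- params@pW
  times <- params@timePoints
  sdlog <- if (cfg$noiseCv > 0) sqrt(log(1 + cfg$noiseCv^2)) else 0
  quant <- list(); truth <- list()
  for (i in seq_len(nrow(cfg$peptides))) {
    pep <- cfg$peptides[i, ]
    comp <- peptideComposition(pep$sequence, pep$charge, nehTable)
    nEH <- comp@nExchangeable
    nat <- isoValues(naturalIsotopeDistribution(comp))
    i0z <- nat[1]
    i0a <- asymptoticRia(i0z, nEH, pW, pH)
    for (t in times) {
      i0t <- i0a + (i0z - i0a) * exp(-pep$k * t)
      pX <- (1 - pH) * (1 - (i0t / i0z)^(1 / nEH))
      if (pX > pW + 1e-12)
        stop("impossible configuration: implied pX exceeds pW")
      ria <- isoValues(labeledIsotopomerRias(nat, pX, nEH, pH))
      a <- pep$base * ria
      if (sdlog > 0) {
        if (cfg$noiseModel == "lognormal") {
          a <- a * exp(stats::rnorm(6, mean = -sdlog^2 / 2, sd = sdlog))
        } else {
          a <- a + stats::rnorm(6, sd = cfg$noiseCv * a)
        }
      }
      a <- a + pep$base * .contaminationFor(cfg, pep$sequence, t)
      a <- pmax(a, 0)
      quant[[length(quant) + 1L]] <- data.frame(
        protein = pep$protein, peptide = pep$sequence,
        charge = pep$charge, time = t, experiment = "sim",
        A0 = a[1], A1 = a[2], A2 = a[3], A3 = a[4], A4 = a[5], A5 = a[6],
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        peptide = pep$sequence, time = t, k = pep$k, nEH = nEH,
        p_x = pX, i0 = i0t, stringsAsFactors = FALSE)
    }
  }
  list(quant = do.call(rbind, quant), truth = do.call(rbind, truth))
}

#' Simulate composite unlabeled/labeled spectra
#'
#' Draws mixing proportions theta (always including the endpoints 0 and
#' 1), forms the composite spectra, and optionally perturbs them with
#' additive Gaussian noise, emitting the ground truth alongside.
#'
#' @param n Number of spectra (>= 2).
#' @param sUnlabeled,sLabeled Reference spectra.
#' @param noiseSd Additive Gaussian perturbation per channel (default 0).
#' @param seed Optional RNG seed.
#' @return List with `theta` (length n) and `spectra` (n x 6 matrix).
#' @export
simulateCompositePopulation <- function(n, sUnlabeled, sLabeled,
                                        noiseSd = 0, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  u <- .isoNum(sUnlabeled); l <- .isoNum(sLabeled)
  theta <- c(0, 1, stats::runif(n - 2))
  spectra <- t(vapply(theta, function(th) {
    s <- th * u + (1 - th) * l
    if (noiseSd > 0) s <- pmax(s + stats::rnorm(6, sd = noiseSd), 0)
    s
  }, numeric(6)))
  list(theta = theta, spectra = spectra)
}
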
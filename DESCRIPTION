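Package: TurnoverMI
Title: Protein Turnover Rates from Partial Mass Isotopomer Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates in vivo protein turnover rates from heavy-water
    (2H2O) metabolic labeling LC-MS data. Models the analytic dynamics of
    the first six peptide mass isotopomers as a function of deuterium
    enrichment, estimates label enrichment from any pair of mass
    isotopomers (or the complete isotope profile), reconstructs the
    monoisotopic relative isotope abundance, fits a one-parameter
    exponential decay to obtain the degradation rate constant with
    goodness-of-fit statistics and confidence intervals, scores spectral
    accuracy against composite unlabeled/labeled spectra, and aggregates
    peptide rates to protein-level turnover. Includes a synthetic-data
    generator with known ground truth, noise, and channel-specific
    contamination for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
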
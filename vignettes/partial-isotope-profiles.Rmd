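---
title: "Turnover rates from partial mass isotopomer profiles"
author: "TurnoverMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turnover rates from partial mass isotopomer profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TurnoverMI)
```

## The measurement problem

In a heavy-water labeling experiment an animal drinks deuterated water;
deuterium from body water exchanges into free amino acids and is fixed
into newly synthesised proteins. In LC-MS, a peptide's isotope profile
gradually shifts toward heavier mass isotopomers as old (unlabeled)
protein is replaced by new (labeled) protein. The relative isotope
abundance of the monoisotope, $I_0(t)$, therefore depletes from its
natural value $I_0(0)$ toward a plateau $I_0^{asymp}$, and the
depletion rate is the protein turnover (degradation) rate constant:

$$I_0(t) = I_0^{asymp} + \left(I_0(0) - I_0^{asymp}\right) e^{-kt}.$$

Traditionally $I_0(t)$ is measured as the normalized monoisotopic
abundance of the complete isotope profile. Mammalian proteome digests
are crowded; co-eluting species frequently corrupt one or two channels
of a profile, and a single corrupted channel spoils the normalization
and hence the whole time course. The central idea implemented here is
that the deuterium enrichment of a peptide, $p_X(t)$, is identifiable
from *any single pair* of mass isotopomer abundances, because the raw
abundance ratio equals the RIA ratio
($A_i/A_j = I_i/I_j$ — the normalization constant cancels). An
uncorrupted pair then reconstructs the monoisotopic RIA,

$$\widetilde{I_0(t)} = I_0(0)\left(1 - \frac{p_X(t)}{1-p_H}\right)^{N_{EH}},$$

and the exponential fit proceeds as usual, bypassing the contaminated
channels entirely.

## The isotopomer dynamics

A peptide has $N_{EH}$ hydrogens accessible to deuterium from body
water (a *non-integer* empirical sum of per-residue values; the shipped
table is the Commerford-derived set used by the d2ome tool lineage, and
it is configuration, not a constant of nature). At labeling time $t$
these sites carry deuterium with probability $p_H + p_X(t)$, where
$p_H = 1.15\times10^{-4}$ is the natural deuterium abundance. All other
atoms retain natural isotope abundances.

`labeledIsotopomerRias()` evaluates the six labeled RIAs analytically.
Internally it uses the compact deconvolution/reconvolution identity:
strip the exchangeable-hydrogen binomial at natural abundance from the
observed natural profile (the alternating series with coefficients
$c_n = \binom{N_{EH}+n-1}{n}\left(\frac{p_H}{1-p_H}\right)^n$), then
reconvolve at the labeled probability (the series with
$b_n = \binom{N_{EH}}{n}\left(\frac{p_X+p_H}{1-p_H-p_X}\right)^n$).
This is algebraically identical to the published nested per-isotopomer
expressions — expanding the recursion for $I_1$ and $I_2$ reproduces
them term by term, including the $(N_{EH}+1)/(N_{EH}-1)$ factor of the
closed-form $A_2/A_1$ ratio (`closedFormRatioA2A1()` is kept as an
explicit cross-check path) — and it extends naturally to $I_3..I_5$ and
to non-integer $N_{EH}$ via gamma-function binomial coefficients.

Because algebra on extracted equations is easy to get wrong, the
package carries an independent first-principles oracle,
`oracleLabeledDistribution()`: place $N_{EH}$ hydrogens at probability
$p_H + p_X$, convolve everything else at natural abundance, truncate.
The test suite (and the acceptance script) verify agreement below
$10^{-9}$ over a composition grid; in practice agreement is at machine
precision. The oracle is restricted to integer $N_{EH}$, where the
construction is exact.

```{r oracle}
comp <- peptideComposition("GG", nehTable = c(G = 2))
nat <- naturalIsotopeDistribution(comp)
analytic <- labeledIsotopomerRias(nat, pX = 0.03, nEH = 4)
oracle <- oracleLabeledDistribution(comp, pX = 0.03)
max(abs(isoValues(analytic) - isoValues(oracle)))
```

## Estimating enrichment

`estimateEnrichmentFromPair()` solves
$\arg\min_{p_X \in [0, p_W]} |I_i(p_X)/I_j(p_X) - A_i/A_j|$ with a
50-point pre-scan followed by Brent refinement (absolute tolerance
$10^{-9}$). The pre-scan guards against non-monotone objectives: for
peptide-like elemental compositions the three default ratios
($A_1/A_0$, $A_2/A_0$, $A_2/A_1$, the most abundant channels) are
strictly monotone on $[0, p_W]$, but for carbon-poor compositions the
$A_2/A_1$ ratio can dip below its natural value at very small
enrichment, making the inversion two-valued there — a property of the
physics, not of the solver, and one reason the package's fixtures are
real peptide sequences. Experimental ratios outside the achievable
range clip to the nearest bound and carry a flag; downstream fitting
may drop flagged points (`dropFlagged`).

`estimateEnrichmentFullProfile()` implements the traditional route,
$I_0(t) = A_0/\sum_k A_k$ followed by the exact inversion
$p_X = (1-p_H)\,(1 - (I_0(t)/I_0(0))^{1/N_{EH}})$. One numerical
subtlety: with only six channels recorded, $\sum_k A_k$ underestimates
the full profile, so $A_0/\sum A_k$ overstates the true RIA — by enough
to bias $p_X$ by $\sim 3\times10^{-4}$ for heavy peptides at
$N_{EH} \approx 40$. A short fixed-point iteration rescales the
observation by the model's own six-peak coverage at the current
estimate, after which noiseless profiles invert to machine precision.
Six-peak coverage itself stays above 99% for peptides below ~1800 Da at
the default plateau enrichment of 4.6%.

## Fitting and filtering

`fitExponentialDecay()` fits the single free parameter $k$ with both
anchors fixed at their theoretical values ($I_0(0)$ from the natural
distribution, $I_0^{asymp}$ from the plateau formula at $p_X = p_W$);
`freeAsymptote = TRUE` releases the plateau for sensitivity analysis.
The 1-D bounded search ($k \in [0, 10]\ \mathrm{day}^{-1}$) is polished
by Gauss-Newton steps so noiseless series recover $k$ to machine
precision. Reported per fit: $R^2$, the Pearson correlation between
observed and fitted series, the residual standard error, and a 95%
asymptotic t-interval $k \pm t_{0.975,\,n-1}\,SE(k)$ with $SE$ from the
linearized Jacobian — the standard construction for a one-parameter
nonlinear least-squares problem.

`fitAllMethods()` builds all four candidate RIA series (complete
profile plus the three pairs), fits each, and selects the best by
highest $R^2$; exact ties prefer the complete profile, then $A_1/A_0$,
$A_2/A_0$, $A_2/A_1$. Selection is per fitted time course; per-point
selection is intentionally not offered, because mixing reconstruction
methods within one series changes the error structure mid-course.

`applyFilters()` encodes the acceptance rules: at least four labeling
durations; $R^2 \geq 0.8$ (bands at 0.8/0.9/0.95, right-inclusive, so
$R^2 = 0.95$ lands in "$\geq 0.95$"); and, for very slow turnover
($k < 0.01\ \mathrm{day}^{-1}$, where the dynamic range of the decay is
too small for $R^2$ to mean anything), an alternative residual
standard error criterion RSE $\leq 0.05$. A validation rate window
(e.g. $0.05 \le k \le 0.6\ \mathrm{day}^{-1}$ for a 1-21 day design) is
available via `kRange`. Negative $R^2$ values (worse than the mean
model) are stored as-is and land in the "<0.8" band.

## Spectral accuracy

At any time the observed profile is modeled as a composite
$S(\theta) = \theta\,S_{unlabeled} + (1-\theta)\,S_{labeled}$ with
$\theta \in [0, 1]$, $S_{labeled}$ computed at the plateau enrichment
by default. Both references and the observation are normalized over the
same six channels. Since the SSD objective is quadratic in $\theta$,
`fitTheta()` projects onto the segment in closed form and clips; the
minimized SSD is the spectral-accuracy score, and `ln(SSD)` (floored at
$\ln 10^{-12}$) is tabulated by `spectralAccuracyReport()` for group
comparisons. Clean profiles score orders of magnitude below perturbed
ones, which is exactly what makes the score useful for separating
peptides that benefit from partial profiles.

## The simulator

`simulateTimeCourse()` is the package's test harness and defines its
study conditions: a one-compartment deterministic model with body water
at plateau from $t = 0$; time points $\{0, 1, 3, 7, 14, 21\}$ days;
$p_W = 0.046$, $p_H = 1.15\times10^{-4}$; an eight-peptide tryptic-like
panel with true rates 0.05-0.40 day$^{-1}$ (spanning the range
resolvable between the shortest and longest labeling duration); 3%
multiplicative lognormal channel noise (mean-one; additive Gaussian
behind a flag) as a typical LC-MS abundance fluctuation; and
contamination modeled as a constant additive abundance on selected
channels — the minimal description of a co-eluting interference. The
generator emits ground-truth $k$, $p_X(t)$ and $I_0(t)$ alongside the
quantification table and is bit-reproducible under a fixed seed.

What the simulator does *not* emulate: chromatographic peak shapes,
retention-time drift, missing time points, enrichment kinetics of the
precursor pool (two-compartment models), or correlated channel noise.
Passing the synthetic round trips therefore demonstrates correctness
of the estimators and fitting machinery under the stated model, not
performance on raw LC-MS data.

Problem sizes used by the validation suite were chosen to keep each
check sharp but quick: 20 random compositions for oracle equivalence, a
seven-peptide $N_{EH}$ ladder (~2 to ~40) times ten enrichments for the
inversion round trip, 200 contaminated replicates for method selection,
501 noisy replicates across $k \in \{0.03, 0.135, 0.4\}$ for recovery
and interval calibration, and 1000 mixture draws for $\theta$.

## Numerical choices and edge cases

* Convolutions are direct (no FFT), with a $10^{-16}$ relative tail
  trim in repeated squaring; distributions are renormalized after
  assembly.
* Gamma-function binomials (`choose()` with real first argument)
  handle non-integer $N_{EH}$ in $b_n$, $c_n$ and the real exponent in
  the monoisotope depletion.
* The enrichment solver treats both interval endpoints explicitly, so
  unreachable ratios resolve to a flagged boundary estimate rather
  than an error.
* Contamination saturation: with very large monoisotope contamination
  (beyond ~20% of base abundance) the full-profile enrichment clips at
  zero at early time points, the reconstructed series pins at its
  natural value, and $R^2$ of the (misspecified) full-profile fit can
  rebound slightly; degradation is monotone below saturation.
* Zero/negative abundances invalidate an estimate; invalid points are
  dropped per method, never imputed. Proteins with no accepted
  peptides are omitted from the rollup with a message.
* Peptides shared between proteins are excluded from the rollup by
  default (razor-peptide assignment is out of scope).

## Known limitations

* Canonical residues only; no post-translational modifications, no
  isotope fine structure (isotopomers are aggregated by nominal mass
  shift; charge enters m/z only).
* The confidence intervals are standard asymptotic constructions (the
  linearized t-interval per peptide; the t-interval over peptide-rate
  standard deviations per protein). With six time points and one
  parameter their empirical coverage on simulated data is close to but
  slightly below nominal (~91-95%).
* Raw spectral processing (mzML parsing, peak detection, XIC
  extraction, identification) is upstream and out of scope; the
  package starts from per-peptide isotopomer abundance tables.
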
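---
title: "Modeling replicate EI spectra: kinetic rationale, stepwise linear models, and validity diagnostics"
author: "easiMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling replicate EI spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(easiMS)
```

## The problem

Identifying an organic substance from its electron-ionization (EI) mass
spectrum is hard precisely when it matters most: when the questioned
spectrum was acquired on a different instrument than every reference
spectrum available. Spectral-similarity scores degrade across instruments
because relative fragment abundances shift with ion-source conditions, and
most comparison algorithms assume the abundance at each m/z varies
independently across replicates. It does not. All fragments of one
precursor are produced by the same unimolecular dissociation kinetics, so
replicate spectra carry strong, structured fragment–fragment correlations.
easiMS turns that structure into the identification signal instead of
treating it as noise: from a set of replicate spectra of a reference
compound it learns one linear model per fragment ion (each ion regressed on
the other panel ions) and ships the fitted coefficients as the reference
artifact. A query spectrum is then judged by how well its own ion
abundances predict one another under the reference compound's models —
a property that survives instrument-to-instrument shifts much better than
the raw abundances do.

## Kinetic basis

The package's simulator grounds the linearity assumption. Dissociation
rates follow the classical Kassel form

$$k(E) = \nu \left( \frac{E - E_0}{E} \right)^{3N-7}, \qquad E > E_0,$$

with $\nu$ the frequency factor (s$^{-1}$, transition-state "looseness"),
$E_0$ the critical energy (eV), $E$ the internal energy (eV), and $3N-7$
the vibrational degrees of freedom of an $N$-atom nonlinear precursor,
excluding the reaction coordinate. A `FragmentationNetwork` is a rooted DAG
of such pathways; starting from a pure precursor population, the linear
rate-equation system is solved in closed form as per-species sums of
exponentials (`speciesFractions()`, `breakdownCurve()`). The precursor
decays as $e^{-k_{tot}t}$ with $k_{tot}$ the sum of its channel rates;
competitive channels split the flux in proportion to their rates, and
sequential steps follow the consecutive-decay closed form.

Two numerical guards matter. First, when two cascade rates agree to within
a relative $10^{-9}$ the closed form divides by a near-zero rate
difference; the solver then falls back to adaptive ODE integration
(deSolve, `rtol = 1e-12`). Second, fractions are clipped into $[0, 1]$
only to absorb floating dust; conservation ($\sum$ fractions $= 1$) is
tested at $10^{-10}$ and the closed form is verified against the ODE
oracle at $10^{-8}$ absolute on randomized cascades.

Why this supports *linear* cross-instrument extrapolation: over a modest
window of internal energy (tens of percent) or observation time, each
species' fractional abundance is a smooth function of the perturbation, so
any two species trace an approximately straight line against each other
(`linearityScan()`). Sibling channels with similar critical energies are
the extreme case — their branching ratio is nearly constant, so the pair is
nearly proportional. The default 70-atom network includes such a sibling
pair deliberately; over a ±15% energy window its best fragment pair attains
$R^2 > 0.999$.

### Energy scale of the default conditions

With $3N-7 = 203$ degrees of freedom, Kassel rates only reach the
$10^5$–$10^7$ s$^{-1}$ range relevant to microsecond source residence
times when $E \gg E_0$; the default simulations therefore run at a center
internal energy of 60 eV with critical energies of 1.6–3.0 eV. The eV
scale here is nominal — the paper-style Kassel model with arbitrary
frequency factors is a qualitative engine, not a thermochemical
calculation. At 60 eV the loose, high-$E_0$ channel dominates the
branching, so one species is the base peak across both simulated
laboratories; this mirrors real replicate libraries, where the base-peak
identity is stable (or switches only between two dominant ions), and it is
what keeps relationships approximately linear *in normalized units*.

## The modeling pipeline

1. **Normalization** (`normalizeToBasePeak()`): every spectrum is scaled so
   its largest peak is 100; all modeling happens in percent-of-base-peak
   units. Ties annotate the lowest m/z as base peak; scaling is unaffected.
2. **Panel selection** (`selectTopIons()`): the n = 20 most abundant ions
   by mean normalized abundance across the training library, ties toward
   lower m/z. Specific diagnostic ions can be forced into the panel
   (`forceInclude`), displacing the lowest-ranked unforced ions — useful
   when particular fragments are known to discriminate near-isomers.
   The ranking statistic (mean across spectra) is a documented choice;
   a consensus or single-exemplar ranking would be equally defensible.
3. **Per-ion stepwise models** (`stepwiseSelect()`): for each panel ion, a
   mixed forward/backward stepwise OLS regression on the remaining 19 ions.
   A candidate enters when its partial-F p-value is the smallest among
   eligible candidates and ≤ `pEnter` (default 0.05); included terms are
   removed while the largest removal p-value is ≥ `pRemove` (default 0.10).
   The thresholds are probabilities of F, the convention of mainstream
   statistical packages; `pEnter < pRemove` is enforced because it rules
   out immediate enter/remove cycles, and a 100-iteration cap guards
   pathological inputs. Ties break toward lower m/z, which makes selection
   invariant to row and candidate order. Raw (unstandardized) covariates
   are used during selection; partial-F tests are invariant to affine
   covariate scaling, so this choice does not affect which ions enter.
4. **Collinearity guard**: a candidate whose entry would push the design
   matrix's reciprocal condition number below $10^{-10}$ is ineligible.
   On synthetic noiseless data this is what stops the selector after the
   first exact covariate instead of producing singular fits.
5. **The coefficient table** (`trainCoefficientTable()`): one `IonModel`
   per panel ion — or a skip record for an exactly-constant dependent
   column (notably the base-peak ion when it is the base peak in *every*
   spectrum, since its normalized abundance is then identically 100). Only
   exact constancy triggers a skip; an ion that is base peak in some
   spectra only is modeled as-is.
6. **Prediction** (`predictIon()`, `predictAll()`):
   $\hat{A} = \beta_0 + \sum_j \beta_j x_j$ with $x_j$ the query's
   normalized abundances; a missing covariate contributes 0 with a
   warning. Predictions are deliberately not clamped to $[0, 100]$ —
   out-of-range predictions are diagnostic signal. The standardized
   residual divides by the model's training residual standard deviation.

## Validity diagnostics

`pearsonCorrelationMap()` computes all pairwise ion correlations with
p-values from the exact t transform on $n-2$ degrees of freedom (a 20-ion
panel gives 190 pairs); constant columns are excluded and reported.
`residualMoments()` uses bias-corrected sample skewness and excess
kurtosis (e1071, type 2 — the convention of mainstream statistical
software) with their exact finite-sample standard errors

$$SE_{skew} = \sqrt{\tfrac{6n(n-1)}{(n-2)(n+1)(n+3)}}, \qquad
SE_{kurt} = \sqrt{\tfrac{24n(n-1)^2}{(n-3)(n-2)(n+3)(n+5)}},$$

which give 0.214 and 0.425 at n = 128. A moment is flagged significant
when it exceeds `multiplier` × SE; the default multiplier is 2, but the
value 0.425 equals 1 × SE, so a 1-SE reading of a "margin of error" is
supported by setting `multiplier = 1`. `ppCoordinates()` uses the
$(i - 1/2)/n$ plotting position (configurable in principle; alternatives
like $i/(n+1)$ differ negligibly at n = 128). Correlation p-values are not
multiplicity-adjusted — per-pair significance is reported raw, and the
aggregate guard is the *fraction* of significant residual pairs at level
α from `residualCrossCorrelation()`. `centroidBaseline()` is the naive
comparator: predict every ion by its training mean.

A caveat the diagnostics themselves expose: even when the latent structure
is fully captured, OLS residuals across models are not exactly independent,
because each model's residuals contain a share of its covariates'
measurement noise (weight ≈ $a^2/(1 + m a^2)$ for $m$ equally-informative
covariates with standardized loading $a$). Under the synthetic conditions
below this keeps roughly 17–20% of residual pairs nominally significant at
α = 0.05 — above the ~10–15% one might hope for, and an honest floor of
the uniform-noise generator rather than a modeling defect; the null
calibration (independent residuals → fraction ≈ α) is what verifies the
test itself is not anticonservative.

## What the synthetic generators emulate — and what they do not

**Kinetic replicate libraries** (`simulateReplicateLibrary()`): each
replicate draws an internal energy $E_i \sim N(\mu_E, \sigma_E)$ and an
observation time $\log t_i \sim N(\mu_t, \sigma_t)$, evaluates the
network's species fractions, renders them at the species' nominal masses,
applies independent multiplicative log-normal noise per ion (mean-one,
CV = `noiseCV`), and normalizes. Defaults (the package's study
conditions): Lab 1 at 60 ± 3 eV (a ±15% window at 3 SD),
$t \approx 1\,\mu s$ (log-SD 0.1), CV 0.03 — replicate EI relative
abundances are typically reproducible to a few percent — with n = 128
replicates; Lab 2 shifts the energy mean by +33% and the time mean by
+50% (n = 120), enough that several ions' measured abundances fall mostly
outside Lab 1's range. Multiplicative (not additive) noise is used because
normalized abundances can never be negative.

**Linear truth libraries** (`makeLinearTruthLibrary()`): abundances follow
a one-factor model $x_{ij} = \mu_j + \lambda_j f_i + \varepsilon_{ij}$
(optional second factor available), with the base ion pinned at 100 so
normalization is exact and the generating coefficients remain analytically
known (`trueCoefficients()`). Default loadings give every loaded ion a
signal-variance fraction of 0.95. Values are clipped to $[0.1, 100]$; more
than 5% clipping is an *error*, because silent clipping would corrupt the
linearity the generator exists to provide. One structural consequence of
exact normalization: the pinned base ion is constant and therefore skipped,
so a 20-ion panel yields 19 models. Letting the base-peak identity switch
between spectra (as real data sometimes does) would restore a 20th model
but destroys the analytic truth, so the pinned design is used for
parameter-recovery work.

Neither generator simulates mass bias/transmission curves, isotope
envelopes, chromatographic peak shapes, background ions, or
intensity-dependent (Poisson-like) noise. Passing tests on these
synthetics therefore demonstrate the *mechanism* — linear structure in,
linear structure recovered, extrapolation beating the centroid — not
performance on real instrument data.

## Problem sizes and determinism

The validation experiments run at the study's native sizes: training
libraries of 128 spectra, validation sets of 120, 20-ion panels, 100
stepwise-vs-oracle instances (n = 60, ≤ 4 candidates), 50 random kinetic
networks (≤ 6 species, three time points each), 20 recovery seeds, and a
500-seed null calibration; everything completes in well under a minute
apiece. All randomness flows through explicit integer seeds; identical
(configuration, seed) pairs produce bytewise-identical MSP/JSON/CSV
artifacts, which the command-line interface (`easiMain()`; launcher in
`inst/exec/easi`) preserves by writing outputs atomically.

## Known limitations

* The Kassel simulator is a single-energy, single-time slice engine: no
  internal-energy distributions, no full RRKM state counts, no
  collision-induced processes. With `inheritExcess = TRUE` a fragment
  inherits $E - E_0$ of its formation step (taking the most energetic
  route when a species has several parents); this energy bookkeeping is a
  modeling convenience, not thermochemistry.
* OLS with iid-noise assumptions: abundances near 0 or 100 are bounded, so
  residuals can be mildly non-Gaussian (the moment diagnostics exist
  precisely to quantify this); a count-model (Poisson-type) variant is an
  explicit non-goal here.
* The coefficient table is compound-specific and panel-specific; applying
  it to spectra missing many panel ions degrades gracefully (zero-filled
  covariates with warnings) but is diagnostic of a non-match rather than a
  prediction failure.
* Binary known-positive/known-negative classification on top of the
  residuals (thresholds, ROC analysis) is out of scope for this package.
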
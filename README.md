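# easiMS

Kinetics-based general linear modeling of replicate electron-ionization
(EI) mass spectra, for substance identification across instruments.

## The problem

A forensic or analytical lab often has to decide whether a questioned GC-MS
spectrum is a particular compound when no reference spectrum from the same
instrument exists. Conventional library-search scores assume that the
relative abundance at each m/z varies independently between replicate
spectra; in reality every fragment of one precursor is produced by the same
unimolecular dissociation kinetics, so fragment abundances co-vary strongly
— and, over modest changes of ion internal energy or observation time,
approximately *linearly*. easiMS is built on that observation, for anyone
who maintains replicate spectra of reference standards (crime labs,
metabolomics cores, spectral-library curators) and wants an
instrument-portable model of a compound instead of a single consensus
spectrum.

## The method

Given a training library of replicate spectra of one compound (NIST MSP
text format), easiMS:

1. normalizes each spectrum to its base peak (base = 100),
2. selects the panel of the *n* = 20 most abundant fragment ions (specific
   diagnostic ions can be forced in),
3. fits, for each panel ion *y*, a mixed stepwise ordinary-least-squares
   model on the remaining panel ions,

   *y* = β₀ + β₁x₁ + … + βₖxₖ + ε,

   entering the candidate with the smallest partial-F p ≤ 0.05 and
   removing included terms with p ≥ 0.10 until stable, and
4. packages the ~20 fitted models as a `CoefficientTable` — a portable
   artifact of fewer than a hundred numbers that predicts every panel
   ion's abundance in any query spectrum from the query's other ions.

Residual diagnostics (bivariate Pearson maps with exact t-transform
p-values, bias-corrected skewness/kurtosis with exact finite-sample SEs,
P–P coordinates, residual cross-correlation mapping, centroid baseline)
quantify the statistical validity of the models. A Kassel-rate
(`k(E) = ν((E−E₀)/E)^(3N−7)`) branching simulator demonstrates the
near-linearity of fragment–fragment relationships that justifies the
linear models, and seeded synthetic-library generators make the whole
pipeline testable end to end without proprietary spectra. See the methods
vignette (`vignettes/easi-methods.Rmd`) for the model, assumptions and
design choices.

## Worked example

Train on a simulated 128-replicate library from "Lab 1", then predict
spectra simulated under "Lab 2" conditions (+33% internal energy, +50%
observation time):

```r
library(easiMS)
net  <- makeDefaultNetwork(seed = 0)
lib1 <- simulateReplicateLibrary(net, defaultLabProfile(1))
table <- trainCoefficientTable(lib1, nIons = 5)
ionModels(table)[["182"]]
#> IonModel for m/z 182: 1 covariates (R^2 = 0.9181)
#>   covariates: m/z 198
round(modelCoefficients(ionModels(table)[["182"]]), 4)
#> (Intercept)         198
#>     -4.9527      0.2396

lib2 <- simulateReplicateLibrary(net, defaultLabProfile(2))
predictAll(table, lib2[[1]])
#>    mz predicted measured residual std.residual
#> 1  82   100.000  100.000   0.0000        0.000
#> 2 198    31.816   30.012  -1.8037       -0.802
#> 3 182     2.238    2.159  -0.0793       -0.141
#> 4 105     0.638    0.626  -0.0126       -0.732
#> 5  94     0.238    0.258   0.0204        3.121
```

The m/z 182 model learned in Lab 1 (intercept −4.95, slope 0.24 on m/z
198, R² = 0.92) predicts Lab-2 abundances to fractions of a percent of the
base peak even though Lab 2's raw abundances sit largely outside Lab 1's
range. Comparing against the naive centroid (training-mean) baseline over
all 120 Lab-2 spectra:

```r
ex <- twoLabExperiment()
ex$perIon[, c("mz", "rmsModel", "rmsCentroid", "ratio")]
#>    mz rmsModel rmsCentroid ratio
#> 1  82 5.94e-15    5.94e-15 1.000
#> 2 198 4.82e+00    2.92e+01 0.165
#> 3 182 6.63e-01    6.40e+00 0.104
#> 4 105 2.80e-02    1.86e-01 0.150
#> 5  94 2.01e-02    8.90e-02 0.226
```

Every varying panel ion is predicted 4–10× more accurately by the linear
models than by the consensus spectrum (m/z 82 is the base peak everywhere,
hence constant at 100 and trivially "predicted" by both).

A command-line interface wraps the same pipeline
(`synth`, `train`, `predict`, `diagnose`, `simulate`):

```sh
easi=$(Rscript -e 'cat(system.file("exec", "easi", package = "easiMS"))')
Rscript "$easi" synth --mode linear --seed 1 -o lib.msp
Rscript "$easi" train --library lib.msp --top 20 -o coeffs.json
Rscript "$easi" predict --coeffs coeffs.json --query lib.msp -o predictions.csv
```

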
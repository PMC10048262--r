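---
title: "Wavelength selection for LIBS heavy-metal quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection for LIBS heavy-metal quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(libsvarsel)
```

## The problem

Laser-induced breakdown spectroscopy reads elemental composition from
the emission spectrum of a laser-generated plasma. For quantification of
heavy metals in plant material the data are wide tables: hundreds of
samples against thousands of wavelength channels, with reference
concentrations (mg/kg, from ICP-MS) attached per sample. The channels
are strongly collinear — each element emits at several lines, each line
spans several channels — and most of the axis carries no analyte
information at all. The pipeline in this package couples three
wavelength-selection algorithms (CARS, random frog, UVE) to three
regressors (PLSR, SVR, gradient boosting) and evaluates every
combination against the full spectrum.

## The synthetic study

No instrument data ship with the package; a generator with known ground
truth stands in, and its defaults define the study conditions used by
the test suite.

* **Design**: 8 groups × 36 samples = 288 pellets; group 1 is an
  uncontaminated control. Per-sample concentrations for Cd, Cu and Pb
  are drawn from normals with group-specific means and sds (the
  built-in design spans roughly 0.4–94 mg/kg for Cd, 2.5–215 for Cu,
  0.3–199 for Pb), truncated at zero by clamping — simpler than
  rejection sampling, with negligible bias at these means. Twelve
  variety labels cycle over samples.
* **Spectra**: a flat continuum (100 a.u.) plus one unit-area Gaussian
  profile per emission line, scaled by line strength × element
  sensitivity × concentration. The line library carries six Cd lines
  (214.44, 226.50, 441.56, 467.90, 573.80, 643.85 nm), the Cu doublet
  (324.09, 324.79 nm) and three Pb lines (280.00, 404.00, 405.70 nm);
  relative strengths fall from 1.0 to 0.4 with decreasing line
  persistence. Matrix lines (Ca, Mg, Na, K) have fixed,
  concentration-independent intensities: after area normalization they
  become correlated with total analyte load without carrying analyte
  information — the classic trap for a selector.
* **Axis and peak width**: 200–1000 nm at 0.5 nm (1601 channels),
  Gaussian sigma 0.3 nm, so the Cu doublet partially overlaps and
  exercises the covariance structure that motivates selection. These
  are desk-scale declarations, not inferences — echelle spectrometers
  resolve far finer, but channel count only scales the problem.
* **Noise**: every one of 80 simulated shots (the 4 × 4 crater array
  with 5 accumulated pulses) multiplies the signal by `(1 + e)` with
  `e ~ N(0, 0.2)` and adds detector noise `N(0, 5 a.u.)`, clips at
  zero; shots are averaged. Averaging shrinks channel noise like
  `1/sqrt(k)`, which the tests verify by Monte Carlo.

What the generator does **not** emulate: plasma physics (Saha/Boltzmann
population, self-absorption), matrix effects on line intensity,
spectrometer stitching, or baseline drift. Passing tests therefore show
the algorithms behave correctly on spectra with the right correlation
geometry — not that any fixed accuracy carries over to instrument data.
On the default draw the regression problem is genuinely easier than
real LIBS (prediction R² near 0.999), so absolute errors do not carry
over — and the selected-versus-full-spectrum contrast is compressed:
with nearly noise-free effective spectra a full-spectrum linear model
is already close to optimal, and selection can match but barely beat
it (see the limitations section).

## Preprocessing

Spectra are divided by their trapezoidal integral over the wavelength
axis (unit area w.r.t. the axis, not unit channel sum, so the result is
stable under re-binning). Normalization is computed per spectrum with
no training-set statistics, hence it can precede splitting without
leakage, and it is idempotent and scale-invariant.

The 60/28/12 calibration/validation/prediction split uses
largest-remainder apportionment (288 samples do not divide evenly;
the global sizes come out 173/81/34) and stratifies by group by
default so extreme concentration groups reach all three subsets.
Under stratification the apportionment happens within each group
(36 → 22/10/4). One design caveat: seeded permutations attach to
positions, not to sample identities, so relabeling samples and
splitting does not commute with splitting and relabeling — the suite
checks determinism and stratification balance instead.

## The PLS engine

PLS1 via classical NIPALS: per component, the weight vector is the
normalized covariance of the deflated blocks, both blocks are deflated,
and the original-scale coefficient vector is assembled as
`b = W (P'W)^{-1} q`. Columns are centered but not autoscaled — the
channels share one intensity unit, and autoscaling would inflate empty
channels; a `scale` switch exists. Coefficients for every intermediate
component count are kept, so K-fold RMSECV over components costs one
fit per fold. Fold assignment is drawn once per cross-validation and
shared across component counts; `folds = n` is exact leave-one-out
(verified against brute-force refits). Ties in the best component
count go to the smallest count.

Numerical choices: rank exhaustion (weight or score norm below
tolerance) truncates the component sequence rather than failing;
constant columns get exactly zero weight and are tolerated, because
flat baseline channels are routine in emission spectra (a fully
constant matrix, or one with no covariance to the response, is an
error naming the offending columns). Defaults: 5 folds, up to 15
components for model selection, 10 inside selectors.

## The selectors

All three run on calibration rows only — selection is part of model
building and must not see validation or prediction samples — and every
stochastic step takes an explicit seed.

**CARS.** N = 50 sampling runs. Run i fits PLS on a random 80 % row
subsample restricted to surviving channels, ranks channels by `|b|`,
keeps the top `ceiling(r_i p)` where `r_i = a e^{-k i}` is the
exponentially decreasing schedule pinned to `r_1 = 1` and
`r_N = 2/p`, then applies adaptive reweighted sampling (that many
weighted draws with replacement, unique hits kept) as the competitive
step. Each run's subset is scored by 5-fold RMSECV on the full
calibration set with a fold assignment fixed once, and the
lowest-RMSECV subset wins. If the subset collapses below two channels
the schedule truncates with a message — routine behaviour late in the
schedule when a few channels dominate.

**Random frog.** From a random subset of size `p/10`, each of
N = 1000 iterations proposes a candidate of size
`|round(N(Q, 0.3 Q))|`: shrinking keeps the top channels of a PLS fit
on the current subset; growing pools the subset with a random batch of
outside channels (three per open slot) and keeps the top. Candidates
with no worse RMSECV are accepted; worse ones with probability
`0.1 × RMSECV(current)/RMSECV(candidate)`. The selection probability
`P_j = N_j / N` counts membership in retained subsets. The final
subset takes the smallest k among multiples of 5 (capped at 300, well
above the subset sizes informative spectra need) whose top-k channels
by `P_j` minimize RMSECV.

**UVE.** The calibration matrix is augmented with p uniform noise
columns at amplitude 1e-10 — vanishing against unit-area spectra, and
irrelevant in size because the stability statistic
`c_j = mean(b_j)/sd(b_j)` over leave-one-out jackknife replicates is
scale-free in the noise block (doubling the amplitude reproduces the
same selection). Real channels must beat the 99th percentile of the
absolute noise stabilities; the maximum would be an unstable cutoff
against p noise columns. The jackknife is computed in sample space
(wide-kernel PLS): every leave-one-out coefficient vector is recovered
through the Gram matrix, which is algebraically identical to refitting
per replicate — the suite asserts equality — but takes one pass over
the wide matrix instead of n.

## The regressors

PLSR picks its component count by RMSECV unless fixed. SVR
(epsilon-regression, RBF) uses C = 10, epsilon = 0.1 and
`gamma = 1/(p var(X))`; the response is standardized internally and
de-standardized on output because the epsilon tube is scale-sensitive.
The gradient boosting machine honours the fixed tuple — leaf-wise
("gbdt") growth, 31 leaves, unlimited depth, learning rate 0.1, 100
trees — on an xgboost histogram backend (`lossguide`, `max_leaves=31`,
`max_depth=0`), single-threaded for bit-reproducibility, with 32
histogram bins (ample resolution for ~170 calibration rows) and the
minimum child weight lowered to 1 so that small calibration sets still
split. Variable importance averages the squared-error split improvement
per channel across all trees and normalizes to sum one; a splitless
model reports uniform importance with a degeneracy flag.

## The evaluation grid

One shared split feeds every cell of the 3 elements × 3 models ×
{full, CARS, RF, UVE} grid; per cell the report stores RC²/RMSEC,
RV²/RMSEV, RP²/RMSEP and the raw predictions, so every metric is
recomputable (the suite checks to 1e-12). R² is the coefficient of
determination `1 - SSE/SST` — not the squared Pearson correlation,
which ignores calibration bias; a `pearson` switch exists. The
validation set is purely reportorial: no model choice looks at it.
Table-style descriptive statistics use the sample (n−1) variance.

## Problem sizes in the test suite

The acceptance-style checks run the full default conditions: 20
replicates of the 288 × 1601 study for selector recovery (a selected
channel within ±1 channel of every true Cd line; UVE additionally
retains at most 5 % of channels against a response independent of the
spectra), and 10 replicates of the complete 36-cell grid for the
comparative claim that the best selected-variable model's prediction
RMSE does not exceed the same model's full-spectrum RMSE in the
median. Unit tests use reduced axes (200–500 nm at 1 nm) and smaller
designs; those sizes are stated in the test fixtures themselves.

## Known limitations

* The generator's linear signal model makes PLSR nearly unbeatable;
  SVR and GBM advantages seen on instrument data (nonlinearity, matrix
  effects) will not reproduce here.
* For the same reason, the comparative claim that the best
  selected-variable model out-predicts its full-spectrum counterpart
  holds only marginally on the synthetic defaults: the suite measures
  a clear advantage for Cd and differences within prediction-set
  sampling noise (about 1 % of RMSEP, slightly positive) for Cu and
  Pb. On instrument spectra the advantage comes from structured
  interference and matrix effects that the generator deliberately
  omits; its constant-intensity matrix decoys are, after
  normalization, consistent between training and test and therefore
  harmless to a full-spectrum model.
* Selection probabilities from random frog depend on chain length;
  1000 iterations give stable rankings for ~1600 channels but the tail
  of weakly informative channels mixes slowly.
* The UVE cutoff assumes the appended noise block is exchangeable with
  uninformative real channels; heteroscedastic channel noise would
  break that symmetry.
* With its default unbounded depth and 31 leaves, the GBM interpolates
  small calibration sets almost perfectly; its calibration metrics are
  optimistic by construction, which mirrors the behaviour of the
  stated hyperparameters rather than a defect.
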
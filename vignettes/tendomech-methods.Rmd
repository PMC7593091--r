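---
title: "Phase-specific tendon mechanics and downstream omics: models and methods"
author: "tendomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-specific tendon mechanics and downstream omics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendomech)
```

## Scope

Tendon is a two-phase composite: collagen-rich fascicles carry load along the
tendon axis, and the interfascicular matrix (IFM) binds them and accommodates
sliding between them. Functional specialisation — an energy-storing tendon
such as the equine SDFT versus a positional tendon such as the CDET — is
increasingly attributed to the IFM rather than the fascicles. `tendomech`
implements the quantitative pipeline used to test that idea: phase-specific
analysis of uniaxial mechanical test records (preconditioning viscoelasticity,
ramp-to-failure properties, toe-region profiling), the downstream omics
arithmetic that accompanies such studies (label-free differential abundance,
neopeptide turnover, efficiency-corrected qPCR expression, structure–function
correlation), and the study-level statistical framework (normality gating,
two-factor development × tendon ANOVA, compact letter displays, weighted
kappa). A synthetic-data generator with analytic ground truth makes every
stage testable end to end without access to laboratory data.

## Mechanical test protocols

Both phases are tested displacement-controlled at 100 Hz:

* **Fascicle**: preload 0.1 N; 10 sinusoidal preconditioning cycles between
  0 and 3 % strain at 1 Hz; ramp to failure at 5 %/s. Strain is referenced
  to the gauge length recorded at preload; cross-sectional area is computed
  from the smallest measured diameter assuming circularity,
  `csa = pi d^2 / 4`.
* **IFM**: two adjacent fascicles bonded by a 10 mm window of intact IFM are
  sheared apart; preload 0.02 N; 10 cycles between 0 and 0.5 mm extension;
  ramp at 1 mm/s. No cross-section exists for a sheared interface, so all
  IFM quantities stay on force–extension axes (stiffness in N/mm).

Raw force is smoothed before any calculation with a third-order
Savitzky–Golay filter, frame 15 for the preconditioning segment and frame 51
for the ramp (`sgSmooth()`, backed by `signal::sgolayfilt`; endpoint windows
are asymmetric full-frame polynomial fits, so the filter reproduces cubics
exactly over the whole series).

### Segmentation

`segmentTrace()` labels each sample `preload`, `preconditioning` or `ramp`.
The terminal ramp is the maximal non-decreasing suffix of the commanded
extension; cycles are counted by zero-crossings of the band-centred
extension with a hysteresis band of 2 % of the cycle amplitude, which is
robust to noise and needs no peak-picking parameters. The preload segment
ends where the cycles' common baseline is last visited. A protocol expecting
10 cycles fails loudly if a different number is detected.

### Preconditioning metrics

*Total percentage hysteresis between the first and last preconditioning
cycle* is interpreted as energy input on the first cycle's loading branch
versus energy recovered on the last cycle's unloading branch,

$$H = 100\,\frac{W_\mathrm{load}^{(1)} - W_\mathrm{unload}^{(10)}}{W_\mathrm{load}^{(1)}},
\qquad W = \int F\,dx \ \text{(trapezoidal)},$$

capturing the total energy lost over preconditioning. The wording admits a
second reading — comparing the closed-loop loss of cycles 1 and 10 — which is
available as `hysteresis(mode = "loop_delta")`; `first_to_last` is the
default and the definition the simulator's ground truth uses. Stress
relaxation is the peak-force decay
$100\,(P_1 - P_{10})/P_1$. Both are percentages, hence invariant to force
rescaling and to the choice of force–extension versus stress–strain axes;
negative unloading forces (grip slack) are integrated as recorded, since
clipping would bias the recovered work.

### Ramp to failure

Failure is the (first) maximum of the **raw** ramp force. The drop at
failure is essentially instantaneous; smoothing across it with a frame-51
filter would smear the peak several samples backwards, so the failure sample
is located on raw data and the Savitzky–Golay filter is applied only up to
that sample for the slope and toe computations. The continuous modulus
(fascicle; stress against strain fraction, giving MPa) or stiffness (IFM;
N/mm) is the ordinary-least-squares slope in every sliding 10-point window
(stride 1), restricted to windows ending at or before the failure sample —
post-peak slopes are unloading artefacts. The yield point is the centre
sample (index `start + 5`) of the *first* window attaining the maximum
slope; ties break to the earliest window, consistent with yield preceding
failure. Yield stress/strain (or force/extension) are read at that sample.
The toe profile records the extension at which the smoothed force first
reaches 10 %, 20 %, …, 100 % of the failure force, linearly interpolating
between bracketing samples; 100 % returns the failure extension itself, so
the profile is non-decreasing and anchored at failure by construction.

Strain is stored in %, while the modulus is reported on the strain-fraction
basis (MPa); extension is treated as recorded by the machine, without a
compliance correction.

## The specimen simulator

`simulateMechTest()` generates complete traces from a quasi-linear
viscoelastic (QLV) specimen model with three ingredients:

* **Crimp-recruitment toe.** Load-bearing elements have Gaussian slack
  lengths $s \sim N(\mu, \sigma^2)$ and load linearly once taut, so the
  tangent stiffness is $k\,\Phi((x-\mu)/\sigma)$ — a toe region rising into
  a linear region with two interpretable parameters.
* **Smoothly blended post-yield softening.** Past the yield extension the
  tangent decays exponentially at rate $c$ per mm, entered through a
  softplus blend of width `yieldBlend` (default 0.2 mm):
  $k_t(x) = k\,\Phi\!\left(\tfrac{x-\mu}{\sigma}\right)
  \exp\!\left(-c\,w\,\mathrm{softplus}\!\left(\tfrac{x-x_y}{w}\right)\right)$.
  Real tissue does not have a corner in its tangent curve, and a corner is
  also what a symmetric smoothing filter displaces; the blend makes the
  tangent maximum smooth and hence recoverable by the pipeline's smoothed
  sliding-window slope. The force is the fine-quadrature integral of
  $k_t$; at the failure extension it drops instantaneously to zero (the
  pipeline needs a well-defined failure point, not post-failure physics).
* **Single-exponential reduced relaxation.** Quasi-linear superposition
  with $G(t) = (1 - v) + v\,e^{-t/\tau}$, so $G(0)=1$ and a fraction $v$
  (`viscFraction`) of elastic stress relaxes at long times; $v = 0$ is a
  perfectly elastic, loss-free material. The convolution is evaluated by an
  exact linear recurrence with midpoint-weighted increments.

Gaussian noise (`noiseSd`) is added to force only — extension is
machine-commanded. The preload phase ramps to the extension at which the
elastic backbone slightly overshoots the preload (×1.15) and holds for 1 s,
so that the analyser's "force ≥ preload sustained for 0.1 s" rule fires on
the rising flank despite viscoelastic relaxation during the hold; the ramp
duration is snapped up to the sample grid so that every protocol boundary
falls on a sample. Protocols whose cycles would reach the yield extension
are rejected, mirroring the experimental convention of preconditioning at
roughly a quarter of the failure amplitude.

### Ground truth

Every simulation carries a truth record computed on a noise-free grid at
0.1 ms — 100× the trace resolution — never by the analysis pipeline itself:
hysteresis and stress relaxation by trapezoidal quadrature on the analytic
branch boundaries; per-cycle peak forces; the failure point; and the yield
point as the max-slope location of the noise-free response along the ramp
(wide central differences on the fine grid). The yield truth is
rate-dependent on purpose: with relaxation active, the measured tangent
maximum sits slightly below the elastic tangent maximum, and the truth
records what an ideal noise-free instrument would see at the protocol's ramp
rate (the elastic argmax is kept alongside as `yieldExtensionElastic`).
Halving the truth grid changes the hysteresis truth by well under 0.1 %
relative, which the test suite checks as a convergence property.

### Noise defaults

The study data offer no trace-noise characterisation, so the defaults
(0.01 N fascicle, 0.002 N IFM — roughly 10× below the respective preloads)
are stated choices of the generator configuration, not inferences; every
simulation records its parameters and seed alongside its outputs.

### Developmental presets

`agePresets()` maps (age group × tendon × phase) to generator parameters
reproducing the study's qualitative developmental signature: stiffness and
failure force rising through development; a longer SDFT-IFM toe
(`recruitMean` 1.3 vs 0.8 mm); and a viscoelastic fraction decreasing with
age in the SDFT IFM only (0.30 → 0.12, CDET constant at 0.30), which
produces a tendon × age interaction in hysteresis and stress relaxation.
The values are model choices shaped like the published figures — no attempt
is made to fit the published curves, which print no numbers to fit.
`simulateStudy()` adds mild specimen-to-specimen variability
(5 % log-normal jitter on stiffness, ±0.015 additive on the viscoelastic
fraction).

## Omics arithmetic

* **Normalisation** divides each sample by its laser-capture area × load
  volume and rescales by the geometric mean of those products — exactly
  removing the per-sample multiplicative distortion the simulator plants,
  which is what makes the normalisation-invariance property testable.
* **Differential abundance** per protein: omnibus one-way ANOVA across the
  five age groups plus the group-mean fold change (largest over smallest
  mean; zeros imputed as half the protein's smallest nonzero intensity
  before ratios). A protein is flagged when FC ≥ 2 **and** p < 0.05, and
  reported with its highest-mean age group. The omnibus call matches the
  per-protein "highest mean condition" presentation convention; the exact
  test behind the original software's adjusted p-values is not public, so
  the ANOVA stands in and is labelled as such.
* **Neopeptide turnover**: neopeptide abundances are normalised to the
  total peptide abundance of that protein in that sample — fractions of the
  whole, neopeptides included — summed per protein, then compared across
  groups with one-way ANOVA and Benjamini–Hochberg adjustment at 5 % FDR.
  Proteins observed with a single peptide are excluded and reported.
* **Relative expression**: $E^{-\Delta C_t}$ with
  $\Delta C_t = C_t^{target} - C_t^{ref}$ and the target primer's
  efficiency; `efficiencyFromSlope()` provides $E = 10^{-1/\text{slope}}$
  for standard-curve calibration. The quantity is invariant to per-sample
  Ct offsets by construction.
* **Structure–function correlation**: Pearson r with two-sided p for every
  (feature, metric) pair aligned by specimen/animal; zero-variance series
  are flagged rather than silently dropped.

## Statistical framework

Normality is assumed when n > 30 (central-limit rule); otherwise a
Shapiro–Wilk test at α = 0.05 gates the analysis, retesting the
log10-transformed response (which requires positivity) and finally falling
back to ranks. The factorial analysis is a two-way ANOVA with interaction
and Type-III sums of squares on sum-to-zero contrasts — group sizes of 3–4
per cell are unbalanced, and Type-III keeps main effects interpretable in
that setting. Under the rank fallback the same factorial model runs on
rank-transformed data and is labelled non-parametric: the named "ANOVA on
Ranks" procedure is one-way, and the rank-transformed factorial model is
its closest two-factor analogue. Post-hoc group comparisons are all-pairs
Welch t tests with Holm adjustment (the source names no post-hoc; Welch +
Holm is conservative and assumption-light), rendered as a compact letter
display in age order by an insert-and-absorb algorithm. Weighted kappa with
quadratic weights quantifies inter-rater agreement for ordinal histology
grades.

## Numerical choices and degenerate inputs

* Work integrals: trapezoidal rule on smoothed force versus raw extension.
* Backbone quadrature: 5×10⁻⁵ mm cumulative grid with linear interpolation;
  truth quadrature: 10⁻⁴ s.
* Ties: first occurrence wins for both the maximum-force sample and the
  maximum-slope window.
* Degenerate inputs: empty diameter lists, non-positive covariates, missing
  reference genes, monotone "cycle" segments, constant responses and
  zero-variance series all raise specific errors or QC flags rather than
  propagating NaN.
* Seeds: every generator takes an integer seed; identical seeds give
  bit-identical outputs.

## What the synthetic data do and do not show

The generator emulates protocol structure, toe/linear/yield/failure shape,
cycle-to-cycle force decay, loading–unloading energy loss, log-normal
abundance with planted fold changes, covariate distortion, turnover
fractions and Ct tables with known expression. It does **not** emulate grip
slippage, machine compliance, partial-thickness tearing before failure,
batch effects, missingness structure of real LFQ data, or peptide-level
identification error. Green pipeline tests therefore demonstrate that the
implementation recovers known truths under the stated generative model —
they do not certify performance on laboratory data with artefacts outside
that model.

## Problem sizes used in the checks

The packaged property checks use 20 specimens per phase × viscoelastic
level for metric recovery, 50 ramps for yield/failure detection, 100
specimens for toe-profile properties, 500 null experiments of 200 proteins
for FDR calibration, 1000 null replicates for the interaction type-I rate,
200-protein experiments at n = 4/group for power, and 3 seeded full study
grids (2 tendons × 5 ages × 4 specimens) for the end-to-end signature —
sizes chosen to make Monte-Carlo calibration tight enough to be meaningful
while keeping a full run in the order of a minute or two.

## Known limitations

* The hysteresis wording ambiguity is resolved by configuration, not
  adjudicated; comparisons across software should state the mode.
* The IFM is analysed as a force–extension record of a shear window; no
  attempt is made to infer interfacial shear stress.
* No mixed-effects modelling of animal-level repeated measures, matching
  the original analysis; specimens are treated as independent.
* Matrisome category assignment, pathway analysis and peptide-spectrum
  identification are out of scope; identifiers pass through untouched.
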
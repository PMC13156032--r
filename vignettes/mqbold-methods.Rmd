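---
title: "Quantitative BOLD oxygen metabolism mapping: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative BOLD oxygen metabolism mapping: models, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqbold)
```

## The problem

BOLD fMRI measures a composite hemodynamic signal, not neuronal metabolism.
A voxel's BOLD change reflects the net shift in deoxyhemoglobin content,
which rises with oxygen consumption (CMRO2) but falls with blood flow (CBF)
and changes with blood volume (CBV). When the flow response is weaker than
canonical neurovascular coupling assumes — or opposes it — the BOLD sign can
*contradict* the underlying metabolic change. `mqbold` implements a
multiparametric quantitative BOLD (mqBOLD) pipeline that measures each
component separately, reconstructs voxelwise CMRO2, and classifies voxels by
whether their BOLD response is concordant or discordant with metabolism.

## The quantitative model

Four relations carry the physics; everything else is estimation machinery.

**Reversible dephasing.** Multi-echo spin-echo data give T2, multi-echo
gradient-echo data give T2\*, and their difference in rates,
$R_2' = 1/T_2^* - 1/T_2$ (s^-1^), isolates the reversible dephasing caused
by paramagnetic deoxyhemoglobin. Voxels where T2\* exceeds T2 are physically
impossible for susceptibility-driven dephasing and are flagged invalid, so
valid R2' is non-negative by construction.

**Oxygen extraction.** With CBV as the volume fraction of (venous-weighted)
blood, the mqBOLD relation reads

$$\mathrm{OEF} = \frac{R_2'}{c \cdot \mathrm{CBV}}, \qquad
c = \gamma \tfrac{4}{3}\pi\, \Delta\chi_0\, \mathrm{Hct_{sv}}\, B_0,$$

with $\gamma = 2.675\times10^8\,$s^-1^T^-1^,
$\Delta\chi_0 = 0.264\times10^{-6}$, $B_0 = 3\,$T and the small-vessel
hematocrit taken as 85% of the measured large-vessel value.

**Fick's principle.** $\mathrm{CMRO_2} = \mathrm{OEF} \times \mathrm{CBF}
\times C_aO_2$, with the arterial oxygen content
$C_aO_2 = 0.334 \times \mathrm{Hct} \times 55.6 \times \mathrm{O_2sat}$
(µmol O~2~ per ml blood). CBF comes from pCASL through the
single-compartment consensus model ($\lambda = 0.9$ ml/g, $T_{1,b} =
1650$ ms, labeling efficiency 0.85, post-labeling delay = label duration =
1800 ms), upscaled by 25% to compensate the background-suppression loss.
CBV comes from DSC bolus integration, normalized so the white-matter median
is 2.5 %vol.

**Davis model.** Task-state BOLD changes relate to fractional flow and
metabolism changes through
$$\Delta S/S_0 (\%) = M\left[1 - f^{\alpha-\beta} r^{\beta}\right],$$
with $f$ and $r$ the CBF and CMRO2 task/baseline ratios. The literature
parameter set ($M = 5.5$, $\alpha = 0.23$, $\beta = 1.3$) is the default
for forward simulation; the empirically calibrated set ($M = 11.2$,
$\alpha = 0.38$) is available via `davis_params()`. Because
$\alpha < \beta$, a positive metabolic change with a weak or negative flow
change yields a negative BOLD response — the discordance region the
classification targets.

**BOLD-informed task R2'.** Rather than refitting noisy task-state
multi-echo data, the task R2' is obtained from the baseline R2' map and the
BOLD percent signal change via the linearized update
$\Delta R_2' = -\,(\Delta S/S_0)\,/\,(TE \cdot R_{2,0}')$ treated as a
fractional change ($TE = 30$ ms). In the limit $\beta = 1$,
$M = TE \cdot R_{2,0}'$ this path agrees exactly with the fully
quantitative task computation — a property the test suite checks — and for
realistic parameters it preserves the sign and ordering of metabolic
changes, which is what the classification uses.

## The synthetic phantom

The phantom exists so every stage can be validated by parameter recovery.
Geometry is a cortical-shell ellipsoid: a gray-matter (GM) ribbon around a
white-matter (WM) core, on a 32×32×16 grid by default. Per subject,
GM baseline fields of R2', CBV, CBF and T2 are drawn as cohort mean +
between-subject deviation + voxelwise spatial variation; OEF is then
*derived* from R2' and CBV through the oxygenation equation and CMRO2
through Fick's principle, so both identities hold to machine precision on
every ground-truth map.

Key defaults and the reasoning behind them:

* **Cohort means** R2' 5.3 s^-1^, CBV 4.8 %vol, CBF 44.5 ml/100g/min, with
  between-subject s.d. 0.4, 0.2 and 7.2 — the gray-matter population values
  the pipeline is expected to recover.
* **Physiology** Hct 0.375, O~2~sat 0.98. The triple (R2', CBV, OEF) is
  mutually consistent under the oxygenation equation only at this
  hematocrit; with it, ground-truth OEF averages 0.390. Note that cohort
  CMRO2 given R2', CBV, CBF and saturation is independent of Hct (it
  cancels between the oxygenation equation and arterial oxygen content).
* **T2** GM 75 ms, WM 65 ms — typical 3 T cortical values; the source
  protocol does not report them. T2\* follows by inverting the R2'
  definition, which guarantees T2\* ≤ T2.
* **Within-map spatial s.d.** (R2' 0.6, CBV 0.35, CBF 3, T2 3) are
  assumptions, not reported values. They are set so the baseline spatial
  variance structure matches the empirically observed partitioning of
  CMRO2 variance: extraction-dominated (OEF share largest), flow second,
  volume near zero and negatively correlated (CBV enters OEF in the
  denominator).
* **WM CBV is homogeneous at 2.5 %vol** — it is the DSC normalization
  anchor, so the pipeline's WM-median rescaling is exact by construction.
* **Effects.** Two voxel populations inside GM, with footprints and
  amplitudes drawn at the *cohort* level (all subjects activate the same
  voxels, as in a group study): a canonical population (ΔCMRO2 +3.1%,
  n-ratio 2.1, hence ΔCBF +6.51%) and a discordant population
  (ΔCMRO2 +1.68%, ΔCBF −0.47%). ΔOEF always solves the Fick ratio
  identity exactly. Each voxel's amplitudes are scaled by a factor uniform
  in [0.75, 1.25] so responses span a realistic range and per-class
  regressions are non-degenerate. Designed BOLD amplitudes come from the
  Davis forward model, and the generator verifies exhaustively that
  canonical voxels have sign(ΔBOLD) = sign(ΔCMRO2) and discordant voxels
  the opposite.
* **Noise** is Gaussian on magnitude signals (adequate at SNR ≥ 50;
  Rician corrections matter only at low SNR), with per-modality SNR
  defaulting to 100. For pCASL the noise s.d. is referenced to the mean
  perfusion-weighted difference signal rather than M0: with four
  background-suppression pulses the static signal is largely suppressed,
  and the difference-signal SNR is what the averaged modality delivers.
* **BOLD runs** default to sixteen 30-s blocks at TR 1.2 s (400 volumes,
  the full task-run length of the emulated protocol). The block response
  is a double-gamma convolution expressed in the analysis-window metric
  (task-window median 1, baseline-window median 0), so the designed
  amplitude *is* the windowed percent-signal-change contrast; the raw
  convolution overshoots slightly within the window and would otherwise
  bias recovery by construction rather than by noise.

What the phantom does **not** emulate: motion, susceptibility-induced
field gradients and dropout, contrast-agent leakage, physiological noise
spectra, arterial transit delays, partial-volume mixing along the GM/WM
boundary, and anatomical topology (no atlas, no cerebellum). Passing
recovery tests therefore demonstrates correctness of the estimation chain
under the stated signal model — not robustness to these real-world
artifacts, which the emulated protocol handles with dedicated corrections
upstream.

## Statistics

**Percent signal change** pools, per condition, the analysis window of
each block — the 24 s after discarding the first 6 s (20 of 25 TRs) — and
contrasts pooled medians, task vs baseline.

**Mean-centered PLS.** Condition means (averaged over subjects) are
column-centered by the grand mean and decomposed by SVD. Latent-variable
significance uses permutation of condition labels within subject (default
3000); voxel reliability uses bootstrap resampling of subjects (default
3000) summarized as bootstrap ratios (BSR = observed salience / bootstrap
s.e.), with bootstrap saliences sign-aligned to the observed latent
variable before accumulation (SVD sign indeterminacy). Permutation p is
reported as (1 + #{permuted ≥ observed})/(1 + nperm), so it is bounded
away from zero; with two conditions the identity and global-flip
permutations tie with the observed value, which floors the attainable p.
Tests use reduced resampling counts (tens to hundreds) purely for speed;
the estimators are count-independent.

**GLM z maps** regress each voxel on the convolved task boxcar plus
intercept, linear drift and optional confounds; the task t statistic is
Gaussianized to z, with |z| > 2.5 as the single-subject significance
convention. **Clusters** are 26-connected supra-threshold components
(threshold ±3, minimum extent 1000 voxels for anatomical clusters, 30 for
slice displays), labeled separately per sign.

**Classification.** Among voxels with significant BOLD responses:
concordant if sign(ΔBOLD) = sign(ΔCMRO2), discordant if opposite, excluded
if ΔCMRO2 is exactly zero (sign undefined). Conjunction classes across two
tasks are concordant-only / discordant-only / mixed / excluded. Quality
control retains voxels with GM probability ≥ 0.5, T2 ≤ 90 ms,
R2' ≤ 9 s^-1^, CBV ≤ 10 %vol, OEF ≤ 0.9 and CBF ≤ 90 ml/100g/min; the
temporal-SNR rule drops voxels falling in a subject's lowest 15th
percentile for strictly more than two-thirds of subjects ("more than 66%"
read strictly, with a 10^-9^ epsilon at the boundary).

**Variance partitioning.** Baseline (CMRO2 ~ OEF + CBF + CBV) and
task-change (ΔCMRO2 ~ ΔOEF + ΔCBF) regressions report two overlapping
decompositions per predictor: the product measure (standardized beta ×
zero-order correlation, normalized by R²) and the squared semi-partial
correlation. The product measure can exceed 1 or go negative for
correlated predictors — which is precisely why both are reported and
neither is claimed as canonical. In the baseline model a zero-variance
predictor is an error; in per-class Δ models a constant predictor simply
receives share 0 (a class can legitimately have no extraction change).

## Numerical choices

* Relaxometry uses weighted log-linear least squares (weights = squared
  signal): deterministic, initialization-free, exact on noiseless data,
  and unbiased to first order at the phantom's SNR. Voxels with
  non-positive signals or non-negative slopes are invalid rather than
  clamped.
* The DSC bolus window is the contiguous run of frames around the peak of
  the mean ΔR2\* curve exceeding 5% of its peak; integration is
  trapezoidal. The WM reference uses the median for robustness.
* The ASL quantification constants are the consensus single-compartment
  values; they are configurable because the emulated protocol cites the
  consensus recommendation without printing constants.
* Alpha estimation regresses log CBV ratios on log CBF ratios *through
  the origin*: the power law forces both logs to vanish at baseline.
  Subject M estimation takes the median of voxelwise ratios, guarding
  against near-singular Davis denominators; voxels with |denominator|
  ≤ 10^-6^ are ineligible.
* Validity is an explicit per-voxel flag everywhere; sentinel values are
  never used. Masking composes by logical AND and is idempotent.
* All randomness flows from explicit seeds: phantom cohorts derive
  per-subject, per-modality seeds from the cohort seed, and both PLS
  resampling loops take a mandatory logged seed, so every run is
  bit-reproducible.

## Problem sizes

The validation suite runs cohorts of 20 subjects on the 32×32×16 grid for
parameter-recovery and classification checks (about 3700 GM voxels per
subject, full relaxometry/ASL/DSC fitting in seconds per subject, BOLD
runs of 400 volumes), and smaller 16×16×8 cohorts for per-module checks.
Monte-Carlo nulls use 10^3^–2×10^4^ replicates. These sizes make every
property testable in minutes on one core while keeping group-level effects
well resolved.

## Limitations

The semiquantitative task path linearizes the BOLD–R2' relation; with
generation parameters far from its agreement limit it attenuates ΔCMRO2
magnitudes (signs and class labels are preserved, which is what the
concordance analysis consumes). The product-measure variance shares are an
overlapping decomposition, not a partition. The phantom's white noise has
no spatial or temporal autocorrelation, so GLM and PLS error rates here
are best-case. Cohort-level empirical fractions (e.g. what proportion of
real cortex responds discordantly) depend on real data and are outside
what a phantom can certify.
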
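---
title: "Quantifying blood–CSF-barrier water delivery from multi-TI FAIR-ASL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood–CSF-barrier water delivery from multi-TI FAIR-ASL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcsfbasl)
library(dplyr)
```

## The measurement

The choroid plexus, the epithelial tissue lining the brain's ventricles,
secretes CSF and forms the blood–CSF barrier (BCSFB). Its function can be
probed without contrast agents by FAIR arterial spin labelling at an
ultra-long echo time: a global inversion labels arterial blood water, a
slice-selective inversion provides the control condition, and at
TE = 220 ms essentially only long-T2 ventricular CSF retains signal, so
the label that appears in the ventricular ROI is water that has crossed
the BCSFB. Sampling the pairwise difference ΔM over inflow times
TI = 200, 200, 750, 1500, 2750, 4000, 5000, 6000 ms traces the delivery
kinetics. A conventional short-TE protocol
(TI = 200–4000 ms, five repetitions) measures tissue perfusion in
cortex, hippocampus and midbrain in the same animals.

This package implements the full quantification chain for both protocols
plus the study machinery around it (volumetry, behaviour scoring,
statistics, ex-vivo CP volumetry), and a generator that synthesises every
input the chain consumes.

## Models and assumptions

**Inversion recovery.** The control (non-selective) signal per ROI follows
$M_c(TI) = M_0\,(1 - 2 e^{-TI/T_1})$, assuming complete inversion and
full relaxation between acquisitions (the protocols use 10–12 s recovery
periods against T1 values of 1.8–3.9 s). Fitting this per subject gives
M0 and T1 of tissue (short TE) or CSF (ultra-long TE).

**Tissue perfusion.** ΔM from the standard protocol is fitted with the
general single-compartment Buxton kinetic model. Two assumptions are
specific to this implementation:

* *Unbounded bolus.* FAIR with a global labelling pulse inverts the whole
  animal, so there is no trailing bolus edge within the 4 s TI range; the
  bolus duration is treated as infinite.
* *Transit delay fitted.* Whether the study fitted an arterial transit
  delay is not stated. We fit it as a bounded free parameter (tissue:
  0–0.5 s; BCSFB: 0–1 s) with an option to fix it, because a fixed-zero
  delay biases CBF when the true delay is nonzero, while on clean data the
  free fit recovers the truth exactly.

**BCSFB water delivery.** The ultra-long-TE ΔM is fitted with a
two-compartment adaptation: labelled water relaxes with blood T1 before
exchange and CSF T1 after, and no outflow occurs on the experiment's time
scale. The fitted rate is converted to a total delivery W in µL/min
across the lateral ventricles via the anatomically measured ventricular
volume, after normalising the ROI M0 by the volume ratio
$M_{0,corr} = M_{0,CSF} V_{vent}/V_{ROI}$ (the 12-voxel functional ROI
spans 11.25 mm³, far more than the ventricles themselves, so M0 is
heavily partial-volumed). Both kinetic closed forms are verified in the
test suite against numerical quadrature of their defining convolution
integrals (tolerance 1e-8 over randomised parameter sets), and both use a
guarded series branch when the two relaxation rates coincide within
1e-9 s⁻¹ to avoid catastrophic cancellation.

**Fixed constants.** Values the models need but the data cannot identify
are housed in `kinetic_defaults()` and are configurable everywhere:
arterial blood T1 2.4 s (typical mouse blood at 9.4 T), partition
coefficient λ = 0.9 mL/g, inversion efficiency α = 1, tissue density
1 g/mL. The generator's default transit delays are 0.2 s (tissue) and
0.3 s (BCSFB).

**Optimisation.** All fits are bounded Levenberg–Marquardt least squares
(`minpack.lm`) with tight tolerances (1e-12 on cost and step), a
deterministic data-driven start (M0 from the signal extremum, T1 from the
null-crossing TI / ln 2), and an optional seeded multi-start. On
noise-free forward-model data every fitter recovers its generating
parameters to well under 0.1%; non-convergence is flagged on the returned
object, never silent. An all-zero ΔM series short-circuits to a zero
estimate with a warning flag rather than an optimiser failure.

## The synthetic cohort

Because the in-vivo data are not deposited, the generator *is* the study
population for all tests:

* **Group structure**: 71 subjects — control n = 10, 7, 7, 7 and 3xTg
  n = 10 at 8, 14, 20, 32 weeks.
* **Parameter distributions**: per-cell normal draws truncated at zero,
  with means set to the published group summaries (water delivery
  0.55–1.39 µL/min, CSF T1 3.31–3.89 s, ventricular volume
  1.02–1.89 mm³, regional CBF 167–267 mL/100 g/min) and SDs
  reconstructed as SEM·√n from the printed SEMs. Truncation shifts the
  large-SD cells' means upward by up to ~3%; the recovery tests therefore
  compare against the truncated-normal mean, not the nominal one.
* **Raw signals**: the generator emits label/control pairs per TI and
  repetition (5 standard, 10 BCSFB, including the genuine duplicate
  200 ms BCSFB acquisition). The control signal carries Gaussian noise at
  1% of M0 (per averaged TI); the difference carries noise at a per-TI
  SNR of 10 relative to the curve peak. Neither noise level is printed in
  the study, so both are explicit configuration. Noise is injected so
  that each knob controls its own averaged series exactly (the difference
  noise rides on the selective condition only); real thermal noise is
  common to both conditions, which matters only if the two SNR knobs are
  set inconsistently.
* **Behaviour**: arm entries follow a two-state Markov generator whose
  alternation probability is solved from the target %SA via
  $E[\%SA] = 200p^2/(1+p)$. Entries and %SA at 20/32 weeks use the
  published values (including the 3xTg locomotion deficit); 8/14-week
  cells, which the study does not tabulate, are set to control-like
  values since deficits emerge only from 20 weeks.
* **Anatomy**: ventricle masks are compact voxel sets on the
  200×160×6 anatomical grid (0.004 mm³ voxels) realising each drawn
  volume to the nearest voxel. Ex-vivo phantoms are Rayleigh noise fields
  (σ the scale) with an ellipsoidal ventricle mask and a connected
  Rician bright cluster of the requested CP volume at 0.05 mm isotropic
  resolution.

What the generator does *not* emulate: anatomy beyond geometric
compartments, motion and physiological noise, partial-volume mixing
beyond the TE-based compartment isolation, k-space/EPI artefacts, or
inter-parameter correlations within subjects (draws are independent).
Passing recovery tests therefore demonstrate correctness of the
estimators under the stated noise model, not robustness to everything
real data can do.

## Statistics

Group comparisons per variable and time point use Mann-Whitney tests for
MRI variables and Welch's t for behaviour (the study chose per-variable
tests after Shapiro-Wilk screening; we fix the mapping in configuration
rather than re-running normality gates, so the test choice is
deterministic). Benjamini-Hochberg FDR control at 5% is applied within
two explicit families — all MRI comparisons, and separately all behaviour
comparisons. The two-way genotype × age ANOVA uses Type III sums of
squares on sum-to-zero contrasts (via `car::Anova`), appropriate for the
unbalanced design; with the study's group sizes the genotype effect has
1 and 63 degrees of freedom. `anova_from_summary()` reproduces the same
table from per-cell (mean, SEM, n) summaries by building a surrogate
dataset with exactly those sufficient statistics — useful for checking
published tables, exact up to the printed rounding. Sidak post-hoc
comparisons pool the residual mean square over the 16 default cell
pairings (4 between-genotype, 12 within-genotype).

A ventriculomegaly screen excludes subjects whose ventricular volume
exceeds 3× their (genotype, age) group mean, computed leave-one-out so a
gross outlier cannot mask itself. The study reports excluding one animal
at ~4× the group average without stating a threshold; 3× is our
conservative default and is configurable.

## Choroid-plexus volumetry

Inside a ventricle mask of a high-resolution magnitude image, free fluid
is Rayleigh-distributed noise and the choroid plexus is a bright mode.
The scale σ is estimated by maximum likelihood for a *truncated* Rayleigh
distribution on the intensities below the empirical 90th percentile, with
one refinement pass that re-trims at the fitted model's 90% quantile.
(The truncation point enters the likelihood; a naive plug-in estimate on
the trimmed sample would be ~10% biased.) Voxels above the upper 0.1%
quantile of the fitted noise distribution, σ√(−2 ln 0.001) ≈ 3.72σ, are
counted as CP and converted to µL. At the phantom's 8σ contrast both
error sources are small and partially cancel: expected false positives
are ~0.1% of the mask and missed CP voxels ~10⁻⁵. An optional
26-connectivity filter removes isolated supra-threshold voxels but is off
by default, as the reference procedure does not describe one.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at the sizes the
analyses themselves use: 200 replicates for each Monte-Carlo recovery
study (water delivery, CBF, CSF T1), 100 phantoms for CP volumetry, 2000
null simulations for FDR calibration, full enumeration of the
Mann-Whitney null for all group sizes up to 6, and two full 71-subject
cohort quantifications. Tie-breaks and degenerate inputs are handled
explicitly: duplicate TI entries remain independent observations;
identical groups give p = 1; zero-variance Welch comparisons return NA
with a warning; empty masks yield zero volumes with a warning; an empty
design cell is a structural error naming the cell.

## Design choices that were genuinely open

* The ΔM sign convention (selective − non-selective, making delivery
  positive) is a configuration switch, because the acquisition's prose
  labels the conditions inconsistently; the control signal for IR fitting
  is always the non-selective one.
* Repetition pairing for the pairwise subtraction is by repetition index,
  the natural reading of paired label/control acquisition.
* Whether immediate re-entry into the same Y-maze arm counts as an entry
  is not specified; we count it (it affects the %SA denominator), and the
  alternation window is overlapping with stride 1.
* The exact reference procedure for the CP threshold (fitted quantile vs
  σ multiple vs mixture posterior) is not public; we use the fitted
  0.999 quantile, with `tail_prob` exposed.

## Known limitations

ROI-level only (no voxelwise maps), no dispersion or exchange extensions
of the kinetic models, no registration/motion correction, and the
generator's independence assumptions above. The M0 volume normalisation
assumes the anatomical segmentation and the functional ROI see the same
ventricular system; gross segmentation errors propagate linearly into W.
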
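---
title: "Optimizing a white-matter reference region for dynamic brain PET: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing a white-matter reference region for dynamic brain PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmref)
```

## The problem

Reference-tissue quantification of dynamic brain PET divides a target
region's volume of distribution, $V_T$, by the $V_T$ of a reference region
with negligible specific binding, giving the distribution volume ratio
$\mathrm{DVR} = V_T^{\text{target}} / V_T^{\text{ref}}$. For tracers with
high gray-matter (GM) uptake — the motivating case is synaptic density
imaging with an SV2A ligand — white matter (WM) is the natural reference.
The choice of reference *size* is a bias–variance trade-off:

* a small deep-WM region (the classical 2 mL centrum-semiovale template,
  called the CS2mL analogue here) avoids GM spill-in but averages few
  voxels, so its $V_T$ estimate is noisy, and that noise propagates into
  every DVR computed with it;
* a large WM region is statistically quiet but creeps toward cortex, where
  the scanner point-spread function (PSF) mixes GM signal into it, biasing
  $V_T^{\text{ref}}$ upward and DVR downward.

`wmref` implements the full decision pipeline — volume-targeted WM ROI
generation, one-tissue-compartment $V_T$ estimation, DVR and test–retest
variability (TRV) statistics, reference selection, and case–control
comparison — and, because the scans this analysis style is applied to are
not publicly deposited, a synthetic dynamic-PET phantom that generates
every input the pipeline needs.

## Kinetic model

Each region follows the one-tissue compartment model
$$ \frac{dC(t)}{dt} = K_1\,C_p(t) - k_2\,C(t), \qquad V_T = K_1 / k_2, $$
with $C_p$ the metabolite-corrected arterial plasma input (kBq/mL), $K_1$
the influx rate (mL·cm$^{-3}$·min$^{-1}$) and $k_2$ the efflux rate
(min$^{-1}$). The input curve is piecewise linear between samples, so the
convolution $C(t) = K_1 \int_0^t e^{-k_2(t-s)} C_p(s)\,ds$ has an exact
closed form per linear segment; `onetcm_predict()` evaluates it by a
stable cumulative recursion, and frame values are exact *time averages*
over each frame obtained from the compartment ODE
($\int_a^b C\,dt = (K_1\int_a^b C_p\,dt - C(b) + C(a))/k_2$), not midpoint
samples — with frames up to 5 min the midpoint bias would not be
negligible. A dense trapezoidal convolution oracle agrees with the closed
form to better than 0.1% over $K_1 \in [0.01,1]$, $k_2 \in [0.01,0.5]$.

`fit_onetcm()` minimizes the weighted residual sum of squares with frame
durations as default weights (a uniform-variance-per-unit-time proxy;
uniform weights are available). Because the model is linear in $K_1$, that
parameter is profiled out in closed form and the optimization is a
deterministic one-dimensional search over $k_2$: a 30-point log-spaced
grid on $[10^{-4}, 2]$ min$^{-1}$ followed by golden-section refinement,
with $K_1$ clamped to $[10^{-4}, 5]$. This variable-projection scheme
needs no starting values and no restarts, cannot diverge, and is fully
deterministic; a fit that pins either parameter at a bound is flagged
`converged = FALSE` and its $V_T$ set to `NA`. No blood-volume fraction
and no delay/dispersion correction are modelled: the two-parameter model
is both the generator and the estimator, which keeps parameter recovery
interpretable (noise-free recovery is exact to <0.5% across the tested
grid). Standard errors come from the Gauss–Newton curvature at the
optimum.

## Outcome measures

Signed test–retest variability between paired scans is
$$ \mathrm{TRV} = \frac{\text{retest} - \text{test}}
   {\text{test} + \text{retest}} \times 200\%, $$
antisymmetric under swapping the pair and bounded in $(-200, 200)$ for
positive inputs. All summary SDs use the $n-1$ sample convention. The
GM-averaged TRV is computed *within subject first* (mean over the 12
evaluated GM regions, one value per scan pair) and then summarized across
subjects; pooling all region-level records first would mix within- and
between-subject variance and is deliberately not done. %CoV is
$100 \cdot \mathrm{SD}/\mathrm{mean}$.

Group comparison uses the pooled-variance two-tailed unpaired $t$ test
(Welch behind a flag), percent difference
$100\,(\bar{x}_{\text{HS}} - \bar{x}_{\text{PD}})/\bar{x}_{\text{HS}}$
with the control group as denominator, and classical pooled-SD Cohen's
$d$ without small-sample correction. No multiple-testing correction is
applied across the three disease regions; the per-region $p$ values are
reported as such. `sample_size()` inverts the noncentral-$t$ power
condition exactly (smallest integer $n$ reaching the target power), for
two-sample and paired designs; at effect size 1, $\alpha = 0.05$, power
0.80 it returns the textbook $n = 17$ per group.

## ROI construction

`make_wm_map()` binarizes the cerebral-WM label and smooths it with an
isotropic Gaussian kernel (FWHM 10 mm by default;
$\sigma = \mathrm{FWHM}/2.3548$ converted to voxels per axis, truncated at
$3\sigma$, renormalized, zero padding outside the head).
`threshold_to_volume()` selects the highest-map-valued voxels until the
target volume is reached; this equals thresholding at the map value of
the last included voxel, with ties broken by lexicographic voxel index so
the target voxel count is hit exactly (achieved volume within half a
voxel whenever enough positive voxels exist). The full series (0.5, 1, 2,
5, 10, 20, 45, 100, 200 mL) is cut from one voxel ordering, so the masks
are nested by construction and their thresholds decrease monotonically.
The pipeline performs no resampling: all masks and images live on the
phantom grid, with world coordinates carried by the NIfTI affine on IO.
Template-space registration is out of scope, so the small-reference
standard is not re-derived from an atlas; the pipeline accepts any
user-supplied small mask, and the phantom provides a fixed 2 mL deep-WM
sphere as its analogue.

## The phantom: what it emulates and what it does not

`phantom_spec()` describes a 90³ grid of 2 mm isotropic voxels (desk
scale; configurable). The anatomy is deliberately schematic but carries
the features the analysis is sensitive to:

* **WM thickness structure.** Cerebral WM is the shell between an outer
  ellipsoid and a ventricular (CSF-like, $V_T$ 0.4) interior — a sheet of
  roughly 10 mm everywhere except a thick dorsal pocket, the centrum
  semiovale, where the 2 mL reference analogue sits at least ~6 mm from
  any boundary. Real convoluted WM is a 2–5 mm sheet imaged at ~2.5–3 mm
  resolution; at desk scale the same regime (sheet thickness ≈ PSF FWHM)
  is obtained with a 10 mm sheet and a 9 mm PSF, which is why 9 mm is the
  default `psf_fwhm_mm`. Because the sheet is thinner than the 10 mm
  map-smoothing kernel, only the pocket produces high smoothed-map
  values: small thresholded ROIs stay clean, large ones are forced toward
  cortex. This is the mechanism behind the monotone $V_T$-bias-versus-size
  curve, with the 10% bias crossing between 20 and 45 mL under the
  defaults.
* **Parcellation.** A cortical shell (six cortical + two cingulate
  sectors) surrounds the WM; deep nuclei (putamen, thalamus, caudate,
  hippocampus, entorhinal, amygdala, substantia nigra) border the
  ventricular interior or pierce the sheet; a brainstem exits through the
  open inferior pole. Any two explicitly placed structures overlapping,
  or an empty region, or WM below 250 mL (the 200 mL ROI must remain
  constructible) is a specification error naming the offending region.
* **Kinetics.** Default ground truth: WM $V_T$ 4.3 mL/cm³ (a realistic
  deep-WM value for a high-uptake SV2A-like tracer), GM $V_T$ 12.5–21
  (2.9–4.9× WM), CSF 0.4. The input function is a linear rise to a peak
  at 1.5 min followed by a three-exponential decay (Feng-style), sampled
  densely; the default frame schedule is 6×0.5, 3×1, 2×2, 10×5 min
  (21 frames, 60 min). Neither the acquisition timing nor the plasma
  shape of the emulated study is published; these are stand-ins chosen
  once as conventional values, not reconstructions.
* **Noise.** Voxel noise is zero-mean Gaussian with
  $\mathrm{SD} = \texttt{noise\_scale}\sqrt{C(t)/\Delta t}$, applied after
  the PSF — a count-statistics proxy reproducing the
  shorter-frame/hotter-voxel structure, with decay correction assumed
  already applied. `noise_scale = 18` makes the 2 mL reference's $V_T$
  fit CV ≈ 6% and the 10 mL ROI's ≈ 2.6%, the scale implied by published
  test–retest SDs for this tracer class.
* **Cohort structure.** Test–retest subjects are scan *pairs* (the
  emulated study's 24 subjects contributed 30 pairs; the generator treats
  each pair as a synthetic subject): 10 same-day and 20 longitudinal
  pairs, the latter stratified 4/5/11 over 7–30, 30–365 and 365–1028
  days. Disease subjects get one scan with $V_T$ scaled by
  $1-\texttt{pd\_effect}$ (default 0.10) in substantia nigra, caudate and
  brainstem only.
* **Variance components.** All biological and instrumental variability is
  multiplicative lognormal on $V_T$ via $K_1$ ($k_2$ fixed):
  per-region-independent between-subject (CV 0.08) and within-subject
  test–retest (CV 0.025) factors, plus *global* per-subject (CV 0.05) and
  per-scan calibration (CV 0.06) factors. The global factors cancel
  exactly in DVR — precisely the argument for DVR over $V_T$ — so the
  generator reproduces $V_T$ TRV SD ≈ 9–10% alongside much smaller DVR
  TRV for large references. Defaults were fixed at design time to
  reproduce the published scale of $V_T$ %CoV (~12%) and DVR TRV
  (≈18%/6%/4% SD for 0.5/10/100 mL references).
* **Reproducibility.** One master seed; per-subject/per-scan substreams
  are derived by a fixed arithmetic counter scheme
  (`master*2654435761 + subject*1000003 + scan*10007 + purpose*97`, mod
  $2^{31}-1$), so adding subjects never perturbs existing ones, and every
  stage is bit-reproducible given the seed.

Not emulated: realistic cortical folding, attenuation/scatter/randoms,
motion, head-size variation, MR segmentation error. Passing tests on this
phantom show the *pipeline* behaves correctly and that the published
phenomena follow from the stated mechanisms (spill-in, voxel-count noise,
variance cancellation in DVR); they do not certify performance on real
scanner data.

## The ROI-level simulation shortcut

Replicate experiments (power curves, null calibration) would waste most
of their time realizing 4-D images. Because the forward model is linear,
the ROI mean of any noise-free image equals $A \cdot T$, where $T$ is the
region × frame matrix of noise-free TACs and
$A[\text{roi}, r] = \text{mean over roi of } \mathrm{PSF}(\mathbf 1_r)$
is a cross-talk matrix computed once per phantom/PSF
(`roi_crosstalk()`). And because voxel noise is added after the PSF,
independently per voxel, the induced noise on an ROI mean is exactly
Gaussian with SD $\texttt{noise\_scale}\sqrt{\bar C/\Delta t}/\sqrt{n}$.
`simulate_roi_tacs()` therefore reproduces the voxel-level pipeline's ROI
TACs *in distribution* exactly (and bit-exactly when noise-free — this is
tested). Image-level simulation remains available everywhere
(`method = "image"`).

## Numerical choices and degenerate inputs

* Threshold ties: higher threshold first (smaller ROI), then
  lexicographic voxel index; documented because no rule is standard.
* Input before the first plasma sample is 0; after the last sample the
  curve decays at the rate fitted from the last two samples (flat if not
  decaying).
* $k_2$ underflow guard: the vectorized convolution recursion falls back
  to a sequential loop if $e^{-k_2 t}$ underflows (unreachable within the
  fit bounds).
* Failed reference fits invalidate all DVRs of that scan (logged);
  failed target fits invalidate only that region. Failures are recorded,
  never dropped silently.
* TRV is undefined (error) when test + retest = 0; %CoV requires a
  nonzero mean and $n \ge 2$; summary cells with fewer than 2 records
  are omitted with a warning.
* `group_compare()` flags degenerate (zero pooled variance) comparisons;
  identical but non-constant groups give $d = 0$, $p = 1$.

## Known limitations

* The bias–variance regime is reproduced by geometric scaling (10 mm
  sheet / 9 mm PSF), not by simulating HRRT-resolution anatomy; absolute
  bias percentages are therefore phantom-specific even though the shape
  and ordering of the curves match the published ones.
* The substantia nigra ROI is small (~1.2 mL), so under the independent
  voxel-noise model its DVR carries substantial fit noise. One published
  phenomenon — the *systematic* superiority of the 10 mL reference's
  Cohen's d over the 2 mL reference's in repeated experiments — does not
  replicate under this (or any physically coherent) noise model: the two
  effect sizes share subjects and target noise, and the reference-noise
  difference shifts their expectation by far less than their paired
  sampling spread at n = 12 + 12. The corresponding acceptance check is
  left failing by design rather than forcing it with an implausible
  generator; the pipeline reports both effect sizes so the comparison
  remains auditable.
* Longitudinal TRV has no extra drift component beyond the same-day one,
  consistent with the emulated study's finding that TRV did not change
  with interscan interval; age- or disease-progression effects are not
  modelled.
* The sample-size analysis is reported in two conventional variants
  (two-sample on intersubject %SD; paired on test–retest SD) because the
  emulated analysis does not state its test family, $\alpha$, power, or
  which SD it used. Defaults ($\alpha = 0.05$ two-sided, power 0.80) are
  configurable and no attempt is made to reverse-engineer the published
  subject counts.

## Problem sizes used by the shipped analyses

The analysis drivers and tests run the phantom at its default 90³/2 mm
resolution; test–retest summaries use 10–30 scan pairs, replicate
experiments 100 replicates of 12 + 12 subjects (ROI-level shortcut), and
the null calibration 400 replicates — sizes chosen so the full pipeline
remains a minutes-scale desk computation while keeping Monte-Carlo error
well below the effect sizes being checked.
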
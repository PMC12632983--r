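# wmref — white-matter reference-region optimization for dynamic brain PET

`wmref` is an analysis pipeline for choosing the size of a white-matter
(WM) reference region in reference-tissue quantification of dynamic brain
PET, motivated by synaptic density (SV2A) imaging, where gray matter (GM)
uptake is high and WM provides the low-binding reference.

The outcome measure is the distribution volume ratio
**DVR = V<sub>T</sub><sup>target</sup> / V<sub>T</sub><sup>ref</sup>**,
with regional V<sub>T</sub> = K<sub>1</sub>/k<sub>2</sub> estimated by a
one-tissue compartment model

&nbsp;&nbsp;&nbsp;&nbsp;dC/dt = K₁·C_p(t) − k₂·C(t)

fit to frame-averaged time–activity curves against an arterial input
function. Reference size trades bias against variance: a tiny deep-WM
sphere (the classical 2 mL centrum-semiovale template, "CS2mL analogue")
avoids GM spill-in but is statistically noisy; a large WM ROI is quiet but
creeps toward cortex, where the scanner point-spread function mixes GM
signal in. The pipeline quantifies both arms of the trade-off:

* **ROI builder** — binarize the cerebral-WM segmentation, smooth with a
  10 mm FWHM Gaussian, threshold the map to exact target volumes
  (0.5–200 mL, nested by construction);
* **Kinetics** — exact closed-form 1TCM prediction for piecewise-linear
  inputs and a deterministic variable-projection weighted fit;
* **Quantify** — DVR per reference, signed test–retest variability
  TRV = (retest − test)/(test + retest) × 200%, GM-averaged
  within subject first, mean ± SD and %CoV summaries;
* **Evaluate** — reference bias table (percent V<sub>T</sub> difference
  from the 2 mL standard, <10% selection criterion), largest-passing
  reference selection, TRV-versus-interscan-interval regression,
  pooled-t / Cohen's d / percent-difference group comparison, and a
  noncentral-t sample-size calculator;
* **Synthetic data** — a digital brain phantom (thin WM sheet + thick
  centrum-semiovale pocket between cortex and ventricles, deep nuclei,
  brainstem) with region-wise 1TCM kinetics, Gaussian PSF spill-in,
  count-like frame noise, and test–retest / case–control cohorts, so the
  whole pipeline runs end to end without any scanner data.

## Worked example

The numbered drivers under `analysis/` run the full study on the synthetic
cohort (30 test–retest pairs, 20 disease subjects) and write tables under
`results/`:

```sh
Rscript analysis/01_phantom_and_rois.R
Rscript analysis/02_reference_bias.R 1
Rscript analysis/03_test_retest.R 1
Rscript analysis/04_pd_comparison.R 1
```

Stage 1 prints:

```
Phantom: 90x90x90 voxels at 2 mm; cerebral WM 268 mL.
All 9 WM reference ROIs hit their target volume within 0.240 mL (one voxel).
Deep-WM 2 mL analogue: 2.24 mL.
```

Stage 2 tabulates first-scan mean V<sub>T</sub> per reference (seed 1):
the 2 mL analogue averages 4.22 mL/cm³ with %CoV 11.9, and the percent
difference from it grows with ROI size — +5.4% at 10 mL, +8.9% at 20 mL,
+12.0% at 45 mL, +22.8% at 200 mL — the spill-in arm of the trade-off.
Stage 3 shows the variance arm: the SD of GM-averaged DVR TRV over
longitudinal pairs falls from 11.8% (2 mL analogue) to 5.9% (10 mL WM ROI)
to 4.0% (100 mL), and the interscan-interval regressions are flat (p ≥
0.7) with residual sums of squares shrinking as the reference grows (1921
→ 528 → 380 for 2 mL → 10 mL → 45 mL). The selection rule — largest ROI
within 10% V<sub>T</sub> of the small standard — lands on the 10–20 mL
range depending on the draw. Stage 4 compares disease vs control DVR in
substantia nigra, caudate and brainstem with both the selected and the
2 mL reference (percent difference, t, p, Cohen's d, per-group %SD) and
converts the measured variability into sample sizes.

The same machinery is available programmatically:

```r
library(wmref)
cp  <- simulate_input_function()
sch <- default_frame_schedule()
y   <- onetcm_predict(K1 = 0.3, k2 = 0.06, cp, sch)   # VT = 5
fit_onetcm(y, cp)
#> 1TCM fit: K1 = 0.3000, k2 = 0.06000, VT = 5.000 (converged)
```

`run_pipeline(default_config(seed = 1))` executes every stage in one call
and writes a manifest with per-file checksums; identical config and seed
give byte-identical tables.

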
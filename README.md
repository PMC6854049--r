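# emmscar

Multimodal fusion of left-ventricular **electromechanical mapping (EMM)**
with **cardiac MRI**, and a **myocardial scar prediction model** built on
the fused data.

## The problem

During catheter procedures (VT ablation, intramyocardial injection of
regenerative therapeutics, biopsy), operators must distinguish infarcted
from healthy myocardium *intra*-procedurally.  Late gadolinium-enhanced
MRI (LGE-MRI) is the gold standard for scar imaging but is rarely
available in the cath lab, whereas electroanatomical/electromechanical
mapping (NOGA-style) is: it records unipolar voltage (UV, mV), bipolar
voltage (BV, mV), local linear shortening (LLS, %) and local activation
time (LAT, ms) at 3-D-localized endocardial points.  `emmscar` implements
the complete analysis that ties the two modalities together and asks how
well the four catheter parameters jointly predict MRI-defined transmural
scar.

## What the package does

1. **Synthetic LV studies with known ground truth** (`simulate_study`):
   truncated prolate-spheroid ventricles, an apicoseptal mostly-transmural
   scar covering ~21% of the endocardium, ~112 EMM points per subject with
   scar-conditioned parameter distributions, per-sector circumferential
   strain curves (healthy/scar medians -26.0% / -15.7%), LGE slice images
   with pixel-level truth, and a rigid EMM-to-MRI misalignment (rotation
   <= 10 deg).
2. **LGE quantification** (`quantify_lge`): full-width-at-half-maximum
   scar segmentation, area-based transmurality (TM) in 80 circumferential
   sectors per slice, wall thickening WT and fractional WT%, and transfer
   of sector values onto mesh vertices.
3. **Strain features** (`strain_feature_table`): peak circumferential
   strain, time-to-peak, tangent-method onset of shortening, and the
   -7.5% akinetic-sector filter.
4. **Registration** (`register_emm`): apex pre-alignment plus iterative
   closest point onto the endocardial mesh with the total rotation clamped
   to 10 degrees; points > 5 mm from the surface or basal of the imaged
   stack are excluded and the registration error (mean +/- SD distance of
   retained points) reported.
5. **Projection** (`match_dataset`): inverse-distance-weighted averaging
   of per-vertex TM/WT/WT% onto each retained point within 5 mm, and
   dichotomization of TM at 50% into the scar label.
6. **Scar model + internal validation** (`fit_scar_glmm`,
   `internal_validation`): random-intercept logistic model on z-scored
   predictors, AIC backward selection, 500-sample bootstrap odds-ratio
   intervals, C-statistic (plus a point-weighted within-subject version),
   random-slope calibration slope, and Harrell optimism correction by
   point-level bootstrap.
7. **EMM-vs-feature-tracking associations** (`assoc_emm_ft`): univariable
   linear mixed models (LLS vs WT/WT%/peak strain; LAT vs onset and
   time-to-peak) with Snijders-Bosker explained variance.

The core model, for point *i* of subject *j* with scaled predictors
*x<sub>ij</sub>*:

> logit P(scar<sub>ij</sub> = 1 | x<sub>ij</sub>, u<sub>j</sub>) =
> b0 + b' x<sub>ij</sub> + u<sub>j</sub>,  u<sub>j</sub> ~ N(0, s<sub>u</sub><sup>2</sup>),

with scar = TM >= 50%, fitted by marginal maximum likelihood
(`lme4::glmer`, Laplace or adaptive Gauss-Hermite).  Predictions for new
subjects use a mean (zero) random intercept.

## Worked example

```r
library(emmscar)

cfg <- run_config(lv = lv_config(n_subjects = 5, seed = 42), n_boot = 50)
rep <- run_pipeline(cfg)
print(rep)
print(rep$or_table)
```

```
run_report (seed 42, 5 subjects)
  points: 536 registered, 67 excluded (12.5%), 463 matched
  registration error 1.68 +/- 1.23 mm
  scar model predictors: uv, bv, lls, lat
internal validation (point-level bootstrap)
  C-statistic           0.954 [0.926-0.968]
  within-subject C      0.947
  calibration slope     0.997 [0.800-1.180]
  optimism-corrected C  0.956, slope 0.918 (n_boot = 50, used 50)
  sens/spec at p >= 0.50: 87.8% / 95.7%
  predictor        or      lower     upper
1        uv 0.1163936 0.06428411 0.1619388
2        bv 0.2320055 0.11835509 0.3592448
3       lls 0.5188315 0.29745378 0.6501357
4       lat 0.6704386 0.50152749 0.8702007
```

Reading the output: of 536 simulated mapping points, 67 fell farther than
5 mm from the registered mesh or basal of the imaged stack; the remaining
points matched MRI values with a 1.7 mm mean surface distance.  All four
EMM parameters survive AIC backward selection.  The odds ratios are per
SD of each predictor — UV is by far the strongest scar marker (OR 0.12
per SD: lower voltage, much higher scar probability), followed by BV,
then the mechanical parameters.  Discrimination is excellent on this
synthetic cohort (C = 0.95) and the optimism-corrected values sit close
to the apparent ones, i.e. little overfitting at ~460 points for 4
predictors.  A calibration slope near 1 means predicted probabilities are
neither over- nor under-dispersed.

`run_pipeline(cfg, outdir = "out", render = TRUE)` additionally writes the
matched-point table, odds ratios, associations, transforms and a JSON
report, plus per-subject scar-truth and prediction maps.  A thin CLI
wrapper lives at `inst/scripts/run_pipeline.R`.

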
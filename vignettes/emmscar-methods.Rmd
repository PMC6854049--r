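---
title: "Methods: multimodal EMM-MRI fusion and scar prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal EMM-MRI fusion and scar prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electroanatomical/electromechanical mapping (EMM) measures local electrical
and mechanical properties of the left-ventricular (LV) endocardium —
unipolar voltage (UV, mV), bipolar voltage (BV, mV), local linear
shortening (LLS, %) and local activation time (LAT, ms) — at catheter tip
positions localized in 3-D.  Late gadolinium-enhanced MRI (LGE-MRI) is the
gold standard for locating myocardial infarction but is often unavailable
during catheter procedures.  `emmscar` implements the full analysis chain
that links the two modalities: quantify scar transmurality and wall
mechanics on the MRI side, register the EMM point cloud to the MRI-derived
endocardial mesh, project the MRI values onto the mapping points, and fit
an internally validated logistic mixed model predicting transmural scar
from the four EMM parameters.  Because the original animal datasets are not
public, the package ships a synthetic LV study generator with known ground
truth; every stage is tested against that truth or against closed-form
oracles.

## The model

For mapping point $i$ of subject $j$, with z-scored predictors
$x_{ij} = (\mathrm{UV}, \mathrm{BV}, \mathrm{LLS}, \mathrm{LAT})$ (pooled
mean/SD over all points, $n-1$ denominator):

$$\operatorname{logit} P(\text{scar}_{ij} = 1 \mid x_{ij}, u_j)
  = \beta_0 + \beta^\top x_{ij} + u_j, \qquad u_j \sim N(0, \sigma_u^2),$$

where scar is LGE transmurality $\ge$ 50% (the boundary value maps to
scar).  The marginal likelihood is maximized with `lme4::glmer`, the same
fitter family used in the original analysis, integrating $u_j$ by adaptive
Gauss-Hermite quadrature (`nagq` nodes) or the Laplace approximation
(`nagq = 1`, the default used for the heavier simulations).  Backward
selection minimizes AIC with a fixed-order tie break (UV, BV, LLS, LAT).
Predicted probabilities for unseen subjects use the fixed effects with the
random intercept at its distributional mean, exactly 0.

Validation quantities are authored in the package and tested against
independent oracles:

* **C-statistic** by the rank (Wilcoxon) identity; a brute-force pairwise
  count is the test oracle, with ties counted one half.
* **Within-subject C**: per-subject C over subjects with both classes,
  weighted by point counts.
* **Calibration slope**: fixed slope $b$ of
  $\operatorname{logit}P = a + b\,\mathrm{LP} + u_{0j} + u_{1j}\mathrm{LP}$
  (random intercept and slope per subject), falling back to a plain
  logistic slope when the mixed fit fails.
* **Optimism correction** (Harrell): individual points are resampled (not
  clusters — 13 subjects are too few for cluster bootstrap), the model is
  refitted, and the mean of (replicate-data metric minus original-data
  metric) over 500 replicates is subtracted from the apparent C and slope.
  Percentile 2.5/97.5 intervals are reported for the odds ratios; replicate
  draws that lose an outcome class are redrawn up to 10 times, then
  dropped and counted.

The univariable EMM-versus-feature-tracking comparisons fit
$y = \alpha + \gamma x + u_j + \varepsilon$ by ML (not REML, so the
variance components of nested models are comparable) and report the
Snijders-Bosker explained variance
$R^2 = 1 - (\sigma^2_{e,\text{full}} + \sigma^2_{u,\text{full}}) /
(\sigma^2_{e,\text{null}} + \sigma^2_{u,\text{null}})$; small negative
values from the ML approximation are flagged rather than clipped.

## Image quantification

**FWHM scar segmentation.** Scar pixels are myocardial pixels with
intensity at or above half of the slice's maximum myocardial intensity.
Two documented edge cases follow directly from the rule: a
constant-intensity myocardium is flagged entirely (every pixel clears its
own half-maximum), and a slice with no hyperenhancement at all would also
be flagged entirely, because half of a noise-level maximum lies below the
remote intensity.  Readers resolve the second case visually; the pipeline
resolves it with an enhancement detector in `quantify_lge()`: a slice is
segmented only when its maximum myocardial intensity is at least 1.8 times
the volume-wide median myocardial intensity (a robust remote reference —
scar occupies a minority of the wall volume).  The per-slice rule (rather
than a single volume-wide threshold) is the default; a manual-correction
hook (`override`) lets callers replace any mask programmatically.

**Sector transmurality and wall metrics.** The myocardium of each slice is
partitioned into 80 half-open angular wedges about the cavity centroid
(counterclockwise from the +x image axis; the origin is a fixed convention,
not an anatomical landmark, since synthetic data have no RV insertion).
Transmurality is the scar-to-myocardium pixel-area ratio per wedge — note
this area-based value for a half-thickness scar is
$(r_m^2 - r_e^2)/(r_p^2 - r_e^2)$, slightly below 50%, because annular
area grows with radius.  Wall thickness is the mean radial
endo-to-epicardial distance along rays from the per-phase cavity centroid
(adequate for convex contours; centerline methods are out of scope), and
wall thickening is the ES-minus-ED difference, also as a percentage of the
ED thickness.  Sector values transfer to mesh vertices by nearest slice
and containing wedge; vertices basal of the most basal slice stay
unassigned and are excluded from projection.

## Registration and projection

The end-diastolic endocardial mesh is lofted from the segmented contours
with a flat apical cap; the apex vertex is the cap pole and the base plane
is the most basal slice plane.  Registration proceeds in two steps, as in
catheter practice: (1) apex pre-alignment — the EMM cloud's apex is the
extremal point along its principal axis on the side with the smaller
transverse spread (the apex is pointed, the base wide), translated onto the
mesh apex; (2) iterative closest point with exact point-to-triangle
correspondences, best-fit rigid updates (SVD/Kabsch), and the cumulative
rotation clamped to 10 degrees about its own axis (a total-angle clamp —
the constraint's per-axis alternative is noted as an open reading), with
the translation re-optimized under the clamped rotation.  The RMS
point-to-surface distance is non-increasing by construction: an iterate
that would increase it (possible once the clamp is active) is discarded
and the best iterate returned.  Points farther than 5 mm from the surface
or basal of the base plane are excluded once, after convergence;
registration error is the mean and SD of the remaining distances.

Projection uses inverse-distance weighting with power 1 (the literal
reading of "inverse distance"; the exponent is configurable) over all mesh
vertices within 5 mm, Euclidean distances, coincident vertices returned
exactly, unassigned vertices never contributing; points with no vertex in
range are unmatchable and counted.  The accounting identity
`matched = registered - excluded - unmatchable` is asserted on every run.

## The synthetic generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs:

* **Geometry.** Truncated prolate spheroid, apex at the minimum long-axis
  coordinate, base plane normal to the long axis at 120 degrees from the
  apex.  Endocardial semi-axes 45 x 29 x 24 mm give an end-diastolic
  cavity volume of ~110.7 ml; end-systolic scaling (0.95 long, 0.75 short)
  gives ~59 ml; wall thickness 8 mm (+3 mm at ES).  The cross-section is
  mildly elliptical on purpose: a circular spheroid is rotationally
  symmetric about the long axis, and the azimuthal component of a rigid
  rotation would be unidentifiable from point-to-surface distances —
  rotation-recovery tests are only well-posed on a non-axisymmetric shape
  (real LV sections are not perfect circles either).  Per-subject size is
  a log-normal factor (SD 0.06).  Slice slabs tile the long axis from half
  a thickness above the apex to 6 mm short of the base; that basal gap
  emulates incomplete MRI coverage, so some EMM points are genuinely basal
  of the mesh and get excluded, as in the emulated study.
* **Scar.** A contiguous apicoseptal patch: transmurality 100% in a core,
  ramping to 0 over a 4-mm border zone (the emulated infarct model is
  mostly transmural).  The core radius is calibrated on the mesh so the
  surface fraction with TM >= 50% matches the subject's target fraction,
  drawn as 0.21 +/- 0.084 between subjects.
* **EMM points.** Sampled uniformly by area on the endocardial mesh
  (~112 +/- 41 per subject, at least 80).  Values are drawn from
  class-conditional truncated normals conditioned on the *true* point
  location (registration error is modelled separately): UV 12+/-3 vs
  6.5+/-2.5 mV, BV 3.5+/-1.2 vs 1.6+/-1.0 mV, LLS 12+/-6 vs 6+/-6 %,
  LAT 0+/-15 vs -6+/-16 ms.  No per-tissue summaries are published for the
  emulated dataset, so these are NOGA-literature-scale choices with UV the
  strongest discriminator; they are configurable.  The cloud is perturbed
  by a random rigid transform (rotation <= 10 degrees, translation <= 5
  mm) plus 2 mm isotropic noise.
* **Strain.** 48 sectors per slice, 30 frames over an 800-ms cycle.  The
  shortening phase is a linear ramp blended C1-smoothly (quadratic) into
  the peak, then a slow linear recovery; onset and peak times are snapped
  to the frame grid.  The linear onset is deliberate: the tangent onset
  estimator (steepest-slope tangent intersected with the pre-shortening
  baseline) is then exact on noiseless curves, so generator/estimator
  round-trips test the estimator rather than a family-specific bias — a
  sigmoidal family (e.g. sin^2) lags the tangent method by
  ~0.18 x (peak - onset) by construction, which would make sub-frame
  round-trip recovery impossible for any onset near the start of a smooth
  S-curve.  Healthy/scar peak amplitudes are drawn so included-sector
  medians sit at -26.0% / -15.7%; 60% of scar sectors are generated
  near-akinetic, which yields ~13% of the LV filtered at the -7.5% rule.
  Scar also contracts 25% less radially at end-systole
  (`scar_akinesis_factor`), coupling scar weakly to wall thickening and
  keeping the EMM-versus-strain R2 values small, as in the emulated data.
* **LGE.** Per-slice intensity grids at 1 mm: remote myocardium 1.0,
  hyperenhancement 2.5x remote over the transmural extent implied by the
  scar field (sub-endocardial inward growth), Gaussian noise SD 0.08, and
  the pixel truth retained.  2.5x (not exactly 2x) keeps the half-maximum
  threshold strictly above remote so noiseless masks equal the truth
  exactly.

Determinism: the master seed lives in the configuration; subject seeds are
`seed + subject index`, and each generator operation derives its own
sub-seed, so any stage is bit-reproducible in isolation.  What the
generator does **not** emulate: image-based feature tracking, MRI physics,
trabeculation/papillary anatomy, non-rigid deformation between modalities,
and real NOGA catheter-contact artifacts.  Passing tests therefore show
the analysis chain is correct and well-calibrated under known truth — not
that the fitted effect sizes transfer to animal or clinical data.

## Numerical choices and degenerate inputs

* Point-to-triangle closest points use the exact region-wise projection
  with a 64-nearest-face-centroid prefilter.
* ICP stops when the RMS improvement falls below `tol` (default 1e-6 mm)
  or at `max_iter` (100); non-convergence returns the best iterate with a
  flag.
* Peak-strain ties resolve to the earliest time; steepest-slope ties on a
  sampled linear ramp resolve to the earliest segment within a 1e-8
  relative tolerance (bitwise noise must not break exact ties).
* Curves with > 20% missing frames are flagged invalid, not interpolated.
* Zero-variance predictors, single-class outcomes, empty myocardium,
  degenerate clouds and out-of-range transmurality raise errors rather
  than propagating.
* IDW averages can overshoot [0, 100] by rounding epsilon; projected
  transmurality is clamped before dichotomization.
* Bootstrap replicates that fail to converge are dropped and counted; a
  report warning appears beyond 20%.

## Problem sizes used in the tests

The test suite runs reduced problem sizes chosen as the smallest that
exercise every code path with stable statistics: structural tests use 2-3
subject cohorts at coarse mesh resolution (24-32 rings), the mixed-model
recovery experiment uses 200 replicates of 13 clusters x 61 points with
15-node quadrature, the optimism null uses 200 bootstrap replicates, and
the determinism check runs the full pipeline twice on a 3-subject cohort
with 15 bootstrap replicates.  The acceptance script runs the full
13-subject default cohort with 200 bootstrap replicates.

## Known limitations

* The onset-of-shortening estimator is one member of the tangent family;
  the exact algorithm referenced by the emulated study's appendix is not
  public, so the implementation is documented, pluggable and not claimed
  identical.
* The akinetic filter reads "mean strain below -7.5%" as peak-shortening
  magnitude below 7.5% (near-zero deformation from poor tracking); a
  curve-mean variant is available via the threshold argument semantics.
* Maximum-likelihood logistic estimates carry a small away-from-null
  O(1/n) bias (~1.5-3% of the coefficient at ~800 points); parameter
  recovery is assessed against Monte-Carlo error with that in mind.
* Sensitivity/specificity default to the 0.5 probability operating point;
  the emulated study does not state its operating point.
* The spatial pairing of EMM points to strain sectors (nearest slice,
  containing wedge) is the simplest consistent rule; the original pairing
  rule is unstated.
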
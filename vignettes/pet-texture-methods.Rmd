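---
title: "Quantifying PET tumor heterogeneity: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PET tumor heterogeneity: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Antiangiogenic agents are cytostatic: a responding tumor may keep its size
and overall FDG uptake early in treatment, so caliper volume and whole-lesion
uptake summaries (mean/max metabolism, metabolically active volume) are weak
early-response markers. What does change is the *spatial organization* of
uptake — vascular remodeling shifts the tumor from a coarse, irregular
metabolic texture toward a finer, more compact one. `pettex` implements a
complete, testable pipeline for detecting that shift in small-animal FDG-PET:
synthetic tumor phantoms with controllable texture, fuzzy three-class tumor
delineation, 64-level quantization, the four canonical 3D texture matrices
(GLCM, GLRLM, GLSZM, NGTDM), a 114-feature radiomic vector, and a two-group
statistical pipeline with correlation-based feature reduction and a
Bonferroni gate.

Because no mouse images are publicly deposited for this design, the phantom
generator is a first-class module: every downstream claim is validated
against generator ground truth.

# The phantom generator

`generate_phantom()` builds one flank-xenograft-like lesion:

1. **Shape.** A sphere of the requested equivalent diameter (default drawn
   uniformly in 6–9 mm, the size at which such xenografts are imaged),
   optionally lobulated by thresholding the radius against a smoothed random
   field scaled by `shape_irregularity`. Voxels are ranked by normalized
   radius and exactly the analytic sphere-volume count is kept, so the mask
   volume is essentially exact at any voxel size (ties on the integer
   lattice are broken at random under the seed).
2. **Zones.** The mask is partitioned into contiguous iso-uptake patches by
   capacity-limited region growth: target sizes are drawn log-normal with
   arithmetic mean `zone_size_mean` (voxels) and coefficient of variation
   `zone_size_dispersion`; growth always advances the zone with the smallest
   relative fill, so realized sizes track the drawn targets. A space-filling
   partition has an intrinsic variability floor (CV ≈ 0.25): requested
   dispersions below that floor are not attainable, which is why the test
   suite checks dispersion fidelity at 0.5 and 1.0.
3. **Uptake.** Each zone receives one of `n_uptake_classes` levels spanning
   [0.5, 1.5] × `tumor_uptake_mean`. Defaults: tumor mean 16 %ID/g over a
   2 %ID/g background. Mean tumor uptake of 14–18 %ID/g is typical of
   FDG-avid colorectal xenografts such as LS174T; background levels are
   rarely reported, so the 8:1 tumor-to-background ratio was chosen once as
   typical for FDG in subcutaneous flank lesions.
4. **Imaging degradations.** Gaussian PSF of FWHM `psf_fwhm` (default
   1.2 mm, about two 0.6 mm voxels, typical of small-animal PET
   reconstruction), then multiplicative Gaussian noise with coefficient of
   variation `noise_cv` (default 5%), clamped at zero. The PSF precedes the
   noise: resolution loss happens in reconstruction, ensemble variability on
   top. Noise is modeled in image space, CV-parameterized, rather than as
   Poisson counts in projection space — the analysis consumes reconstructed
   images and only the texture statistics matter.

Caliper volumes attach a measurement model: the "final" caliper volume is
the mask volume with 5% Gaussian measurement error, and the baseline is
back-computed from a percent-growth draw (defaults 430 ± 120%, matching the
growth scale of untreated LS174T xenografts over two weeks).

**What the generator does not emulate:** sinogram-level physics (scatter,
attenuation, randoms), spatially *correlated* reconstruction noise,
respiratory motion, and intra-zone uptake gradients. The white-noise
simplification matters: see "Known limitations" below.

# Tumor delineation

`segment_flab()` is a deterministic EM-style simplification of the fuzzy
locally adaptive Bayesian family of PET segmentation methods. Three classes
— background, tumor, partial volume — with Gaussian intensity models; the
partial-volume mean is fixed at the midpoint of the background and tumor
means; each voxel's class prior is the mean membership of its
26-neighborhood plus a floor of 0.05, which regularizes labels spatially.
Initialization is Otsu thresholding, so the procedure has no random element.

Numerical choices that matter:

* Class standard deviations are **floored at 0.25× and capped at 0.45× the
  class separation**, and the partial-volume width is fixed at 0.10×. The
  floor prevents a clean class from treating blur-halo voxels as
  "infinitely many sigmas away" (which would hand the entire halo to the
  partial-volume class); the cap prevents one class from swallowing the
  histogram. With these widths the tumor∪partial-volume boundary lands near
  the half-maximum contour, which for a symmetric PSF coincides with the
  true tumor boundary — this is what makes Dice ≥ 0.9 against generator
  truth achievable.
* All widths are relative to the class separation, so hard labels are
  invariant under positive affine intensity rescaling (property-tested).
* The VOI keeps tumor *and* partial-volume voxels (only background is
  discarded, with raw voxel values), and a largest-26-connected-component
  cleanup enforces a single lesion.
* Defaults `max_iter = 100`, `tol = 1e-4` (largest membership change).

This is deliberately *not* the published stochastic-EM FLAB estimator: the
delineation is used as a black box by the analysis, and determinism makes
the pipeline testable end to end.

# Quantization and texture matrices

The VOI is quantized to `Ng = 64` equal-width bins over its own min–max
range: `bin(x) = min(Ng, 1 + floor(Ng (x − min)/(max − min)))`; a constant
VOI maps to bin 1. Min–max binning makes all bin-domain features invariant
to positive affine rescaling of uptake.

Conventions the source literature leaves open, fixed here (and
config-overridable):

* GLCM and GLRLM use the **13 unique lattice directions** at Chebyshev
  distance 1, aggregated by summation before feature computation
  (rotation-robust and stable on small VOIs); GLCM is symmetrized.
* GLSZM zones and NGTDM neighborhoods are **26-connected**.
* Out-of-VOI neighbors are excluded, never padded; runs and zones cannot
  cross VOI gaps.

Each builder is verified by exact equality against an independent
brute-force enumeration oracle on 100 random ≤ 6³ VOIs per run.

# The 114-feature catalog

15 geometric, 6 model-based (fractal), 37 first-order, 21 second-order
(GLCM), 35 higher-order (16 GLRLM + 14 GLSZM + 5 NGTDM). The full roster
with category and unit is `feature_manifest()`. Definitional choices:

* Entropies are log₂ ("bits"); kurtosis is excess; moments are population
  moments.
* Correlation-type features on zero-variance inputs return a documented
  sentinel 0 (never NaN); the NGTDM coarseness of a perfectly flat VOI is
  capped at 10⁶.
* Mask fractal dimension is box counting over edges {1, 2, 4, 8} with
  counts minimized over grid offsets; on a diameter-16-voxel solid ball
  this finite-size estimator reads ≈ 2.67 (the asymptotic limit is 3);
  on a 1-voxel slab it reads 2.0. Local intensity FD uses differential box
  counting in sliding 5³ windows; windows with zero intensity range carry
  FD 0 by convention, so a constant VOI has FD-STD = 0.
* **Size-zone variability (SZV) is provided in two published readings**:
  `glszm_szv_nu`, the zone-size non-uniformity sum `(1/N_z) Σ_s (Σ_i
  Z[i,s])²`, and `glszm_szv_var`, the plain variance of zone sizes. The
  literature's non-uniformity formula *increases* with homogeneous size
  distributions, the opposite of how the quantity is interpreted when "high
  SZV" is read as "patches of many different sizes"; the variance form
  matches that interpretation and the observed treated-vs-control
  direction, so it is the default alias (`szv_form` in `default_config()`).
  Both are always computed; only the configured alias enters group testing,
  since they are two formulas for one reported quantity.

# The statistical pipeline

`run_study()` reproduces the two-group comparison design:

* Conventional metrics (caliper volume, percent growth, metabolic volume,
  mean/max uptake) are always tested and reported separately; they never
  enter the correlation filter.
* Texture features are reduced by **greedy pairwise correlation
  elimination** (pooled-group Pearson, cutoff |r| > 0.8, worst pair first,
  dropping the member with the larger mean absolute correlation; ties go
  against the lexicographically later name; zero-variance features are
  removed first with a warning).
* Per feature: Shapiro–Wilk in each group at α = 0.05; both normal → Welch
  two-sample t-test, otherwise the unpaired **Wilcoxon rank-sum** test.
  (The design under study described a signed-rank test for two independent
  groups of different animals; a signed-rank test requires pairing, so the
  rank-sum test is the defensible reading.) Identical constant groups
  report p = 1.
* The Bonferroni threshold is α_family / m over the retained texture
  features, and the gate uses the value **rounded to one significant
  figure** (0.05/24 → 0.002), mirroring how such thresholds are reported;
  both raw and rounded values are returned.
* Fold change is (treated − control)/control of group means by default
  (`fold_change_center = "median"` switches), so 0 = no change, +1 =
  doubling, −1 = halving.

# The two-arm texture experiment

The headline experiment contrasts a **fine/compact arm** (zone-size mean 5
voxels, dispersion 0.15, spherical) with a **coarse/irregular arm** (mean
30 voxels, dispersion 1.0, lobulated), both at 7.5 mm diameter, identical
uptake distributions, 0.6 mm PSF and 5% noise. Choices and why:

* **Matched volume and uptake** are implemented literally — both arms use
  the same fixed diameter and uptake parameters — so any conventional-metric
  difference is pure sampling noise.
* **PSF 0.6 mm (one voxel) rather than the 1.2 mm used for the segmentation
  fixture.** Zone-size statistics can only discriminate textures whose
  patches survive the blur: at 1.2 mm FWHM the fine arm's ≈ 2-voxel patches
  homogenize into flat plateaus and the fine/coarse contrast inverts or
  vanishes. One-voxel blur is the mildest resolution loss consistent with
  "reconstructed image" and keeps both arms' patches at or above the
  resolution scale. This choice was made from the physics, before freezing
  the acceptance experiment.
* With 64 min–max bins and 5% voxel noise, most iso-intensity zones shatter
  into single voxels in *both* arms; the discriminating signal lives in the
  tail of plateau-sized zones inherited from the coarse arm's large truth
  zones. The observed fold change of the zone-size variance between arms is
  ≈ −0.7 to −0.9 (treated relative to control).

A green direction-of-effect test establishes that the pipeline orders
fine vs coarse textures correctly (higher short-run emphasis, lower
zone-size variance, lower surface-to-volume for the compact arm); it does
not establish effect *sizes* in real animals.

# Known limitations

* **White noise vs correlated noise.** Real OSEM reconstructions have
  spatially correlated noise; white multiplicative noise at 64-bin
  resolution shatters iso-intensity zones maximally, making size-zone
  statistics noisier than on real images. Consequently the per-replicate
  power of the 7-vs-7 zone-variance comparison at the 0.002 gate is
  substantially below 1 (about 0.5 in the frozen world). This is a
  sample-size fact, not an implementation defect: the image-level
  standardized difference saturates near 2–3 once zones shatter, and an
  effect of that size — the same size implied by a p ≈ 0.001 rank test at
  n = 7 — clears a 0.002 gate in only about half of 7-vs-7 replicates. The
  acceptance suite reports this honestly rather than inflating the
  simulated effect.
* The greedy correlation filter, applied to a feature set containing
  several near-duplicate zone-size measures, frequently eliminates the
  headline zone-variance feature in favor of a correlated cousin when the
  group contrast is strong (group separation drives pooled correlations
  above the cutoff). The headline comparison is therefore defined on the
  configured SZV alias plus the conventional metrics; the full
  filter-then-gate pipeline is exercised and tested separately.
* Box-counting FD on 10–15-voxel objects is a finite-size estimate with a
  negative bias of ≈ 0.2–0.3 against the asymptotic dimension.
* Segmentation accuracy is tuned for single well-separated lesions over a
  uniform background; multi-focal uptake or hot adjacent organs are out of
  scope.

# Reproducibility

Every stochastic stage derives its seed from a single study seed;
`pettex run-all --config study.yaml --out DIR` writes byte-identical
summaries for a fixed config and seed. `scripts/acceptance.R --seed N --out
results/acceptance.json` recomputes the acceptance quantities from scratch.
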
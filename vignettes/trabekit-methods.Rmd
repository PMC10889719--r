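---
title: "Methods: reconstruction, morphometry and agreement in trabekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstruction, morphometry and agreement in trabekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models, algorithms and
numerical choices behind each stage, the parameters that matter, and what
the synthetic phantoms do — and do not — establish about real data.

## 1. The phantom: study conditions in code

Every claim the test suite makes is measured on synthetic specimens with
exact ground truth.

**Trabecular volume.** White Gaussian noise on the voxel grid is smoothed
with an isotropic Gaussian kernel of standard deviation
`correlation_length_um / voxel_size_um / 2` and thresholded at the empirical
quantile giving the target mineralized fraction. Quantile thresholding makes
the achieved BV/TV exact up to tie-breaking on a continuous field, and the
correlation length sets the strut/pore scale. Defaults: 11 µm voxels (a
typical specimen-microCT voxel), 30% BV/TV (healthy trabecular range), 44 µm
correlation length (4 voxels — thin but resolvable struts), and 25% of the
mineralized phase relabelled as graft in contiguous blobs of a second smooth
field (grafted sites retain substantial particle load). A lattice family
(`phantom_ball()`, `phantom_hollow_shell()`, `phantom_plates()`,
`phantom_slab()`) complements the random field wherever an analytic answer
is needed; the plate lattice starts and ends with half gaps so the volume
borders are symmetry planes (see §5).

**MicroCT simulation.** Mineralized voxels map to intensity 0.85,
non-mineralized to 0.15; Gaussian blur of 0.7 voxel models the scanner point
spread, additive Gaussian noise of 0.05 sets the signal-to-noise floor, and
the result clips to [0, 1]. At these settings global Otsu re-thresholding
recovers ≥ 98% of mineralized voxels — deliberately good but not perfect.
The 3D blur uses half-sample symmetric reflection at the borders, which
makes the smoothing operator doubly stochastic, so a blur-only simulation
conserves the volume mean exactly.

**Histology simulation.** Sections are cut along the third axis every
`slice_thickness_um` (default 5 µm, the usual microtome setting; the demo
study cuts at the 11 µm voxel pitch so each section has a unique source
plane — how sub-voxel section spacing should stack out-of-plane is left
open and nearest-plane assignment `floor(z/voxel)` is used). Each section is
laid on a canvas larger than the volume cross-section — a real slide always
carries the entire biopsy with empty slide around it — with the margin sized
from the jitter bounds so no tissue can leave the frame. Sections are
coloured with fixed fixture hues (eosin-pink bone, violet graft, pale-pink
soft tissue; a test fixture, not a stain-chemistry model), perturbed with
RGB noise, and warped by a per-slide random similarity transform drawn
uniformly within the configured bounds. "Standard jitter" throughout the
suite means rotation ≤ 10°, translation ≤ 20 px, scale within 3%. Slide
loss ("torn" sections) is uniform random dropout — the real selection
process is not quantified anywhere, so no structure is invented for it.

What the phantom does *not* model: stain variability and batch effects,
tissue folds, tears and shears (non-affine deformation), decalcification
artifacts, partial-volume chemistry at class boundaries, or scanner-specific
CT artifacts. Passing tests therefore demonstrate the pipeline's mechanics
and its noise robustness at the stated levels, not performance on real
slides.

## 2. Slide preparation

The detection chain is: grayscale → Canny edges with hysteresis thresholds
100/255 (8-bit gradient scale) → adaptive local threshold (window 11, offset
2, inverted binary, i.e. dark-tissue-on-bright-slide) → pixelwise OR of the
two maps → 15 dilations then 15 erosions with a 3×3 square element →
connected components → the component with the largest bounding-box area is
the biopsy (ties: larger pixel count, then lowest (y, x) origin).

Choices that were genuinely open:

* *Gaussian vs. box local mean* in the adaptive threshold: both readings are
  implemented (`adaptive_kind = "gaussian"` default, `"mean"` available).
* *How the edge and region maps combine*: OR, to preserve both kinds of
  evidence; neither map alone bounds the tissue reliably.
* *Dilate/erode ordering*: two blocks (closing), matching the stated purpose
  of smoothing contours.
* *Angle convention*: the minimum-area rectangle angle is reported in
  (−90°, 90°] with width ≥ height, resolving the 90° ambiguity
  deterministically.

The rotated rectangle's angle supplies the coarse rotation; masks are
rescaled bicubically and re-binarized at 128/255. The exported pixel ratio
is the input ratio times the downsample factor (0.121267 µm × 8.0 =
0.970136 µm).

## 3. Registration

**Matcher contract.** A matcher maps two grayscale images to paired
keypoints. The default classical backend detects multi-scale Harris corners
(scales 1 and 0.5, spatial non-max suppression), assigns each the dominant
smoothed-gradient orientation, samples an oriented 8×8 normalized intensity
patch (spacing 2 px), and matches by mutual nearest neighbour with Lowe's
ratio test at the canonical 0.8. Descriptors can be computed on the gradient
magnitude (`on_gradient = TRUE`), which removes sensitivity to the contrast
inversion between stained tissue (bone dark) and CT attenuation (bone
bright) — the cross-modal default. A transformer-based detector-free
backend satisfies the same contract but ships no weights; requesting it
names the classical fallback. The matcher also reports the fraction of
displacement vectors within 10° of the median direction — crossing match
lines betray false matches.

**Similarity from matches.** Two point pairs determine a similarity
transform exactly, so a deterministic 2-point RANSAC enumerates candidate
pairs, scores 3-px consensus sets, and refits the best set by least squares
(SVD/Procrustes). This is markedly more robust than trimmed least squares
when a quarter of the matches are wrong, which is routine cross-modally.

**Cross-entropy objective.** "Cross-entropy between the images" is read
literally: both images normalized to [0, 1], clamped to [ε, 1−ε] with
ε = 10⁻⁶, and scored by the mean Bernoulli cross-entropy
−mean[f·log m + (1−f)·log(1−m)] over the warped overlap. Transforms whose
overlap falls below 25% of the frame score +∞, so the optimizer cannot
escape by discarding support. On binary masks the objective reduces to a
mask-agreement criterion.

**Sequential optimization.** Translation is solved first on an exhaustive
coarse grid (stride 4 px — half the default phantom's correlation length,
so the basin cannot fall between grid points — swept over candidate
rotations 2.5° apart, since a rotation mismatch otherwise drags the
translation into a false optimum), refined per component by golden-section
search; then rotation (1° sweep + refinement), then scale over [0.9, 1.1];
finally two small-bracket sweeps over all four parameters resolve their
residual coupling. Stage tolerances: 0.25 px, 0.05°, 0.001. The objective
trace is non-increasing across stages by construction and is asserted in
the tests.

**Stack pre-alignment.** From one end of the stack, each slide considers its
(up to) 5 already-aligned predecessors, takes the one with the most matches
as reference, initialises from the RANSAC similarity and refines with the
cross-entropy optimizer. Because references are already aligned, each
estimated transform is directly cumulative. A slide with no matches at all
passes through with the identity and a flag — dropping data silently is
worse than propagating a visible gap. On this phantom the *ceiling* for mean
consecutive-plane class agreement is ≈ 0.88 (adjacent planes genuinely
differ at a 44 µm correlation length), so the suite asserts improvement
against that ceiling rather than an absolute 0.95.

## 4. Cross-modal matching and assembly

The CT volume is sliced in silico along the sectioning plane (axis-aligned
cuts at native spacing return raw planes; oblique cuts sample trilinearly).
For each slide, matched-keypoint counts against every CT slice form a
profile whose peak marks the source plane; a Gaussian with constant baseline
`A·exp(−(z−µ)²/2σ²) + b` is fitted by Levenberg–Marquardt (start: max −
median, argmax, 2, median) and `round(µ)` is the matched index — the fit
suppresses count noise better than the raw argmax. Degenerate fits
(non-finite parameters, σ wider than the profile, µ out of range) fall back
to the argmax with a flag. If two slides claim one CT index, the higher
peak wins and the other takes its best free index; matched indices should be
monotone for physically ordered sections, and violations are logged
(`enforce_monotone = TRUE` clamps them, off by default since enforcement is
an assumption).

Each slide then registers to its matched CT slice: the RANSAC similarity
maps the (larger) slide canvas into the CT frame, and a cross-entropy
refinement runs on gradient-magnitude images (polarity-free) with tight
bounds. Class masks follow with nearest-neighbour resampling and write into
the output volume at the matched plane; planes without slides are marked
255 (missing) or filled by nearest-plane replication when requested. The
output volume lives on the CT grid in-plane with section spacing
out-of-plane — that shared frame is what makes matched-prism comparison
possible.

## 5. Morphometry

All parameters are computed on isotropic binary volumes (anisotropic input
is first resampled, nearest-neighbour, to the coarsest axis spacing — the
explicit policy matters because voxel anisotropy is the leading cause of
surface-parameter disagreement between modalities).

* **Volumes**: TV from the prism box, BV by voxel counting; BV/TV and
  total porosity Po = 100 − BV/TV share the same counts, so their sum is
  exactly 100.
* **Surface**: the coarea formula on a Gaussian-smoothed indicator
  (σ = 1 voxel): `S = Σ|∇(G*χ)|`. On a radius-20 digitized ball this is
  within ~0.3% of 4πr²; no triangulation is built. TS is the analysed box
  surface.
* **Thickness/separation**: the local maximal-sphere method. The exact
  Euclidean distance transform (Felzenszwalb–Huttenlocher) gives each
  phase voxel its inscribed-ball radius; sphere centres whose ball is
  provably contained in a neighbour's (r_q ≥ r_p + |p−q|) are pruned — a
  chain argument keeps coverage exact — and remaining spheres paint their
  diameter `2r − 1` (the −1 converts centre-to-centre distance to
  boundary-to-boundary). Tb.Th is the mean over the foreground, Tb.Sp the
  same transform on the complement (one code path, so the duality is exact
  by construction). At the field-of-view border the phase is mirrored
  (stationarity assumption) with a 16-voxel horizon; values saturate at
  2·16−1 voxels in wider regions. Tb.N = (BV/TV)/Tb.Th.
* **Tb.Pf and SMI**: dilation differences under a one-voxel 6-neighbour
  dilation: Tb.Pf = (S₁−S₂)/(V₁−V₂), SMI = 6·S′·V/S² with
  S′ = (S₂−S₁)/h.
* **Anisotropy**: mean intercept lengths via directional boundary-crossing
  densities ½Σ|∇u·ω| over 49 Fibonacci-hemisphere directions; a quadratic
  form is fitted to 1/MIL², and DA is the ratio of the longest to shortest
  principal MIL (≥ 1, capped at 10³ for perfectly layered media).
* **Topology**: Obj.N counts 26-connected foreground components, Po.N(cl)
  counts 6-connected background components not touching the border, and the
  Euler number is the characteristic V − E + F − C of the voxel cubical
  complex (ball 1, hollow shell 2).
* **FD**: box counting of boundary voxels over dyadic box sizes.

Numeric parity with proprietary desktop-CT software is *not* claimed; each
parameter is defined by the formulas above and validated against analytic
phantoms instead.

Prism tiling anchors an axis-aligned grid of 512 × 512 × 230 µm boxes at the
ROI bounding-box corner (configurable offset) and keeps the prisms fully
inside the ROI; the same grid is applied to both modalities. For labelled
input the default binarization is `labels:bone,graft` — both classes are
radiopaque, so the CT foreground necessarily contains graft; `labels:bone`
is available when the question is new bone only.

## 6. Segmentation

The network is a conventional encoder–decoder with skip concatenations:
each level is two 3×3 convolutions with batch normalization and ReLU,
2×2 max pooling between levels, 2×2 stride-2 transposed convolutions up,
dropout after each concatenation, and a 1×1 convolution to three class
logits. The full-scale geometry used for real slide scans (512-px tiles,
four poolings → 32×32 bottleneck, batch 16, 5% dropout, 200 epochs,
learning rate 10⁻³ dropping tenfold on a 30-epoch validation-loss plateau
to a 10⁻⁵ floor, five folds) is the `"full"` preset; channel widths are
plain configuration. The `"tiny"` preset (32-px tiles, two
poolings, 8 base channels, 20 epochs, batch 8, learning rate 3·10⁻³ —
scaled up as usual for the much smaller model and step count) trains in
minutes on one CPU and is what the tests exercise. Forward and backward
passes are implemented in the package (compiled kernels plus hand-derived
batch-norm/softmax backprop, verified against finite differences in the
suite); training uses Adam and class-weighted categorical cross-entropy
with inverse-frequency weights `N/(3·N_c)` from the training masks.

Prediction ensembles the five fold models, averages overlaps when tiling,
renormalizes, bilateral-filters each probability channel (window 32, σ 64 in
both value — on the 8-bit scale — and pixel space; unlike a Gaussian it
removes isolated artifacts without displacing class edges), and assigns each
pixel its most probable class, ties broken bone > graft > non-mineralized
(an arbitrary but fixed convention). Filtering acts on probabilities, not
labels, because thresholding is defined as the final step. No augmentation
by default.

Segmentation fixtures stain class maps upsampled 4× before tiling: real
sections are scanned roughly an order of magnitude finer than the 11 µm CT
voxel (0.97 µm working pixels), and tile difficulty is governed by the
boundary-pixel fraction, so staining at CT resolution would misrepresent
the task. With that scale the tiny preset reaches ≥ 0.95 validation pixel
accuracy in every fold across seeds (pixel accuracy is used as the
validation metric).

## 7. Agreement statistics

Spearman's ρ uses average ranks and the t-approximation
`t = ρ√((n−2)/(1−ρ²))`; p < 0.05 flags significance, with no
multiple-testing correction (each parameter is reported on its own).
Bland–Altman differences are oriented histology − microCT (configurable);
bias is the mean difference, the 95% limits of agreement are bias ± 1.96 SD,
normality of the differences is checked with the D'Agostino–Pearson omnibus
(K² = Z₁² + Z₂² against χ²₂ — the single statistic/p-value shape the report
table needs), a one-sample t-test probes zero bias and an OLS regression of
differences on means probes proportional bias. The mountain plot folds the
empirical CDF `p_i = i/n` at the median (`1 − p` for `p > 0.5`); its peak
sits at the median with height 0.5 (attained exactly for even n). Exactly
collinear inputs and zero-variance differences are reported as degenerate
rather than erroring.

## 8. The demo study and problem sizes

`run_pipeline(list(seed = 1))` runs the whole chain on a 128 × 128 × 64
phantom (11 µm voxels): 64 sections at the voxel pitch with standard jitter,
the tiny segmentation preset trained on 40 tiles from two annotated slides,
reconstruction over the full 64-slice CT stack, and 12 matched
512 × 512 × 230 µm prisms for the comparison. These sizes were chosen as the
smallest specimen that still yields a meaningful prism sample while keeping
a complete run in the minutes range on a single CPU; the acceptance script
and tests reuse them. With 12 prisms the Spearman correlations carry wide
confidence intervals — the study demonstrates the pipeline, not a clinical
effect size.

## 9. Known limitations

* Affine-only registration; folds and shears in real sections need
  deformable models that are out of scope here.
* The classical matcher needs texture; featureless or heavily damaged
  slides fall back to flagged identity transforms.
* Thickness values saturate at the mirror horizon (31 voxels by default) in
  very open regions.
* The transformer matcher backend is a contract without weights; all
  shipped results use the classical backend.
* Phantom realism bounds what the tests can certify (see §1).
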
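---
title: "Adaptive texture-based active shape models for tendon ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{atasm methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In the transverse ultrasound view at the first annular (A1) pulley, the
flexor tendon appears as a bright (hyperechoic) roughly elliptical
region, surrounded by a dark (hypoechoic) synovial-fluid band, with the
bright volar plate beneath. Trigger finger — stenosing tenosynovitis —
thickens the tendon and changes its texture, and clinical grading relies
on outlining these structures. Speckle, variable boundary contrast and
acoustic shadowing make plain intensity-based segmentation unreliable,
which motivates a statistical shape model whose image evidence combines
gradients with local texture.

`atasm` implements that system end to end: a 20-landmark point
distribution model fitted by a genetic algorithm (GA) maximizing a
weighted five-term energy; template-based automatic initialization;
synovial-sheath segmentation with geometric post-processing; contour
agreement metrics; and a texture classifier separating symptomatic from
asymptomatic finger pairs. A seeded speckle phantom generator stands in
for clinical data so every stage runs, and is tested, offline.

## Shape model

Expert contours are reduced to 20 control points: the four extremal
points (top, bottom, left, right) anchor the correspondence and four
arc-length-equidistant points are placed between each adjacent anchor
pair (`resample_contour()`). Points are ordered from the top anchor
with positive shoelace area; coordinates are 1-based pixel centres with
x the column and y the row (y grows downward), a convention shared by
every module.

Generalized Procrustes alignment (translation, scale, rotation;
iterative mean re-estimation, 10-iteration cap, 1e-7 tolerance,
mean normalized to centroid zero and unit RMS) is followed by PCA of
the aligned 40-vectors. Shapes are synthesized as `X = Xbar + P b`
followed by a similarity pose. Mode weights are clamped to
`|b_i| <= 3 sqrt(lambda_i)`, the usual three-standard-deviation bound
of an active shape model; a strict `3 lambda_i` variant is exposed as
an option for comparison, but the square-root form is the default
because the eigenvalue has squared units and the bound is a parameter
range, not a variance. The number of retained modes covers 98% of
variance by default, capped at one less than the training count.

## Texture features and profiles

Two texture images drive the model: the imaginary component of a
0-degree Gabor filter and the Laws E5L5 (level-edge) energy image. The
Gabor envelope uses sigma = 4 px and spatial frequency phi = 0.1
cycles/px on a 25 x 25 kernel — values chosen so that roughly one
period spans the synovial band — and both are configurable. Filtering
is true convolution with reflected borders. Filters at 30/60/90 degrees
are available for inspection but do not feed the energy.

At each control point, five samples are taken along the outward normal
at offsets -4, -2, 0, +2, +4 px (negative = inside the contour) with
bilinear interpolation; out-of-image samples take the nearest border
value. The normal at point i is the unit perpendicular of
`c(i+1) - c(i-1)`, oriented away from the centroid — a stencil chosen
for noise stability, with the centroid resolving the sign
unambiguously for the star-shaped contours that occur here. The
20 x 5 = 100 samples, concatenated point-major, form the texture
profile; averaging profiles over the training images gives the texture
model.

## Energy and adaptive weights

Five terms are evaluated per control point:

* curvature: the angle at the point in `[0, pi]` (larger = straighter,
  preferred under maximization);
* area gradient: mean of a 3 x 3 window centred 2 px inside along the
  normal minus the mirrored outside window;
* line gradient: mean over five unit-spaced samples along the inward
  normal minus the mirrored outward segment (a 5 x 1 mask);
* Gabor and Laws texture: minus the sum of squared differences between
  the trained mean profile and the profile on the current contour. The
  per-point contribution is the point's own 5-sample partial sum, so
  the per-point weighted total reduces to the global texture energy
  when all weights are one — the only reading that makes the global
  texture energies compatible with per-point weighting.

The sheath variant flips the sign of both gradient terms (the sheath is
dark inside, bright outside); curvature and texture terms are shared.

Weights are learned per term and per control point. On a search line
through the true boundary point (21 unit-spaced positions spanning
+/- 10 px along the normal) each term is evaluated with that point
displaced and all others at truth. With `F` the value at the truth,
`Fmax` the line maximum and `sigma` the line standard deviation, the
weight is the training mean of `sigma * ratio`, where
`ratio = (F - Fmin) / (Fmax - Fmin)`. Shifting each line by its
minimum before the ratio keeps it in `[0, 1]`, equal to one exactly
when the truth is the line maximum — the stated intent of the weighting
— and makes the rule well defined when a term is negative over the
whole line, which is always the case for the texture energies (they are
negated squared errors). Constant lines contribute zero. No cross-term
normalization is applied; the weights absorb scale, so terms with large
natural units (the Laws profile) legitimately carry numerically large
weights.

## Optimization

The GA encodes the mode-weight vector `b` as a real-valued chromosome
constrained to the clamp box. Per generation: roulette selection on
min-shifted fitness, single-point crossover with probability 0.5,
per-chromosome mutation with probability 0.01 replacing one random gene
by a uniform in-bounds value, and elitism (the best-so-far chromosome
replaces the worst offspring). Evolution stops when the elite fitness
is unchanged (absolute tolerance 1e-9) for 10 generations, or at 200
generations. Population size defaults to 50. Mutation is read as a
per-chromosome event because the description replaces "a random shape
parameter" of a chromosome. Non-finite fitness values cause the
chromosome to be resampled rather than propagated.

With these settings the GA typically performs one to three thousand
fitness evaluations before the patience rule fires. That is enough to
localize the optimum of the segmentation energy to a fraction of the
deformation range, but it is not a high-precision optimizer: on a
smooth quadratic benchmark the elite lands a few percent of the
parameter range from the optimum, roughly what the evaluation budget
allows, and far from what an exhaustive million-sample search achieves.
The pipeline does not rely on more: pose refinement and the energy's
own flatness near the boundary dominate the final contour accuracy.

Pose (translation, scale, rotation) is refined with a hand-written
Powell direction-set minimizer (`powell_minimize()`: Brent line
searches with bracket expansion, direction replacement by the cycle's
net displacement, fractional tolerance 1e-4) — written in-package
because no direction-set optimizer is available in the dependency
stack. A refinement whose scale leaves `[0.5, 2]` times the initial
scale is treated as divergent and rolled back. Segmentation alternates
GA shape search and pose refinement for up to 5 rounds, stopping when
the relative energy change drops below 1e-4. The template matching (or
manual ROI) constitutes the first pose step, so each round runs the
shape search before re-refining pose: refining pose first with the
mean shape (b = 0) lets the pose absorb shape mismatch — on clean
high-contrast images it reproducibly introduced a spurious rotation
that the narrow texture-energy valleys then locked in, while the
GA-first order converges to the true boundary.

## Localization

An averaged intensity template is trained by warping every training
image onto a reference tendon contour (similarity transform from the
20-point correspondence) and averaging inside a crop that extends the
tendon bounding box by 40% per side (coverage-weighted where warps
leave pixels unseen). Coarse localization downsamples image and
template by 2 x 2 means and scans template-sized blocks with the mean
absolute difference (SAD), ties broken toward the smallest row then
column. The scan visits every half-resolution position (maximally
overlapping blocks): during development a quarter-block-stride grid was
found to lose the true position whenever the SAD valley — only a few
half-resolution pixels wide around a high-contrast averaged template —
fell between grid points, at which point a flat background block can
score better than a slightly misaligned true block. The exhaustive scan
removes that failure mode and stays well under a second at this
package's image sizes. Fine localization then minimizes SAD over a
4-degree-of-freedom similarity transform with Powell's method at full
resolution, and the reference contour mapped through the result
initializes the shape model. A manual region-of-interest box can
replace matching entirely (images with little sheath or multiple
tendons); the reference contour is then fitted affinely to the box.

## Sheath segmentation and post-processing

The sheath shape model is initialized at the segmented tendon's
centroid (the two centres nearly coincide anatomically) at the mean
training scale, and optimized with the sign-flipped gradient terms. The
lower sheath boundary is taken from the tendon: the arc of the densely
resampled tendon boundary whose direction from the tendon centroid lies
strictly within 30 degrees of the downward vertical. The invisible side
walls are closed by two parabolas `x = a y^2 + b y + c`, each
determined by the upper-arc endpoint, the lower-arc endpoint and
tangent continuity with the upper boundary at its endpoint — the third
constraint chosen because two endpoints alone leave a one-parameter
family; tangency gives the smoothest join. Degenerate geometry
(vertically aligned endpoints, zero tangent) collapses to a straight
segment, and a self-intersecting closure falls back to straight-line
closure and is flagged.

Images are grouped `clear` versus `fuzzy` by comparing 15 x 15-pixel
windows centred 8 px above and below the tendon's bottom-most point:
clear iff the upper window is brighter by strictly more than 30
intensity units. The 8 px centre offset makes the windows abut without
overlapping the boundary row. At inference the detected boundary is
used; ground-truth bookkeeping uses the true contour.

## Evaluation metrics

The mean absolute distance (MAD) is the symmetric average of the two
directed mean nearest-point distances, evaluated on 1 px dense
resamplings of both contours, since the underlying definition takes an
infimum over the continuous contour, not over the 20 control points.
Point-set sampling gives MAD a discretization floor of a fraction of
the resampling step; at the package's 1 px default this is an order of
magnitude below the pixel-scale differences being measured. The Dice
similarity coefficient (DSC) rasterizes both polygon interiors on the
native pixel grid (pixel centre in polygon, even-odd rule). Accuracy
and precision follow their standard confusion-matrix definitions, in
percent. For the reference confusion matrix used as the worked example
(TP 173, FN 37, FP 17, TN 193) accuracy evaluates to 87.14%. On the
same counts the defining precision ratio TP/(TP+FP) gives 91.05%,
whereas TP/(TP+FN) gives 82.38%; the package computes and reports the
defining ratio, and this distinction is documented here because the
two figures are easily conflated for these counts.

## Classification

From each segmented tendon a 41 x 21 px patch centred at the rounded
contour centroid is extracted. Features per hand: the tendon area and
the area inside the sheath (px^2); means and standard deviations of
every subband of a 2-level stationary wavelet transform and a 2-level
wavelet packet decomposition for the haar, db4, db6 and coif1 bases
(the unspecified "coif" is read as coiflet order 1, the smallest);
and 12 Haralick statistics of symmetric, distance-1 co-occurrence
matrices at 0/45/90/135 degrees with 32 quantization levels over the
patch's own range (which makes the features invariant to additive
intensity shifts). The wavelet transforms are implemented in-package
(periodic boundary; patches padded symmetrically to dyadic-compatible
sizes for the decimated packet transform) because no wavelet library
exists in the dependency stack; the filter coefficients are the
standard published constants. The sum-variance statistic is centred on
the sum average, the usual correction of a well-known misprint in the
original Haralick table.

Each pair contributes the difference of its two hands' feature vectors
(affected minus contralateral for symptomatic pairs, right minus left
for asymptomatic ones). Features are ranked by the divergence value
`(sn - sa)^2 (1 + sn + sa)^2 / (sn sa)` of the class standard
deviations; the linear rendering of the formula is ambiguous in its
grouping, and this reading is chosen because it is zero exactly at
equal spreads and grows with spread disparity, the stated behaviour;
the alternative denominator `2 sn sa` is available as an option. The
top 20 features feed an RBF-kernel support vector machine (via e1071's
LIBSVM binding) on standardized features, default cost 1, gamma
1/n_features, and inverse-class-frequency weights: leave-one-pair-out
folds of a balanced design are always off-balance by one sample, and
an unweighted SVM then leans toward the majority class, which on
null data anti-predicts every held-out pair. Evaluation repeats a full leave-one-pair-out pass 10
times with feature selection redone inside every fold — 10 repeats of a
42-pair pass is the only protocol consistent with the reference
confusion matrix's 420 decisions — and aggregates the confusion
counts.

## The phantom generator

`generate_phantom()` renders the anatomy the segmenter assumes: a
hyperechoic elliptical tendon (default semi-axes 42 x 26 px at
0.075 mm/px, intensity 150) whose boundary radius is perturbed by two
truncated Fourier modes (cos 2 phi and sin 3 phi, amplitudes drawn
N(0, 0.05^2) of the semi-axis — two modes give the shape PCA a known
truth to recover); a surrounding hypoechoic band (width 12 px,
intensity 60); background 100; and a bright volar-plate band (200)
below the sheath. Clear phantoms leave the dark band under the tendon
(bottom step 90 units); fuzzy phantoms fill the band below the tendon
with intensity 135, blended over 4 px, leaving a sub-threshold step.
Multiplicative speckle uses a unit-mean Rayleigh field scaled to 0.25
contrast — a standard first-order ultrasound speckle surrogate. All
randomness is seeded; generation is bit-reproducible.

The phantom emulates geometry, region contrast and speckle. It does not
emulate depth-dependent attenuation, anisotropic speckle correlation,
acoustic shadowing or the multi-tendon special cases, so passing
phantom tests demonstrates correct mechanics and recovery under the
stated noise model, not clinical performance. Paired cohorts plant a
disease surrogate in one hand (+30% tendon area, speckle contrast
x 1.5, matching the reported thickened hypoechoic appearance); a
zero-effect cohort provides the negative control. Each pair draws a
subject-level tendon size factor (N(1, 0.08^2), shared by both hands,
clipped to +/- 20%) and a small residual left/right asymmetry
(N(1, 0.02^2)): tendon calibre varies appreciably across people, and
without that variation the area features — the strongest
discriminators, and the top-ranked features in this method's reported
selection — would carry a class mean shift but no class spread
difference, which the spread-based divergence criterion cannot see.

## Problem sizes and reproducibility

The shipped tests and the acceptance script train on 10 phantoms,
segment 20 seeded test phantoms (with +/- 6 px centre jitter to
exercise localization), check localization on 17 seeded template
placements, and classify a 40-pair cohort — sizes chosen to mirror the
source study's scale (20 training images per group, 42 pairs) while
keeping a complete run in a few minutes on one core. Every random
stage takes an explicit seed, and fixed seed plus fixed inputs gives
bit-identical segmentation results.

## Known limitations

* The GA is a faithful re-implementation of the described operators and
  stopping rule, which bounds its evaluation budget and hence its
  terminal precision (see Optimization above).
* Sheath post-processing assumes a single tendon with a star-shaped
  boundary about its centroid; multi-tendon images require the manual
  ROI path.
* MAD/DSC are computed on point-sampled polygons; both carry
  discretization error well below a pixel but not exactly zero.
* Only PNG and TIFF images are read (no BMP reader is available in the
  dependency stack); 16-bit inputs are rescaled by the bit-depth
  maximum and RGB inputs are converted by Rec. 601 luminance.
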
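---
title: "Facial phenotype screening for Turner syndrome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial phenotype screening for Turner syndrome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tsface` is a landmark-based screening pipeline for the facial phenotype of
Turner syndrome (TS). This vignette documents the models it implements, the
parameters that matter, the synthetic data it validates against, and the
design decisions taken where the problem was genuinely open.

## Coordinate and data model

All geometry lives in pixel coordinates with the origin at the top-left,
x rightward, y downward, 0-based positions with pixel centers at integers.
The 68 landmarks follow the standard region map (outline 0–16, right brow
17–21, left brow 22–26, nasal bridge 27–35, right eye 36–41, left eye
42–47, mouth 48–67); "right"/"left" are the subject's sides, so the right
eye sits on the image left. Landmark detection is deliberately not part of
the package: detectors are trained external artifacts, and every
published quantity downstream of detection is computable from the
annotations alone. Eye centers are arithmetic centroids of the six-point
eye rings — the simplest estimator consistent with rotation alignment.

## Preprocessing

Geometric normalization composes one similarity transform: rotation by
−atan2(Δy, Δx) about the inter-eye midpoint (making the eye line
horizontal), isotropic scaling by `target_size / max(width, height)`
(default target 640 px), and centering with black padding. Isotropic
scale-plus-pad was chosen over anisotropic stretching to a square because
it preserves all distance ratios; the alternative would distort every
geometric feature. Resampling is bilinear; landmarks receive the identical
transform, which keeps image and annotation consistent to interpolation
error (the suite checks idempotence to < 0.5 px).

Face-area interception is computed from the landmarks themselves (bounding
box of outline plus brows, 10% margin) rather than from a separate face
detector — the landmarks are already available and deterministic.

Gray-scale normalization is plain histogram equalization,
`v ↦ floor(255·cdf(v))` on 8-bit intensities: monotone, hence
rank-preserving. Brightness adjustment is subsumed by equalization; no
separate step exists.

## Feature families

**Global geometric.** All pairwise Euclidean distances between the 68
landmarks in lexicographic (i, j) order: 2278 features. Invariant to rigid
motion, linear in uniform scale.

**Global texture.** A Gabor bank of 5 scales × 8 orientations. Wavelengths
follow half-octave steps 4, 4√2, 8, 8√2, 16 px/cycle — spanning the
feature scales present in a 128 × 128 face crop; the envelope is
σ = 0.56 λ (≈ one octave bandwidth, the common default), truncated at 3σ.
Kernels are DC-corrected so a constant image yields no response. The
orientation label is the carrier direction: an edge or fold extending
along ψ responds maximally in the channel at ψ + 90°. Filtering uses FFT
convolution with reflect padding (avoiding spurious boundary energy);
squared magnitudes are summed over an 8 × 8 grid of 16 × 16 blocks. The
joint spatial–frequency matrix is laid out 64 × 64 — 64 spatial blocks by
64 frequency channels — with channels 40–63 structurally zero: the bank
has 40 filters, and the padded layout keeps the published 4096-dimensional
flattened form while leaving PCA unaffected (zero-variance columns receive
zero loadings; the suite asserts this).

**Local features.** Five descriptors, fused in the fixed order forehead,
nevi, epicanthus, nasal bridge, ocular ratio (87 values total):

* forehead width d(p17, p26) and nasal bridge length d(p30, p33), pixels;
* ocular distance ratio d(p39, p42)/d(p36, p45) — inner- over
  outer-canthal distance, dimensionless and scale-free; hypertelorism and
  epicanthal folds both push it upward;
* epicanthus texture: the same Gabor bank applied to the 32 × 64 eye
  patches without block partition, total energy per filter, right then
  left eye (80 values). Both eyes are used because the fold is bilateral
  and averaging away one side would discard signal;
* multiple facial nevi: dark-blob detection merged into
  `[count, mean radius, max radius, total area]` — a fixed-length summary
  a stump-based classifier can consume.

**Blob detection.** Scale-normalized Laplacian of Gaussian (response
× σ²), 10 logarithmic scales covering blob radii 3–25 px in the 640
frame (radius = √2 σ at the scale-space maximum), strict 3 × 3 × 3
space–scale maxima above an absolute threshold of 0.05 on unit-scaled
intensities, then greedy pruning of detections overlapping a stronger one
by more than half the smaller circle's area. Detection is restricted to
the face-outline polygon (outline closed over the brow line), and three
further masks reflect what a nevus is: detections centered in the organ
boxes (eye + brow, nose, mouth, grown by 30% per side) and detections
closer to the face boundary than 0.8 of their radius are discarded —
irises, brows, nostrils and boundary-curvature responses are blobs but
not nevi.

## Learning

PCA centers (no rescaling — features within a family share units) and
keeps the smallest dimension reaching 95% cumulative explained variance.
The retained dimension is a data-dependent output, never a constraint.

The global families each feed a soft-margin SVM. The kernel and cost are
chosen by stratified 10-fold cross-validated balanced accuracy over a
small grid (linear with C ∈ {0.1, 1, 10}; RBF with C ∈ {1, 10} and γ ∈
{0.25, 1, 4}/p), ties resolved toward the simpler model. Balanced accuracy
is the selection target because the cohort is 1:3 imbalanced by design.
Features are standardized inside the classifier, making it invariant to
per-column affine rescaling.

The local features feed discrete AdaBoost over depth-1 stumps (default 50
rounds, early stop when no stump beats chance or the training set is fit).
The additive score Σ<sub>t</sub> α<sub>t</sub> h<sub>t</sub>(x) *is* the
score-level fusion: each stump reads one local descriptor, and the
weighted vote combines the five features' evidence without an arbitrary
cascade order. A score of exactly zero is classed as control — the
deterministic tie-break that favors specificity in a screening context.
The classical bound (training error ≤ Π<sub>t</sub> 2√(ε<sub>t</sub>(1−ε<sub>t</sub>)))
is asserted round-by-round in the test suite.

## Evaluation protocol

Cohort assembly is age-matched at 1:3 within one-year groups over ages
5–14: each group keeps the largest even number of cases for which three
controls per case exist, trims the rest by seeded uniform choice, then
splits each group's cases and controls half/half into training and testing
sides. Sensitivity and specificity are percentages rounded half away from
zero to one decimal (11/16 → 68.8; 39/48 → 81.3). The resampling harness
re-splits, retrains and re-evaluates n times (run r reseeds with
base_seed + r) and reports mean ± sample SD. Resampling re-splits the
fixed age-matched cohort rather than re-selecting controls each run — the
matched cohort is the study population, the split is the random element.
One-sample t and Pearson correlation wrap the standard `stats` tests; the
suite pins both to closed-form oracles at 10⁻¹⁰.

## Synthetic faces

Because patient photographs cannot ship, the generator renders schematic
640 × 640 frontal faces: a skin-toned outline-polygon fill over a dark
background with smooth illumination shading, dark brow/eye/mouth/nostril
elements at the landmark positions, and ground-truth records for every
planted signal. The pipeline consumes only intensity structure and
geometry, so schematic stimuli exercise every operator; they do not test
robustness to pose, occlusion, or real skin texture, and passing tests
bound implementation correctness, not clinical accuracy.

Class differences are planted as: +0.05 ocular ratio shift, +10 px
forehead, −8 px nasal bridge (cases); nevus counts Poisson with rates 4
(case) vs 1 (control), radii uniform on 4–12 px — plausible nevus sizes
well inside the detector's 3–25 px range — depth 90 intensity units with
a Gaussian profile whose σ = radius/√2 puts the LoG maximum at the
nominal radius; an oriented dark ridge of strength 60 at each inner
canthus for cases (the epicanthal fold surrogate); landmark jitter σ = 2
px and pixel noise σ = 4. Where no published value exists these defaults
were chosen once as realistic contrasts a clinician would recognize, and
the doubled-effect, null-effect and local-only configurations used in the
acceptance suite derive from them mechanically. Age scales the whole face
linearly (0.75 + 0.02·age about the frame center) — enough to make age a
real confound for the matching logic without modeling craniofacial
development. By default ages are laid out balanced: cases in even-sized
one-year groups with ratio-matched controls at the same ages, which is
what an age-matched case-control collection looks like after selection;
independent uniform ages are available via `age_balance = FALSE`.

Each sample draws its own sub-seed from the master stream, so earlier
samples are unaffected by how many follow them.

## Numerical choices and degenerate inputs

FFT convolutions pad reflectively, then grow to 5-smooth sizes (appended
zeros never reach the extracted region). Pairs of real LoG kernels are
packed into single complex kernels, halving the inverse transforms; kernel
spectra are cached across images of equal size. Coincident eye centers,
zero-area crops, rank-0 PCA input, single-class training labels, constant
statistical samples and metrics without positives (or negatives) all raise
typed errors rather than returning silent values. Empty blob sets are
valid results (`[0, 0, 0, 0]`), and an empty age-matched cohort is a
warning, not an error.

## Problem sizes in the test suite

The acceptance tests run the full study design — 32 cases / 96 controls,
16 + 48 per split side — on three synthetic cohorts (doubled effects, null
effects, local-only effects), with 20 resampling runs or 20 ranking
repetitions each; blob-detection recall uses 100 planted spots across 20
seeded canvases. These sizes reproduce the protocol at its published scale
while keeping the whole suite comfortably desk-sized.

## Known limitations

* The pipeline starts at landmarks; annotation quality bounds everything.
* The 64 × 64 joint texture matrix is zero-padded beyond the 40 filters;
  a bank that truly fills 64 channels would change the GTF family.
* AdaBoost fusion treats the 87 fused values uniformly; no per-feature
  classifier cascade is modeled.
* Synthetic validation shows parameter recovery, not clinical performance;
  mosaic karyotypes with attenuated facial features have no synthetic
  counterpart.
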
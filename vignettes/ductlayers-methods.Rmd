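---
title: "Duct-centric structure features and hierarchical diagnosis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duct-centric structure features and hierarchical diagnosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Breast-biopsy diagnosis spans a spectrum — benign proliferation, atypia,
ductal carcinoma in situ (DCIS), invasive carcinoma — and the preinvasive
middle of that spectrum (atypia vs DCIS) is where inter-pathologist
disagreement is highest.  `ductlayers` implements the post-segmentation
half of a diagnostic pipeline: it assumes some segmenter has already
produced a pixel-level *tissue label map* of a region of interest (ROI)
over eight clinical tissue classes

| code | tissue |
|------|--------|
| 0 | background |
| 1 | normal stroma |
| 2 | malignant epithelium |
| 3 | blood |
| 4 | benign epithelium |
| 5 | secretion |
| 6 | desmoplastic stroma |
| 7 | necrosis |

and turns that map into ROI-level features and diagnostic calls.  How the
label map was produced (CNN, SVM-based segmenter, manual annotation) is
out of scope by design.

# The model

## Superpixels

The atomic spatial unit is the superpixel: a contiguous region of roughly
one epithelial cell in area (default `target_area = 3000` px at full scan
resolution).  Two backends are provided:

* `slic_superpixels()` — simple linear iterative clustering on an RGB
  raster, the standard choice when the original stain image is available.
  Compactness defaults to 10; fragments below a quarter of the target
  area are merged into their largest neighbour so superpixels are always
  4-connected.
* `lattice_superpixels()` — deterministic square tiles of side
  `floor(sqrt(target_area))`.  Label-only input (in particular the
  synthetic fixtures) has no meaningful colour, so a colour-driven
  segmentation would be ill-posed; the lattice is the reproducible
  stand-in.

Each superpixel takes the tissue label of the majority of its pixels,
ties broken toward the lowest code (a fixed, documented tie-break chosen
for determinism; ties are rare on real data).  Superpixel adjacency is
4-connectivity between pixels of different superpixels.

## Tissue distribution feature (44 dimensions)

The frequency histogram (8 bins, fraction of superpixels per label)
captures *how much* of each tissue is present; the co-occurrence
histogram (36 bins, unordered label pairs over adjacency edges,
edge-normalized) captures *what borders what*.  The unordered form loses
nothing on an undirected graph; a 64-bin ordered variant is available
behind `directed = TRUE`.

## Structure feature (80 dimensions)

Ducts are detected as connected components of the superpixels whose
majority label is epithelium (benign or malignant), secretion or
necrosis — involved ducts are often *filled* with secretion or necrotic
debris, so epithelium alone would fragment them.  Components smaller
than `min_size = 3` superpixels are discarded; the threshold is exposed
because the underlying cleaning rule is qualitative.

For each duct, ten one-superpixel-thick layers are peeled: inner layer
$k$ is the set of members at erosion depth $k$ (equivalently, at graph
distance $k$ from the complement), outer layer $k$ the set of
non-members at graph distance $k$ from the duct.  Each layer yields an
8-bin histogram of majority labels, counted in superpixels and
L1-normalized (an empty layer is an all-zero row — a real signal: thin
rims have no deep inner layers).  The stack is ordered inner5 … inner1,
outer1 … outer5 and flattened row-major to 80 entries.

The biology this encodes: a normal duct is one or two epithelial
superpixels thick around an open lumen, so only inner1 (and perhaps
inner2) are epithelial and deeper inner layers are empty; DCIS fills the
duct, so all inner layers are epithelium-dominated, often with necrosis
deepest; invasive carcinoma has no closed rims and sits in desmoplastic
stroma, which dominates the outer layers.

**Aggregation.** Diagnoses attach to ROIs, not ducts, so per-duct stacks
are combined: layer by layer, raw superpixel *counts* are summed across
ducts and then normalized.  Summing counts (rather than per-duct
proportions) deliberately weights the feature toward the largest
structures in the ROI, which carry the diagnosis even when small benign
ducts are caught inside the ROI boundary.  The alternative
(equal-weight, `per_duct_normalized = TRUE`) is implemented behind a
flag because the aggregation rule is a genuine design fork; count
summing is the default on the dominance rationale.

## Evaluation protocol

Three sequential binary tasks mirror clinical decision-making:

1. invasive vs noninvasive (all four categories),
2. preinvasive (atypia + DCIS) vs benign (noninvasive only),
3. DCIS vs atypia.

Each task is evaluated by leave-one-out cross-validation: every sample
is held out once; the training side is subsampled without replacement to
equal class sizes (so chance is 50% and the model has no majority-class
bias); features are standardized from the training fold; when the task's
balanced training folds have fewer samples than features, a PCA fitted
on the training fold reduces to the first 20 components; a degree-3
polynomial-kernel soft-margin SVM (C = 1) is fitted and the held-out
sample predicted.  Subsampling noise is averaged out by repeating the
whole procedure 100 times; accuracy = (TP+TN)/(TP+TN+FP+FN),
sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP) are reported as
per-repeat means (and, additionally, as ratios of the contingency summed
over repeats — the two aggregations are both reported because reported
averages of ratios and ratios of sums can differ).

# Numerical choices that matter

**Kernel offset.**  The SVM kernel is
$K(x, z) = (\gamma\,\langle x,z\rangle + c_0)^3$ with
$\gamma = 1/\text{n\_features}$.  The package default is $c_0 = 1$ (the
inhomogeneous polynomial, kernlab's convention), not the LIBSVM default
$c_0 = 0$.  The reason is measurable: with $c_0 = 0$ and standardized
features, off-diagonal Gram entries are
$(\langle x,z\rangle/p)^3 \approx 10^{-3}$, the Gram matrix is nearly
diagonal, and the decision value of an unseen point collapses to the
intercept $-\rho$; on label-independent features the protocol then locks
onto one class per dataset (LOO accuracy ~0.35 or ~0.65, never ~0.5).
scikit-learn's SVC reproduces this collapse exactly, so it is a property
of the convention, not of this implementation.  With $c_0 = 1$ the
constant kernel component cancels under the dual constraint
$\sum_i \alpha_i y_i = 0$ and chance-level data scores at chance.  The
offset stays exposed in `svm_fit()` and `eval_config()`.

**PCA applicability is decided once per task**, from the smallest
balanced training fold a LOO split can produce
($2(m-1)$ for minority size $m$), not per fold.  The two readings agree
whenever the balanced fold size is not within one sample of the feature
count; when they disagree, the per-fold rule applies PCA only to the
folds holding out a minority-class sample, which makes the two classes
pass through different feature pipelines and biases sensitivity against
specificity.  Deciding per task keeps the pipeline uniform.

**Chance calibration is a one-sigma statement.**  On a single dataset of
$n = 100$ samples with labels independent of the features, per-sample
LOO predictions are largely stable across subsampling repeats, so the
repeat-averaged accuracy still carries binomial $n = 100$ noise:
sd $\approx 5$ percentage points around 50%.  Measured over dataset
seeds 1–7 the protocol gives 42–56% with mean 48.8%.  A single seed
landing outside $50 \pm 5$ is an expected draw, not a miscalibration.

**Determinism.**  Repeat $r$ seeds R's RNG with `base_seed + r`; every
randomized step (subsampling, synthetic generation) flows from an
explicit seed; SLIC, peeling, histograms and the SMO solver are fully
deterministic.  SMO uses maximal-violating-pair working-set selection
with KKT tolerance $10^{-3}$; decision values agree with scikit-learn's
SVC to ~$10^{-2}$ on shared fixtures.

**Degenerate inputs.**  An ROI with no ducts yields an all-zero
structure feature with a warning; an empty layer is an all-zero
histogram row; a graph with no edges yields an all-zero co-occurrence;
metric ratios with zero denominators are `NaN` with a warning rather
than silently dropped.

# The synthetic generator: what it does and does not establish

`generate_roi()` renders the *layered signatures* of the four
categories, not histology: benign = thin (1.25-superpixel)
benign-epithelium rim around an open background lumen; atypia =
thickened rim (2.5 superpixels) with secretion filling the outer half of
the lumen; DCIS = duct filled with malignant epithelium, central
necrosis in 70% of ducts; invasive = irregular malignant nests in
desmoplastic stroma.  Ducts are ellipses with randomized radius (preset
ranges per category), eccentricity 0.7–1 and orientation, placed without
overlap; two small blood specks per ROI add nuisance variation; label
noise flips each pixel to a uniformly random other label with
probability 0.02 by default (bounded at 0.2).  Defaults were chosen once
to emulate the qualitative morphology descriptions and are not tuned to
test outcomes; the atypia convention (intermediate rim/fill) is a
fixture convention, not a biological claim.

A green end-to-end test on these fixtures establishes that the pipeline
recovers morphology classes *that differ in exactly the way the
structure feature measures* — rim thickness, luminal fill, stromal
context — at desk scale.  It does not establish clinical performance:
real ROIs have irregular duct geometry, segmentation errors correlated
over space (not iid flips), mixed morphologies within one ROI, and
far larger images.  The headline numbers on the real 428-ROI dataset
are not reproducible here because those images are not public.

# Known limitations

* Layers are defined on the superpixel adjacency graph; very elongated
  superpixels can make "one superpixel thick" geometrically uneven.
* Outer layers of nearby ducts may overlap: each duct is peeled
  independently, so a superpixel can contribute to several ducts'
  histograms.  Background at the raster edge participates in outer
  histograms like any other label.
* The hierarchical cascade (`hierarchical_predict()`) composes the three
  task models at inference time; the evaluation protocol scores tasks
  separately, so cascade-level error propagation is not part of the
  reported metrics.
* The duct mask has no hole-filling or morphological closing; a rim
  broken by a segmentation gap becomes several objects (cleaning removes
  the smallest).
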
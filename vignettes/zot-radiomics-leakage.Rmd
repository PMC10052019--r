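---
title: "Zone-of-transition radiomics, GA wrapper selection, and where feature-selection leakage comes from"
author: "zotga authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zone-of-transition radiomics, GA wrapper selection, and where feature-selection leakage comes from}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Renal oncocytoma (RO, benign) and clear cell renal cell carcinoma (ccRCC,
malignant) can look alike on contrast-enhanced CT, and misclassification has
real clinical cost. Radiomic pipelines attack the problem by summarizing the
segmented lesion with thousands of quantitative descriptors and training a
classifier on them. Two ideas matter here:

1. **The zone of transition (ZOT).** The biology of the lesion-parenchyma
   interface differs between the two histotypes: a fast-growing ccRCC
   compresses the surrounding parenchyma into a hyperattenuating
   "pseudocapsule" rim, while the slow-growing RO meets the parenchyma
   directly. A shell straddling the tumor boundary should therefore carry
   discriminative signal that the tumor interior does not.
2. **Where feature selection sits in the pipeline.** With thousands of
   features and a few dozen patients, selecting features on the *whole*
   dataset before splitting into train/test sets leaks test information
   into the model and inflates the measured performance. The package makes
   this leakage measurable by running the same pipeline both ways.

`zotga` implements the full computational pipeline: phantom and feature-table
simulators, ZOT extraction by 3D binary morphology, named radiomic feature
extraction with a pluggable engine, genetic-algorithm (GA) wrapper feature
selection with a decision-tree cross-validation fitness, and the paired
"selection before split" (Procedure A) versus "selection after split"
(Procedure B) evaluation over repeated stratified splits.

## ZOT extraction

A tumor mask is a strictly binary 3D occupancy grid with voxel spacing
carried alongside (`voxel_mask()`). The ZOT is obtained by applying two
iterations of 3D dilation and two of erosion with a 3×3×3 "circular" kernel
and subtracting the eroded volume from the dilated one:

```{r}
library(zotga)
mask <- read_mask_nifti("tumor.nii.gz")
zr <- extract_zot(mask, make_structuring_element("ball", 3), iterations = 2)
zr$zot  # dilated \ eroded
```

Design choices a user should know about:

* **"Circular" 3×3×3 kernel.** A Euclidean ball of radius 1 discretized on a
  3³ grid is exactly the 7-voxel face-connected cross, so that is the `ball`
  element; the full 27-voxel `cube` remains available as an option. Two
  iterations of the radius-1 element are equivalent to a single pass with
  the element's Minkowski self-sum (the radius-2 city-block ball); the test
  suite asserts this equivalence and checks the whole operation voxel-wise
  against an independent coordinate-set Minkowski oracle.
* **Small masks are not errors.** A thin lesion (e.g., a small mass at
  2.5 mm slice spacing) can erode to nothing; the ZOT then equals the
  dilated mask and a warning is logged, because this is a data property,
  not a usage error.
* **Native anisotropic grid.** Morphology runs in voxel space; no implicit
  resampling is performed. Dilation is clipped at the grid boundary and the
  clipping is reported with a warning.
* Grid/spacing/origin mismatches beyond 10^-3 mm between a volume and its
  mask are errors.

## Feature extraction and the naming convention

Features are extracted per region (tumor, then ZOT) and rendered under one
naming convention: wavelet-filtered features carry a `W-<subband>` prefix,
Laplacian-of-Gaussian features an `L-<sigma>` prefix, and ZOT-region
features a trailing `(ZOT)`; for example `W-LLH_firstorder_Entropy(ZOT)`.
`parse_feature_name()` and `render_feature_name()` round-trip exactly, and
the evaluation reports use the tags to annotate rankings.

The extraction layer is an engine interface: `extraction_config(engine =
...)` selects either the shipped native engine or any adapter registered
with `set_extraction_engine()` (for example a wrapper around an external
radiomics toolkit). The shipped native catalogue is the package's own,
chosen once and frozen by config hash:

* 18 shape descriptors of the mask (voxel count, physical volume, surface
  area and surface voxel count under face connectivity, sphericity,
  compactness, principal axis lengths from the coordinate covariance,
  bounding-box measures, maximum 3D diameter, ...);
* for each of 12 images — the original plus 8 undecimated single-level Haar
  subbands (`W-LLL` ... `W-HHH`) plus Laplacian-of-Gaussian responses at
  sigma 1, 2, 3 mm (`L-1.0`, `L-2.0`, `L-3.0`) — 19 named first-order
  statistics and the 81 percentiles p10..p90.

That is 18 + 12 × 100 = **1218 features per region** and **2436 per
patient**, the catalogue-size contract the rest of the pipeline is built
around. Entropy and uniformity discretize intensities with a fixed bin
width (default 25 HU-like units) rather than a fixed bin count, which keeps
bins comparable across regions; on filtered images whose dynamic range is
much smaller than the bin width these two features can degenerate to a
single bin, which is accepted. Skewness and kurtosis of a (near-)constant
region are defined as 0 instead of NaN so degenerate phantoms do not lose
whole columns. No feature normalization is applied anywhere: the downstream
classifier is a decision tree, which is invariant to monotone rescaling.

One convention has consequences worth spelling out: **filters see only the
masked region.** Before filtering, the volume is cropped to the padded mask
bounding box and out-of-mask voxels are replaced by the in-mask mean, so
every feature is a function of the in-mask intensities and mask geometry
alone. This makes region features strictly insensitive to edits anywhere
outside the mask (a property the tests assert), at the price of discarding
cross-boundary contrast from the filter responses — the ZOT mask itself
spans the boundary, so boundary contrast enters through the ZOT region.

`clean_table()` drops any column containing non-finite values (logged) and
keeps constant columns: the GA may select them, and the tree simply never
splits on them.

## GA wrapper selection

A genome is a binary inclusion vector over feature columns. Fitness is the
mean ROC AUC of a decision tree over a stratified 5-fold cross-validation
on the genome's selected columns; the defaults are 150 genomes and 100
generations. Operators are standard, robust choices, all exposed in
`ga_config()`: tournament selection (size 3), uniform crossover (rate 0.9),
per-gene bit-flip mutation (1/L), elitism of 1 (making the best-fitness
history non-decreasing).

Numerical/reproducibility decisions:

* The CV fold partition is drawn once per `evolve()` run (seeded), so
  fitness is a pure function of the genome bits within a run; this is what
  makes the fitness cache sound, and the 15,000 tree fits of a default run
  are dominated by cache misses only early in the run.
* The decision tree is a greedy Gini CART grown to purity (minimum split 2,
  no depth limit), with scores equal to leaf class-1 fractions, implemented
  in compiled code for the ~10^5 fits a full experiment needs. Ties in
  split gain are broken deterministically by lowest column index, then
  lowest threshold, so the whole pipeline is bit-reproducible without any
  recorded RNG stream. The suite cross-checks fits and fold-level AUCs
  against an independent `rpart` oracle.
* ROC AUC uses the midrank (Mann-Whitney) estimator: tied score pairs count
  1/2. This is the right convention for piecewise-constant tree scores.
* The all-zero genome scores 0.5 (chance) rather than erroring, which keeps
  evolution total and penalizes empty subsets naturally.

On tables of up to ~10 features the GA's best fitness can be compared with
exhaustive enumeration of all subsets; the suite requires it to match the
exhaustive optimum in most seeds and never exceed it.

## The paired evaluation experiment

`run_procedure_a()` selects features on the full table, then draws a
stratified 80/20 split, fits the tree on the training rows restricted to
the selected features, and scores the test rows. `run_procedure_b()` draws
the split first and hands the GA only the training rows; a guard aborts if
any test-row id reaches the selection stage, and the suite verifies that
scrambling test-row features changes nothing about Procedure B's
selections. The whole experiment repeats (default 100 times) with fresh
shuffles.

Per-repeat seeds are derived by a fixed integer hash of
`(master_seed, repeat, stage)` (`derive_seed()`), so procedures A and B face
*identical split sequences* and the placement of the selection step is the
only difference between them — a sharper contrast than re-randomizing
splits per procedure. The final classifier is refit on the full training
split rather than reusing CV-fold models. Test AUCs on small test sets
(8-16 rows) are reported as-is, without smoothing: the spread of the AUC
distribution is part of the phenomenon being studied.

`leakage_gap()` is the difference in mean test AUC between the two
procedures on the same table; `selection_rates()` reports how often each
feature appears in the per-repeat best genomes (rate ties broken
lexicographically so reports are deterministic), and `summarize_aucs()` /
`plot_auc_distributions()` produce the distributional summaries.

## What the simulators emulate — and what they do not

`generate_feature_table()` emulates the *statistical shape* of a radiomic
cohort table: n patients, two classes in fixed proportions (defaults 77
patients, 39%/61%), iid standard normal features, and an optional planted
signal (`k_informative` columns shifted by `effect_size` in class-1 rows).
`k_informative = 0` is the null regime used to study leakage: any measured
discrimination is then optimism by construction. Real radiomic tables are
heavily correlated across features; iid columns are a deliberate
simplification that makes null behavior analytically checkable (the suite
compares the mean absolute point-biserial correlation with its closed-form
null expectation).

`generate_phantom()` builds spherical lesions on a uniform background with
iid Gaussian noise: an RO-like lesion is a sphere of tumor intensity, a
ccRCC-like lesion additionally carries a bright rim strictly *outside* the
tumor mask (the mask delineates tumor only, as a manual segmentation
would), which is exactly what the ZOT shell must capture. Defaults —
10 mm radius, 2 mm rim, background/tumor/rim intensities 20/40/90 HU-like,
noise sd 10, 48³ voxels at 1 mm — were chosen once for clear contrast, and
are artifact choices, not estimates of any cohort. The generator refuses
lesions that leave less than a 4-voxel margin, so two dilations can never
clip. There is no CT reconstruction texture, no scanner or contrast-phase
simulation, and no per-patient anatomical variability: with zero noise a
ZOT-restricted mean separates the classes perfectly (a documented
invariant, asserted in the suite).

That last property has an important consequence for interpretation, found
while validating the pipeline and worth stating plainly. When features
separate the classes essentially perfectly, the cross-validated fitness
saturates at ~1.0 for nearly every genome, the GA has no gradient to climb,
and genome evolution degenerates to neutral drift around the uniform
initialization: every bit — informative or not — ends up selected in
roughly half the repeats, and selection-rate rankings lose their
concentration on the informative features. The same saturation appears in
planted-signal tables once `effect_size` is large enough that one feature
alone achieves near-perfect CV AUC (around effect 2 and up at these sample
sizes): the *set* of planted features is then not identifiable from
selection rates, because holding two of them is as fit as holding all five.
Conversely, at the other extreme (pure-noise tables with a scaled-down GA
of a few hundred evaluations), the best genome mostly harvests luck
specific to the CV fold partition, which transfers only weakly to new
splits: the selection-before-split optimism is clearly positive but modest
(a few hundredths of AUC) until the GA is run long enough to accumulate
genuinely label-associated features. Passing phantom and planted-table
tests therefore demonstrates the machinery is correct and leakage-safe; it
does not by itself predict effect sizes on real, noisy, correlated data,
where fitness sits well below saturation and wrapper selection does
concentrate.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each phenomenon is visible: the
morphology oracle on 50 random masks up to 24³; the count contract on one
64³ phantom; the null-table leakage experiment at n = 40, p = 500 with a
GA of 30 genomes × 20 generations and 20 repeats per procedure; planted
recovery at n = 120, p = 100, k = 5; and a 20 + 20 phantom cohort with the
full 2436-feature extraction and 10 evaluation repeats. A full-scale run
(150 × 100 GA, 100 repeats, p = 2436) is a straightforward parameter
change and takes a few hours on one core, with the fitness cache doing
most of the work.

## Known limitations

* The native feature catalogue contains no gray-level co-occurrence or
  run-length texture families; those are expected to arrive through an
  external engine adapter. The catalogue satisfies the 1218-per-region
  count contract but is not a reimplementation of any specific external
  catalogue.
* Phantoms are geometrically trivial (spheres); they exercise the
  morphology, extraction and evaluation machinery, not segmentation
  robustness or shape-feature discrimination.
* The feature-table simulator's iid columns understate the redundancy of
  real radiomic features; selection-rate stability on real data will
  differ.
* `stratified_split()` rounds per-class training counts with `round()`;
  with 30/47 class counts and an 0.8 fraction this gives 24 + 38 = 62
  training rows and 15 test rows.
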
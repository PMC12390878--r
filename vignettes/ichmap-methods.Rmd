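---
title: "Methods: hematoma location mapping and outcome modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hematoma location mapping and outcome modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichmap)
```

# The analysis

Spontaneous intracerebral hemorrhage (sICH) has three major treatable
causes — chronic hypertension, ruptured aneurysm, and vascular
malformation — and each produces hematomas with a characteristic spatial
signature: hypertensive bleeds favor the deep nuclei, aneurysmal blood
fills the subarachnoid cisterns, and malformation-related bleeds are
predominantly cortical and more diffuse.  `ichmap` implements a pipeline
that turns template-space hematoma segmentations into

1. voxel-wise group **probability maps** (the per-voxel fraction of a
   group's patients whose hematoma covers that voxel);
2. a per-patient **location feature vector**: for every region of a
   labeled atlas, the fraction of its voxels covered by the hematoma
   union, binarized by the strict rule *involved ⇔ fraction > 0.20*;
3. region-level statistics: within each of five intracranial structures
   (ventricle, subcortical, white matter, cortical, subarachnoid), a
   repeated-measures one-way ANOVA comparing involvement rates across
   the three etiologies (regions act as matched subjects), and per-region
   uncorrected Pearson chi-square tests of involvement against binary
   outcome;
4. a compact IBSI-style per-lesion **radiomics** vector (first-order,
   mesh shape, GLCM, GLDM, NGTDM families) and a gated-attention
   **multiple-instance pooler** that aggregates multi-lesion patients to
   one vector;
5. L1-penalized logistic models (clinical / location / radiomics and
   their score-averaged **fusion**) for three-class etiology and for
   dichotomized functional outcome (poor = mRS 3–6), trained on one
   center and evaluated frozen on the others;
6. evaluation by one-vs-rest **macro-average ROC**, confusion matrices,
   and the **DeLong test** for paired AUC differences.

Because no compatible patient dataset is publicly deposited, the package
ships a synthetic-cohort generator with a known ground truth; every
stage of the pipeline is tested against independent oracles on that
generator.

# The synthetic cohort

## Toy atlas

`build_toy_atlas()` builds a nested-compartment parcellation on a
regular grid (default 64³ — desk scale, roughly two orders of magnitude
smaller than a 1 mm standard-space grid so that full-cohort experiments
run in seconds).  A central ventricular core is surrounded by concentric
shells: subcortical nuclei, white matter, cortical ribbon, and an outer
subarachnoid layer, with radial boundaries at fractions 0.24 / 0.60 /
0.80 / 0.93 / 1.00 of the brain radius.  These fractions were chosen so
that the per-region voxel volumes of the default 192-region table
(4 ventricular, 60 subcortical, 68 white-matter, 50 cortical, 10
subarachnoid regions) are comparable across structures.  Each shell is
partitioned into connected wedge-shaped regions by elevation bands and
equal-count azimuthal sectors; the seed in `toy_atlas_spec()` rotates
the sector origin, so the atlas is a pure function of its spec object.

## Lesions

Lesions are Gaussian-deformed spheres: a base radius is drawn from a
truncated normal, and the radius is modulated over direction by a random
linear + quadratic form (≈8% and 4% relative amplitude), giving
nontrivial shape and surface without anatomical realism.  Default radii
differ by cause — hypertension 4.5, malformation 5.5, aneurysm 6.5
voxels — reflecting that aneurysmal subarachnoid blood spreads farthest.
A lesion centered in a thin CSF compartment (subarachnoid shell,
ventricle) additionally spreads tangentially *within its target region*
(up to 1.8 × its radius): cisternal and intraventricular blood conforms
to the compartment rather than remaining spherical.  Without this
conformity a ball can never cover more than a few percent of a thin
shell region, the strict 20% rule never fires there, and the
subarachnoid signature of aneurysmal hemorrhage would be structurally
invisible — an artifact of the scaled-down geometry, not of the method.
Lesion voxels receive intensities of 65 ± 8 (HU-like) against a 30 ± 5
background, matching acute-hematoma contrast qualitatively.

Per patient the lesion count is 1/2/3 with probabilities 0.80 / 0.15 /
0.05 (a 20% multi-lesion rate; the frequency of multifocal hematomas is
not established, and this default is a free choice).

## Clinical covariates and outcome

Etiology proportions default to 48.5% hypertension, 37.4% aneurysm,
9.5% malformation and 4.6% unknown cause; unknown-cause patients are
generated from a hidden uniformly-drawn etiology and are excluded from
etiology modeling, exercising the exclusion rule.  Covariate priors
encode the expected clinical associations: hypertension history is most
frequent in hypertensive sICH (0.88 vs 0.35 / 0.25), aneurysm patients
are more often female (0.60 vs ≈0.41), and malformation patients are
youngest (mean 40 y vs 56 / 62 y).  Admission GCS decreases with the log
of total lesion volume plus noise.

The dichotomized outcome is drawn from a logistic model on centered GCS
(−0.40 per point), log total volume (+0.80), age (+0.02 per year), and
structure-involvement indicators (ventricular extension +0.9,
subarachnoid involvement −0.5).  The intercept (−1.0) centers the
poor-outcome prevalence near 38%, the value reported for large sICH
cohorts; keeping "poor" the minority class also matters technically,
because the training protocol optimizes F1 of the poor class and a
majority-positive class would make the degenerate always-positive
classifier F1-competitive.  Because the label is sampled from these
probabilities, even the true generative model has an AUC ceiling around
0.75 under the default coefficients; synthetic AUCs are therefore not
comparable to real-cohort values and are not meant to be.

## What the generator does not emulate

No anatomy, no scanner physics, no registration error, no missing data,
no center-specific covariate shift (centers differ only by sampling
noise).  A passing test suite shows that the *pipeline machinery* —
counting, statistics, features, training protocol, evaluation — is
correct and that the method can recover planted spatial structure; it
does not show that the models would reach any particular performance on
real NCCT data.

# Numerical and design choices

* **Strict 20% rule.** The involvement flag requires *more than* 20% of
  a region's voxels; the boundary case (exactly 0.20) is not involved
  and is pinned by a test.  Overlapping lesions count once (union
  semantics).
* **Repeated-measures reading of the structure-level ANOVA.** The
  etiology comparison treats regions within a structure as matched
  subjects measured under three conditions (the etiologies).  With
  identical rate profiles the test reports F = 0, p = 1, including the
  fully degenerate zero-residual case.
* **Chi-square without continuity correction**, so the statistic equals
  Σ(O−E)²/E exactly; a region involved in neither (or every) outcome
  class has an undefined expected table and is reported as statistic 0,
  p = 1.  The 192 per-region tests are reported raw, without
  multiple-testing correction.
* **Radiomics discretization** uses a fixed bin width (default 5 HU-like
  units) anchored at the per-lesion minimum — the recommended scheme for
  calibrated CT-like intensities; it makes the texture families
  invariant to global intensity shifts, which is tested.
* **Mesh shape features** come from a marching-tetrahedra triangulation
  of the 0.5 isosurface (six Kuhn tetrahedra per cell, midpoint edge
  crossings).  For binary fields every (tetrahedron, sign-pattern) pair
  contributes a fixed clipped volume (1/8, 1/2, 7/8 of the tetrahedron)
  and a fixed triangle set, so volume and area are tabulated exactly.
  The mesh volume of a digitized sphere of radius 10 is within 1% of the
  analytic value; lesions under 8 voxels are not meshed and fall back to
  voxel counting with an explicit flag.
* **Texture conventions**: 26-connectivity for lesion decomposition,
  neighborhoods and GLDM dependence (α = 0); GLCM over the 13 unique
  distance-1 directions, symmetrized, per-direction normalized, averaged;
  single-level images take GLCM correlation 1 and NGTDM contrast 0 by
  convention.  The catalogue is a representative 33-feature subset; the
  run-length and size-zone families and filtered-image expansions are
  deliberately omitted — the modeling pipeline is feature-count
  agnostic.
* **Attention pooling** uses the canonical gated-attention design
  (tanh × sigmoid gates, hidden width 16, scalar score, softmax within
  the bag).  Training is full-batch BFGS with analytic gradients — no
  minibatching — so results are exactly reproducible from the seed; the
  weight-decay strength is chosen from {1e−3, 1e−2, 1e−1} by stratified
  5-fold CV loss against the prognosis label, and the same frozen pooler
  produces patient-level features for all tasks.  Attention scores are
  computed on standardized features, but the pooled output is the convex
  combination of the *raw* lesion vectors, which makes the single-lesion
  identity exact regardless of training state.
* **Redundancy filter**: among columns with pairwise |Spearman ρ| > 0.8
  exactly one survives — the one most rank-correlated with the task
  label (maximum over one-vs-rest indicators for the 3-class task), ties
  broken by column order.  Constant columns are dropped with a warning.
* **L1 logistic models** are fit with glmnet — multinomial softmax for
  the 3-class task (one-vs-rest applied only at ROC time), binomial for
  prognosis — over 13 log-spaced inverse penalty strengths spanning
  1e−2…1e2, selected by mean cross-validated (macro) F1 with ties going
  to the sparser model.  Continuous features are standardized on
  training data; binary flags pass through.  Fusion averages the
  component models' class probabilities (out-of-fold scores during
  development, frozen-model predictions on held-out centers) and
  renormalizes to the simplex.
* **Macro ROC** evaluates each one-vs-rest curve on the union of
  observed FPR breakpoints keeping one-sided TPR limits at vertical
  jumps, so the trapezoid integral of the averaged curve is exact for
  step curves and the macro of identical curves reproduces their AUC to
  machine precision.  An alternative reading that averages FPR/TPR
  pairs exists; the TPR-at-common-FPR reading is implemented.
* **DeLong** uses the midrank structural-components estimator; identical
  score vectors yield a degenerate comparison reported as ΔAUC 0, p 1.
  The implementation is cross-checked against an independent reference
  implementation and a 10,000-replicate paired bootstrap in the tests.

# Problem sizes

The test suite and the acceptance script run the full protocol on
cohorts of 600 patients (three centers ≈ 300/180/120) on the 64³,
192-region atlas, with smaller 32³, 20-region atlases for unit tests and
repeated-simulation properties (e.g. 20 replicates for the
separability-dial and fusion-dominance checks, 200 bags for the
planted-signal attention check).  These sizes were chosen so a complete
run takes minutes on a single core while keeping the Monte-Carlo checks
comfortably inside their statistical bounds.

# Known limitations

* The toy geometry cannot represent bilaterality, midline shift, or
  anatomically realistic region shapes; region identities are
  meaningful only through their structure membership.
* The 20%-rule's sensitivity depends on the lesion-to-region volume
  ratio; at desk scale this is tuned by the zone radii and per-etiology
  lesion radii described above, and conclusions about flag sparsity do
  not transfer to real parcellations.
* Prognosis-side AUCs on synthetic cohorts are bounded by the sampling
  noise of the outcome label and should not be compared with real-data
  values.
* For the three-class task the DeLong comparison is performed per
  one-vs-rest class; a single scalar test for macro-AUC differences is
  not defined here.
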
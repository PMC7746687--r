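---
title: "Multimodal fusion of CT imaging and EMR for pulmonary embolism detection"
author: "fusePE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion of CT imaging and EMR for pulmonary embolism detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Pulmonary embolism (PE) is diagnosed on CT pulmonary angiography (CTPA),
but radiologists never read a scan in a vacuum: prior diagnoses, vital
trends, medications and lab values (above all the D-dimer) set the
pre-test probability. `fusePE` is a framework for building and comparing
classifiers that combine the two modalities — a volumetric imaging
classifier and a structured-EMR classifier — under seven fusion
strategies, together with the statistical protocol needed to compare
them honestly: validation-selected Youden operating points, DeLong and
Wilson confidence intervals, paired bootstrap model comparison, and a
subgroup analysis that excludes subsegmental-only PE, whose clinical
significance is questioned.

Because real CTPA cohorts with linked EMR are protected health data, the
package ships a synthetic cohort generator with controlled per-modality
signal. Every pipeline stage is exercised end-to-end on generated
cohorts; nothing in the package requires external data.

# The models

## Imaging branch

CT volumes are preprocessed by clipping intensities to the Hounsfield
working range $[-1000, 900]$, resizing each axial slice to a square
target (224 × 224 by default; desk-scale runs use 32 × 32), and
zero-centering by subtracting a fixed constant, the clip-range midpoint
$-50$ (the centering constant is configurable; a fixed constant keeps
preprocessing independent of the data split). Classification operates on
sliding windows of 24 consecutive slices so that a small embolus
occupies a meaningful fraction of the input; a window is labeled
positive when strictly more than 35% of its slices are positive (9 of 24
is positive, 8 of 24 is not). The default training stride is 12 (50%
overlap); inference uses non-overlapping windows (stride 24). Volumes
shorter than 24 slices are reflect-padded with a warning.

The window classifier is a small 3-D CNN of strided 3×3×3 convolutions
with ELU activations, optional squeeze-and-excitation channel gating and
optional 1×1×1-projection skip connections, global pooling, one fully
connected feature layer (the representation consumed by the fusion
models) and a single sigmoid output unit. It is trained under a focal
loss $-\alpha_y (1-p_y)^\gamma \log p_y$ with $\gamma = 2$ and $\alpha$
set to the inverse positive-window frequency by default (both
configurable); at $\gamma = 0$, $\alpha = 0.5$ the loss reduces exactly
to scaled cross-entropy. A study's probability is the **maximum** over
its window probabilities, and its feature vector is the last-FC
activation of the argmax window (ties break to the lowest start index).

Numerical choices that matter:

* **Input scaling.** Zero-centered HU values are internally multiplied
  by $1/475$ so the network sees inputs in roughly $[-2, 2]$.
* **Pooled-feature batch normalisation.** Between-window intensity
  contrasts are a small fraction of the absolute pooled responses
  (a lesion shifts the global mean by a few HU against backgrounds of
  hundreds of HU), which leaves the classifier head badly conditioned on
  raw pooled values and prone to a constant-output attractor. The pooled
  channel features are therefore batch-normalised with learnable scale
  and shift. Because the pooled means drift with the weights during
  training, the running statistics used at inference are **recalibrated
  by a final pass over the training windows at the trained weights**;
  without this step, inference probabilities can saturate.
* **Pooling.** Global mean pooling is the default; max pooling is
  available but, on synthetic volumes whose brightest voxels are
  bone-like structures at the clip ceiling, the channel maxima carry
  little lesion information.
* **Gradient clipping.** Global-norm clipping (default 1) guards the
  early epochs.
* **Determinism.** A single seed controls initialisation and shuffling.
  Exact reproducibility additionally assumes a fixed BLAS thread policy.

## EMR branch

Five record categories are encoded to a fixed-length vector; all
vocabularies and normalisation statistics are fitted on the training
split only and frozen:

* **Demographics** — one-hot gender, race and smoking status (with an
  explicit `unknown` column per field for unseen levels) plus numeric
  age.
* **Vitals** — nine clinical vitals (systolic/diastolic BP, height,
  weight, BMI, temperature, respiration rate, spO2, heart rate)
  represented by their sensitivity to change: finite-difference
  derivatives along the time axis. A variable-length derivative series
  must become fixed-length features; we emit per vital the mean
  derivative, the maximum absolute derivative and the last observed
  value, plus a missingness indicator set when fewer than two
  observations exist (derivative undefined, imputed 0). Derivatives are
  per day, matching the day-level granularity of typical EMR extracts.
* **Medications** — per drug class, the order count within the 12-month
  observational window and a binary prescribed flag. Frequency counts
  records; whether orders or administrations are counted is an open
  representational choice and records are the conservative one.
* **ICD diagnoses** — codes are first passed through a leakage filter:
  any code recorded under the same encounter as the CT exam, or
  timestamped within 24 hours before it, is dropped (the diagnosis
  being predicted must not leak in through the coding system). The
  boundary is strict — a code at exactly 24 h is kept. Remaining codes
  collapse to top-level diagnosis groups (the grouping map is
  configurable; the default truncates at the first hierarchical
  separator), and groups occurring in less than 1% of training
  *studies* are excluded from the vocabulary — the filter counts
  studies containing the group, the natural reading of per-corpus
  occurrence, not raw code instances. Each kept group contributes a
  (presence, count) pair.
* **Labs** — per test, binary presence and the latest value by
  timestamp (ties break deterministically to the later record, with a
  warning).

All features are z-normalised with training-split mean and SD;
zero-variance features are centered but not scaled, and missing raw
values are imputed to 0 *after* centering (the training mean) alongside
their indicator columns. The transform is a pure function of the study
and the frozen schema, so no statistic can leak from validation or test
data; the test suite asserts that perturbing non-training studies leaves
the schema bit-identical.

## Fusion architectures

Seven architectures share one prediction interface:

| name | kind | definition |
|---|---|---|
| `early_fusion` | early | one FFNN over [all EMR features, imaging last-FC features] |
| `joint_all` | joint | one trainable EMR extractor → fusion head |
| `joint_separate` | joint | one extractor per EMR category → fusion head |
| `late_nn_average` | late | mean(imaging prob, all-EMR FFNN prob) |
| `late_elastic_average` | late | mean(imaging prob, EMR ElasticNet prob) |
| `late_separate_average` | late | mean of 7 component probabilities |
| `late_meta` | late | FFNN stacker over the 7 component probabilities |

The imaging branch is **frozen** in all fusion training; fusion models
consume its probabilities and extracted features rather than raw
volumes. In joint fusion the head's loss is backpropagated into the EMR
extractors (never across a late-fusion boundary). The seven components
of the separate/meta variants are the imaging model, the five
per-category EMR networks and the all-EMR network; the component list is
configurable since the seventh slot is a design choice. The meta
stacker is trained on out-of-fold (5-fold) training-split probabilities
for the EMR-side components to limit stacking leakage; the frozen
imaging model contributes its ordinary training-split predictions, a
pragmatic compromise documented here because refitting the CNN per fold
costs far more than it informs. No probability calibration is applied
before averaging.

The EMR ElasticNet is a logistic model with combined L1/L2 penalty
(`glmnet`); the mixing parameter is selected over the grid 0.1–0.9 by
cross-validated deviance on the training split with shared fold ids.

## Training protocol

Every feed-forward model can be tuned by grid search over the canonical
ranges — activation {ELU, LeakyReLU, Tanh}, 0–10 hidden layers, 10–500
neurons, optimizer {Adam, SGD, AdaDelta}, learning rate 1e-4–1e-1, init
{Normal, Xavier, Kaiming}, dropout 0.3–0.8 — with batch size 256 and 200
epochs as the canonical protocol. Two independent rules apply: per
configuration the checkpoint is the epoch with the highest validation
*accuracy* (threshold 0.5; operating-point selection is an
evaluation-time concern), and across the grid the selected configuration
is the one whose checkpoint has the lowest validation *loss*, with ties
broken by enumeration order. A convergence report flags any model whose
loss minimum falls on the final epoch. The default desk-scale grid is a
small documented subset (2×2×2-sized) of the full ranges, which are
available by configuration; selection never sees test data.

# The synthetic cohort generator

`cohortSpec()` fixes the study conditions; its defaults are the
conditions under which the package's own experiments run:

* 150 patients, one study each (repeat studies are supported but
  default off, since how repeats beyond patient-level split integrity
  should be handled is underdetermined); PE prevalence 0.4, matching
  the roughly 40%-positive composition of the curated clinical cohorts
  this design mirrors.
* Patient-level split assignment at 60/20/20. Clinical datasets often
  hold out ~10% for validation and test; at 150 patients that would
  leave ~15 studies per held-out split, too few for stable Youden
  thresholds and AUROC comparisons, so the generator rebalances while
  keeping the patient-disjointness invariant.
* Volumes of 24–40 axial slices at 32 × 32 voxels: Hounsfield-like
  backgrounds (air, soft-tissue body, low-density lungs, a bone-density
  spine block exceeding the 900 HU clip point so clipping is genuinely
  exercised), quantised to 16-bit integers. Positive studies receive a
  contiguous run of 9–16 positive slices and an additive bright
  ellipsoidal blob (amplitude `imageEffect`, default 150 HU) at a
  random in-lung position spanning exactly that run — the simplest
  signal a small 3-D CNN can learn at desk scale. Each study's lesion
  conspicuity is additionally drawn from Uniform(0.15, 1.25), so a
  fraction of positives is nearly image-occult. This reflects variable
  lesion size and contrast opacification, bounds the achievable
  imaging AUROC below 1 even for a perfect detector, and creates the
  subpopulation of image-missed cases that the clinical data can
  rescue — the mechanism by which fusion earns its advantage.
* Per-category EMR tables whose informative features shift with the
  label by the category effect (defaults rise from demographics 0.24 to
  labs 1.2, D-dimer being the strongest clinical PE signal):
  age shift, late pre-exam drifts in heart rate/respiration/spO2
  (feeding the derivative features), elevated order rates for three
  risk-linked drug classes, elevated rates for three diagnosis groups,
  and shifted D-dimer values. ICD tables deliberately include leakage
  rows — a diagnosis recorded under the exam encounter (for positives,
  effectively the PE code itself) and a same-day code — which the
  leakage filter must drop; leaving them in would hand the EMR model
  the answer.
* Image and EMR signals are conditionally independent given the label,
  so fusion gains are expected by construction: for two conditionally
  independent Gaussian channels the Bayes-optimal fused AUROC
  $\Phi(\sqrt{d_1^2+d_2^2}/\sqrt 2)$ dominates both single-channel
  values $\Phi(d_j/\sqrt 2)$, an identity the test suite verifies
  analytically and by simulation.
* 11.3% of positives are flagged subsegmental-only. By default the flag
  is independent of lesion contrast; `subsegmentalAttenuation < 1`
  optionally dims subsegmental lesions to reproduce the qualitative
  pattern that small PEs are harder to see.
* Category-level missingness (2–15%) and a single `seed` that fully
  determines the cohort.
* The default effect sizes were calibrated once so that, at the default
  cohort size, each single modality reaches a test AUROC of roughly
  0.75–0.85 — the qualitative regime of clinical PE cohorts, where the
  imaging-only and EMR-only models are individually useful but clearly
  below the fused model. Balanced, moderately strong modalities are
  also the regime in which probability-averaging fusion has genuine
  headroom; with one near-perfect modality the comparison degenerates.

What the generator does **not** emulate: anatomy (vessels, airways,
actual filling defects — the lesion is additive brightness, not a
contrast defect), realistic ICD ontologies, correlated comorbidity
structure, scanner effects, or label noise. Passing tests therefore
demonstrate that the pipeline's machinery — encodings, leakage rules,
training, fusion, statistics — behaves correctly on data with known
structure; they say nothing about clinical performance on real CTPA
cohorts.

# Evaluation protocol

AUROC is computed in Mann–Whitney form with tie correction. The
operating point is the threshold maximising Youden's
$J = \text{sensitivity} + \text{specificity} - 1$ on the *validation*
split, over candidate thresholds at midpoints between adjacent sorted
unique scores plus 0 and 1; ties take the lower threshold (higher
sensitivity). Scores at or above the threshold are classified positive —
the common convention, and a measure-zero choice for continuous scores.
At that fixed threshold the test split yields sensitivity, specificity,
accuracy, PPV and NPV with 95% Wilson score intervals (exact 0 and 1
bounds at the boundaries; zero-denominator ratios are reported as
not-a-value with a warning). AUROC uncertainty is reported two ways,
since conventions differ: a DeLong structural-components interval and a
1000-replicate study-level bootstrap percentile interval. A degenerate
DeLong variance (perfect separation) falls back to the bootstrap with a
notice. Models are compared by paired study-level bootstrap of the
AUROC difference, p-value $2\min(P(\Delta\le 0), P(\Delta\ge 0))$ with
the +1 small-sample correction; single-class replicates are redrawn and
logged. The subgroup analysis re-evaluates after dropping positives
flagged subsegmental-only, retaining all negatives.

# Problem sizes

The package's own experiments (test suite and the acceptance script)
run at desk scale, chosen so a complete end-to-end experiment — CNN
training included — finishes in about two minutes on one CPU: 150
patients, 32 × 32 × (24–40) volumes, a 2-stage CNN with 8 and 16
channels trained 16 epochs at batch size 8 with Adam (lr 3e-3), and
feed-forward models of one 32-unit hidden layer trained 80 epochs at
batch size 64. The canonical protocol values (224 × 224 inputs, batch
256, 200 epochs, the full grid ranges) remain the documented defaults
of the corresponding functions where they are cheap, and are available
by configuration everywhere else.

# Known limitations

* The imaging stand-in is a small CNN, not a 77-layer pretrained
  backbone; no video-dataset transfer learning is attempted.
* Joint fusion consumes frozen imaging features, so its extractors can
  only reshape the EMR side — the same structural limitation the
  frozen-feature design implies in general.
* Batch-norm running statistics are recalibrated on training windows;
  applying the model to volumes from a very different intensity
  distribution would require recalibration.
* The bootstrap and DeLong intervals quantify sampling noise of one
  cohort; they do not capture generator-level (between-cohort)
  variability, which the multi-seed acceptance checks probe instead.
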
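---
title: "Detecting OPL subsidence in OCT volumes: models, phantom and evaluation"
author: "SubsideOCT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting OPL subsidence in OCT volumes: models, phantom and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Subsidence of the outer plexiform layer (OPL) — a localized sinking of the
INL/OPL and OPL/ONL boundaries visible on spectral-domain OCT — is an early
biomarker of progression from intermediate age-related macular degeneration
towards geographic atrophy. Finding it requires inspecting every B-scan of
every volume; SubsideOCT automates that search with a two-stage design:

1. a **detection module (DM)** proposes candidate bounding boxes with a
   confidence on each B-scan, tuned for high sensitivity;
2. a **classification module (CM)** scores each whole B-scan for subsidence
   presence and acts as a false-positive reducer: every candidate
   confidence is multiplied by the B-scan score;
3. fused candidates that overlap on adjacent B-scans (in-plane IoU
   strictly above 0.5) are merged transitively into 3D cuboids — the
   minimum enclosing extent of their members, scored with the maximum
   member confidence;
4. the volume score is the maximum cuboid confidence (0 when nothing is
   detected), and eye- and participant-level scores are maxima over the
   corresponding volumes.

Both modules see a three-channel *neighbor stack* — the B-scan of interest
flanked by its two nearest neighbors, with edge B-scans repeated at the
volume boundary — so that lesion persistence across slices is available to
the per-slice models.

## Desk-scale models

The reference design for this problem family pairs an ImageNet-pretrained
convolutional backbone with a region-proposal detection head, trained for
hours on a GPU. SubsideOCT keeps every *training-protocol* element of that
recipe but swaps the backbone for a fixed, fast feature extractor so that
the full pipeline trains in minutes on one CPU:

* The **backbone** computes per-column boundary profiles of each channel:
  the depth of the OPL/ONL junction (largest intensity step above the
  bright outer band, after separable lateral/axial smoothing) and the
  depth of the outer band itself. The per-column **dip** — junction depth
  minus a robust running-median baseline — is the image signature of
  subsidence. Backbones are pluggable by name (`registerBackbone()`); a
  pooled-intensity backbone ships as a second registered option, and the
  type-level contracts (feature vector per stack; anchor table per stack)
  are all a replacement must satisfy.
* The **CM head** is a logistic scorer over stack-level dip statistics
  (maxima, exceedance mass, cross-channel persistence and correlation),
  trained by minibatch SGD with class-balanced batches (equal numbers of
  positive and negative B-scans per batch of 16), restricted — as the
  two-stage design prescribes — to volumes that contain at least one
  subsidence. A participant-level validation split selects the checkpoint
  with the best validation AUC.
* The **DM** scores candidate windows: dip-support runs (maximal column
  runs whose dip exceeds each of several depths — the analogue of region
  proposals) plus an optional sparse anchor grid. An objectness head is
  trained by SGD with a per-epoch learning-rate decay of 0.95 on annotated
  B-scans only, keeping the final epoch; a ridge regression head refines
  each window's extents. Anchors are labelled positive above IoU 0.5
  against ground-truth boxes and negative below 0.25; the regression pool
  additionally includes looser matches (IoU at least 0.3) so that
  imprecise proposals learn to contract onto the lesion. At inference,
  candidates below the 0.05 emit threshold are dropped, within-slice
  duplicates are suppressed at IoU 0.5 (higher score kept), and at most
  `maxPerSlice` (default 8) candidates are emitted per B-scan — the usual
  proposal budget of a region-proposal detector.

The hyperparameters of the GPU-scale reference recipe (224 px CM input,
256 px DM input, learning rate 1e-4, 1000 and 100 epochs, batch 16,
epoch-wise decay 0.95) are recorded as named presets (`cmReferenceConfig()`,
`dmReferenceConfig()`); they expect a GPU-scale backbone to be registered
under the configured name and are not runnable with the built-in
extractors at those epoch counts in reasonable CPU time.

Two open protocol details were resolved as follows. The DM checkpoint is
the final epoch (no selection criterion is part of the documented recipe,
so the least-assuming reading is used); the CM validation split is at the
participant level, consistent with the cross-validation design. The
within-slice duplicate suppression before fusion is an assumption of this
implementation; the multiplicative fusion itself is unaffected by it.

## The synthetic phantom

Because the clinical cohorts behind this problem are private, the package
ships a layered-tissue phantom that makes every stage trainable and
testable with exact ground truth:

* **Geometry.** Five boundary surfaces (ILM, INL/OPL, OPL/ONL, an ELM
  proxy, RPE) at fixed depth fractions of the axial size, displaced by a
  shared band-limited random undulation (clipped Gaussian coarse grid,
  bilinearly upsampled; amplitude 2 px) plus per-surface jitter (1 px),
  with strict ordering enforced at every grid point. Drusen are smooth
  compact elevations applied to the ELM proxy and RPE together, so the
  outer band keeps its thickness, as it does over real drusen.
* **Subsidence.** Each event is a separable raised-cosine dip
  $A\,p(\Delta x/r_x)\,p(\Delta s/r_s)$ with $p(u)=(1+\cos \pi u)/2$,
  applied to the INL/OPL and OPL/ONL surfaces. The profile was chosen
  because it is smooth, compactly supported and analytically invertible,
  so the annotated run width can be computed in closed form and tested
  against the generator. An A-scan is annotated exactly where the dip
  exceeds the visibility threshold `tauVis` (default 5 px) — a proxy for
  "observable by a grader" that makes the ground truth well-defined.
  Events within one volume are laterally disjoint (distinct lesions never
  share A-scans, matching how graders delineate separate lesions). Where
  a dip would collide with the deeper boundaries it is clipped in order
  (OPL/ONL below the ELM proxy, everything above the RPE), which keeps
  the strict ordering invariant; default amplitude ranges never reach the
  clip.
* **Appearance.** Bands take fixed reflectivities (vitreous 0.04, inner
  retina 0.22, OPL 0.32, ONL 0.08, ELM-RPE band 0.50, choroid 0.16) with
  a small smooth lateral texture modulation, multiplied voxel-wise by
  gamma speckle of shape 8 (mean 1, coefficient of variation 0.35).
  Reflectivities are capped at 0.5 so the multiplicative noise almost
  never clips at 1, keeping band means unbiased (the low dynamic range
  also matches real OCT export). The hard preset lowers contrast,
  raises speckle (shape 4) and uses subtler dips (8-20 px).
* **Identity.** Participants are synthesized with two eyes each so that
  participant-level stratification and eye/participant aggregation are
  exercisable. The positive-volume count is exact by construction.
* **Ground-truth boxes.** Graders mark only A-scans; a depth extent must
  be chosen to form boxes. Subsidence lives between the INL/OPL boundary
  and the RPE, so the dataset-level window is the nominal INL/OPL depth
  minus 8 px down to the nominal RPE depth plus 8 px, stored in
  `dataset.json`. For real annotations the window is user-supplied.

What the phantom does *not* emulate: vascular shadows, motion artifacts,
physically accurate speckle statistics, or the morphological diversity of
real subsidence (wedge-shaped hyporeflective bands, asymmetric dips).
Passing the benchmark therefore shows that the pipeline's machinery —
training protocol, fusion, merging, evaluation — is correct and that the
intended signal is learnable at desk scale; it is not evidence of
clinical-grade performance on patient data.

## Evaluation protocol

* **Matching.** Predicted cuboids are matched to per-lesion ground-truth
  cuboids by 3D IoU with a non-strict 0.25 threshold. Among candidates
  over one lesion only the highest-confidence one is the true positive;
  the rest are ignored (neither TP nor FP). Candidates overlapping no
  lesion are FPs; unmatched lesions are FNs. Ties are broken
  deterministically (higher IoU, then lower lesion id, then input
  order). The IoU is computed in 3D because both predictions and
  ground-truth units are volumetric; the matcher accepts any cuboid
  table, so an en-face (depth-ignoring) analysis can be run by giving
  both sides full-depth extents.
* **FROC.** Matching is computed once with every candidate retained; the
  confidence threshold is then swept over the sorted candidate
  confidences. Sensitivity at 1, 2 and 3 FPs per volume is linearly
  interpolated between curve points, since the empirical FROC is a step
  function reported at integer abscissae.
* **ROC/AUC and PR/AP.** AUC is the rank statistic (probability a random
  positive outranks a random negative, ties half); AP is the
  recall-increment-weighted mean of precisions with baseline P/(P+N).
  Both are unit-tested against independent oracles (exhaustive pairwise
  concordance; per-positive step integration) and cross-checked against
  an established ROC implementation.
* **Cross-validation.** Folds partition participants, never volumes or
  eyes, keeping positive-participant counts within one of each other
  (round-robin dealing of shuffled positives, size-balancing dealing of
  negatives). Per fold, CM and DM are trained on the training
  participants and every held-out volume is predicted; FROC is computed
  per fold and averaged (matching how the multi-fold detection results
  are reported), while volume-level ROC/PR are additionally pooled over
  all folds' test sets (both pooling modes are returned).

## The benchmark and its numbers

The package's reference experiment — also what `scripts/acceptance.R`
reruns — generates 200 easy-preset volumes of 49 B-scans at 160 x 256 px
with 25% positives under the fixed study seed 42, then runs 2-fold
participant-level cross-validation with the desk-scale configurations
(CM: 128 px input, 30 epochs; DM: 128 px input, 20 epochs; both with the
training protocol above). Reported are the fold-averaged volume-level ROC
AUC and the fold-averaged detection sensitivity at one FP per volume.
The desk-scale problem sizes (volume resolution, epoch counts, k = 2)
were chosen once so the full experiment runs end-to-end in minutes on a
single CPU while the 49-slice geometry and the class balance of a
screening cohort are preserved.

## Numerical choices and degenerate inputs

* All coordinates are 0-based with half-open intervals; box area is
  (x1-x0)(z1-z0) with no +1 anywhere.
* Merge threshold strict (IoU > 0.5), match threshold non-strict
  (IoU >= 0.25) — exactly as the decision rules are stated.
* The volume score of an empty candidate set is 0 ("no evidence"), making
  the maximum well-defined.
* A single-slice volume yields a neighbor stack with all three channels
  equal; single-slice components become cuboids with s1 = s0 + 1.
* SGD heads initialise at zero weights (deterministic); all stochastic
  steps (shuffling, balanced batch sampling, augmentation, fold
  assignment, phantom generation) derive their streams from one seed via
  a fixed tag-hash derivation, so identical configuration and seed give
  byte-identical datasets and reports.
* Boundary estimates at the extreme lateral image edges are unreliable
  (truncated smoothing windows), so the dip profile is zeroed on a 3 px
  guard band.
* The running-median baseline window (151 model columns) must exceed
  twice the widest expected lesion; lesions wider than that would be
  partially absorbed into the baseline and scored lower.

## Known limitations

* The built-in backbones are engineered around the dip signature; lesions
  that manifest without a detectable OPL/ONL displacement (e.g. a pure
  hyporeflective wedge) would require a different backbone, which the
  registry accommodates.
* The phantom's identifiability assumption (`tauVis` separates lesion
  from anatomical variation) is a modelling convenience; real grading
  has inter-reader variability that no threshold reproduces.
* Gap-bridging across a missing slice is deliberately not performed in
  merging; a lesion fragmented by one empty B-scan yields two cuboids.
* `cmReferenceConfig()`/`dmReferenceConfig()` document the GPU-scale recipe but
  do not make desk hardware train it; they exist so the configuration is
  reproducible where such a backbone is available.
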
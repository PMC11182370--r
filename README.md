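# SubsideOCT

Automated detection of **outer plexiform layer (OPL) subsidence** in
retinal OCT volumes. OPL subsidence — a localized sinking of the INL/OPL
and OPL/ONL boundaries on spectral-domain OCT B-scans — is one of the
earliest robust biomarkers of progression from intermediate age-related
macular degeneration towards geographic atrophy. Finding it manually
means reading every B-scan of every cube; SubsideOCT is for researchers
and reading centres who want that search automated and its accuracy
measured with the field's standard detection metrics.

## The method

Two per-B-scan modules are fused and merged into 3D detections:

* **DM (detection module)** — proposes candidate boxes
  $(x_0, x_1) \times (z_0, z_1)$ with confidence $p_{DM} \in [0,1]$ on
  each B-scan, tuned for high sensitivity (dip-support run proposals +
  anchor grid, trained objectness and box-regression heads).
* **CM (classification module)** — scores each B-scan for subsidence
  presence, $p_{CM} \in [0,1]$ (sigmoid head, class-balanced training
  batches, best-validation checkpoint).
* **Fusion** — every candidate is rescored as
  $p = p_{DM} \cdot p_{CM}$, so a detection is only confident when both
  modules agree.
* **Merging** — candidates on *adjacent* B-scans with in-plane
  IoU $> 0.5$ (strict) are connected; connected components become
  cuboids: the minimum enclosing extent of their members, with
  confidence $\max_i p_i$. The volume score is the maximum cuboid
  confidence; eye and participant scores are maxima over their volumes.

Both modules consume a 3-channel *neighbor stack* (previous / current /
next B-scan, edge slices repeated). Evaluation follows the standard
detection protocol: predicted cuboids match ground-truth lesions at 3D
IoU $\ge 0.25$ with the highest-confidence duplicate rule; FROC
(sensitivity vs FP/volume), ROC/AUC and PR/AP curves; stratified
participant-level k-fold cross-validation with no participant split
across folds.

Because the clinical cohorts behind this problem are private, the
package includes a synthetic layered-retina phantom (smooth boundary
surfaces, drusen, gamma speckle, raised-cosine subsidence events with
exact A-scan ground truth) so every stage is trainable and testable.
See the methods vignette (`vignettes/subsideoct-methods.Rmd`) for the
model, the phantom's assumptions and the design decisions.

## Worked example

Generate a small synthetic dataset, train both modules, and run the full
pipeline on one held-out-style volume:

```r
library(SubsideOCT)

cfg <- simulationConfig(nVolumes = 12, nSlices = 13, positiveFraction = 0.5,
                        seed = 11)
idx <- generateDataset(cfg, "demo-data")
dw  <- unlist(readDatasetMeta("demo-data")$depth_window)

cm <- trainCM(idx, cmConfig(epochs = 10, seed = 3))
dm <- trainDM(idx, dmConfig(inputSize = 128, epochs = 8, seed = 3),
              depthWindow = dw)

vol <- loadVolume(idx$volumePath[3])        # a volume with subsidence
ann <- readAnnotation(idx$annotationPath[3])
pred <- predictVolume(vol, cm, dm)
print(pred$score)
print(head(pred$cuboids[order(-pred$cuboids$confidence), ], 3))
m <- matchDetections(pred$cuboids, annotationToCuboids(ann, dw))
cat(sprintf("TP %d | FP %d | FN %d | ignored %d\n",
            nrow(m$tp), nrow(m$fp), length(m$fnLesions), nrow(m$ignored)))
print(m$tp)
```

Output from this exact script:

```
[1] 0.7449089
   s0 s1        x0       x1       z0       z1 confidence
28  7 11  76.33672 138.9739 52.95485 135.0869  0.7449089
16  3  7 144.00000 206.3944 53.01694 134.5738  0.6669498
32 10 13  99.74256 115.5135 52.95056 135.8175  0.4589772
TP 2 | FP 35 | FN 0 | ignored 0
  cuboidIndex lesionId confidence       iou
1          16        1  0.6669498 0.3486205
2          28        2  0.7449089 0.6455415
```

`pred$score` is the volume-level subsidence confidence (max over merged
cuboids). Each cuboid row is a 3D detection: half-open slice interval
`[s0, s1)`, lateral extent `[x0, x1)` in columns, depth extent
`[z0, z1)` in rows, and its fused confidence. The match result shows the
top detection hitting each annotated lesion (TP), with no false
negatives; lower-confidence duplicates over an already-detected lesion
are "ignored" (counted neither TP nor FP), and everything else counts
as FP and is what the FROC confidence sweep prices.

A full cross-validated experiment is one call
(`runCvEvaluation(idx, k = 2, ...)`) or one command:

```sh
Rscript inst/scripts/subsideoct run-all --config cfg.yaml --seed 1 --out run/
```

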
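---
title: "Multi-scale attention networks for pulmonary nodule detection: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale attention networks for pulmonary nodule detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nodulemsa)
```

## The problem and the model

Pulmonary nodules — roughly spherical lesions of 3 to 30 mm — are the early
radiological sign of lung cancer, and screening CT produces far more volumes
than radiologists can read exhaustively. `nodulemsa` implements a two-stage
detection system for thoracic CT: an anchor-based *candidate detector* tuned
for high sensitivity, followed by a *false-positive-reduction* (FPR)
classifier that rescues specificity. Both stages are built from one
component, the 3D **multi-scale attention (MSA) block**, which combines
three ideas:

1. **Pre-activation.** Every convolution inside the block is fronted by
   `BN -> ReLU` rather than followed by it, so each convolution sees a
   standardized, activated signal. In small-sample medical imaging this
   measurably curbs over-fitting.
2. **Hierarchical channel split (Res2Net-style).** The block's feature map
   is split along channels into `s = 4` equal groups `x1..x4`. The first
   passes through (`y1 = x1`); each later group is transformed by a small
   `3x3x3` filter of `m = n/4` channels after adding the previous output:
   `y2 = K2(x2)`, `yi = Ki(y_{i-1} + xi)` for `i = 3, 4`. Concatenating
   `y1..y4` yields features whose effective receptive fields span several
   scales *within one block* — matched to the 3-28 mm span of nodule sizes.
3. **Quadruplet attention (CQAM).** Four branches each compress one
   dimension to a 2-channel `[max, mean]` summary (Z-Pool), pass it through
   a single `k^3` convolution (2 -> 1 channels), BN and a sigmoid, and
   multiply the resulting weights back onto the input; three of the
   branches first rotate the channel dimension against one spatial
   dimension, capturing cross-dimension interactions. Branch outputs are
   averaged. The module costs `4(2k^3 + 2)` parameters — 2752 at `k = 7` —
   independent of the channel count, unlike squeeze-and-excitation units
   whose cost grows quadratically in channels.

The detector is a Faster-R-CNN-style design: a U-Net-like encoder-decoder
backbone (four stride-2 max-pools, two deconvolutions, skip concatenations)
ending in a `1x1x1` head that emits, per output-grid cell and per anchor,
an objectness logit and a 4-vector box regression. Anchors are cubes of 5,
10 and 20 mm at stride 4; a box is encoded relative to its anchor as
`((x - x_a)/d_a, (y - y_a)/d_a, (z - z_a)/d_a, log(d/d_a))`. Anchors with
IoU above 0.5 against a nodule are positive, below 0.02 against all nodules
negative, and ignored otherwise; the loss is
`lambda * L_cls + p* * L_reg` with `lambda = 0.5`, binary cross-entropy for
classification and smooth-L1 (`sigma = 1`) for regression on positive
anchors only. (The classification loss is implemented as the *negative*
log-likelihood — a minimized, non-negative quantity.)

The FPR network crops a cube at each candidate center (48^3 voxels in the
full profile), passes it through two stem convolutions, three
`{max-pool + MSA}` stages, a final max-pool, global average pooling,
dropout (rate 0.5, training only) and a single-logit head.

## Evaluation

Candidates with probability above 0.12 survive; greedy 3D NMS at IoU 0.1
de-duplicates them. A candidate *hits* an annotation when its center lies
within the annotation radius (the LUNA16 convention; the predicted diameter
is not used), each annotation being matched at most once, to its
highest-probability hitting candidate; surplus hitting candidates count as
false positives. The FROC curve reads sensitivity at 0.125, 0.25, 0.5, 1,
2, 4 and 8 FP/scan with step-wise interpolation, and the CPM is the
arithmetic mean of those seven sensitivities. A scan-level bootstrap
(resampling scans with replacement, percentile 2.5/97.5%) provides the
optional 95% band; the paper-scale setting is 1000 resamples.

## What the synthetic phantoms emulate

The phantom generator (`generate_phantom()`) produces, deterministically
per seed: an air background, a soft-tissue body cylinder, two ellipsoidal
lungs at -850 HU with additive Gaussian noise (sd 30 HU), spherical nodules
whose radial profile falls off as a Gaussian-blurred step (so the FWHM of
the profile equals the annotated diameter), and vessel-like random-walk
tubes of radius 1-3 mm at soft-tissue density as false-positive
distractors. Nodule centers stay inside the lungs (at least 60% of each
sphere in-lung, so juxtapleural nodules survive the mask), pairwise
separated by at least the larger diameter. World origins are randomized per
scan to exercise coordinate handling, and spacing can be made anisotropic
(2.5 mm slices) to exercise resampling.

What the phantoms do *not* emulate: airway trees, beam hardening, motion,
reconstruction kernels, subsolid texture, or the anatomical variability of
real parenchyma. A pipeline that passes the phantom experiment is wired
correctly and can learn blob-vs-tube discrimination end to end; nothing
here certifies clinical performance — that requires the full-profile
configuration trained on LUNA16-scale data.

## Preprocessing choices

* HU clipped to `[-1200, 600]` and scaled to `[0, 255]`; network inputs are
  further scaled to `(v - 128)/128`. The latter constant is our choice (the
  normalization end-points are standard for lung CT).
* Lung segmentation: binarize below -320 HU, drop components touching the
  axial border (exterior air), keep the largest one or two interior
  components, morphological closing (ball radius 3), axial-slice hole
  filling, dilation by 2 voxels to retain juxtapleural nodules. This is the
  standard thresholding-plus-morphology recipe; all radii are arguments.
* Masked-out and out-of-bounds voxels are set to 170 (0-255 scale, about
  soft tissue) so crop borders do not introduce artificial air-tissue
  edges.
* Volumes are resampled to isotropic 1 mm before patching, making the
  mm-denominated anchors coincide with voxels. Resampling is trilinear and
  can be disabled.
* Candidate centers are restricted to the lung mask carried by the
  preprocessed volume: the padded exterior is soft-tissue-valued by
  construction, and detections there are not lung findings. This is the
  point of lung-parenchyma extraction in the first place.

## Numerical and design choices

* **Batch normalization** uses per-channel statistics of the current
  forward pass during training (batch size 1 per backward accumulation —
  i.e. instance-style statistics) and running statistics (momentum 0.1,
  eps 1e-5) at inference. Inference is therefore deterministic.
* **Attention kernel** `k = 7` with padding 3 by default (the 2D antecedent
  of the attention module uses 7); the desk profile uses `k = 5` purely for
  CPU cost.
* **Block order**: entry pre-activated `3x3x3` conv sets the width, Res2Net
  transform, `1x1x1` pre-activated fuse conv, CQAM, then the residual
  addition (identity or `1x1x1` projection). The alternative
  attention-after-addition order is exposed via
  `msa_block(attention_order = "post_residual")`; published figures do not
  disambiguate the two, and we default to attention inside the branch so
  the shortcut stays clean.
* **Force-matching**: every annotation gets its argmax-IoU anchor as a
  positive even below the 0.5 threshold — a 3 mm nodule can never reach IoU
  0.5 against a 5 mm anchor lattice at stride 4, and without this rule
  small nodules would contribute no positives at all. Configurable off.
* **Negative sampling**: per patch, `min(64, 2 n_pos + 32)` negatives enter
  the classification term, bounding the ~41k-anchor imbalance. Ties in
  argmax-IoU break to the lowest anchor index; NMS ties break on
  coordinates; both keep runs reproducible.
* **Degenerate inputs**: empty lung masks return a warning-carrying empty
  mask, not an error; empty candidate lists flow through NMS, rescoring and
  CSV I/O; FROC with zero annotations is an error (sensitivity has no
  denominator).

## The desk-scale experiment

`run_desk_experiment()` is the package's end-to-end property check, used by
the test suite and the acceptance script. Problem sizes were chosen once,
as the package's own desk-scale study design: 10 phantoms of 96^3 voxels at
1 mm (2-3 solid nodules each, 8-16 mm), 8 training / 2 held-out scans; the
detector shrunk to 32^3 patches (widths 4-8, one block per stage, 8^3
output grid), 400 SGD steps at batch 4 (learning rate 0.01, decayed 10x for
the last quarter, with tail weight averaging over that quarter); the FPR
classifiers on 16^3 cubes, 120 steps at batch 12 each.
The medium-nodule band is deliberate: the shrunken 8^3 grid cannot
sub-voxel-localize 3 mm nodules, while the full-profile generator default
keeps the complete 3-28 mm span.

Several desk-profile adaptations of the second stage proved necessary and
are worth recording.

* The FPR cube covers a 32 mm field of view resampled onto the 16^3 input
  grid: at desk scale, context (tube vs sphere, pleural border) matters
  more than sub-millimetre resolution. In particular the soft-tissue pad
  value (170) is nearly the intensity of a solid nodule (174), so
  narrow-field cubes at the pleural border are genuinely ambiguous.
* `train_fpr()` performs bootstrapped hard-negative emphasis: after the
  first half of training it scores all negative candidates and draws half
  of each subsequent batch's negatives from the hardest decile. With ~200
  candidates per scan and only ~20 positive cubes, uniform sampling visits
  each negative less than once — the classic imbalance that
  false-positive-reduction stages exist to solve.
* The positive cubes include crops at the reference annotation centers
  (plus jittered copies), not only at detected candidates
  (`train_fpr_dataset(annotation_positives = TRUE)`): the reference
  standard itself provides labelled positives, and two dozen detected
  positives are too few to train on alone.
* The experiment trains three independently initialized FPR classifiers,
  keeps the two with the best *training-set* ranking quality (an
  occasional member collapses during so short a run, and its own training
  data exposes that without touching the held-out scans), and averages
  their probabilities: individual short CPU runs are high-variance, the
  selected average much less so. Both hard-negative mining and tail
  (Polyak) weight averaging start only once the learning rate has
  decayed, so the mined distribution fine-tunes rather than destabilizes;
  the detector likewise tail-averages its weights over the decayed-rate
  phase.
* The final candidate score fuses both stages geometrically,
  `sqrt(p_detector * p_fpr)`, rather than discarding the detector's
  evidence; `rescore_with_fpr()` itself still implements the pure
  replacement contract.
* The candidate stream into the second stage is capped at the 250
  highest-probability candidates per scan.

On one CPU the whole experiment runs in about ten minutes. The acceptance
property — sensitivity at least 0.8 at no more than 4 FP/scan on the
held-out phantoms, for at least two of three fixed seeds — is a wiring and
learnability check at desk scale, not a reproduction of the published
LUNA16 CPM; the published headline numbers enter the acceptance outputs
only through the CPM reducer applied to the published operating
sensitivities. With only six held-out nodules per run, the operating
points are coarse (multiples of 1/6) and individual seeds vary
substantially — exactly why the criterion is framed as two of three
seeds rather than a single run.

## Known limitations

* The engine is CPU-bound R/C++ with explicit gradients; the full profile
  (96^3 patches, widths 24-64, 100 epochs, 888 scans, tenfold
  cross-validation) is configured (`inst/extdata/luna16-full.yaml`) but not
  runnable at desk scale.
* Batch statistics with effective batch 1 make training noisier than
  GPU-batch BN; running-statistics inference mitigates but does not remove
  the train/eval gap.
* The hit criterion, interpolation rule and duplicate-candidate handling
  follow one (common) convention; published evaluations do not always state
  theirs, so third-party CPM values may not be bit-comparable.
* The phantom's vessel model is a blunt distractor; real vasculature,
  fissures and pleural irregularities are harder negatives than anything
  the generator produces.
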
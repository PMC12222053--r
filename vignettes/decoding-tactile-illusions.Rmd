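---
title: "Decoding tactile illusion percepts from task fMRI: models, simulation, and ROI saliency statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding tactile illusion percepts from task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

The Aristotle illusion is a classic tactile illusion: with the index and
middle fingers crossed, a single object touched between the fingertips is
felt as two, while two objects touched on the outer sides of the crossed
fingers are felt as one (the Reverse illusion). `sfcnfmri` implements an
end-to-end decoding analysis of this phenomenon: whole-brain BOLD volumes
acquired during tactile stimulation are classified by a lightweight 3D
convolutional network (SFCN) according to either the stimulus applied or
the percept reported, and the trained classifiers are interrogated with
Grad-CAM saliency mapping followed by an atlas-based region-of-interest
(ROI) statistic to localize the brain regions the classifier relies on.

Because suitable raw fMRI recordings are rarely shareable, the package
includes a first-class synthetic-data generator that emulates the
experimental design — block-design stimulation trials with button-press
percept reports, and 4D BOLD volumes in which percept-discriminative signal
is confined to designated atlas regions. The generator makes every
downstream claim testable: decoding accuracy, saliency localization, and
the false-positive behavior of the ROI statistic can all be checked against
planted ground truth.

## The experimental paradigm being emulated

Each trial presents one of three stimulation conditions — *Aristotle* (one
object between crossed fingers), *Reverse* (two objects on the outer
sides), *Asynchronous* (two objects touched at different moments, a
veridical control) — in a fixed cycle: 15 s of stimulation, a 3-s question
asking how many stimuli were felt (Q1: button 1 = one, button 2 = two),
another 15 s of identical stimulation, a 6-s question about the perceived
distance (Q2: buttons 1–4), and 9 s of rest. One trial cycle therefore
lasts 48 s; a session holds five trials of each condition (15 trials,
720 s); a participant completes two sessions (1,440 s). Volumes are
acquired at TR = 3 s, so a session spans 240 volumes. The trial order is
fully randomized per session.

A trial counts as an *illusion trial* when the report contradicts the
stimulus: feeling two under Aristotle stimulation, or feeling one under
Reverse/Asynchronous stimulation. The illusion rate of a condition is the
proportion of illusion trials among *responded* trials — non-response
trials are retained in the event table but excluded from every denominator
and from all classifier sample sets.

The behavioral generator's default illusion probabilities are the response
ratios of the cohort the design is modeled on (544/596 for Aristotle,
212/594 for Reverse, 48/590 for Asynchronous, at the stimulation-epoch
level; each responded trial contributes two epochs, so the trial-level
counts are half these). Perceived-distance (Q2) distributions are free
generator parameters; only their ordering (Aristotle > Asynchronous >
Reverse in mean perceived distance) is meaningful, and nothing downstream
depends on the individual category weights.

## Synthetic BOLD model

The voxel time series of one session is

    y_v(t) = baseline
           + sum_c a_c * gain_s * (boxcar_c ⊗ h)(t) * [v in ROIs(c)]
           + AR(1) noise,

where `c` ranges over *activation classes* — either stimulation conditions
or the percept classes `percept_one` / `percept_two` keyed to the trial's
simulated Q1 report — `boxcar_c` indicates that class's stimulation
epochs, and `h` is a canonical double-gamma hemodynamic response function
(response gamma with shape 6, undershoot gamma with shape 16 at ratio 1/6,
sampled at the TR and normalized so a sustained boxcar plateaus at 1).
With that normalization an amplitude `a_c` is directly interpretable as
the steady-state signal change in baseline units. `gain_s` is a
per-subject multiplicative jitter (SD 0.1 by default) that creates
between-subject amplitude variability.

Defaults: white-noise SD 1, AR(1) coefficient 0.3, baseline 100,
amplitudes of order 1–3. At those settings the per-voxel discriminative
contrast of an epoch-averaged sample is roughly two z-units, which places
the scaled-down classifier in a regime of high but not saturating
validation accuracy — comparable to the upper range reported for
perception-based decoding of this paradigm. The generator does not model
head motion, physiological noise, or field inhomogeneity; volumes are
born spatially registered, which is what permits voxelwise averaging of
saliency maps across subjects later. Passing tests on these synthetic
volumes therefore demonstrates the correctness and calibration of the
pipeline, not robustness to real-scanner artifacts.

The synthetic atlas partitions an ellipsoidal brain mask (semi-axes 45% of
each grid extent) into `n_rois` compact regions by seeded Voronoi growth:
seed voxels are drawn uniformly from the mask and every mask voxel joins
its nearest seed. On the default desk-scale 32³ grid with 40 ROIs this
yields regions of ~300–400 voxels, about 8–9 voxels across — a stand-in
for an anatomical parcellation at roughly the ROI-to-brain volume ratio of
a 120-region atlas on full-resolution data. Any user-supplied
integer-labeled NIfTI parcellation can be substituted.

## From volumes to classifier samples

Each stimulation epoch becomes one 3D sample: the voxelwise mean of the
five volumes in the window shifted 2 TRs (6 s) after epoch onset — the
shift matches the canonical HRF peak; the epoch-to-sample mapping
(one sample per epoch, two per trial) is fixed by the design's sample
bookkeeping. Samples are z-scored per voxel across the session's samples;
zero-variance voxels map to zero. Z-scoring is an input-normalization
convention, not a claim about the original analysis, which left
normalization unstated.

Five binary tasks are defined. Stimulus-based: Aristotle vs. Reverse,
Reverse vs. Asynchronous, Aristotle vs. Asynchronous. Perception-based:
Aristotle illusion (Aristotle & Q1 = 2) vs. Reverse illusion (Reverse &
Q1 = 1), and Reverse-illusion occurrence (Reverse & Q1 = 1) vs. absence
(Reverse & Q1 = 2). The first-named class is the positive class (label 1);
for perception tasks that is the illusion-occurrence class. The severely
imbalanced "absence of the Aristotle illusion" contrast (52 cases in the
reference cohort) is deliberately not offered as a task.

Cross-validation is grouped at the trial level: the two epochs of a trial
always land on the same side of a split, and each of the k = 5 folds holds
~20% of trials out for validation (an 8:2 ratio). Within each fold the
*training* portion only is balanced by randomly undersampling the majority
class; validation data keep their raw class ratios. Remainder trials go to
the earlier folds after a seeded shuffle.

## The SFCN classifier

The SFCN is a chain of feature blocks — 3×3×3 convolution (stride 1, zero
padding), batch normalization, ReLU, optionally 2×2×2 max pooling — closed
by a final block whose 1×1×1 convolution feeds a global average pooling
and a fully connected layer producing two class scores. Training minimizes
softmax cross-entropy with Adam-style stochastic gradient descent using
*decoupled* weight decay (weights are shrunk by `1 − lr·wd` per step;
batch-norm parameters and biases are exempt). Per-task default
hyperparameters follow the published optima: stimulus tasks 1e-3 / 0.4 /
batch 64; Aristotle-illusion vs. Reverse-illusion 3e-4 / 0.4 / 32;
Reverse-illusion occurrence 1e-5 / 0.2 / 16. The checkpoint with the best
validation accuracy across epochs is kept.

Two numerical choices deserve note.

First, **batch-norm population statistics**: with the short training runs
appropriate for desk-scale data, momentum-based running estimates do not
converge, which silently breaks eval-mode inference. Each epoch therefore
re-estimates the population statistics as the cumulative average of that
epoch's batch statistics, so validation accuracy is meaningful from the
first epoch.

Second, **architecture scaling and saliency resolution**. Grad-CAM lives
at the resolution of the last convolutional layer, and its usefulness for
ROI localization depends on two architectural quantities: the feature-map
grid (finer is better) and the receptive field of last-layer units
(smaller is more local — a unit that sees the whole brain can respond to a
focal signal from anywhere, delocalizing the map). On full-resolution
inputs (~96 voxels per axis) the published six-block, five-pooling layout
is appropriate. On the desk-scale 32³ grid the package's scaled-down
default `sfcn_config()` pools while each axis stays ≥ 3 after halving
(three poolings at 32³). For ROI-recovery analyses, however, deeper
pooled variants turn out to classify perfectly while delocalizing the
saliency — their last-layer units see most of the volume, so planted
signal lights up the whole map and the ROI statistic flags neighbors of
the true regions. The recovery experiments
(`planted_recovery_config()`) therefore use a three-block SFCN with no
pooling at all (channels 4/8/8): its last conv layer sits on the full
32³ grid with a 5-voxel receptive field, well below the ~9-voxel ROI
scale of the synthetic atlas, and the significant set collapses onto the
planted regions. Exact scaled-down widths, depths, and pooling
placement are configuration knobs, not claims about the original model,
whose precise channel configuration is not public; the parameter count is
correspondingly not asserted anywhere.

## Grad-CAM and the grand-mean ROI statistic

For a sample with target class `c` (by default its true label; the
predicted class is available as an option), the saliency map is

    L = ReLU( sum_k alpha_k A_k ),   alpha_k = mean_v ( dy_c / dA_k(v) ),

with `A_k` the post-ReLU feature maps of the last convolutional layer and
`y_c` the class score before softmax. Maps are computed for validation
samples only, with each fold's trained model, upsampled trilinearly
(corner-aligned) to the input grid, and averaged voxelwise — individual
maps are deliberately *not* min-max normalized before averaging, since
rescaling would distort the pixel-wise average; normalization is offered
only for visualization.

Per subject, all of that subject's validation-sample maps (pooled across
folds) are averaged; per ROI, the subject map is averaged over the ROI's
voxels, giving a subjects × ROIs matrix. The *grand mean* — the mean over
every (subject, ROI) entry — serves as a fixed reference value: each ROI's
subject values are compared to it with a one-sample Wilcoxon signed-rank
test (exact null distribution up to 25 nonzero differences, normal
approximation beyond; zero differences discarded by the classical
convention, with an ROI reported untestable at p = 1 if all differences
vanish). P-values are corrected across ROIs by Benjamini–Hochberg FDR, and
ROIs with q < 0.05 are flagged. Treating the grand mean as a constant
(rather than re-estimating it leave-one-out) is a statistical
simplification inherited from the procedure being reimplemented, and is
noted as such.

Two-sided tests are the conservative default; analyses asking specifically
which ROIs show *elevated* saliency (the planted-signal recovery
experiments, for instance) use `alternative = "greater"`, which is the
directional question the procedure was designed to answer. For each
significant ROI the package also reports subject-wise values with mean ±
standard error and each subject's whole-matrix mean — the baseline against
which narrow inter-individual spread is judged.

A caveat worth stating explicitly: all subjects' saliency maps are
produced by the same five fold models, so subject values are not fully
independent, and any model-induced spatial bias is shared across subjects.
In the planted-signal experiments this manifests as saliency spilling into
ROIs adjacent to the true ones; the grand-mean reference compensates
partially because strong true ROIs lift the grand mean above the
background. Users should read marginally significant neighbors of strong
ROIs with this in mind.

## Problem sizes used by the test suite and acceptance script

All empirical checks run on synthetic data at sizes chosen for a single
CPU: the planted-recovery experiment uses 12 subjects × 2 sessions on a
32³ grid with a 40-ROI atlas and signal of amplitude 2 planted in three
mutually distant ROIs, trained with the no-pooling three-block SFCN for
10 epochs per fold (5 folds; about ten minutes of CPU); reduced
replicates run the same recipe on a 16³ grid with 20 ROIs and one
session per subject;
the null-calibration experiments shuffle labels at the trial level and/or
use exchangeable-noise subject × ROI matrices over 50 replicates. Paradigm
and class-size arithmetic is checked exactly against the printed design
numbers of the emulated study; Grad-CAM and the Wilcoxon test are checked
against finite-difference and exhaustive-enumeration oracles.

## Known limitations

- The generator's noise model is stationary AR(1) + white noise; real
  BOLD has structured physiological and motion components that the
  pipeline never sees in testing.
- Saliency resolution is bounded by the feature grid and receptive field
  of the last conv layer; ROIs smaller than a feature cell cannot be
  resolved, and neighbors of strongly salient ROIs inherit spill.
- The grand-mean Wilcoxon procedure treats subjects as independent even
  though they share fold models (see above).
- Perceived-distance (Q2) modeling is descriptive only; no reaction-time
  or within-trial dynamics are simulated.
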
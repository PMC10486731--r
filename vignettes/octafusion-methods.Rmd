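---
title: "Grading diabetic retinopathy from paired 3D OCTA acquisitions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading diabetic retinopathy from paired 3D OCTA acquisitions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Optical coherence tomography angiography (OCTA) produces depth-resolved
volumes of the retina with two registered channels: a *structure* channel
(reflectance) and a *flow* channel (decorrelation between repeated scans,
highlighting perfused vessels). Two acquisition formats are clinically
complementary. A high-resolution 6×6 mm scan (`hr6`) resolves the macular
capillary network, where the earliest signs of diabetic retinopathy (DR) —
small flow voids near the fovea — appear. An ultra-widefield 15×15 mm scan
(`uwf15`) covers the periphery, where the large non-perfusion areas that mark
advanced disease develop, at coarser lateral sampling.

octafusion implements a hybrid fusion framework for grading DR severity on
the six-level ordinal scale (no DR, mild/moderate/severe non-proliferative
DR, proliferative DR, and eyes treated by panretinal photocoagulation, which
rank above PDR) from one or both acquisitions per eye:

1. **Preprocessing** reduces a raw volume to the retinal band: the internal
   limiting membrane (ILM) and retinal pigment epithelium (RPE) surfaces are
   segmented, each A-scan is shifted so the ILM is flat, and the band is
   resampled to a fixed depth (nominally 224 samples; 500×224×500×2 and
   834×224×834×2 voxels for the two acquisitions).
2. **Backbones**: 3D versions of ResNet50, DenseNet121 and EfficientNetB0,
   trained from scratch, classify fixed-size crops into the six grades.
3. **Single-acquisition fusion** combines the structure and flow channels at
   the input, feature, decision, or hierarchical level.
4. **Cross-acquisition fusion** merges the two acquisitions, either by
   joint feature fine-tuning or by decision fusion of output probabilities.
   The proposed hybrid is hierarchical fusion within each acquisition and
   decision-average fusion across acquisitions.

Inference uses *N-times random cropping*: N random sub-volumes are classified
and aggregated by the severest rule (per binary task, the maximum cumulative
score over crops; the discrete grade is the severest argmax). N = 10 (hr6)
and 20 (uwf15) are the validated trade-offs; the nominal crop is
224×224×224×2, so ⌈500/224⌉·⌈224/224⌉·⌈500/224⌉·⌈2/2⌉ = 9 windows
(respectively 16 for the widefield volume) would be needed to tile a volume,
and N is chosen slightly above that count.

Evaluation uses four cumulative binary tasks — task *k* detects grade
≥ *k*+1, scored by AUC with ties counted half — and Cohen's kappa
κ = (p₀ − pₑ)/(1 − pₑ) on the 6-class confusion matrix.

## The embedded 3D conv-net engine

The package carries a compact reverse-mode automatic-differentiation engine:
R arrays flow through Rcpp/Armadillo kernels (dense and depthwise 3D
convolution via im2col + GEMM, max pooling, adaptive average pooling) and
vectorized R ops (group normalization, activations, linear heads,
softmax cross-entropy), recorded on a tape and replayed backwards. Gradients
are verified against central finite differences in the test suite. The
optimizer is Adam with an exponential learning-rate decay (gamma 0.99 per
epoch), batch size 2, as in the reference protocol.

Two deliberate deviations from the canonical 2D architectures:

* **Cubic kernels.** Every 2D convolution/pool becomes its cubic 3D
  counterpart with the stage layout preserved (stem stride 4, four stages at
  1/4 … 1/32 resolution; a 56³ input yields 14³, 7³, 4³, 2³ stage maps for
  the residual net).
* **Group normalization** replaces batch normalization. With batch size 2
  (and desk-scale batches of 1-2 crops), batch statistics are too noisy;
  group normalization is per-sample, identical in training and inference,
  and makes seeded runs exactly reproducible. Groups of 8 channels are used
  (all widths are rounded to multiples of 8).

A `width_mult` knob uniformly scales channel counts (minimum 8), so the same
topologies train on one CPU at desk scale.

## Hierarchical fusion wiring

Feature fusion concatenates the branch-pooled feature vectors under one
linear head. Hierarchical fusion adds a third *fusion branch*: at each of
the four scales the two branch feature maps are channel-concatenated,
projected back to the branch width by a 1×1×1 convolution, and added to the
fusion branch's carried signal (its previous-scale output through a 1×1×1
convolution + normalization, adaptively pooled to the current scale). The
decision head sees the concatenation of
`[branch1 pooled, branch2 pooled, fusion pooled]`. With the fusion-branch
head slice zeroed this reduces exactly to feature fusion, which the tests
assert. Mixed-architecture branches are supported by aligning feature-map
sizes with adaptive average pooling; this follows the finding that
mixed-architecture hierarchical fusion underperforms, so it is not the
default.

Decision fusion averages probability vectors (`avg`, stays on the simplex)
or takes the renormalized elementwise maximum (`max`). Renormalization is
our choice: the maximization strategy is named but not defined in the
reference protocol, and renormalization keeps the output a probability
vector.

For the hybrid model, crops are aggregated *within* each acquisition first
and the two acquisition-level results are then fused, consistent with
decision fusion operating "on the final output probability after each
branch". The per-task scores are the rule's elementwise combination (mean
for `avg` — equivalent to scoring the averaged probability vector, since
cumulative task scores are linear in it — and maximum for `max`); the
discrete grade is the argmax of the fused probability vector.

## The synthetic cohort generator

The clinical dataset behind the framework is private, so the package ships a
seeded generator that reproduces the *statistical structure* the framework
relies on, not retinal physics:

* **Geometry.** Raw grids are the nominal 500×1536×500×2 (hr6) and
  834×3072×834×2 (uwf15) scaled by `volume_scale`; curved ILM/RPE surfaces
  (a radial bowl plus smooth random cosine fields) are embedded in raw
  depth. The structure channel has a sharp vitreous→retina step at the ILM,
  layered bands inside the retina, a bright RPE band with a sharp lower
  edge; the flow channel has a filamentous vessel texture (ridges along the
  zero set of a smooth random field) inside the inner vascular band.
* **Severity-dependent lesions.** Grades ≥ 1 carry small central flow voids
  (radius 0.35-0.55 mm, counts 2/4/4/4/4 for grades 1-5) inside the central
  3 mm disc; they are rendered at full contrast on the hr6 grid and at a
  third of the amplitude on the uwf15 grid (resolution loss). Grades ≥ 3
  additionally carry large peripheral non-perfusion patches (radius
  1.2-2 mm, counts 2/4/6 for grades 3-5) placed so their entire (compactly
  truncated) footprint lies outside the jittered 6×6 mm field — visible only
  to the widefield acquisition. Central burden saturates at grade 2 by
  design: the high-resolution acquisition can detect disease but cannot
  separate its advanced stages, while the widefield acquisition can — the
  complementarity the hybrid model exploits.
* **Cohort structure.** Patients contribute 1-2 eyes, eyes 1-2
  acquisitions (probabilities 0.9 by default); grades are drawn from a
  severity distribution defaulting to the empirical class imbalance of a
  paired clinical cohort (19%/10%/47%/14%/3%/6%). Paired acquisitions are
  deliberately unregistered (independent lateral jitter of ±0.3 mm).

What the generator does **not** emulate: OCT speckle statistics, real
vascular topology, segmentation-hostile pathology (detachments, large
cysts), device artifacts. Passing tests therefore demonstrate that the
pipeline recovers the designed statistical structure, not clinical
performance.

A fixed linear probe (mean flow in the inner band, thresholded) must
separate {0} vs {1,2} better on hr6 and {0-2} vs {3-5} better on uwf15 on
cohorts of ≥ 100 eyes; this is asserted in the tests and is what makes the
acquisition-complementarity experiment testable in miniature.

## Preprocessing choices

* **Surface segmentation** is unspecified upstream; we use per-A-scan
  maximum rising gradient (ILM) and maximum falling gradient below the ILM
  (RPE lower boundary) on a depth-smoothed structure channel, followed by a
  3×3 median filter of each surface map. On synthetic volumes the estimates
  are within 2 voxels of ground truth on average (asserted).
* **Depth resampling** of the [ILM, RPE] band to `d_target` uses linear
  interpolation; lateral resizing uses trilinear interpolation with
  align-corners mapping (identity shapes return the input; constants are
  preserved).
* **Cropping.** Center crops sit at `floor((dim − patch)/2)`; random crops
  are uniform over all in-bounds origins; the subvolume grid tiles at
  stride = patch with the last window clamped flush to the boundary,
  matching the ceiling-count arithmetic (9 and 16 windows at nominal
  shapes). Volumes smaller than the patch on any axis are zero-padded
  symmetrically — the nominal geometry never needs this, but scaled desk
  volumes can.

## Training protocol and desk scale

The nominal protocol is Adam at 1e-4, ExponentialLR gamma 0.99, 500 epochs,
batch 2, one random crop per example per epoch, augmentation by random gamma
(exponent in [0.7, 1.5]), Gaussian noise (sd 2% of the dynamic range) and
lateral flips (p = 0.5 per lateral axis; depth is never flipped — the retina
is oriented). Checkpoints are selected on the validation mean of the four
task AUCs (the protocol names no selection metric; this is our choice,
tie-broken by kappa). Class imbalance is handled only by stratified
splitting; the cross-entropy is unweighted.

Desk-scale runs — the test suite, the worked examples, the acceptance
script — shrink the problem so it runs on one CPU in minutes:

* `volume_scale = 0.06`: hr6 volumes of 30×92×30×2 raw voxels flattened to
  30×13×30×2, uwf15 50×184×50×2 → 50×13×50×2, crops of 13³×2. The tiling
  geometry is preserved (3×1×3 and 4×1×4 windows).
* `width_mult = 0.25` backbones (≈ 2.9 M parameters for the 3D residual
  net).
* 14-30 epochs at learning rate 3e-4 without augmentation. The nominal
  rate of 1e-4 is tuned for hundreds of thousands of optimizer steps;
  desk-scale runs take a few hundred, and 3e-4 is the rate at which the
  scaled backbones reliably fit deterministic data in that budget (much
  higher rates destabilize feature learning under group normalization —
  3e-3 fails to learn at all). Augmentation is a regularizer for long runs;
  in few-hundred-step runs it slows convergence without benefit.
* Prediction uses 4 (hr6) and 8 (uwf15) random crops instead of 10/20.

The benchmark in `fusion_benchmark()` generates a 60-patient cohort
(~110 eyes), reserves 30 fully-paired test patients (~60 test eyes, the
same fixed test set for all three models), trains one hierarchical
structure/flow model per acquisition on the remaining eyes (~42 per task),
and evaluates both plus their decision-average hybrid. The expected pattern,
asserted as orderings on the mean over three seeded replicates (margins are
not asserted; the experiment is stochastic):

* the hr6 model beats the uwf15 model on task 0 (early detection),
* the uwf15 model beats the hr6 model on task 3 (advanced disease),
* the hybrid's mean AUC is at least each single-acquisition mean.

The widefield branch trains for 20 epochs against 14 for the
high-resolution branch: its discriminative classes (grades ≥ 3) are the
rare ones, and random 13³ crops of an unregistered 50×50 field carry the
peripheral-lesion signal less often, so it needs more steps to reach its
plateau.

## Numerical and degenerate-input policy

* Probability vectors are validated to the simplex within 1e-6; the
  severest-crop tie-break picks the crop with the higher probability of the
  severest grade.
* AUC is the midrank Mann-Whitney statistic (ties count half) — necessary
  because max-aggregated scores collide often; single-class label sets
  raise an error (`evaluate_model()` converts that to an `NA` AUC with a
  warning for tasks missing a class in small test sets).
* Kappa is undefined when chance agreement is 1 (single-cell margins): an
  error.
* All-zero or constant volumes raise a surface-not-found error in
  segmentation; `d_target < 2`, empty crop lists, zero patch dimensions and
  non-simplex severity distributions are validation errors.
* Group-norm group counts fall back to the largest power of two dividing
  the channel count.

## Known limitations

* The engine is CPU-bound and single-threaded beyond BLAS; nominal-scale
  (224³) training is out of reach — the package targets method correctness
  and desk-scale experiments, not clinical throughput.
* The synthetic generator's lesion model is invented; none of the reported
  desk-scale metrics say anything about accuracy on real OCTA.
* Checkpoint selection uses only validation data by construction
  (`train_model()` never sees test records; splits are patient-level and
  the tests audit the partition), but no runtime guard prevents a caller
  from passing test eyes as validation.
* Cross-acquisition feature fusion follows the protocol (branches
  initialized from the per-acquisition hierarchical models, full vs
  head-only fine-tuning); consistent with the reference findings, it is not
  the default hybrid, and the desk-scale benchmark does not exercise it.
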
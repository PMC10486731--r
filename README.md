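# octafusion

Hybrid multimodal fusion of 3D OCTA volumes for diabetic-retinopathy (DR)
severity grading, in R.

Optical coherence tomography angiography (OCTA) volumes carry two registered
channels — *structure* (reflectance) and *flow* (decorrelation, i.e. blood
flow) — and come in two clinically complementary formats: high-resolution
6×6 mm scans (`hr6`) that resolve the small macular flow voids of early DR,
and ultra-widefield 15×15 mm scans (`uwf15`) that see the large peripheral
non-perfusion areas of advanced DR. octafusion implements the full pipeline
for grading DR on the six-level ordinal scale (no DR, mild/moderate/severe
NPDR, PDR, panretinal-photocoagulation-treated) from one or both
acquisitions per eye:

* **Synthetic cohorts** (`cohort_spec()`, `generate_cohort()`): seeded
  rank-4 volumes with curved ILM/RPE surfaces, vessel-like flow texture and
  severity-dependent lesions whose detectability differs by acquisition —
  a stand-in for private clinical data with the statistical structure the
  framework assumes.
* **Preprocessing** (`segment_surfaces()`, `flatten_and_crop()`,
  `resize_volume()`, `center_crop()`, `random_crop()`, `subvolume_grid()`,
  `traversal_patch_count()`): retinal-band extraction between the internal
  limiting membrane and retinal pigment epithelium, ILM flattening, depth
  resampling (500×1536×500×2 → 500×224×500×2 at nominal scale) and the four
  cropping strategies.
* **3D backbones** (`build_backbone()`): ResNet50, DenseNet121 and
  EfficientNetB0 converted to cubic 3D kernels with a `width_mult` scaling
  knob and four-scale feature pyramids, running on an embedded
  reverse-mode autodiff engine (Rcpp/Armadillo conv kernels, group
  normalization, Adam).
* **Fusion** (`build_input_fusion()`, `build_feature_fusion()`,
  `fuse_decisions()`, `build_hierarchical_fusion()`, `build_hybrid_model()`,
  `cross_feature_finetune()`): structure/flow fusion at input, feature,
  decision or hierarchical level; cross-acquisition fusion by feature
  fine-tuning or decision rules. The proposed hybrid is hierarchical fusion
  per acquisition + decision averaging across acquisitions.
* **Inference & evaluation** (`predict_eye()`, `aggregate_severest()`,
  `task_score()`, `roc_auc()`, `cohens_kappa()`, `evaluate_model()`):
  N-times random-crop prediction with severest-prediction aggregation, four
  cumulative binary tasks (task *k* detects grade ≥ *k*+1) scored by
  tie-aware AUC, and Cohen's kappa κ = (p₀ − pₑ)/(1 − pₑ) on the 6-class
  confusion matrix.
* **Training** (`split_dataset()`, `train_model()`, `augment_patch()`):
  patient-level splits with a fully-paired fixed test set and stratified
  five-fold cross-validation, Adam (lr 1e-4, exponential decay 0.99),
  random-crop training with gamma/noise/flip augmentation.

Results are tibble-friendly: `tidy()`, `glance()` and `autoplot()` methods
cover evaluation reports, training histories and split plans.

## Worked example

Crop-count arithmetic for the nominal geometries (one 224³×2 window per
batch):

```r
library(octafusion)
traversal_patch_count(c(500, 224, 500, 2), c(224, 224, 224, 2))
#> [1] 9
traversal_patch_count(c(834, 224, 834, 2), c(224, 224, 224, 2))
#> [1] 16
```

A desk-scale end-to-end run — synthetic cohort, preprocessing, one
hierarchical structure/flow model per acquisition, decision-average hybrid —
in one call (about six minutes on one CPU):

```r
bench <- fusion_benchmark(seed = 1)
bench$summary
#> # A tibble: 3 x 8
#>   model  kappa  auc0  auc1  auc2  auc3 mean_auc n_eyes
#>   <chr>  <dbl> <dbl> <dbl> <dbl> <dbl>    <dbl>  <int>
#> 1 hr6    0.237 0.868 0.850 0.663 0.478    0.715     60
#> 2 uwf15  0     0.429 0.457 0.5   0.853    0.560     60
#> 3 hybrid 0.04  0.857 0.798 0.759 0.746    0.790     60
```

Reading the table: the high-resolution model detects *any* DR well
(`auc0` = 0.87) but cannot rank advanced disease (`auc3` ≈ 0.48, chance
level), the widefield model shows the mirror image (`auc0` ≈ 0.43,
`auc3` = 0.85), and the hybrid inherits the better half of each
(mean AUC 0.79 ≥ both singles) — the qualitative complementarity pattern the
framework is built on. Kappa is computed on the 6-class confusion matrix of
the severest-crop grades; on ~60 desk-scale test eyes it is noisy and the
single-acquisition models mostly predict the majority grade.

The individual stages are available as a YAML-configured pipeline with a
thin command-line wrapper:

```sh
Rscript inst/cli/octafusion.R pipeline --out-dir runs/demo --seed 1
Rscript inst/cli/octafusion.R benchmark-crops --out-dir runs/demo
```

which writes NIfTI volumes, CSV manifests/predictions and
`metrics.json` / `benchmark_crops.json` (kappa and `auc0`..`auc3` per
model / per cropping strategy).

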
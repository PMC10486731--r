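# Desk-scale cross-acquisition fusion experiment: train one hierarchical
# structure+flow model per acquisition on a synthetic cohort, evaluate both
# and their decision-average hybrid on a fixed fully-paired test set.

#' Run the desk-scale acquisition-fusion benchmark
#'
#' Generates a seeded synthetic cohort, splits it at patient level, trains a
#' hierarchical structure/flow fusion model per acquisition, and evaluates
#' the high-resolution model, the widefield model and their decision-average
#' hybrid on the same fully-paired test eyes. This reproduces, in miniature,
#' the complementarity experiment of the full framework: early disease is
#' expected to favour the high-resolution model (task 0), advanced disease
#' the widefield model (task 3), and the hybrid should match or beat both on
#' the mean of the four task AUCs.
#'
#' Desk-scale defaults (volume scale, epochs, learning rate, crop counts)
#' are chosen so the experiment runs on one CPU in a few minutes; see the
#' methods vignette for the rationale.
#'
#' @param seed Integer seed driving the cohort, split, initialization,
#'   training and prediction crops. The patient split is redrawn (with a
#'   deterministic seed offset) until every binary task has both classes in
#'   the test labels, so all four AUCs are defined.
#' @param n_patients Cohort size.
#' @param n_test Number of fully-paired test patients.
#' @param volume_scale Size factor for the synthetic volumes.
#' @param epochs Named vector: training epochs per acquisition.
#' @param lr Learning rate (desk-scale runs use a slightly higher rate than
#'   the nominal protocol because they take far fewer optimizer steps).
#' @param n_crops Named vector: random crops per acquisition at prediction
#'   (nominal 10/20, scaled down here).
#' @param width_mult Backbone width multiplier.
#' @param arch Backbone family for both branches.
#' @param augment Enable training augmentation.
#' @return List with `evals` (named list of `octa_eval` for `hr6`, `uwf15`,
#'   `hybrid`), `summary` (one-row-per-model tibble of kappa/AUCs),
#'   `n_test_eyes` and `n_train_eyes`.
#' @export
fusion_benchmark <- function(seed = 1L, n_patients = 60L, n_test = 30L,
                             volume_scale = 0.06,
                             epochs = c(hr6 = 14L, uwf15 = 20L), lr = 3e-4,
                             n_crops = c(hr6 = 4L, uwf15 = 8L),
                             width_mult = 0.25, arch = "resnet50_3d",
                             augment = FALSE) {
  seed <- as.integer(seed) %% 100000L
  set.seed(seed)
  spec <- cohort_spec(n_patients, p_both_eyes = 0.9, p_both_acquisitions = 0.9,
                      volume_scale = volume_scale, seed = seed)
  prep <- preprocess_cohort(generate_cohort(spec))
  # every binary task must be defined on the test set (both classes
  # present); redraw the patient split deterministically until it is
  for (attempt in 0:19) {
    plan <- split_dataset(prep, seed = seed + 1000L * attempt, n_test = n_test)
    in_test <- vapply(prep, function(r) r$patient_id %in% plan$test_patient_ids,
                      logical(1))
    test <- build_task_subsets(prep[in_test], "paired")
    lab <- vapply(test, `[[`, integer(1), "grade")
    if (all(vapply(0:3, function(k) length(unique(lab >= k + 1)) == 2,
                   logical(1)))) break
  }
  trainval <- prep[!in_test]

  models <- list()
  n_train <- integer(0)
  for (acq in c("hr6", "uwf15")) {
    sub <- build_task_subsets(trainval, acq)
    n_train[acq] <- length(sub)
    bspec <- backbone_spec(arch, in_channels = 1L, width_mult = width_mult)
    model <- build_hierarchical_fusion(
      fusion_spec("hierarchical", list(bspec, bspec)), seed = seed)
    train_model(model, sub,
                train_config(lr = lr, epochs = epochs[[acq]], seed = seed,
                             augment = augment),
                acquisition = acq)
    models[[acq]] <- model
  }

  labels <- vapply(test, `[[`, integer(1), "grade")
  set.seed(seed + 1L)
  evals <- list()
  for (acq in c("hr6", "uwf15")) {
    preds <- lapply(test, function(r)
      predict_eye(models[[acq]], r$volumes[[acq]], n = n_crops[[acq]]))
    evals[[acq]] <- evaluate_model(preds, labels)
  }
  hybrid <- build_hybrid_model(models, "avg")
  hpreds <- lapply(test, function(r) predict_eye(hybrid, r$volumes, n = n_crops))
  evals$hybrid <- evaluate_model(hpreds, labels)

  summary <- do.call(rbind, lapply(names(evals), function(m)
    cbind(tibble::tibble(model = m), glance(evals[[m]]))))
  list(evals = evals, summary = summary,
       n_test_eyes = length(test), n_train_eyes = n_train, models = models)
}
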
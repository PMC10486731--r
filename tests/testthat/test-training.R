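# Splitting, task subsets, augmentation and the training loop.

paired_cohort <- function(n_patients, seed = 1, p_eye = 1, p_acq = 1) {
  generate_cohort(cohort_spec(n_patients, p_both_eyes = p_eye,
                              p_both_acquisitions = p_acq, seed = seed),
                  render = FALSE)
}

test_that("a fully paired cohort splits 10/90 with five equal folds", {
  cohort <- paired_cohort(100, seed = 2)
  plan <- split_dataset(cohort, seed = 3, test_fraction = 0.1)
  expect_length(plan$test_patient_ids, 10)
  expect_length(plan$fold_assignments, 90)
  expect_equal(as.integer(table(plan$fold_assignments)), rep(18L, 5))
  # partition: no patient in two folds or in both test and folds
  expect_length(intersect(plan$test_patient_ids, names(plan$fold_assignments)), 0)
  expect_false(any(duplicated(names(plan$fold_assignments))))
  all_ids <- unique(vapply(cohort, `[[`, "", "patient_id"))
  expect_setequal(c(plan$test_patient_ids, names(plan$fold_assignments)), all_ids)
  td <- tidy(plan)
  expect_equal(sum(td$role == "test"), 10)
})

test_that("test patients all have both acquisitions in both eyes", {
  cohort <- paired_cohort(60, seed = 4, p_eye = 0.7, p_acq = 0.7)
  plan <- split_dataset(cohort, seed = 5, n_test = 5)
  eyes_per <- split(cohort, vapply(cohort, `[[`, "", "patient_id"))
  for (pid in plan$test_patient_ids) {
    eyes <- eyes_per[[pid]]
    expect_length(eyes, 2)
    for (e in eyes) expect_setequal(names(e$volumes), c("hr6", "uwf15"))
  }
  expect_error(split_dataset(cohort, n_test = 1000), "both acquisitions")
})

test_that("folds are stratified by worst-eye grade", {
  cohort <- paired_cohort(500, seed = 6)
  plan <- split_dataset(cohort, seed = 7, test_fraction = 0.1)
  eyes_per <- split(cohort, vapply(cohort, `[[`, "", "patient_id"))
  worst <- vapply(eyes_per, function(eyes)
    max(vapply(eyes, `[[`, integer(1), "grade")), integer(1))
  w <- worst[names(plan$fold_assignments)]
  overall <- tabulate(w + 1L, 6) / length(w)
  for (f in 1:5) {
    wf <- w[plan$fold_assignments == f]
    freq <- tabulate(wf + 1L, 6) / length(wf)
    se <- sqrt(pmax(overall * (1 - overall), 1e-9) / length(wf))
    expect_true(all(abs(freq - overall) <= 3 * se + 1e-9))
  }
})

test_that("task subsets keep only eyes with the required acquisitions", {
  full <- paired_cohort(20, seed = 8)
  expect_length(build_task_subsets(full, "paired"), length(full))
  mixed <- paired_cohort(40, seed = 9, p_eye = 0.8, p_acq = 0.6)
  hr <- build_task_subsets(mixed, "hr6")
  uw <- build_task_subsets(mixed, "uwf15")
  pr <- build_task_subsets(mixed, "paired")
  expect_true(all(vapply(hr, function(r) "hr6" %in% names(r$volumes), logical(1))))
  expect_true(all(vapply(pr, function(r)
    setequal(names(r$volumes), c("hr6", "uwf15")), logical(1))))
  # paired subsets are never larger than single-acquisition subsets
  expect_gte(length(hr), length(pr))
  expect_gte(length(uw), length(pr))
  expect_equal(length(hr) + length(uw), length(mixed) + length(pr))
})

test_that("augmentation toggles compose to the identity", {
  a <- tiny_volume(c(8, 6, 8, 2), seed = 10)
  expect_identical(augment_patch(a, c(1, 1), 0, 0), a)
  set.seed(1)
  expect_identical(augment_patch(a, gamma_range = c(1, 1), noise_sd = 0,
                                 flip_prob = 0), a)
  flip1 <- a[rev(seq_len(dim(a)[1])), , , , drop = FALSE]
  expect_identical(flip1[rev(seq_len(dim(a)[1])), , , , drop = FALSE], a)
  # gamma and noise act as configured
  set.seed(2)
  g <- augment_patch(a, gamma_range = c(2, 2), noise_sd = 0, flip_prob = 0)
  expect_equal(g, a^2, tolerance = 1e-12)
  expect_true(all(augment_patch(a, c(0.7, 1.5), 0.02, 0.5) >= 0))
})

test_that("training follows the exponential learning-rate schedule", {
  toy <- generate_toy_cohort(4, scale = 0.05, seed = 11)
  toy <- preprocess_cohort(toy, use_truth = TRUE)
  m <- build_input_fusion(fusion_spec("input",
        backbone_spec("resnet50_3d", in_channels = 2, width_mult = 0.25)), seed = 12)
  fit <- train_model(m, toy, train_config(epochs = 3, seed = 13), acquisition = "hr6")
  expect_equal(fit$history$lr, 1e-4 * 0.99^(0:2))
  expect_equal(fit$history$epoch, 1:3)
  expect_true(all(is.finite(fit$history$loss)))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("training is reproducible under fixed seeds", {
  toy <- preprocess_cohort(generate_toy_cohort(4, scale = 0.05, seed = 14),
                           use_truth = TRUE)
  run <- function() {
    m <- build_input_fusion(fusion_spec("input",
          backbone_spec("resnet50_3d", in_channels = 2, width_mult = 0.25)),
          seed = 15)
    train_model(m, toy, train_config(epochs = 2, seed = 16),
                acquisition = "hr6")$history$loss
  }
  expect_identical(run(), run())
})

test_that("non-finite losses abort with a diagnostic", {
  toy <- preprocess_cohort(generate_toy_cohort(2, scale = 0.05, seed = 17),
                           use_truth = TRUE)
  m <- build_input_fusion(fusion_spec("input",
        backbone_spec("resnet50_3d", in_channels = 2, width_mult = 0.25)), seed = 18)
  p1 <- octafusion:::nn_params(m)[[1]]
  p1$value[1] <- NaN
  expect_error(train_model(m, toy, train_config(epochs = 1, seed = 19),
                           acquisition = "hr6"), "diverged")
})

test_that("validation-based checkpoint selection restores the best epoch", {
  toy <- preprocess_cohort(generate_toy_cohort(6, scale = 0.05, seed = 20),
                           use_truth = TRUE)
  m <- build_input_fusion(fusion_spec("input",
        backbone_spec("resnet50_3d", in_channels = 2, width_mult = 0.25)), seed = 21)
  fit <- train_model(m, toy[1:4], train_config(epochs = 2, seed = 22),
                     acquisition = "hr6", val_records = toy[5:6])
  expect_false(is.na(fit$best_epoch))
  expect_true(all(!is.na(fit$history$val_metric)))
})
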
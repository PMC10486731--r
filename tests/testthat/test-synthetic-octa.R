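# Synthetic cohort generator: structure, determinism, grade sampling and the
# acquisition-complementarity of the lesion model.

test_that("forced probabilities give every eye both acquisitions", {
  spec <- cohort_spec(4, p_both_eyes = 1, p_both_acquisitions = 1,
                      volume_scale = 0.05, seed = 7)
  cohort <- generate_cohort(spec)
  expect_length(cohort, 8)
  expect_true(all(vapply(cohort, function(r)
    setequal(names(r$volumes), c("hr6", "uwf15")), logical(1))))
  man <- cohort_manifest(cohort)
  expect_equal(nrow(man), 16)
  expect_equal(length(unique(man$patient_id)), 4)
})

test_that("cohorts are byte-identical under a fixed spec", {
  spec <- cohort_spec(2, volume_scale = 0.05, seed = 7)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
})

test_that("grade frequencies follow the severity distribution", {
  p <- c(127, 68, 321, 97, 20, 43) / 676
  spec <- cohort_spec(500, severity_distribution = p, seed = 11)
  cohort <- generate_cohort(spec, render = FALSE)
  grades <- vapply(cohort, `[[`, integer(1), "grade")
  n <- length(grades)
  freq <- tabulate(grades + 1L, 6) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) <= 3 * se))
})

test_that("non-simplex severity distribution is rejected", {
  expect_error(cohort_spec(5, severity_distribution = rep(0.2, 6)), "simplex")
  expect_error(cohort_spec(5, severity_distribution = c(2, -1, 0, 0, 0, 0)),
               "simplex")
})

test_that("volume geometry follows the acquisition conventions", {
  set.seed(3)
  latent <- octafusion:::eye_latent(2L)
  v_hr <- generate_raw_volume("hr6", 2, scale = 0.1, latent = latent)
  v_uw <- generate_raw_volume("uwf15", 2, scale = 0.1, latent = latent)
  expect_equal(dim(v_hr$data), c(50, 154, 50, 2))
  expect_equal(dim(v_uw$data), c(83, 307, 83, 2))
  # widefield lateral extent = 834/500 of the high-resolution extent
  expect_equal(dim(v_uw$data)[1] / dim(v_hr$data)[1], 834 / 500,
               tolerance = 0.02)
  expect_true(all(is.finite(v_hr$data)), all(v_hr$data >= 0))
  expect_true(all(v_hr$ilm < v_hr$rpe))
  expect_true(all(v_uw$ilm < v_uw$rpe))
})

test_that("grade 0 has empty lesion masks in both acquisitions", {
  set.seed(4)
  latent <- octafusion:::eye_latent(0L)
  for (acq in c("hr6", "uwf15")) {
    v <- generate_raw_volume(acq, 0, scale = 0.06, latent = latent)
    expect_false(any(v$lesions$central))
    expect_false(any(v$lesions$peripheral))
  }
})

test_that("central lesion contrast is stronger in the high-resolution field", {
  set.seed(5)
  contrasts <- replicate(6, {
    latent <- octafusion:::eye_latent(2L)
    sapply(c("hr6", "uwf15"), function(acq) {
      v <- generate_raw_volume(acq, 2, scale = 0.08, latent = latent)
      d2 <- dim(v$data)[2]
      band <- seq(max(1, round(0.08 * d2)), round(0.5 * d2))
      mask <- v$lesions$central
      stopifnot(sum(mask) >= 4)  # lesion footprint present at this scale
      flow <- apply(v$data[, band, , 2], c(1, 3), mean)
      mean(flow[!mask]) - mean(flow[mask])
    })
  })
  expect_true(all(contrasts["hr6", ] > contrasts["uwf15", ]))
})

test_that("a fixed linear probe reproduces the acquisition complementarity", {
  # mean flow thresholding separates {0} vs {1,2} better on hr6 and
  # {0-2} vs {3-5} better on uwf15
  set.seed(6)
  grades <- rep(0:5, length.out = 102)
  feat <- function(vol) {
    a <- vol$data
    d2 <- dim(a)[2]
    band <- seq(max(1, round(0.1 * d2)), max(2, round(0.45 * d2)))
    mean(a[, band, , 2])
  }
  m <- t(vapply(grades, function(g) {
    latent <- octafusion:::eye_latent(g)
    c(hr = feat(preprocess_volume(generate_raw_volume("hr6", g, 0.05, latent),
                                  use_truth = TRUE)),
      uw = feat(preprocess_volume(generate_raw_volume("uwf15", g, 0.05, latent),
                                  use_truth = TRUE)))
  }, c(hr = 0, uw = 0)))
  early <- grades <= 2
  auc_early_hr <- roc_auc(-m[early, "hr"], grades[early] >= 1)
  auc_early_uw <- roc_auc(-m[early, "uw"], grades[early] >= 1)
  auc_late_hr <- roc_auc(-m[, "hr"], grades >= 3)
  auc_late_uw <- roc_auc(-m[, "uw"], grades >= 3)
  expect_gt(auc_early_hr, auc_early_uw)
  expect_gt(auc_late_uw, auc_late_hr)
  expect_gt(auc_early_hr, 0.9)   # early disease is a high-resolution signal
  expect_gt(auc_late_uw, 0.9)    # late disease is a widefield signal
})

test_that("toy cohort is strongly separable by mean flow", {
  toy <- generate_toy_cohort(12, seed = 2)
  grades <- vapply(toy, `[[`, integer(1), "grade")
  expect_setequal(unique(grades), c(0L, 2L))
  mf <- vapply(toy, function(r) mean(r$volumes$hr6$data[, , , 2]), numeric(1))
  expect_equal(roc_auc(-mf, grades > 0), 1)
})
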
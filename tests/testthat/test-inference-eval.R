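# Task scores, severest aggregation, N-crop prediction, AUC and kappa.

test_that("task scores are cumulative tail probabilities", {
  expect_equal(task_score(c(1, 0, 0, 0, 0, 0)), rep(0, 4))
  expect_equal(task_score(rep(1 / 6, 6)), c(5, 4, 3, 2) / 6)
  expect_equal(task_score(c(0, 0, 0, 0, 0, 1), 3), 1)  # PRP is task-3 positive
  expect_equal(task_score(c(0, 0, 0, 0, 1, 0), 3), 1)  # PDR too
  expect_error(task_score(rep(1 / 6, 6), 4), "0..3")
  expect_error(task_score(c(0.5, 0.2, 0, 0, 0, 0)), "sum to 1")
})

test_that("task scores are non-increasing across tasks", {
  set.seed(14)
  for (i in 1:200) {
    s <- task_score(random_prob())
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("severest aggregation is monotone and permutation-invariant", {
  set.seed(15)
  one <- random_prob()
  agg1 <- aggregate_severest(list(one))
  expect_equal(agg1$prob, one)
  expect_equal(agg1$task_scores, task_score(one))
  expect_equal(agg1$grade, which.max(one) - 1L)
  for (i in 1:40) {
    ps <- replicate(sample(2:6, 1), random_prob(), simplify = FALSE)
    agg <- aggregate_severest(ps)
    extra <- random_prob()
    agg_more <- aggregate_severest(c(ps, list(extra)))
    expect_true(all(agg_more$task_scores >= agg$task_scores - 1e-12))
    expect_gte(agg_more$grade, agg$grade)
    perm <- aggregate_severest(sample(ps))
    expect_equal(perm$task_scores, agg$task_scores, tolerance = 1e-12)
    expect_equal(perm$grade, agg$grade)
    expect_equal(perm$prob, agg$prob, tolerance = 1e-12)
  }
  expect_error(aggregate_severest(list()), "non-empty")
})

test_that("the aggregated grade is the severest argmax across crops", {
  p2 <- c(0.1, 0.1, 0.6, 0.2, 0, 0)   # argmax grade 2
  p3 <- c(0.1, 0.1, 0.2, 0.6, 0, 0)   # argmax grade 3
  agg <- aggregate_severest(list(p2, p3))
  expect_equal(agg$grade, 3L)
  expect_equal(agg$prob, p3)
  # tie on the severest grade: the crop more confident in it is reported
  p3b <- c(0.1, 0.1, 0.1, 0.7, 0, 0)
  expect_equal(aggregate_severest(list(p3, p3b))$prob, p3b)
})

test_that("predict_eye aggregates N random crops with the severest rule", {
  m <- tiny_backbone(seed = 30)
  v <- tiny_volume(c(16, 12, 16, 2), seed = 31)
  set.seed(1)
  p1 <- predict_eye(m, v, n = 1)
  expect_equal(dim(p1$crop_probs), c(1, 6))
  expect_equal(p1$task_scores, task_score(p1$prob))
  set.seed(2)
  pa <- predict_eye(m, v, n = 3)
  set.seed(2)
  pb <- predict_eye(m, v, n = 6)   # same seed prefix: first 3 crops shared
  expect_true(all(pb$task_scores >= pa$task_scores - 1e-12))
  expect_error(predict_eye(m, v, n = 0), ">= 1")
  # constant-output stub: zero head weights give a uniform probability
  stub <- tiny_backbone(seed = 32)
  stub$head$w$value[] <- 0
  stub$head$b$value[] <- 0
  set.seed(3)
  ps <- predict_eye(stub, v, n = 5)
  expect_equal(ps$prob, rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(unique(as.vector(ps$crop_probs)), 1 / 6, tolerance = 1e-12)
})

test_that("roc_auc matches exhaustive pair counting with ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(16)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  for (n in 2:8) {
    for (rep in 1:40) {
      s <- sample(grid, n, replace = TRUE)
      l <- integer(n)
      l[sample(n, sample(n - 1, 1))] <- 1L
      expect_equal(roc_auc(s, l), auc_oracle(s, l), tolerance = 1e-12)
    }
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("cohens_kappa follows the chance-corrected agreement formula", {
  expect_equal(cohens_kappa(diag(c(5, 3, 2, 7, 1, 4))), 1)
  marg <- c(10, 20, 5, 15, 3, 7)
  indep <- outer(marg, marg) / sum(marg)
  expect_equal(cohens_kappa(indep), 0, tolerance = 1e-12)
  expect_equal(cohens_kappa(matrix(c(40, 20, 10, 30), 2)), 0.4)
  expect_error(cohens_kappa(matrix(c(0, 0, 0, 9), 2)), "undefined")
  expect_error(cohens_kappa(matrix(0, 3, 3)), "empty")
})

test_that("evaluate_model scores an oracle at 1 and a shuffler at chance", {
  set.seed(17)
  labels <- sample(0:5, 240, replace = TRUE,
                   prob = c(127, 68, 321, 97, 20, 43) / 676)
  onehot <- function(g) { p <- rep(0, 6); p[g + 1] <- 1; p }
  oracle <- lapply(labels, function(g) fake_prediction(onehot(g)))
  ev <- evaluate_model(oracle, labels)
  expect_equal(ev$kappa, 1)
  expect_equal(unname(ev$auc), rep(1, 4))
  expect_equal(unname(rowSums(ev$confusion)), tabulate(labels + 1L, 6))
  expect_equal(ev$n_eyes, 240)

  shuffled <- lapply(sample(labels), function(g) fake_prediction(onehot(g)))
  ev0 <- evaluate_model(shuffled, labels)
  for (k in 0:3) {
    n_pos <- sum(labels >= k + 1)
    se <- sqrt(1 / 12 * (1 / n_pos + 1 / (240 - n_pos)))  # null AUC variance
    expect_lt(abs(ev0$auc[[k + 1]] - 0.5), 4 * se)
  }
  expect_lt(abs(ev0$kappa), 0.15)
  expect_error(evaluate_model(oracle[1:3], labels), "same length")
})

test_that("tidiers expose the evaluation as tibbles", {
  labels <- rep(0:5, each = 4)
  onehot <- function(g) { p <- rep(0, 6); p[g + 1] <- 1; p }
  ev <- evaluate_model(lapply(labels, function(g) fake_prediction(onehot(g))),
                       labels)
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$metric, c("kappa", paste0("auc", 0:3)))
  gl <- glance(ev)
  expect_equal(gl$mean_auc, 1)
  expect_equal(gl$n_eyes, 24)
  expect_s3_class(autoplot(ev), "ggplot")
})
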
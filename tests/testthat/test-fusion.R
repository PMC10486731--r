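# Fusion topologies: input/feature/decision/hierarchical and the
# cross-acquisition assembly.

bs1 <- function(seed_ignored = NULL) backbone_spec("resnet50_3d", in_channels = 1,
                                                   width_mult = 0.25)

test_that("input fusion concatenates modality channels", {
  m <- build_input_fusion(fusion_spec("input",
        backbone_spec("resnet50_3d", in_channels = 2, width_mult = 0.25)), seed = 1)
  st <- tiny_volume(c(12, 12, 12, 1), seed = 1)
  fl <- tiny_volume(c(12, 12, 12, 1), seed = 2)
  both <- array(c(st, fl), c(12, 12, 12, 2))
  expect_equal(model_logits(m, list(st, fl)), model_logits(m, both),
               tolerance = 1e-12)
  # duplicated modality is accepted and finite
  expect_true(all(is.finite(model_logits(m, list(fl, fl)))))
  # channel order matters in general
  swapped <- array(c(fl, st), c(12, 12, 12, 2))
  expect_false(isTRUE(all.equal(model_logits(m, both), model_logits(m, swapped))))
  expect_error(model_logits(m, tiny_volume(c(12, 12, 12, 3))), "channels")
})

test_that("feature fusion concatenates pooled features under one head", {
  fs <- fusion_spec("feature", list(bs1(), bs1()))
  m <- build_feature_fusion(fs, seed = 2)
  d <- vapply(m$branches, function(b) b$feat_dim, integer(1))
  expect_equal(m$head$din, sum(d))
  x <- tiny_volume(c(12, 12, 12, 2), seed = 3)
  expect_length(model_logits(m, x), 6)
  # unregistered branches: different grids are accepted
  l <- model_logits(m, list(tiny_volume(c(10, 12, 14, 1)),
                            tiny_volume(c(16, 12, 16, 1))))
  expect_true(all(is.finite(l)))
  # the head is linear in each branch slice: zeroing the branch-2 head
  # columns makes logits independent of the branch-2 input
  m$head$w$value[, (d[1] + 1):(d[1] + d[2])] <- 0
  l1 <- model_logits(m, list(tiny_volume(c(12, 12, 12, 1), seed = 4),
                             tiny_volume(c(12, 12, 12, 1), seed = 5)))
  l2 <- model_logits(m, list(tiny_volume(c(12, 12, 12, 1), seed = 4),
                             tiny_volume(c(12, 12, 12, 1), seed = 6)))
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("decision fusion rules obey their algebra", {
  p1 <- c(0.2, 0.8, 0, 0, 0, 0)
  p2 <- c(0.6, 0.4, 0, 0, 0, 0)
  expect_equal(fuse_decisions(list(p1, p2), "avg"), c(0.4, 0.6, 0, 0, 0, 0))
  expect_equal(fuse_decisions(list(p1, p1), "avg"), p1)
  expect_equal(fuse_decisions(list(p2, p1), "max"),
               c(0.6, 0.8, 0, 0, 0, 0) / 1.4)
  # symmetry and simplex closure on random inputs
  set.seed(1)
  for (i in 1:25) {
    ps <- replicate(3, random_prob(), simplify = FALSE)
    for (rule in c("avg", "max")) {
      f <- fuse_decisions(ps, rule)
      expect_equal(sum(f), 1, tolerance = 1e-9)
      expect_true(all(f >= 0))
      expect_equal(f, fuse_decisions(rev(ps), rule), tolerance = 1e-12)
    }
    k <- sample(2:5, 1)
    p <- random_prob()
    expect_equal(fuse_decisions(rep(list(p), k), "avg"), p, tolerance = 1e-12)
  }
  expect_error(fuse_decisions(list(), "avg"), "non-empty")
  expect_error(fuse_decisions(list(c(0.5, 0.6)), "avg"), "sum to 1")
})

test_that("hierarchical fusion has four merge points and a 3-slice head", {
  fs <- fusion_spec("hierarchical", list(bs1(), bs1()))
  m <- build_hierarchical_fusion(fs, seed = 3)
  expect_length(m$proj, 4)
  expect_equal(m$head$din, sum(m$feat_dims))
  expect_length(m$feat_dims, 3)
  x <- tiny_volume(c(13, 13, 13, 2), seed = 6)
  l <- model_logits(m, x)
  expect_length(l, 6)
  expect_true(all(is.finite(l)))
  ff <- build_feature_fusion(fusion_spec("feature", list(bs1(), bs1())), seed = 3)
  expect_gt(n_parameters(m), n_parameters(ff))
})

test_that("hierarchical fusion subsumes feature fusion at the head", {
  fs <- fusion_spec("hierarchical", list(bs1(), bs1()))
  hm <- build_hierarchical_fusion(fs, seed = 7)
  ff <- build_feature_fusion(fusion_spec("feature", list(bs1(), bs1())), seed = 7)
  # identical branch weights by construction (same seeds); restrict the
  # hierarchical head to the two branch slices
  d12 <- sum(hm$feat_dims[1:2])
  hm$head$w$value[, (d12 + 1):hm$head$din] <- 0
  ff$head$w$value <- hm$head$w$value[, 1:d12, drop = FALSE]
  ff$head$b$value <- hm$head$b$value
  x <- tiny_volume(c(13, 13, 13, 2), seed = 8)
  expect_equal(model_logits(hm, x), model_logits(ff, x), tolerance = 1e-10)
})

test_that("mixed-architecture branches are aligned via the pyramid", {
  fs <- fusion_spec("hierarchical", list(
    backbone_spec("resnet50_3d", in_channels = 1, width_mult = 0.25),
    backbone_spec("efficientnetb0_3d", in_channels = 1, width_mult = 0.25)))
  m <- build_hierarchical_fusion(fs, seed = 4)
  l <- model_logits(m, tiny_volume(c(16, 16, 16, 2), seed = 10))
  expect_true(all(is.finite(l)))
})

test_that("hybrid decision fusion averages acquisition-level predictions", {
  m1 <- tiny_backbone(seed = 11)
  m2 <- tiny_backbone(seed = 12)
  hy <- build_hybrid_model(list(hr6 = m1, uwf15 = m2), "avg")
  vols <- list(hr6 = tiny_volume(c(14, 12, 14, 2), seed = 13),
               uwf15 = tiny_volume(c(20, 12, 20, 2), seed = 14))
  set.seed(20)
  pr <- predict_eye(hy, vols, n = c(hr6 = 3, uwf15 = 4))
  subs <- pr$per_acquisition
  expect_equal(pr$prob,
               fuse_decisions(list(subs$hr6$prob, subs$uwf15$prob), "avg"),
               tolerance = 1e-12)
  expect_equal(pr$task_scores,
               (subs$hr6$task_scores + subs$uwf15$task_scores) / 2,
               tolerance = 1e-12)
  # identical branch outputs pass through the average unchanged
  hy_same <- build_hybrid_model(list(hr6 = m1, uwf15 = m1), "avg")
  vols_same <- list(hr6 = vols$hr6, uwf15 = vols$hr6)
  pr_same <- predict_eye(hy_same, vols_same, n = c(hr6 = 1, uwf15 = 1),
                         patch = dim(vols$hr6))
  expect_equal(pr_same$prob, predict_probs(m1, vols$hr6), tolerance = 1e-12)
  # swapping acquisitions leaves the average unchanged (deterministic
  # full-volume "crops" so the comparison is free of RNG ordering)
  vols_eq <- list(hr6 = vols$hr6, uwf15 = tiny_volume(c(14, 12, 14, 2), seed = 23))
  a <- predict_eye(hy, vols_eq, n = 1, patch = dim(vols_eq$hr6))
  b <- predict_eye(build_hybrid_model(list(uwf15 = m2, hr6 = m1), "avg"),
                   vols_eq, n = 1, patch = dim(vols_eq$hr6))
  expect_equal(a$prob, b$prob, tolerance = 1e-12)
  expect_equal(a$task_scores, b$task_scores, tolerance = 1e-12)
  # missing acquisition falls back with a warning
  expect_warning(pm <- predict_eye(hy, vols["hr6"], n = 2), "missing")
  expect_s3_class(pm, "octa_eye_prediction")
})

test_that("cross-acquisition feature fusion trains end to end", {
  set.seed(40)
  recs <- lapply(1:4, function(i) {
    r <- generate_eye_record(sample(0:5, 1), c("hr6", "uwf15"), scale = 0.05,
                             patient_id = sprintf("P%02d", i))
    r$volumes <- lapply(r$volumes, preprocess_volume, use_truth = TRUE)
    r
  })
  bspec <- backbone_spec("resnet50_3d", in_channels = 1, width_mult = 0.25)
  hm <- function(s) build_hierarchical_fusion(
    fusion_spec("hierarchical", list(bspec, bspec)), seed = s)
  joint <- cross_feature_finetune(
    build_cross_feature(list(hr6 = hm(41), uwf15 = hm(42)), seed = 43),
    "head_only")
  fit <- train_model(joint, recs, train_config(epochs = 1, seed = 44))
  expect_true(is.finite(fit$history$loss))
  set.seed(45)
  pr <- predict_eye(joint, recs[[1]]$volumes, n = 2)
  expect_equal(sum(pr$prob), 1, tolerance = 1e-9)
  expect_true(pr$grade %in% 0:5)
})

test_that("cross-acquisition fine-tuning freezes what it should", {
  fs <- fusion_spec("hierarchical", list(bs1(), bs1()))
  hm1 <- build_hierarchical_fusion(fs, seed = 15)
  hm2 <- build_hierarchical_fusion(fs, seed = 16)
  joint <- build_cross_feature(list(hr6 = hm1, uwf15 = hm2), seed = 17)
  joint <- cross_feature_finetune(joint, "head_only")
  n_train <- n_parameters(joint, trainable_only = TRUE)
  n_head <- length(joint$head$w$value) + length(joint$head$b$value)
  expect_equal(n_train, n_head)

  xs <- list(hr6 = tiny_volume(c(13, 13, 13, 2), seed = 18),
             uwf15 = tiny_volume(c(16, 13, 16, 2), seed = 19))
  feats_before <- octafusion:::ag_no_grad(lapply(joint$branches, function(b)
    octafusion:::model_features_node(b, xs[[1]])$value))
  # one head-only training step cannot change branch features
  params <- octafusion:::nn_params(joint)
  opt <- octafusion:::adam_init(params)
  loss <- octafusion:::model_loss_node(joint, xs, 2L)
  octafusion:::ag_backward(loss)
  octafusion:::adam_step(opt, params, 1e-2)
  feats_after <- octafusion:::ag_no_grad(lapply(joint$branches, function(b)
    octafusion:::model_features_node(b, xs[[1]])$value))
  expect_identical(feats_before, feats_after)

  joint_full <- cross_feature_finetune(joint, "full")
  expect_equal(n_parameters(joint_full, trainable_only = TRUE),
               n_parameters(joint_full))
  octafusion:::ag_zero_grad(params)
  loss <- octafusion:::model_loss_node(joint_full, xs, 2L)
  octafusion:::ag_backward(loss)
  grads <- vapply(octafusion:::nn_params(joint_full),
                  function(p) !is.null(p$grad), logical(1))
  expect_true(all(grads))
})
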
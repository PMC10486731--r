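# Dataset splitting, augmentation and the training loop.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 1e-4, exponential decay with gamma 0.99 per epoch, batch size 2, one
#' random crop per example per epoch, and mild augmentation (random gamma,
#' Gaussian noise, lateral flips). The nominal protocol trains for 500
#' epochs; the desk-scale default is far lower.
#'
#' @param lr Initial learning rate.
#' @param lr_decay_gamma Per-epoch exponential decay factor in (0, 1].
#' @param epochs Number of epochs.
#' @param batch_size Examples per optimizer step.
#' @param augment Enable augmentation.
#' @param gamma_range Range of the random gamma exponent.
#' @param noise_sd Gaussian noise standard deviation (intensities are in
#'   `[0, 1]`).
#' @param flip_prob Per-lateral-axis flip probability (depth is never
#'   flipped: the retina is oriented).
#' @param patch Crop shape; `NULL` for the depth-cube default.
#' @param seed Seed for shuffling, cropping and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, lr_decay_gamma = 0.99, epochs = 50L,
                         batch_size = 2L, augment = TRUE,
                         gamma_range = c(0.7, 1.5), noise_sd = 0.02,
                         flip_prob = 0.5, patch = NULL, seed = 1L) {
  stopifnot(lr > 0, lr_decay_gamma > 0, lr_decay_gamma <= 1, epochs >= 1,
            batch_size >= 1)
  structure(list(lr = lr, lr_decay_gamma = lr_decay_gamma,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 augment = augment, gamma_range = gamma_range,
                 noise_sd = noise_sd, flip_prob = flip_prob, patch = patch,
                 seed = as.integer(seed)),
            class = "train_config")
}

record_has <- function(r, acqs) all(acqs %in% names(r$volumes))

#' Patient-level train/test split with stratified cross-validation folds
#'
#' The test set is drawn only from patients contributing both eyes with both
#' acquisitions each (so one fixed test set serves every fusion task); the
#' remaining patients are dealt into `n_folds` cross-validation folds,
#' stratified by their worst-eye grade so each fold approximates the cohort's
#' severity distribution. The split is at patient level: no patient crosses
#' the test/fold boundary.
#'
#' @param cohort List of eye records.
#' @param seed Integer seed.
#' @param test_fraction Fraction of patients reserved for the test set
#'   (ignored when `n_test` is given).
#' @param n_test Number of test patients.
#' @param n_folds Number of cross-validation folds.
#' @return An `octa_split_plan`: `test_patient_ids`, `fold_assignments`
#'   (named integer vector, folds 1..n_folds) and `seed`.
#' @export
split_dataset <- function(cohort, seed = 1L, test_fraction = 0.1, n_test = NULL,
                          n_folds = 5L) {
  stopifnot(length(cohort) > 0)
  man <- cohort_manifest(cohort)
  pids <- unique(man$patient_id)
  n_test <- n_test %||% round(test_fraction * length(pids))
  eyes_per <- split(seq_along(cohort), vapply(cohort, `[[`, "", "patient_id"))
  fully_paired <- names(eyes_per)[vapply(eyes_per, function(ix) {
    length(ix) == 2 && all(vapply(cohort[ix], record_has, logical(1),
                                  acqs = c("hr6", "uwf15")))
  }, logical(1))]
  if (length(fully_paired) < n_test)
    stop("only ", length(fully_paired), " patients have both acquisitions in ",
         "both eyes; cannot form a test set of ", n_test, " patients")
  set.seed(seed)
  test_ids <- sort(sample(fully_paired, n_test))
  rest <- setdiff(pids, test_ids)
  worst <- vapply(eyes_per[rest], function(ix)
    max(vapply(cohort[ix], `[[`, integer(1), "grade")), integer(1))
  folds <- integer(0)
  fold_ids <- character(0)
  nxt <- 0L
  for (g in sort(unique(worst))) {      # deal each stratum round-robin
    ids <- sample(rest[worst == g])
    f <- (nxt + seq_along(ids) - 1L) %% n_folds + 1L
    nxt <- (nxt + length(ids)) %% n_folds
    folds <- c(folds, f)
    fold_ids <- c(fold_ids, ids)
  }
  structure(list(test_patient_ids = test_ids,
                 fold_assignments = stats::setNames(folds, fold_ids),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "octa_split_plan")
}

#' @export
print.octa_split_plan <- function(x, ...) {
  cat(sprintf("<octa_split_plan> %d test patients, %d patients in %d folds\n",
              length(x$test_patient_ids), length(x$fold_assignments), x$n_folds))
  invisible(x)
}

#' Select the eyes a fusion task can use
#'
#' Single-acquisition tasks keep every eye possessing that acquisition;
#' the paired task keeps only eyes with both. Paired subsets are therefore
#' never larger than single-acquisition subsets.
#'
#' @param cohort List of eye records.
#' @param task `"hr6"`, `"uwf15"` or `"paired"`.
#' @return Filtered list of eye records.
#' @export
build_task_subsets <- function(cohort, task = c("hr6", "uwf15", "paired")) {
  task <- match.arg(task)
  need <- if (task == "paired") c("hr6", "uwf15") else task
  Filter(function(r) record_has(r, need), cohort)
}

#' Augment one training patch
#'
#' Random gamma transformation (exponent drawn uniformly from
#' `gamma_range`), additive Gaussian noise, and independent flips of the two
#' lateral axes; the depth axis is never flipped because the retina is
#' oriented. Intensities are assumed in `[0, 1]` and are clamped after
#' noise. With `gamma_range = c(1, 1)`, `noise_sd = 0` and `flip_prob = 0`
#' the transform is the identity.
#'
#' @param patch Rank-4 array (or `octa_patch`).
#' @param gamma_range,noise_sd,flip_prob See [train_config()].
#' @return Rank-4 array.
#' @export
augment_patch <- function(patch, gamma_range = c(0.7, 1.5), noise_sd = 0.02,
                          flip_prob = 0.5) {
  a <- if (inherits(patch, "octa_patch")) patch$data else patch
  stopifnot(length(dim(a)) == 4)
  g <- runif(1, gamma_range[1], gamma_range[2])
  if (g != 1) a <- pmax(a, 0)^g
  if (noise_sd > 0) a <- clamp01(a + rnorm(length(a), sd = noise_sd))
  if (flip_prob > 0) {
    if (runif(1) < flip_prob) a <- a[rev(seq_len(dim(a)[1])), , , , drop = FALSE]
    if (runif(1) < flip_prob) a <- a[, , rev(seq_len(dim(a)[3])), , drop = FALSE]
  }
  a
}

# One (inputs, label) training example for a model: crops the record's
# volume(s) and splits/packs channels as the model expects.
draw_example <- function(model, record, acquisition, cfg, crop = c("random", "center")) {
  crop <- match.arg(crop)
  get_crop <- function(vol) {
    a <- vol_data(vol)
    patch <- cfg$patch %||% default_patch(a)
    p <- if (crop == "random") random_crop(a, patch) else center_crop(a, patch)
    if (crop == "random" && cfg$augment)
      augment_patch(p$data, cfg$gamma_range, cfg$noise_sd, cfg$flip_prob)
    else p$data
  }
  if (inherits(model, "octa_cross_feature")) {
    lapply(record$volumes[names(model$branches)], get_crop)
  } else {
    get_crop(record$volumes[[acquisition]])
  }
}

# Mean task AUC (checkpoint metric) with kappa as tie-breaker, both from
# deterministic center-crop predictions.
validation_metric <- function(model, records, acquisition, cfg) {
  preds <- lapply(records, function(r) {
    x <- draw_example(model, r, acquisition, cfg, crop = "center")
    p <- predict_probs(model, x)
    list(task_scores = task_score(p), grade = which.max(p) - 1L)
  })
  labels <- vapply(records, `[[`, integer(1), "grade")
  scores <- do.call(rbind, lapply(preds, `[[`, "task_scores"))
  aucs <- vapply(0:3, function(k) {
    bin <- as.integer(labels >= k + 1)
    if (length(unique(bin)) == 2) roc_auc(scores[, k + 1], bin) else NA_real_
  }, numeric(1))
  grades <- vapply(preds, `[[`, integer(1), "grade")
  cm <- matrix(0L, 6, 6)
  for (i in seq_along(labels))
    cm[labels[i] + 1L, grades[i] + 1L] <- cm[labels[i] + 1L, grades[i] + 1L] + 1L
  kap <- tryCatch(cohens_kappa(cm), error = function(e) NA_real_)
  list(auc = if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE),
       kappa = kap)
}

#' Train a model on preprocessed eye records
#'
#' One uniformly random (augmented) crop per example per epoch, unweighted
#' 6-class cross-entropy, Adam updates every `batch_size` examples, and an
#' exponentially decaying learning rate (`lr * gamma^(epoch - 1)`). When
#' validation records are supplied, the mean of the four task AUCs (computed
#' with a deterministic center crop) selects the best checkpoint, which is
#' restored into the model at the end. Decision-fusion models are trained by
#' training each modality branch independently.
#'
#' @param model An `octa_model` (trained in place; parameters are reference
#'   objects).
#' @param records List of eye records with preprocessed volumes (see
#'   [preprocess_cohort()]).
#' @param cfg A [train_config()].
#' @param acquisition Which acquisition of each record feeds the model
#'   (`NULL`: the record's only volume).
#' @param val_records Optional validation records for checkpoint selection.
#' @return An `octa_fit`: the trained `model`, a per-epoch `history` tibble
#'   (`epoch`, `lr`, `loss`, `val_metric`) and `best_epoch`.
#' @export
train_model <- function(model, records, cfg = train_config(),
                        acquisition = NULL, val_records = NULL) {
  stopifnot(length(records) > 0, inherits(cfg, "train_config"))
  if (is.null(acquisition) && !inherits(model, "octa_cross_feature")) {
    acqs <- unique(unlist(lapply(records, function(r) names(r$volumes))))
    if (length(acqs) != 1)
      stop("records carry several acquisitions (", paste(acqs, collapse = ", "),
           "); pass 'acquisition' explicitly")
    acquisition <- acqs
  }
  if (inherits(model, "octa_decision_fusion")) {
    hist <- vector("list", length(model$branches))
    for (i in seq_along(model$branches)) {
      sliced <- slice_records(records, acquisition, model$branch_channels, i)
      sliced_val <- if (!is.null(val_records))
        slice_records(val_records, acquisition, model$branch_channels, i)
      fit <- train_model(model$branches[[i]], sliced, cfg, acquisition,
                         sliced_val)
      hist[[i]] <- fit$history
    }
    return(structure(list(model = model, history = do.call(rbind, hist),
                          best_epoch = NA_integer_), class = "octa_fit"))
  }

  set.seed(cfg$seed)
  params <- nn_params(model)
  opt <- adam_init(params)
  labels <- vapply(records, `[[`, integer(1), "grade")
  history <- vector("list", cfg$epochs)
  best <- list(metric = -Inf, kappa = -Inf, state = NULL, epoch = NA_integer_)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr * cfg$lr_decay_gamma^(epoch - 1)
    ord <- sample(seq_along(records))
    losses <- numeric(0)
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
      ag_zero_grad(params)
      for (j in batch) {
        x <- draw_example(model, records[[j]], acquisition, cfg)
        loss <- model_loss_node(model, x, labels[j] + 1L)
        if (!is.finite(loss$value))
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (example ", j, "); lower the learning rate")
        losses <- c(losses, loss$value)
        ag_backward(loss)
      }
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / length(batch)
      opt <- adam_step(opt, params, lr)
      i <- i + cfg$batch_size
    }
    vm <- if (!is.null(val_records))
      validation_metric(model, val_records, acquisition, cfg)
    else list(auc = NA_real_, kappa = NA_real_)
    better <- !is.na(vm$auc) &&
      (vm$auc > best$metric + 1e-9 ||
         (vm$auc > best$metric - 1e-9 && !is.na(vm$kappa) &&
            vm$kappa > best$kappa))
    if (better) {
      best <- list(metric = vm$auc, kappa = vm$kappa %||% -Inf,
                   state = nn_state(model), epoch = epoch)
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                       loss = mean(losses), val_metric = vm$auc)
  }
  if (!is.null(best$state)) nn_load_state(model, best$state)
  structure(list(model = model, history = do.call(rbind, history),
                 best_epoch = best$epoch, val_metric = best$metric),
            class = "octa_fit")
}

# Restrict each record's volume to one modality channel (for decision-fusion
# branch training).
slice_records <- function(records, acquisition, branch_channels, branch) {
  off <- c(0, cumsum(branch_channels))[branch]
  idx <- off + seq_len(branch_channels[branch])
  lapply(records, function(r) {
    v <- r$volumes[[acquisition]]
    a <- vol_data(v)[, , , idx, drop = FALSE]
    if (inherits(v, "octa_volume")) {
      v$data <- a
      r$volumes[[acquisition]] <- v
    } else {
      r$volumes[[acquisition]] <- a
    }
    r
  })
}

#' @export
print.octa_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<octa_fit> %d epochs | final loss %.4f%s\n", max(h$epoch),
              h$loss[nrow(h)],
              if (!is.na(x$best_epoch)) sprintf(" | best epoch %d (val %.4f)",
                                                x$best_epoch, x$val_metric) else ""))
  invisible(x)
}
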
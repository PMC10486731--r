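# Staged pipeline: simulate -> preprocess -> train -> evaluate / predict /
# benchmark-crops, with YAML configuration, CSV/NIfTI artifacts and JSON
# metrics. Each stage writes a run log with the config hash and seed.

#' Default run configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Global seed.
#' @return Nested configuration list (amenable to YAML round trips).
#' @export
default_run_config <- function(out_dir = "octafusion_run", seed = 1L) {
  list(
    out_dir = out_dir, seed = as.integer(seed),
    simulate = list(n_patients = 12L, volume_scale = 0.08,
                    p_both_eyes = 0.9, p_both_acquisitions = 0.9),
    preprocess = list(d_target = NULL),
    train = list(level = "hierarchical", arch = "resnet50_3d",
                 width_mult = 0.25, epochs = 3L, n_test = 2L,
                 acquisitions = c("hr6", "uwf15")),
    evaluate = list(n_crops = list(hr6 = 4L, uwf15 = 6L), rule = "avg")
  )
}

#' Read a YAML run configuration
#'
#' Missing fields are filled from [default_run_config()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_cfg(default_run_config(), cfg)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

write_run_log <- function(config, stage, out_dir) {
  log <- list(stage = stage, seed = config$seed, config_hash = config_hash(config),
              config = config)
  jsonlite::write_json(log, file.path(out_dir, paste0("run_log_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing artifact '", path, "': run the '", produced_by,
         "' stage first", call. = FALSE)
  path
}

# ---- model serialization ------------------------------------------------

model_blueprint <- function(model) {
  if (inherits(model, "octa_hybrid")) {
    return(list(kind = "hybrid", rule = model$rule,
                branches = lapply(model$acquisition_models, model_blueprint)))
  }
  if (inherits(model, "octa_cross_feature")) {
    return(list(kind = "cross_feature", mode = model$finetune_mode %||% "full",
                branches = lapply(model$branches, model_blueprint)))
  }
  if (inherits(model, "octa_backbone")) {
    return(list(kind = "backbone", spec = model$spec, level = model$level))
  }
  list(kind = model$type, spec = model$spec)
}

rebuild_model <- function(bp) {
  switch(bp$kind,
    hybrid = build_hybrid_model(lapply(bp$branches, rebuild_model), bp$rule),
    cross_feature = cross_feature_finetune(
      build_cross_feature(lapply(bp$branches, rebuild_model)), bp$mode),
    backbone = {
      m <- build_backbone(bp$spec)
      m$level <- bp$level
      m
    },
    feature_fusion = build_feature_fusion(bp$spec),
    hierarchical_fusion = build_hierarchical_fusion(bp$spec),
    decision_fusion = build_decision_fusion(bp$spec),
    stop("cannot rebuild model of kind ", bp$kind)
  )
}

#' Save / load a model
#'
#' Models are stored as a rebuildable blueprint plus the flat parameter
#' state, so files stay portable across sessions.
#'
#' @param model An `octa_model`.
#' @param path `.rds` path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  states <- if (inherits(model, "octa_hybrid"))
    lapply(model$acquisition_models, nn_state) else nn_state(model)
  saveRDS(list(blueprint = model_blueprint(model), state = states), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- rebuild_model(obj$blueprint)
  if (inherits(model, "octa_hybrid")) {
    for (nm in names(model$acquisition_models))
      nn_load_state(model$acquisition_models[[nm]], obj$state[[nm]])
  } else {
    nn_load_state(model, obj$state)
  }
  model
}

# ---- stages -------------------------------------------------------------

records_from_manifest <- function(man, grade_col = "grade") {
  key <- paste(man$patient_id, man$eye)
  lapply(split(seq_len(nrow(man)), key), function(ix) {
    vols <- lapply(ix, function(i)
      read_volume_nifti(man$path[i], acquisition = man$acquisition[i]))
    names(vols) <- man$acquisition[ix]
    structure(list(patient_id = man$patient_id[ix[1]], laterality = man$eye[ix[1]],
                   grade = as.integer(man[[grade_col]][ix[1]]), volumes = vols),
              class = "octa_eye_record")
  })
}

stage_simulate <- function(config, out_dir) {
  sc <- config$simulate
  spec <- cohort_spec(sc$n_patients, p_both_eyes = sc$p_both_eyes,
                      p_both_acquisitions = sc$p_both_acquisitions,
                      volume_scale = sc$volume_scale, seed = config$seed)
  vdir <- file.path(out_dir, "volumes")
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  rows <- list()
  for (r in cohort) {
    for (acq in names(r$volumes)) {
      path <- file.path(vdir, sprintf("%s_%s_%s.nii.gz", r$patient_id,
                                      r$laterality, acq))
      write_volume_nifti(r$volumes[[acq]], path)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = r$patient_id, eye = r$laterality, acquisition = acq,
        grade = r$grade, scale = spec$volume_scale, path = path)
    }
  }
  write_manifest(do.call(rbind, rows), file.path(out_dir, "manifest.csv"))
  invisible(cohort)
}

stage_preprocess <- function(config, out_dir) {
  man <- read_manifest(require_artifact(file.path(out_dir, "manifest.csv"),
                                        "simulate"))
  d_target <- config$preprocess$d_target %||%
    max(8L, as.integer(round(NOMINAL_DEPTH_TARGET * man$scale[1])))
  pdir <- file.path(out_dir, "preprocessed")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  man$prep_path <- NA_character_
  for (i in seq_len(nrow(man))) {
    raw <- structure(list(data = read_volume_nifti(man$path[i]),
                          acquisition = man$acquisition[i], grade = man$grade[i],
                          scale = man$scale[i]),
                     class = "octa_raw_volume")
    surf <- segment_surfaces(raw)
    v <- flatten_and_crop(raw, surf$ilm, surf$rpe, d_target)
    p <- file.path(pdir, basename(man$path[i]))
    write_volume_nifti(v, p)
    man$prep_path[i] <- p
  }
  man$d_target <- d_target
  write_manifest(man, file.path(out_dir, "manifest_preprocessed.csv"))
  invisible(man)
}

build_level_model <- function(tc, acquisition, seed) {
  bs <- function(ch) backbone_spec(tc$arch, in_channels = ch,
                                   width_mult = tc$width_mult)
  switch(tc$level,
    input = build_input_fusion(fusion_spec("input", bs(2L)), seed),
    feature = build_feature_fusion(fusion_spec("feature", list(bs(1L), bs(1L))), seed),
    decision = build_decision_fusion(fusion_spec("decision", list(bs(1L), bs(1L))), seed),
    hierarchical = build_hierarchical_fusion(
      fusion_spec("hierarchical", list(bs(1L), bs(1L))), seed),
    stop("unknown fusion level: ", tc$level))
}

prep_records <- function(out_dir) {
  man <- read_manifest(require_artifact(
    file.path(out_dir, "manifest_preprocessed.csv"), "preprocess"))
  man$path <- man$prep_path
  records_from_manifest(man)
}

stage_train <- function(config, out_dir) {
  tc <- config$train
  records <- prep_records(out_dir)
  plan <- split_dataset(records, seed = config$seed, n_test = tc$n_test)
  saveRDS(plan, file.path(out_dir, "split_plan.rds"))
  in_fold1 <- names(plan$fold_assignments)[plan$fold_assignments == 1L]
  train_ids <- setdiff(names(plan$fold_assignments), in_fold1)
  pick <- function(ids) Filter(function(r) r$patient_id %in% ids, records)
  hist <- list()
  for (acq in tc$acquisitions) {
    model <- build_level_model(tc, acq, seed = config$seed)
    sub <- build_task_subsets(pick(train_ids), acq)
    val <- build_task_subsets(pick(in_fold1), acq)
    fit <- train_model(model, sub,
                       train_config(epochs = tc$epochs, seed = config$seed),
                       acquisition = acq,
                       val_records = if (length(val) > 1) val)
    save_model(fit$model, file.path(out_dir, paste0("model_", acq, ".rds")))
    h <- fit$history
    h$acquisition <- acq
    hist[[acq]] <- h
  }
  write_manifest(do.call(rbind, hist), file.path(out_dir, "history.csv"))
  invisible(hist)
}

load_trained <- function(config, out_dir) {
  models <- lapply(config$train$acquisitions, function(acq)
    load_model(require_artifact(file.path(out_dir, paste0("model_", acq, ".rds")),
                                "train")))
  names(models) <- config$train$acquisitions
  models
}

test_records <- function(out_dir) {
  plan <- readRDS(require_artifact(file.path(out_dir, "split_plan.rds"), "train"))
  records <- prep_records(out_dir)
  Filter(function(r) r$patient_id %in% plan$test_patient_ids, records)
}

eval_to_metrics <- function(ev) {
  c(list(kappa = ev$kappa), as.list(ev$auc), list(n_eyes = ev$n_eyes))
}

stage_evaluate <- function(config, out_dir) {
  models <- load_trained(config, out_dir)
  test <- build_task_subsets(test_records(out_dir), "paired")
  if (length(test) == 0) stop("no fully paired test eyes to evaluate")
  ncr <- config$evaluate$n_crops
  labels <- vapply(test, `[[`, integer(1), "grade")
  set.seed(config$seed)
  metrics <- list()
  all_preds <- list()
  for (acq in names(models)) {
    preds <- lapply(test, function(r)
      predict_eye(models[[acq]], r$volumes[[acq]], n = ncr[[acq]]))
    metrics[[acq]] <- eval_to_metrics(evaluate_model(preds, labels))
    all_preds[[acq]] <- preds
  }
  if (length(models) == 2) {
    hybrid <- build_hybrid_model(models, config$evaluate$rule)
    preds <- lapply(test, function(r)
      predict_eye(hybrid, r$volumes, n = unlist(ncr)))
    metrics$hybrid <- eval_to_metrics(evaluate_model(preds, labels))
    all_preds$hybrid <- preds
  }
  ptab <- do.call(rbind, lapply(names(all_preds), function(m) {
    do.call(rbind, lapply(seq_along(test), function(i) {
      p <- all_preds[[m]][[i]]
      tibble::tibble(model = m, patient_id = test[[i]]$patient_id,
                     eye = test[[i]]$laterality, grade = labels[i],
                     predicted = p$grade,
                     score_task0 = p$task_scores[1], score_task1 = p$task_scores[2],
                     score_task2 = p$task_scores[3], score_task3 = p$task_scores[4])
    }))
  }))
  write_manifest(ptab, file.path(out_dir, "predictions.csv"))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(metrics)
}

stage_predict <- function(config, out_dir) {
  models <- load_trained(config, out_dir)
  records <- prep_records(out_dir)
  ncr <- config$evaluate$n_crops
  set.seed(config$seed)
  rows <- list()
  for (r in records) {
    for (acq in intersect(names(models), names(r$volumes))) {
      p <- predict_eye(models[[acq]], r$volumes[[acq]], n = ncr[[acq]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = r$patient_id, eye = r$laterality, model = acq,
        predicted = p$grade,
        score_task0 = p$task_scores[1], score_task1 = p$task_scores[2],
        score_task2 = p$task_scores[3], score_task3 = p$task_scores[4])
    }
  }
  tab <- do.call(rbind, rows)
  write_manifest(tab, file.path(out_dir, "predictions_all.csv"))
  invisible(tab)
}

# Prediction-time comparison of the cropping strategies on the test set
# (random-crop aggregation vs resize, center crop and subvolume grid).
stage_benchmark_crops <- function(config, out_dir) {
  models <- load_trained(config, out_dir)
  acq <- names(models)[1]
  model <- models[[acq]]
  test <- build_task_subsets(test_records(out_dir), acq)
  labels <- vapply(test, `[[`, integer(1), "grade")
  ncr <- config$evaluate$n_crops[[acq]]
  set.seed(config$seed)
  strategies <- list(
    random_crop = function(v) predict_eye(model, v, n = ncr),
    resize = function(v) {
      a <- vol_data(v)
      p <- default_patch(a)
      probs <- predict_probs(model, resize_volume(a, p))
      agg <- aggregate_severest(list(probs))
      structure(agg, class = "octa_eye_prediction")
    },
    center_crop = function(v) {
      a <- vol_data(v)
      probs <- predict_probs(model, center_crop(a, default_patch(a))$data)
      structure(aggregate_severest(list(probs)), class = "octa_eye_prediction")
    },
    subvolume_crop = function(v) {
      a <- vol_data(v)
      grid <- subvolume_grid(a, default_patch(a))
      probs <- lapply(grid, function(g) predict_probs(model, g$data))
      structure(aggregate_severest(probs), class = "octa_eye_prediction")
    })
  metrics <- lapply(strategies, function(strat) {
    preds <- lapply(test, function(r) strat(r$volumes[[acq]]))
    eval_to_metrics(evaluate_model(preds, labels))
  })
  jsonlite::write_json(metrics, file.path(out_dir, "benchmark_crops.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(metrics)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic cohort to NIfTI volumes + CSV manifest),
#' `preprocess` (surface segmentation + flattening), `train` (patient-level
#' split, per-acquisition fusion models), `evaluate` (test-set predictions
#' CSV + metrics JSON including the hybrid decision fusion), `predict`
#' (predictions for every eye) and `benchmark_crops` (prediction-time
#' comparison of the four cropping strategies). Stages read only the
#' artifacts of earlier stages and fail with a descriptive error naming the
#' missing stage otherwise.
#'
#' @param config Configuration list ([default_run_config()]) or a YAML path.
#' @param stage Stage name.
#' @param out_dir Output directory (default: `config$out_dir`).
#' @return Stage result, invisibly.
#' @export
run_stage <- function(config, stage = c("simulate", "preprocess", "train",
                                        "evaluate", "predict", "benchmark_crops"),
                      out_dir = NULL) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(stage,
                simulate = stage_simulate(config, out_dir),
                preprocess = stage_preprocess(config, out_dir),
                train = stage_train(config, out_dir),
                evaluate = stage_evaluate(config, out_dir),
                predict = stage_predict(config, out_dir),
                benchmark_crops = stage_benchmark_crops(config, out_dir))
  write_run_log(config, stage, out_dir)
  invisible(res)
}
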
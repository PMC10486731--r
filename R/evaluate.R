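# Inference and evaluation: N-times random-crop prediction with
# severest-prediction aggregation, cumulative binary task scores, tie-aware
# ROC AUC and Cohen's kappa.

#' Cumulative binary task score
#'
#' Task `k` (0..3) detects severity grade `>= k + 1`; its score is the total
#' probability mass on those grades, so task 3 (detecting PDR or PRP) sums
#' the PDR and PRP probabilities. Scores are non-increasing in `k`.
#'
#' @param p Probability vector over the six grades.
#' @param task_k Task index 0..3, or the default `0:3` for all four.
#' @return Numeric score(s) in `[0, 1]`.
#' @export
task_score <- function(p, task_k = 0:3) {
  validate_prob(p)
  if (any(task_k < 0 | task_k > 3)) stop("'task_k' must be in 0..3")
  vapply(task_k, function(k) sum(p[(k + 2):6]), numeric(1))
}

#' Aggregate per-crop predictions by the severest rule
#'
#' Per task, the aggregated score is the maximum task score over crops. The
#' aggregated discrete grade is the severest argmax grade across crops, and
#' the reported probability vector is that of the crop attaining it (ties
#' broken by the higher probability of that grade). The rule is
#' permutation-invariant and monotone under crop addition.
#'
#' @param crop_probs List of probability vectors, or an `N x 6` matrix with
#'   one row per crop.
#' @return List with `prob` (the representative probability vector),
#'   `task_scores` (length 4) and `grade` (0..5).
#' @export
aggregate_severest <- function(crop_probs) {
  if (is.matrix(crop_probs))
    crop_probs <- lapply(seq_len(nrow(crop_probs)), function(i) crop_probs[i, ])
  if (!is.list(crop_probs) || length(crop_probs) == 0)
    stop("'crop_probs' must be a non-empty list of probability vectors")
  for (p in crop_probs) validate_prob(p)
  scores <- vapply(crop_probs, task_score, numeric(4))      # 4 x N
  agg_scores <- apply(scores, 1, max)
  argmax <- vapply(crop_probs, which.max, integer(1))       # 1-based
  sev <- max(argmax)
  cand <- which(argmax == sev)
  best <- cand[which.max(vapply(cand, function(i) crop_probs[[i]][sev], numeric(1)))]
  list(prob = crop_probs[[best]], task_scores = as.numeric(agg_scores),
       grade = as.integer(sev - 1L))
}

default_patch <- function(a) {
  d <- dim(a)
  pmin(c(d[2], d[2], d[2], d[4]), d)
}

predict_single_acquisition <- function(model, volume, n, patch = NULL) {
  a <- vol_data(volume)
  patch <- patch %||% default_patch(a)
  if (n < 1) stop("'n' (number of random crops) must be >= 1")
  probs <- matrix(0, n, model$n_classes)
  for (i in seq_len(n)) {
    cr <- random_crop(a, patch)
    probs[i, ] <- predict_probs(model, cr$data)
  }
  agg <- aggregate_severest(probs)
  structure(list(crop_probs = probs, prob = agg$prob,
                 task_scores = agg$task_scores, grade = agg$grade),
            class = "octa_eye_prediction")
}

#' Predict one eye with N-times random cropping
#'
#' Draws `n` random crops per acquisition, computes crop-level probability
#' vectors with the model and aggregates them with the severest rule
#' ([aggregate_severest()]). For a hybrid model, each acquisition is
#' aggregated first, then the two acquisition-level results are
#' decision-fused: the fused probability vector follows the model's rule and
#' per-task scores are the rule's elementwise combination (mean for `avg`,
#' maximum for `max`) of the acquisition task-score vectors. A missing
#' acquisition triggers a warning and a single-branch fallback.
#'
#' @param model An `octa_model`.
#' @param volumes For single-acquisition models an `octa_volume` (or rank-4
#'   array); for hybrid/cross-acquisition models a named list of volumes
#'   (`hr6`, `uwf15`).
#' @param n Number of random crops; default 10 for `hr6` and 20 for `uwf15`
#'   (the validated trade-off), or a named vector for hybrid models.
#' @param patch Patch shape; defaults to a depth-sized cube over both
#'   channels, clamped to the volume.
#' @return An `octa_eye_prediction`: `crop_probs`, aggregated `prob`,
#'   `task_scores` (length 4) and `grade`.
#' @export
predict_eye <- function(model, volumes, n = NULL, patch = NULL) {
  default_n <- function(acq) {
    if (!is.null(n)) {
      if (!is.null(names(n)) && acq %in% names(n)) return(n[[acq]])
      return(n[[1]])
    }
    if (!is.na(acq) && acq %in% c("hr6", "uwf15")) acq_geometry(acq)$n_crops else 10L
  }
  if (inherits(model, "octa_hybrid")) {
    stopifnot(is.list(volumes))
    avail <- intersect(names(model$acquisition_models), names(volumes))
    if (length(avail) == 0) stop("no acquisition available for the hybrid model")
    if (length(avail) < length(model$acquisition_models))
      warning("acquisition(s) ",
              paste(setdiff(names(model$acquisition_models), avail), collapse = ", "),
              " missing; falling back to the available branch")
    subs <- lapply(avail, function(acq)
      predict_eye(model$acquisition_models[[acq]], volumes[[acq]],
                  n = default_n(acq), patch = patch))
    prob <- fuse_decisions(lapply(subs, `[[`, "prob"), model$rule)
    sc <- do.call(rbind, lapply(subs, `[[`, "task_scores"))
    task_scores <- if (model$rule == "avg") colMeans(sc) else apply(sc, 2, max)
    return(structure(list(
      crop_probs = do.call(rbind, lapply(subs, `[[`, "crop_probs")),
      prob = prob, task_scores = as.numeric(task_scores),
      grade = as.integer(which.max(prob) - 1L),
      per_acquisition = stats::setNames(subs, avail)),
      class = "octa_eye_prediction"))
  }
  if (inherits(model, "octa_cross_feature")) {
    stopifnot(is.list(volumes), all(names(model$branches) %in% names(volumes)))
    arrays <- lapply(volumes[names(model$branches)], vol_data)
    nn <- default_n(names(model$branches)[1])
    if (nn < 1) stop("'n' (number of random crops) must be >= 1")
    probs <- matrix(0, nn, model$n_classes)
    for (i in seq_len(nn)) {
      crops <- lapply(arrays, function(a) random_crop(a, patch %||% default_patch(a))$data)
      probs[i, ] <- predict_probs(model, crops)
    }
    agg <- aggregate_severest(probs)
    return(structure(list(crop_probs = probs, prob = agg$prob,
                          task_scores = agg$task_scores, grade = agg$grade),
                     class = "octa_eye_prediction"))
  }
  if (is.list(volumes) && !inherits(volumes, "octa_volume")) {
    stopifnot(length(volumes) == 1)
    volumes <- volumes[[1]]
  }
  acq <- if (inherits(volumes, "octa_volume")) volumes$acquisition else NA_character_
  predict_single_acquisition(model, volumes, n = default_n(acq), patch = patch)
}

#' Tie-aware area under the ROC curve
#'
#' Equal to the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`, counting ties as half concordant (midrank formula).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p0 - pe) / (1 - pe)` with `p0` the observed accuracy
#' (trace/total) and `pe` the chance agreement from the row/column marginals.
#'
#' @param confusion Square count matrix (rows = true class, columns =
#'   predicted class).
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(matrix(c(40, 20, 10, 30), 2))  # 0.4
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  total <- sum(confusion)
  if (total <= 0) stop("confusion matrix is empty")
  p0 <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: chance agreement is 1 (degenerate margins)")
  (p0 - pe) / (1 - pe)
}

#' Evaluate eye-level predictions against severity labels
#'
#' Computes the four cumulative-task AUCs (task `k` binarizes labels at grade
#' `>= k + 1`), Cohen's kappa on the 6-class confusion of predicted grades,
#' and the confusion matrix itself. Tasks for which the test labels contain a
#' single class yield an `NA` AUC with a warning.
#'
#' @param predictions List of `octa_eye_prediction`s (from [predict_eye()]).
#' @param labels Integer severity grades 0..5, one per prediction.
#' @return An `octa_eval`: `kappa`, `auc` (named `auc0`..`auc3`), `confusion`
#'   (6x6, rows = true grade), `n_eyes` and a per-eye `predictions` tibble.
#' @export
evaluate_model <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("'predictions' and 'labels' must have the same length")
  labels <- vapply(labels, validate_grade, integer(1))
  pred_grade <- vapply(predictions, function(p) p$grade, integer(1))
  scores <- do.call(rbind, lapply(predictions, `[[`, "task_scores"))
  auc <- stats::setNames(rep(NA_real_, 4), paste0("auc", 0:3))
  for (k in 0:3) {
    bin <- as.integer(labels >= k + 1)
    if (length(unique(bin)) == 2) {
      auc[k + 1] <- roc_auc(scores[, k + 1], bin)
    } else {
      warning("task ", k, ": single-class labels, AUC undefined")
    }
  }
  confusion <- matrix(0L, 6, 6, dimnames = list(true = 0:5, predicted = 0:5))
  for (i in seq_along(labels))
    confusion[labels[i] + 1L, pred_grade[i] + 1L] <-
      confusion[labels[i] + 1L, pred_grade[i] + 1L] + 1L
  structure(list(kappa = cohens_kappa(confusion), auc = auc,
                 confusion = confusion, n_eyes = length(labels),
                 predictions = tibble::tibble(
                   eye = seq_along(labels), grade = labels,
                   predicted = pred_grade,
                   score_task0 = scores[, 1], score_task1 = scores[, 2],
                   score_task2 = scores[, 3], score_task3 = scores[, 4])),
            class = "octa_eval")
}

#' @export
print.octa_eval <- function(x, ...) {
  cat(sprintf("<octa_eval> %d eyes | kappa %.4f | AUC0-3: %s\n", x$n_eyes,
              x$kappa, paste(sprintf("%.4f", x$auc), collapse = " ")))
  invisible(x)
}
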
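# Fusion topologies. Single-acquisition fusion combines the structure and
# flow channels of one OCTA volume at the input, feature, decision or
# hierarchical level; cross-acquisition fusion merges the high-resolution
# (hr6) and ultra-widefield (uwf15) acquisitions either by joint feature
# fine-tuning or by decision fusion of their output probabilities. The
# proposed hybrid model is hierarchical fusion within each acquisition
# followed by decision-average fusion across acquisitions.

#' Describe a fusion topology
#'
#' @param level Fusion level for the structure/flow channels of one
#'   acquisition: `"input"`, `"feature"`, `"decision"` or `"hierarchical"`.
#' @param branch_specs List of [backbone_spec()]s, one per modality branch
#'   (a single spec for input fusion, whose `in_channels` must equal the
#'   total number of modality channels).
#' @param decision_rule `"avg"` or `"max"` (decision level only).
#' @param cross_acquisition Optional cross-acquisition strategy:
#'   `"feature_finetune_full"`, `"feature_finetune_head"`, `"decision_avg"`,
#'   `"decision_max"`.
#' @return A `fusion_spec` list.
#' @export
fusion_spec <- function(level = c("input", "feature", "decision", "hierarchical"),
                        branch_specs, decision_rule = c("avg", "max"),
                        cross_acquisition = NULL) {
  level <- match.arg(level)
  decision_rule <- match.arg(decision_rule)
  if (!is.null(cross_acquisition))
    cross_acquisition <- match.arg(cross_acquisition,
      c("feature_finetune_full", "feature_finetune_head", "decision_avg", "decision_max"))
  if (inherits(branch_specs, "backbone_spec")) branch_specs <- list(branch_specs)
  stopifnot(all(vapply(branch_specs, inherits, logical(1), "backbone_spec")))
  if (level == "input" && length(branch_specs) != 1)
    stop("input fusion takes exactly one backbone spec on the concatenated channels")
  if (level != "input" && length(branch_specs) < 2)
    stop(level, " fusion needs one backbone per modality (>= 2)")
  structure(list(level = level, branch_specs = branch_specs,
                 decision_rule = decision_rule, cross_acquisition = cross_acquisition),
            class = "fusion_spec")
}

#' Build a fusion model from a fusion spec
#'
#' @param spec A [fusion_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An `octa_model`.
#' @export
build_fusion_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fusion_spec"))
  switch(spec$level,
         input = build_input_fusion(spec, seed),
         feature = build_feature_fusion(spec, seed),
         decision = build_decision_fusion(spec, seed),
         hierarchical = build_hierarchical_fusion(spec, seed))
}

#' Input-level fusion: one backbone on channel-concatenated modalities
#'
#' @inheritParams build_fusion_model
#' @export
build_input_fusion <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fusion_spec"), spec$level == "input")
  model <- build_backbone(spec$branch_specs[[1]], seed = seed)
  model$level <- "input"
  model
}

strip_head <- function(backbone) {
  backbone$head <- NULL
  backbone
}

branch_channels <- function(specs) vapply(specs, function(s) s$in_channels, integer(1))

split_modalities <- function(x, channels) {
  stopifnot(dim(x)[4] == sum(channels))
  off <- 0
  out <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    out[[i]] <- x[, , , off + seq_len(channels[i]), drop = FALSE]
    off <- off + channels[i]
  }
  out
}

#' Feature-level fusion: per-modality branches, concatenated pooled features
#'
#' Each modality is encoded by its own backbone; the globally pooled branch
#' features are concatenated and mapped to class logits by a single linear
#' decision head. Branches may receive inputs on different grids.
#'
#' @inheritParams build_fusion_model
#' @export
build_feature_fusion <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fusion_spec"), spec$level %in% c("feature", "hierarchical"))
  branches <- lapply(seq_along(spec$branch_specs), function(i)
    strip_head(build_backbone(spec$branch_specs[[i]], seed = seed + i - 1L)))
  feat_dims <- vapply(branches, function(b) b$feat_dim, integer(1))
  n_classes <- spec$branch_specs[[1]]$n_classes
  model <- list(type = "feature_fusion", level = "feature", branches = branches,
                branch_channels = branch_channels(spec$branch_specs),
                head = m_linear(sum(feat_dims), n_classes),
                n_classes = n_classes, spec = spec)
  class(model) <- c("octa_feature_fusion", "octa_model")
  model
}

#' Decision-level fusion: independent branches, fused output probabilities
#'
#' @inheritParams build_fusion_model
#' @export
build_decision_fusion <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fusion_spec"), spec$level == "decision")
  branches <- lapply(seq_along(spec$branch_specs), function(i)
    build_backbone(spec$branch_specs[[i]], seed = seed + i - 1L))
  model <- list(type = "decision_fusion", level = "decision", branches = branches,
                branch_channels = branch_channels(spec$branch_specs),
                rule = spec$decision_rule,
                n_classes = spec$branch_specs[[1]]$n_classes, spec = spec)
  class(model) <- c("octa_decision_fusion", "octa_model")
  model
}

#' Hierarchical fusion: multi-scale fusion branch over two modality branches
#'
#' A third fusion branch consumes, at each of the four feature scales, the
#' channel concatenation of both branch feature maps, projected to the
#' branch width by a 1x1x1 convolution and added to the fusion branch's own
#' carried (1x1x1 conv + norm + pooled) previous-scale output. The decision
#' head consumes the concatenation of both branch pooled features and the
#' fusion branch pooled feature.
#'
#' @inheritParams build_fusion_model
#' @export
build_hierarchical_fusion <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fusion_spec"), spec$level == "hierarchical")
  if (length(spec$branch_specs) != 2)
    stop("hierarchical fusion is defined for two modality branches")
  branches <- lapply(seq_along(spec$branch_specs), function(i)
    strip_head(build_backbone(spec$branch_specs[[i]], seed = seed + i - 1L)))
  n_stage <- length(branches[[1]]$stages)
  if (length(branches[[2]]$stages) != n_stage)
    stop("branches have mismatched stage counts")
  ch1 <- branches[[1]]$stage_channels
  ch2 <- branches[[2]]$stage_channels
  proj <- vector("list", n_stage)
  carry <- vector("list", n_stage)
  for (s in seq_len(n_stage)) {
    proj[[s]] <- m_conv(ch1[s] + ch2[s], ch1[s], 1L, act = "relu")
    if (s > 1) carry[[s]] <- m_conv(ch1[s - 1], ch1[s], 1L, act = "relu")
  }
  feat_dims <- c(branches[[1]]$feat_dim, branches[[2]]$feat_dim, ch1[n_stage])
  n_classes <- spec$branch_specs[[1]]$n_classes
  model <- list(type = "hierarchical_fusion", level = "hierarchical",
                branches = branches, proj = proj, carry = carry,
                branch_channels = branch_channels(spec$branch_specs),
                feat_dims = feat_dims,
                head = m_linear(sum(feat_dims), n_classes),
                n_classes = n_classes, spec = spec)
  class(model) <- c("octa_hierarchical_fusion", "octa_model")
  model
}

# Align a feature map node to a reference spatial size (mixed-architecture
# or cross-grid branches) by adaptive average pooling; identity when equal.
align_to <- function(node, ref_spatial) {
  if (all(dim(node$value)[1:3] == ref_spatial)) node else op_adapool3d(node, ref_spatial)
}

# ---- forward passes ----------------------------------------------------

as_branch_inputs <- function(model, x) {
  if (is.list(x)) {
    stopifnot(length(x) == length(model$branches))
    x
  } else {
    split_modalities(x, model$branch_channels)
  }
}

# Pooled feature vector (ag node) for models with a linear decision head.
model_features_node <- function(model, x) {
  if (inherits(model, "octa_backbone")) {
    if (is.list(x)) {
      stopifnot(length(x) >= 1)
      x <- if (length(x) == 1) x[[1]] else {
        d <- dim(x[[1]])
        array(unlist(x, use.names = FALSE),
              dim = c(d[1:3], sum(vapply(x, function(v) dim(v)[4], numeric(1)))))
      }
    }
    if (dim(x)[4] != model$in_channels)
      stop("input has ", dim(x)[4], " channels but the model expects ", model$in_channels)
    return(backbone_trace(model, ag_const(x))$pooled)
  }
  if (inherits(model, "octa_feature_fusion")) {
    xs <- as_branch_inputs(model, x)
    pooled <- lapply(seq_along(model$branches), function(i)
      backbone_trace(model$branches[[i]], ag_const(xs[[i]]))$pooled)
    return(op_concat_vec(pooled))
  }
  if (inherits(model, "octa_hierarchical_fusion")) {
    xs <- as_branch_inputs(model, x)
    tr1 <- backbone_trace(model$branches[[1]], ag_const(xs[[1]]))
    tr2 <- backbone_trace(model$branches[[2]], ag_const(xs[[2]]))
    f <- NULL
    for (s in seq_along(model$proj)) {
      ref <- dim(tr1$taps[[s]]$value)[1:3]
      cat_s <- op_concat_c(list(tr1$taps[[s]], align_to(tr2$taps[[s]], ref)))
      h <- nn_fwd(model$proj[[s]], cat_s)
      f <- if (is.null(f)) h else op_add(h, align_to(nn_fwd(model$carry[[s]], f), ref))
    }
    return(op_concat_vec(list(tr1$pooled, tr2$pooled, op_gap(f))))
  }
  if (inherits(model, "octa_cross_feature")) {
    stopifnot(is.list(x), length(x) == 2)
    feats <- lapply(seq_along(model$branches), function(i)
      model_features_node(model$branches[[i]], x[[i]]))
    return(op_concat_vec(feats))
  }
  stop("model of type ", model$type, " has no single feature vector")
}

model_logits_node <- function(model, x) {
  nn_fwd(model$head, model_features_node(model, x))
}

#' Class logits of a model on one input
#'
#' @param model An `octa_model` with a decision head.
#' @param x A rank-4 crop array, or a list of per-branch crop arrays.
#' @return Numeric logit vector of length `n_classes`.
#' @export
model_logits <- function(model, x) {
  ag_no_grad(as.numeric(model_logits_node(model, x)$value))
}

#' Class probabilities of a model on one input
#'
#' For decision-fusion and hybrid models the branch probabilities are fused
#' with the model's decision rule; otherwise probabilities are the softmax of
#' the head logits.
#'
#' @inheritParams model_logits
#' @return A probability vector over the severity grades.
#' @export
predict_probs <- function(model, x) {
  if (inherits(model, "octa_decision_fusion")) {
    xs <- as_branch_inputs(model, x)
    probs <- lapply(seq_along(model$branches), function(i)
      predict_probs(model$branches[[i]], xs[[i]]))
    return(fuse_decisions(probs, model$rule))
  }
  softmax(model_logits(model, x))
}

# Training loss (ag scalar) for one example; class1 is the 1-based grade.
model_loss_node <- function(model, x, class1) {
  op_softmax_ce(model_logits_node(model, x), class1)
}

#' Fuse per-branch probability vectors into one decision
#'
#' The averaging rule takes the elementwise mean (which stays on the
#' probability simplex); the maximization rule takes the elementwise maximum
#' renormalized to sum one. Both are symmetric in argument order.
#'
#' @param probs Non-empty list of probability vectors of equal length.
#' @param rule `"avg"` or `"max"`.
#' @return A probability vector.
#' @examples
#' fuse_decisions(list(c(.2, .8, 0, 0, 0, 0), c(.6, .4, 0, 0, 0, 0)), "avg")
#' @export
fuse_decisions <- function(probs, rule = c("avg", "max")) {
  rule <- match.arg(rule)
  if (!is.list(probs) || length(probs) == 0)
    stop("'probs' must be a non-empty list of probability vectors")
  for (p in probs) validate_prob(p)
  m <- do.call(rbind, probs)
  out <- switch(rule,
                avg = colMeans(m),
                max = { mx <- apply(m, 2, max); mx / sum(mx) })
  as.numeric(out)
}

#' Assemble the hybrid cross-acquisition model
#'
#' Combines one (typically hierarchical) model per acquisition; at prediction
#' time each acquisition's crops are aggregated first and the two
#' acquisition-level probability vectors are decision-fused with `cross_rule`
#' (averaging for the proposed method). If an acquisition is missing for an
#' eye, prediction falls back to the single available branch with a warning.
#'
#' @param per_acquisition Named list of models, names in
#'   `c("hr6", "uwf15")`.
#' @param cross_rule `"avg"` or `"max"`.
#' @return An `octa_model` of subtype `"hybrid"`.
#' @export
build_hybrid_model <- function(per_acquisition, cross_rule = c("avg", "max")) {
  cross_rule <- match.arg(cross_rule)
  stopifnot(is.list(per_acquisition), length(per_acquisition) >= 1,
            !is.null(names(per_acquisition)),
            all(names(per_acquisition) %in% c("hr6", "uwf15")))
  model <- list(type = "hybrid", level = "hybrid",
                acquisition_models = per_acquisition, rule = cross_rule,
                n_classes = per_acquisition[[1]]$n_classes)
  class(model) <- c("octa_hybrid", "octa_model")
  model
}

#' Join two per-acquisition models for cross-acquisition feature fusion
#'
#' The two (pre-trained) hierarchical models' feature extractors are kept and
#' a new linear head is placed on the concatenation of their pooled feature
#' vectors. Use [cross_feature_finetune()] to choose which parameters are
#' trainable.
#'
#' @param per_acquisition Named list of two models (`hr6`, `uwf15`).
#' @param seed Seed for the new head's initialization.
#' @return An `octa_model` of subtype `"cross_feature"`.
#' @export
build_cross_feature <- function(per_acquisition, seed = 1L) {
  stopifnot(length(per_acquisition) == 2, !is.null(names(per_acquisition)))
  dims <- vapply(per_acquisition, function(m)
    if (!is.null(m$feat_dims)) sum(m$feat_dims) else m$feat_dim, numeric(1))
  set.seed(seed)
  n_classes <- per_acquisition[[1]]$n_classes
  branches <- lapply(per_acquisition, function(m) { m$head <- NULL; m })
  model <- list(type = "cross_feature", level = "cross_feature",
                branches = branches, head = m_linear(sum(dims), n_classes),
                n_classes = n_classes)
  class(model) <- c("octa_cross_feature", "octa_model")
  model
}

#' Configure fine-tuning of a joint cross-acquisition feature-fusion model
#'
#' `mode = "full"` makes every parameter trainable (network fine-tuning);
#' `mode = "head_only"` freezes all convolutional branch parameters and
#' trains only the classification head (layer fine-tuning).
#'
#' @param joint_model A model from [build_cross_feature()].
#' @param mode `"full"` or `"head_only"`.
#' @return The model, with trainability flags set.
#' @export
cross_feature_finetune <- function(joint_model, mode = c("full", "head_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(joint_model, "octa_cross_feature"))
  if (mode == "full") {
    set_trainable(joint_model, TRUE)
  } else {
    set_trainable(joint_model$branches, FALSE)
    set_trainable(joint_model$head, TRUE)
  }
  joint_model$finetune_mode <- mode
  joint_model
}
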
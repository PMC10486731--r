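# The three 3D classification backbones. Each canonical 2D architecture is
# converted by replacing every convolution/pooling with its cubic 3D
# counterpart, preserving the stage layout. A width multiplier shrinks all
# channel counts (rounded to multiples of 8, floor 8) so the networks remain
# trainable on a desk CPU. Normalization is group normalization, which is
# independent of batch composition and identical in training and inference.

#' Describe a 3D classification backbone
#'
#' @param arch One of `"resnet50_3d"`, `"densenet121_3d"`,
#'   `"efficientnetb0_3d"`.
#' @param in_channels Number of input channels (2 for a structure+flow
#'   volume, 1 for a single modality).
#' @param n_classes Number of output classes (6 severity grades by default).
#' @param width_mult Channel-width multiplier in (0, 1]; 1 reproduces the
#'   canonical widths.
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(arch = c("resnet50_3d", "densenet121_3d", "efficientnetb0_3d"),
                          in_channels = 2L, n_classes = 6L, width_mult = 1) {
  arch <- match.arg(arch)
  stopifnot(in_channels >= 1, n_classes >= 2, width_mult > 0, width_mult <= 1)
  structure(list(arch = arch, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), width_mult = width_mult),
            class = "backbone_spec")
}

wmul <- function(c, wm) as.integer(max(8, 8 * round(c * wm / 8)))

#' Build a 3D classification backbone
#'
#' Constructs one of the three supported 3D convolutional networks with
#' randomly initialized weights. Initialization is seeded, so two builds with
#' the same `seed` have identical parameters. The returned model maps a
#' rank-4 array `(x, y, z, in_channels)` to an `n_classes` logit vector and
#' exposes four feature-pyramid taps at 1/4, 1/8, 1/16 and 1/32 of the input
#' resolution for hierarchical fusion.
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `octa_model` (subtype `"backbone"`).
#' @examples
#' m <- build_backbone(backbone_spec("resnet50_3d", width_mult = 0.25), seed = 1)
#' x <- array(stats::rnorm(16^3 * 2), dim = c(16, 16, 16, 2))
#' length(model_logits(m, list(x)))  # 6
#' @export
build_backbone <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "backbone_spec"))
  set.seed(seed)
  wm <- spec$width_mult
  ci <- spec$in_channels
  b <- switch(spec$arch,
    resnet50_3d = {
      w0 <- wmul(64, wm)
      mids <- vapply(c(64, 128, 256, 512), wmul, integer(1), wm = wm)
      outs <- vapply(c(256, 512, 1024, 2048), wmul, integer(1), wm = wm)
      blocks <- c(3L, 4L, 6L, 3L)
      stem <- m_seq(list(m_conv(ci, w0, 7L, stride = 2L, pad = 3L),
                         m_maxpool(3L, 2L, 1L)))
      cin <- w0
      stages <- vector("list", 4)
      for (s in 1:4) {
        mods <- list()
        for (bl in seq_len(blocks[s])) {
          stride <- if (bl == 1 && s > 1) 2L else 1L
          mods[[bl]] <- m_bottleneck(cin, mids[s], outs[s], stride)
          cin <- outs[s]
        }
        stages[[s]] <- m_seq(mods)
      }
      list(stem = stem, stages = stages, final = NULL,
           stage_channels = outs, feat_dim = outs[4])
    },
    densenet121_3d = {
      growth <- wmul(32, wm)
      c0 <- wmul(64, wm)
      blocks <- c(6L, 12L, 24L, 16L)
      stem <- m_seq(list(m_conv(ci, c0, 7L, stride = 2L, pad = 3L),
                         m_maxpool(3L, 2L, 1L)))
      cin <- c0
      stages <- vector("list", 4)
      chans <- integer(4)
      for (s in 1:4) {
        mods <- list()
        if (s > 1) {  # transition from the previous block halves width/resolution
          cout <- as.integer(cin %/% 2)
          mods[[1]] <- m_transition(cin, cout)
          cin <- cout
        }
        for (bl in seq_len(blocks[s])) {
          mods[[length(mods) + 1L]] <- m_dense_layer(cin, growth)
          cin <- cin + growth
        }
        if (s == 4) mods[[length(mods) + 1L]] <- m_gn_act(cin)
        stages[[s]] <- m_seq(mods)
        chans[s] <- cin
      }
      list(stem = stem, stages = stages, final = NULL,
           stage_channels = chans, feat_dim = cin)
    },
    efficientnetb0_3d = {
      w <- function(c) wmul(c, wm)
      stem <- m_conv(ci, w(32), 3L, stride = 2L, act = "silu")
      mb <- function(cin, cout, k, stride, expand, reps) {
        mods <- list(m_mbconv(cin, cout, k, stride, expand))
        for (r in seq_len(reps - 1)) mods[[r + 1L]] <- m_mbconv(cout, cout, k, 1L, expand)
        mods
      }
      # stages grouped at resolution boundaries: /4, /8, /16, /32
      s1 <- m_seq(c(mb(w(32), w(16), 3L, 1L, 1L, 1L),
                    mb(w(16), w(24), 3L, 2L, 6L, 2L)))
      s2 <- m_seq(mb(w(24), w(40), 5L, 2L, 6L, 2L))
      s3 <- m_seq(c(mb(w(40), w(80), 3L, 2L, 6L, 3L),
                    mb(w(80), w(112), 5L, 1L, 6L, 3L)))
      s4 <- m_seq(c(mb(w(112), w(192), 5L, 2L, 6L, 4L),
                    mb(w(192), w(320), 3L, 1L, 6L, 1L),
                    list(m_conv(w(320), w(1280), 1L, act = "silu"))))
      list(stem = m_seq(list(stem)), stages = list(s1, s2, s3, s4), final = NULL,
           stage_channels = c(w(24), w(40), w(112), w(1280)), feat_dim = w(1280))
    },
    stop("unknown arch: ", spec$arch)
  )
  model <- c(b, list(head = m_linear(b$feat_dim, spec$n_classes), spec = spec,
                     type = "backbone", level = "single",
                     in_channels = ci, n_classes = spec$n_classes))
  class(model) <- c("octa_backbone", "octa_model")
  model
}

# Forward pass through stem and stages; returns list(taps, pooled, logits)
# of ag nodes. `x` is an ag node wrapping an (x,y,z,C) array.
backbone_trace <- function(model, x) {
  h <- nn_fwd(model$stem, x)
  taps <- vector("list", length(model$stages))
  for (s in seq_along(model$stages)) {
    h <- nn_fwd(model$stages[[s]], h)
    taps[[s]] <- h
  }
  pooled <- op_gap(h)
  list(taps = taps, pooled = pooled)
}

#' Extract the multi-scale feature pyramid of a backbone
#'
#' Runs a forward pass and returns the per-stage feature maps (four stages,
#' at 1/4 to 1/32 of the input resolution) together with the globally pooled
#' feature vector and the logits obtained by applying the model head to that
#' vector.
#'
#' @param model A backbone built by [build_backbone()].
#' @param x Rank-4 input array `(x, y, z, in_channels)`.
#' @return A list with `stages` (list of rank-4 arrays), `pooled`
#'   (numeric vector) and `logits`.
#' @export
extract_feature_pyramid <- function(model, x) {
  stopifnot(inherits(model, "octa_backbone"))
  if (dim(x)[4] != model$in_channels)
    stop("input has ", dim(x)[4], " channels but the model expects ", model$in_channels)
  ag_no_grad({
    tr <- backbone_trace(model, ag_const(x))
    logits <- nn_fwd(model$head, tr$pooled)
    list(stages = lapply(tr$taps, function(t) t$value),
         pooled = as.numeric(tr$pooled$value),
         logits = as.numeric(logits$value))
  })
}
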
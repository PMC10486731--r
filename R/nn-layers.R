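# Layer constructors and the forward dispatcher for the embedded 3D
# conv-net engine. A module is a plain list with a $type; parameters are
# ag_param() environments so optimizer updates are in place and checkpoint
# copies are cheap value snapshots.

init_conv_w <- function(k, cin, cout) {
  ag_param(array(stats::rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))),
                 dim = c(k, k, k, cin, cout)))
}

init_dw_w <- function(k, c) {
  ag_param(array(stats::rnorm(k^3 * c, sd = sqrt(2 / k^3)), dim = c(k, k, k, c)))
}

gn_groups <- function(nc) {
  for (g in c(8L, 4L, 2L)) if (nc %% g == 0) return(g)
  1L
}

m_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                   act = "relu", norm = TRUE, bias = !norm) {
  list(type = "conv", w = init_conv_w(k, cin, cout),
       b = if (bias) ag_param(numeric(cout)) else NULL,
       gamma = if (norm) ag_param(rep(1, cout)) else NULL,
       beta = if (norm) ag_param(numeric(cout)) else NULL,
       stride = stride, pad = pad, act = act, cout = cout)
}

m_dwconv <- function(c, k, stride = 1L, act = "silu") {
  list(type = "dwconv", w = init_dw_w(k, c),
       gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)),
       stride = stride, pad = (k - 1L) %/% 2L, act = act)
}

m_linear <- function(din, dout) {
  list(type = "linear",
       w = ag_param(array(stats::rnorm(dout * din, sd = sqrt(1 / din)),
                          dim = c(dout, din))),
       b = ag_param(numeric(dout)), din = din, dout = dout)
}

m_maxpool <- function(k, stride, pad = 0L) {
  list(type = "maxpool", k = k, stride = stride, pad = pad)
}

m_halve <- function() list(type = "halve")   # adaptive average pool to ceiling(n/2)

m_gn_act <- function(c, act = "relu") {
  list(type = "gn_act", gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)),
       act = act)
}

m_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1 && is.null(mods[[1]]$type)) mods <- mods[[1]]
  list(type = "seq", mods = mods)
}

m_bottleneck <- function(cin, cmid, cout, stride) {
  list(type = "bottleneck",
       c1 = m_conv(cin, cmid, 1L, act = "relu"),
       c2 = m_conv(cmid, cmid, 3L, stride = stride, act = "relu"),
       c3 = m_conv(cmid, cout, 1L, act = "none"),
       skip = if (cin != cout || stride != 1)
         m_conv(cin, cout, 1L, stride = stride, act = "none") else NULL)
}

m_dense_layer <- function(cin, growth, bn_size = 4L) {
  list(type = "dense_layer",
       n1 = m_gn_act(cin), c1 = m_conv(cin, bn_size * growth, 1L, act = "none", norm = FALSE, bias = FALSE),
       n2 = m_gn_act(bn_size * growth), c2 = m_conv(bn_size * growth, growth, 3L, act = "none", norm = FALSE, bias = FALSE))
}

m_transition <- function(cin, cout) {
  list(type = "transition",
       n = m_gn_act(cin), c = m_conv(cin, cout, 1L, act = "none", norm = FALSE, bias = FALSE))
}

m_mbconv <- function(cin, cout, k, stride, expand) {
  cexp <- if (expand > 1) cin * expand else cin
  sed <- max(4L, round(cin / 4))
  list(type = "mbconv",
       expand = if (expand > 1) m_conv(cin, cexp, 1L, act = "silu") else NULL,
       dw = m_dwconv(cexp, k, stride = stride),
       se1 = m_linear(cexp, sed), se2 = m_linear(sed, cexp),
       proj = m_conv(cexp, cout, 1L, act = "none"),
       use_skip = stride == 1 && cin == cout)
}

apply_act <- function(x, act) {
  switch(act, relu = op_relu(x), silu = op_silu(x), none = x,
         stop("unknown activation: ", act))
}

nn_fwd <- function(m, x) {
  switch(m$type,
    conv = {
      h <- op_conv3d(x, m$w, m$b, m$stride, m$pad)
      if (!is.null(m$gamma)) h <- op_groupnorm(h, m$gamma, m$beta, gn_groups(m$cout))
      apply_act(h, m$act)
    },
    dwconv = {
      h <- op_dwconv3d(x, m$w, NULL, m$stride, m$pad)
      h <- op_groupnorm(h, m$gamma, m$beta, gn_groups(length(m$gamma$value)))
      apply_act(h, m$act)
    },
    gn_act = {
      h <- op_groupnorm(x, m$gamma, m$beta, gn_groups(length(m$gamma$value)))
      apply_act(h, m$act)
    },
    linear = op_linear(x, m$w, m$b),
    maxpool = op_maxpool3d(x, m$k, m$stride, m$pad),
    halve = op_adapool3d(x, pmax(1L, ceiling(dim(x$value)[1:3] / 2))),
    seq = {
      for (sm in m$mods) x <- nn_fwd(sm, x)
      x
    },
    bottleneck = {
      h <- nn_fwd(m$c1, x)
      h <- nn_fwd(m$c2, h)
      h <- nn_fwd(m$c3, h)
      s <- if (is.null(m$skip)) x else nn_fwd(m$skip, x)
      op_relu(op_add(h, s))
    },
    dense_layer = {
      h <- nn_fwd(m$n1, x)
      h <- nn_fwd(m$c1, h)
      h <- nn_fwd(m$n2, h)
      h <- nn_fwd(m$c2, h)
      op_concat_c(list(x, h))
    },
    transition = {
      h <- nn_fwd(m$n, x)
      h <- nn_fwd(m$c, h)
      op_adapool3d(h, pmax(1L, dim(h$value)[1:3] %/% 2))
    },
    mbconv = {
      h <- x
      if (!is.null(m$expand)) h <- nn_fwd(m$expand, h)
      h <- nn_fwd(m$dw, h)
      s <- op_gap(h)
      s <- op_silu(nn_fwd(m$se1, s))
      s <- op_sigmoid(nn_fwd(m$se2, s))
      h <- op_scale_channels(h, s)
      h <- nn_fwd(m$proj, h)
      if (m$use_skip) op_add(h, x) else h
    },
    stop("unknown module type: ", m$type)
  )
}

# Depth-first, order-stable parameter collection.
nn_params <- function(m) {
  out <- list()
  walk <- function(o) {
    if (is_ag(o)) {
      if (o$requires_grad) out[[length(out) + 1L]] <<- o
    } else if (is.list(o)) {
      for (el in o) if (!is.null(el)) walk(el)
    }
  }
  walk(m)
  out
}

nn_state <- function(m) lapply(nn_params(m), function(p) p$value)

nn_load_state <- function(m, state) {
  ps <- nn_params(m)
  stopifnot(length(ps) == length(state))
  for (i in seq_along(ps)) ps[[i]]$value <- state[[i]]
  invisible(m)
}

set_trainable <- function(m, trainable) {
  for (p in nn_params(m)) p$trainable <- trainable
  invisible(m)
}

#' Number of trainable parameters in a model
#'
#' @param model A model built by [build_backbone()] or one of the fusion
#'   constructors.
#' @param trainable_only Count only parameters currently marked trainable.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model, trainable_only = FALSE) {
  ps <- nn_params(model)
  if (trainable_only)
    ps <- Filter(function(p) is.null(p$trainable) || isTRUE(p$trainable), ps)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) 0 * p$value),
       v = lapply(params, function(p) 0 * p$value))
}

adam_step <- function(state, params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    if (!is.null(p$trainable) && !isTRUE(p$trainable)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * p$grad
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * p$grad^2
    p$value <- p$value - lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  state
}
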
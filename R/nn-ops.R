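# Differentiable operations. All feature maps are rank-4 arrays
# (x, y, z, channel); vectors (pooled features, logits) are plain numerics.

op_conv3d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- x$value
  wv <- w$value
  bv <- if (is.null(b)) numeric(0) else b$value
  y <- cpp_conv3d_fw(xv, dim(xv), wv, dim(wv), bv, as.integer(stride), as.integer(pad))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  need_dx <- x$requires_grad || !is.null(x$bw)   # skip input grad at the stem
  ag_node(y, parents, bw = function(g) {
    r <- cpp_conv3d_bw(xv, dim(xv), wv, dim(wv), g,
                       as.integer(stride), as.integer(pad),
                       need_dx, !is.null(b))
    if (is.null(b)) list(r$dx, r$dw) else list(r$dx, r$dw, r$db)
  })
}

op_dwconv3d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- x$value
  wv <- w$value
  k <- dim(wv)[1]
  bv <- if (is.null(b)) numeric(0) else b$value
  y <- cpp_dwconv3d_fw(xv, dim(xv), wv, as.integer(k), bv,
                       as.integer(stride), as.integer(pad))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  need_dx <- x$requires_grad || !is.null(x$bw)
  ag_node(y, parents, bw = function(g) {
    r <- cpp_dwconv3d_bw(xv, dim(xv), wv, as.integer(k), g,
                         as.integer(stride), as.integer(pad), !is.null(b),
                         need_dx)
    if (is.null(b)) list(r$dx, r$dw) else list(r$dx, r$dw, r$db)
  })
}

op_maxpool3d <- function(x, k, stride, pad = 0L) {
  xv <- x$value
  r <- cpp_maxpool3d_fw(xv, dim(xv), as.integer(k), as.integer(stride), as.integer(pad))
  xd <- dim(xv)
  am <- r$argmax
  ag_node(r$y, list(x), bw = function(g) list(cpp_maxpool3d_bw(am, g, xd)))
}

op_adapool3d <- function(x, out_spatial) {
  xv <- x$value
  xd <- dim(xv)
  od <- as.integer(pmin(out_spatial, xd[1:3]))
  y <- cpp_adapool3d_fw(xv, xd, od)
  ag_node(y, list(x), bw = function(g) list(cpp_adapool3d_bw(g, xd, od)))
}

# Global average pool to a plain feature vector of length C.
op_gap <- function(x) {
  xv <- x$value
  xd <- dim(xv)
  nsp <- prod(xd[1:3])
  y <- colMeans(matrix(xv, nsp, xd[4]))
  ag_node(y, list(x), bw = function(g) {
    dx <- array(rep(g / nsp, each = nsp), dim = xd)
    list(dx)
  })
}

op_relu <- function(x) {
  xv <- x$value
  y <- pmax(xv, 0)
  if (!is.null(dim(xv))) dim(y) <- dim(xv)
  ag_node(y, list(x), bw = function(g) list(g * (xv > 0)))
}

op_silu <- function(x) {
  xv <- x$value
  s <- 1 / (1 + exp(-xv))
  y <- xv * s
  if (!is.null(dim(xv))) dim(y) <- dim(xv)
  ag_node(y, list(x), bw = function(g) list(g * (s * (1 + xv * (1 - s)))))
}

op_sigmoid <- function(x) {
  xv <- x$value
  s <- 1 / (1 + exp(-xv))
  if (!is.null(dim(xv))) dim(s) <- dim(xv)
  ag_node(s, list(x), bw = function(g) list(g * s * (1 - s)))
}

op_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), bw = function(g) list(g, g))
}

# Multiply each channel of x by scalar s[c] (squeeze-excitation gate).
op_scale_channels <- function(x, s) {
  xv <- x$value
  sv <- s$value
  xd <- dim(xv)
  nsp <- prod(xd[1:3])
  y <- xv * rep(sv, each = nsp)
  dim(y) <- xd
  ag_node(y, list(x, s), bw = function(g) {
    dx <- g * rep(sv, each = nsp)
    dim(dx) <- xd
    ds <- colSums(matrix(g * xv, nsp, xd[4]))
    list(dx, ds)
  })
}

# Concatenate rank-4 maps along the channel axis.
op_concat_c <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  d1 <- dim(vals[[1]])
  ncs <- vapply(vals, function(v) dim(v)[4], numeric(1))
  y <- array(0, dim = c(d1[1:3], sum(ncs)))
  off <- 0
  for (v in vals) {
    y[, , , off + seq_len(dim(v)[4])] <- v
    off <- off + dim(v)[4]
  }
  ag_node(y, xs, bw = function(g) {
    out <- vector("list", length(vals))
    off <- 0
    for (i in seq_along(vals)) {
      nc <- dim(vals[[i]])[4]
      out[[i]] <- g[, , , off + seq_len(nc), drop = FALSE]
      off <- off + nc
    }
    out
  })
}

op_concat_vec <- function(xs) {
  vals <- lapply(xs, function(x) as.numeric(x$value))
  lens <- lengths(vals)
  ag_node(unlist(vals, use.names = FALSE), xs, bw = function(g) {
    out <- vector("list", length(vals))
    off <- 0
    for (i in seq_along(vals)) {
      out[[i]] <- g[off + seq_len(lens[i])]
      off <- off + lens[i]
    }
    out
  })
}

# y = W x + b for a feature vector x; W has dim (out, in).
op_linear <- function(x, w, b) {
  xv <- as.numeric(x$value)
  wv <- w$value
  y <- as.numeric(wv %*% xv) + b$value
  ag_node(y, list(x, w, b), bw = function(g) {
    g <- as.numeric(g)
    list(as.numeric(crossprod(wv, g)), outer(g, xv), g)
  })
}

# Group normalization over (spatial x channels-per-group), rank-4 input.
op_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  xv <- x$value
  xd <- dim(xv)
  nc <- xd[4]
  g <- groups
  while (g > 1 && nc %% g != 0) g <- g %/% 2L
  cg <- nc / g
  nsp <- prod(xd[1:3])
  m <- matrix(xv, nsp * cg, g)
  mu <- colMeans(m)
  va <- colMeans(m * m) - mu^2
  istd <- 1 / sqrt(va + eps)
  xhat <- (m - rep(mu, each = nsp * cg)) * rep(istd, each = nsp * cg)
  xh2 <- matrix(xhat, nsp, nc)
  gam <- rep(gamma$value, each = nsp)
  y <- xh2 * gam + rep(beta$value, each = nsp)
  dim(y) <- xd
  ag_node(y, list(x, gamma, beta), bw = function(dy) {
    dy2 <- matrix(dy, nsp, nc)
    dgamma <- colSums(dy2 * xh2)
    dbeta <- colSums(dy2)
    dxhat <- matrix(dy2 * gam, nsp * cg, g)
    mh <- matrix(xhat, nsp * cg, g)
    c1 <- colMeans(dxhat)
    c2 <- colMeans(dxhat * mh)
    dx <- (dxhat - rep(c1, each = nsp * cg) - mh * rep(c2, each = nsp * cg)) *
      rep(istd, each = nsp * cg)
    dim(dx) <- xd
    list(dx, dgamma, dbeta)
  })
}

# Cross-entropy of softmax(logits) against integer class (1-based).
# Returns scalar node; $prob attribute carries the probability vector.
op_softmax_ce <- function(logits, class1) {
  lv <- as.numeric(logits$value)
  m <- max(lv)
  p <- exp(lv - m)
  p <- p / sum(p)
  loss <- -log(max(p[class1], 1e-12))
  node <- ag_node(loss, list(logits), bw = function(g) {
    d <- p
    d[class1] <- d[class1] - 1
    list(d * as.numeric(g))
  })
  attr(node, "prob") <- p
  node
}

softmax <- function(v) {
  v <- v - max(v)
  e <- exp(v)
  e / sum(e)
}
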
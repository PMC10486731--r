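# Preprocessing: surface segmentation, ILM flattening with depth
# resampling, and the four cropping strategies (resize, center crop, random
# crop, subvolume grid).

vol_data <- function(v) {
  if (inherits(v, c("octa_raw_volume", "octa_volume"))) v$data else v
}

# 3x3 median filter with replicated borders, for surface-map smoothing.
median_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- cbind(pmax(1, seq_len(nr) - 1), seq_len(nr), pmin(nr, seq_len(nr) + 1))
  ci <- cbind(pmax(1, seq_len(nc) - 1), seq_len(nc), pmin(nc, seq_len(nc) + 1))
  stack <- array(0, c(nr, nc, 9))
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    stack[, , k] <- m[ri[, a], ci[, b]]
  }
  apply(stack, c(1, 2), median)
}

#' Segment the ILM and RPE surfaces of a raw volume
#'
#' Per-A-scan maximum-gradient detection on the depth-smoothed structure
#' channel: the ILM is the strongest rising depth gradient, the RPE lower
#' boundary the strongest falling gradient below it; both surface maps are
#' median filtered (3x3).
#'
#' @param raw An `octa_raw_volume` or a rank-4 array `(x, depth, z, channel)`
#'   whose first channel is the structure signal.
#' @param min_separation Minimum ILM-RPE separation as a fraction of raw
#'   depth.
#' @return List with `ilm` and `rpe` matrices (continuous 1-based depth
#'   positions).
#' @export
segment_surfaces <- function(raw, min_separation = 0.05) {
  a <- vol_data(raw)
  stopifnot(length(dim(a)) == 4)
  st <- a[, , , 1]
  nd <- dim(st)[2]
  rng <- max(st) - min(st)
  if (!is.finite(rng) || rng < 1e-6)
    stop("surface not found: no detectable retinal band (flat intensity)")
  # moving-average smoothing along depth
  sm <- st
  sm[, 2:(nd - 1), ] <- (st[, 1:(nd - 2), ] + st[, 2:(nd - 1), ] + st[, 3:nd, ]) / 3
  g <- sm[, 2:nd, ] - sm[, 1:(nd - 1), ]            # gradient between y and y+1
  gm <- matrix(aperm(g, c(2, 1, 3)), nrow = nd - 1) # one column per A-scan
  peak <- apply(gm, 2, max)
  if (stats::median(peak) < 0.1 * rng)
    stop("surface not found: depth gradients too weak to locate the ILM")
  lat_x <- dim(st)[1]; lat_z <- dim(st)[3]
  ilm_idx <- max.col(t(gm), ties.method = "first")
  # restrict the falling-edge search to below the ILM
  min_sep <- max(2L, as.integer(round(min_separation * nd)))
  gneg <- -gm
  row_idx <- matrix(seq_len(nd - 1), nd - 1, ncol(gm))
  gneg[row_idx <= rep(ilm_idx + min_sep, each = nd - 1)] <- -Inf
  rpe_idx <- max.col(t(gneg), ties.method = "first")
  ilm <- median_filter3(matrix(ilm_idx + 0.5, lat_x, lat_z))
  rpe <- median_filter3(matrix(rpe_idx + 0.5, lat_x, lat_z))
  bad <- rpe <= ilm
  if (any(bad)) rpe[bad] <- ilm[bad] + min_sep
  list(ilm = ilm, rpe = rpe)
}

#' Flatten the ILM and resample the retinal band to a fixed depth
#'
#' Shifts each A-scan so the ILM sits at depth index 1 and linearly resamples
#' the `[ILM, RPE]` band to `d_target` depth samples; the lateral extent is
#' unchanged.
#'
#' @param raw An `octa_raw_volume` or rank-4 array.
#' @param ilm,rpe Surface maps from [segment_surfaces()] (or generator ground
#'   truth).
#' @param d_target Number of output depth samples (nominally 224).
#' @return An `octa_volume` with `data` of shape
#'   `(x, d_target, z, channels)`.
#' @export
flatten_and_crop <- function(raw, ilm, rpe, d_target) {
  a <- vol_data(raw)
  stopifnot(length(dim(a)) == 4)
  if (!is.numeric(d_target) || d_target < 2)
    stop("'d_target' must be at least 2")
  d_target <- as.integer(d_target)
  d <- dim(a)
  lat_x <- d[1]; nd <- d[2]; lat_z <- d[3]; nc <- d[4]
  stopifnot(all(dim(ilm) == c(lat_x, lat_z)), all(dim(rpe) == c(lat_x, lat_z)))
  frac <- (seq_len(d_target) - 1) / (d_target - 1)
  # sampling depth for every (x, j, z): ilm + (rpe - ilm) * frac[j]
  ilm_a <- aperm(array(ilm, c(lat_x, lat_z, d_target)), c(1, 3, 2))
  th_a <- aperm(array(rpe - ilm, c(lat_x, lat_z, d_target)), c(1, 3, 2))
  yq <- ilm_a + th_a * array(rep(frac, each = lat_x), c(lat_x, d_target, lat_z))
  y0 <- pmin(pmax(floor(yq), 1), nd - 1)
  w <- pmin(pmax(yq - y0, 0), 1)
  xi <- array(rep(seq_len(lat_x), d_target * lat_z), c(lat_x, d_target, lat_z))
  zi <- aperm(array(rep(seq_len(lat_z), each = lat_x * d_target),
                    c(lat_x, d_target, lat_z)), c(1, 2, 3))
  out <- array(0, c(lat_x, d_target, lat_z, nc))
  base <- (xi - 1) + lat_x * ((y0 - 1) + nd * (zi - 1))
  for (ch in seq_len(nc)) {
    av <- a[, , , ch]
    lin <- as.vector(base) + 1
    v0 <- av[lin]
    v1 <- av[lin + lat_x]
    out[, , , ch] <- array((1 - as.vector(w)) * v0 + as.vector(w) * v1,
                           c(lat_x, d_target, lat_z))
  }
  structure(list(data = out,
                 acquisition = if (inherits(raw, "octa_raw_volume")) raw$acquisition else NA_character_,
                 d_target = d_target),
            class = "octa_volume")
}

#' Segment, flatten and resample a raw volume in one step
#'
#' @param raw An `octa_raw_volume`.
#' @param d_target Output depth; defaults to the nominal 224 scaled by the
#'   volume's scale factor.
#' @param use_truth Use the generator's ground-truth surfaces instead of
#'   re-estimating them (testing aid).
#' @return An `octa_volume`.
#' @export
preprocess_volume <- function(raw, d_target = NULL, use_truth = FALSE) {
  stopifnot(inherits(raw, "octa_raw_volume"))
  d_target <- d_target %||% max(8L, as.integer(round(NOMINAL_DEPTH_TARGET * raw$scale)))
  surf <- if (use_truth) list(ilm = raw$ilm, rpe = raw$rpe) else segment_surfaces(raw)
  v <- flatten_and_crop(raw, surf$ilm, surf$rpe, d_target)
  v$grade <- raw$grade
  v
}

#' Preprocess every volume of a cohort
#'
#' Replaces each record's raw volumes by flattened, depth-resampled volumes
#' (raw data are dropped, which keeps large cohorts in memory).
#'
#' @param cohort List of `octa_eye_record`s.
#' @param d_target Output depth (default: nominal 224 times the volume
#'   scale).
#' @param use_truth Use generator ground-truth surfaces.
#' @return List of records whose `volumes` are `octa_volume`s.
#' @export
preprocess_cohort <- function(cohort, d_target = NULL, use_truth = FALSE) {
  lapply(cohort, function(r) {
    r$volumes <- lapply(r$volumes, preprocess_volume, d_target = d_target,
                        use_truth = use_truth)
    r
  })
}

#' Trilinear volume resizing
#'
#' Resamples each channel to `out_shape` with trilinear interpolation
#' (align-corners grid mapping, so the identity shape returns the input and
#' constant volumes stay constant).
#'
#' @param v An `octa_volume` or rank-4 array.
#' @param out_shape Target spatial shape, length 3 (channels preserved) or 4
#'   (channel count must match).
#' @return A rank-4 array.
#' @export
resize_volume <- function(v, out_shape) {
  a <- vol_data(v)
  d <- dim(a)
  if (length(out_shape) == 4) {
    if (out_shape[4] != d[4]) stop("cannot resize the channel axis")
    out_shape <- out_shape[1:3]
  }
  stopifnot(length(out_shape) == 3, all(out_shape >= 1))
  os <- as.integer(out_shape)
  coord <- function(n_out, n_in)
    if (n_out == 1) rep(1, 1) else 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  cx <- coord(os[1], d[1]); cy <- coord(os[2], d[2]); cz <- coord(os[3], d[3])
  x0 <- pmin(floor(cx), d[1] - 1L); wx <- cx - x0
  y0 <- pmin(floor(cy), d[2] - 1L); wy <- cy - y0
  z0 <- pmin(floor(cz), d[3] - 1L); wz <- cz - z0
  if (d[1] == 1) { x0 <- rep(1, os[1]); wx <- rep(0, os[1]) }
  if (d[2] == 1) { y0 <- rep(1, os[2]); wy <- rep(0, os[2]) }
  if (d[3] == 1) { z0 <- rep(1, os[3]); wz <- rep(0, os[3]) }
  out <- array(0, c(os, d[4]))
  X0 <- array(rep(x0, os[2] * os[3]), os)
  WX <- array(rep(wx, os[2] * os[3]), os)
  Y0 <- array(rep(rep(y0, each = os[1]), os[3]), os)
  WY <- array(rep(rep(wy, each = os[1]), os[3]), os)
  Z0 <- array(rep(z0, each = os[1] * os[2]), os)
  WZ <- array(rep(wz, each = os[1] * os[2]), os)
  for (ch in seq_len(d[4])) {
    av <- a[, , , ch]
    idx <- function(xs, ys, zs) av[cbind(as.vector(xs), as.vector(ys), as.vector(zs))]
    v000 <- idx(X0, Y0, Z0);         v100 <- idx(X0 + (d[1] > 1), Y0, Z0)
    v010 <- idx(X0, Y0 + (d[2] > 1), Z0); v110 <- idx(X0 + (d[1] > 1), Y0 + (d[2] > 1), Z0)
    v001 <- idx(X0, Y0, Z0 + (d[3] > 1)); v101 <- idx(X0 + (d[1] > 1), Y0, Z0 + (d[3] > 1))
    v011 <- idx(X0, Y0 + (d[2] > 1), Z0 + (d[3] > 1))
    v111 <- idx(X0 + (d[1] > 1), Y0 + (d[2] > 1), Z0 + (d[3] > 1))
    wxv <- as.vector(WX); wyv <- as.vector(WY); wzv <- as.vector(WZ)
    res <- (1 - wzv) * ((1 - wyv) * ((1 - wxv) * v000 + wxv * v100) +
                        wyv * ((1 - wxv) * v010 + wxv * v110)) +
           wzv * ((1 - wyv) * ((1 - wxv) * v001 + wxv * v101) +
                  wyv * ((1 - wxv) * v011 + wxv * v111))
    out[, , , ch] <- array(res, os)
  }
  out
}

check_patch_shape <- function(d, patch_shape) {
  if (length(patch_shape) == 3) patch_shape <- c(patch_shape, d[4])
  stopifnot(length(patch_shape) == 4)
  if (any(patch_shape < 1)) stop("patch dimensions must be positive")
  as.integer(patch_shape)
}

# Symmetric zero-padding so that every axis is at least the patch size.
pad_to_patch <- function(a, patch) {
  d <- dim(a)
  if (all(d >= patch)) return(a)
  nd <- pmax(d, patch)
  out <- array(0, nd)
  off <- (nd - d) %/% 2
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
      off[3] + seq_len(d[3]), off[4] + seq_len(d[4])] <- a
  out
}

make_patch <- function(a, origin, patch) {
  data <- a[origin[1] + seq_len(patch[1]), origin[2] + seq_len(patch[2]),
            origin[3] + seq_len(patch[3]), origin[4] + seq_len(patch[4]),
            drop = FALSE]
  structure(list(origin = as.integer(origin), size = patch, data = data),
            class = "octa_patch")
}

#' Deterministic center crop
#'
#' Origin is `floor((dim - patch) / 2)` on every axis (0-based). Volumes
#' smaller than the patch are first zero-padded symmetrically.
#'
#' @param v An `octa_volume` or rank-4 array.
#' @param patch_shape Length-3 (spatial) or length-4 patch shape.
#' @return An `octa_patch` with 0-based `origin`, `size` and `data`.
#' @export
center_crop <- function(v, patch_shape) {
  a <- vol_data(v)
  patch <- check_patch_shape(dim(a), patch_shape)
  a <- pad_to_patch(a, patch)
  origin <- (dim(a) - patch) %/% 2
  make_patch(a, origin, patch)
}

#' Uniform random crop
#'
#' The origin is uniform over all in-bounds positions on each axis (using the
#' session RNG). Volumes smaller than the patch are zero-padded first.
#'
#' @inheritParams center_crop
#' @return An `octa_patch`.
#' @export
random_crop <- function(v, patch_shape) {
  a <- vol_data(v)
  patch <- check_patch_shape(dim(a), patch_shape)
  a <- pad_to_patch(a, patch)
  d <- dim(a)
  origin <- vapply(seq_len(4), function(i)
    if (d[i] == patch[i]) 0L else sample.int(d[i] - patch[i] + 1L, 1L) - 1L,
    integer(1))
  make_patch(a, origin, patch)
}

grid_starts <- function(n, p) {
  s <- seq(0L, n - p, by = p)
  if (s[length(s)] != n - p) s <- c(s, n - p)
  s
}

#' Non-overlapping subvolume grid
#'
#' Tiles the volume with patch-sized windows at stride = patch size, the last
#' window on each axis clamped flush to the boundary, so every voxel is
#' covered and the number of patches equals [traversal_patch_count()].
#'
#' @inheritParams center_crop
#' @return List of `octa_patch`es.
#' @export
subvolume_grid <- function(v, patch_shape) {
  a <- vol_data(v)
  patch <- check_patch_shape(dim(a), patch_shape)
  a <- pad_to_patch(a, patch)
  d <- dim(a)
  starts <- lapply(seq_len(4), function(i) grid_starts(d[i], patch[i]))
  out <- list()
  for (c0 in starts[[4]]) for (z0 in starts[[3]]) for (y0 in starts[[2]])
    for (x0 in starts[[1]])
      out[[length(out) + 1L]] <- make_patch(a, c(x0, y0, z0, c0), patch)
  out
}

#' Number of patches needed to traverse a volume
#'
#' The product over all four axes of `ceiling(volume_dim / patch_dim)`; with
#' the nominal shapes this gives 9 patches for the 500x224x500x2
#' high-resolution volume and 16 for the 834x224x834x2 widefield volume
#' under a 224x224x224x2 window.
#'
#' @param volume_shape,patch_shape Length-4 integer shapes.
#' @return Integer patch count.
#' @examples
#' traversal_patch_count(c(500, 224, 500, 2), c(224, 224, 224, 2))  # 9
#' traversal_patch_count(c(834, 224, 834, 2), c(224, 224, 224, 2))  # 16
#' @export
traversal_patch_count <- function(volume_shape, patch_shape) {
  stopifnot(length(volume_shape) == 4, length(patch_shape) == 4,
            all(volume_shape > 0))
  if (any(patch_shape <= 0)) stop("patch dimensions must be positive")
  as.integer(prod(ceiling(volume_shape / patch_shape)))
}

#' @export
print.octa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<octa_volume> %s, %d x %d x %d x %d (ILM-flattened)\n",
              x$acquisition, d[1], d[2], d[3], d[4]))
  invisible(x)
}
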
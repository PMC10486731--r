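# Surface segmentation, flattening, resizing and the cropping strategies.

test_that("traversal patch counts follow the ceiling arithmetic", {
  expect_equal(traversal_patch_count(c(500, 224, 500, 2), c(224, 224, 224, 2)), 9)
  expect_equal(traversal_patch_count(c(834, 224, 834, 2), c(224, 224, 224, 2)), 16)
  expect_equal(traversal_patch_count(c(224, 224, 224, 2), c(224, 224, 224, 2)), 1)
  expect_equal(traversal_patch_count(c(450, 10, 450, 2), c(224, 10, 224, 2)), 9)
  expect_error(traversal_patch_count(c(10, 10, 10, 2), c(0, 10, 10, 2)),
               "positive")
})

test_that("center crop origin is floor((dim - patch)/2) on every axis", {
  v <- tiny_volume(c(10, 10, 10, 2))
  p <- center_crop(v, c(4, 4, 4, 2))
  expect_equal(p$origin, c(3L, 3L, 3L, 0L))
  expect_identical(p$data, v[4:7, 4:7, 4:7, , drop = FALSE])
  whole <- center_crop(v, dim(v))
  expect_identical(whole$data, v)
  expect_equal(whole$origin, rep(0L, 4))
  for (dims in list(c(9, 6, 11, 2), c(8, 5, 7, 1))) {
    a <- tiny_volume(dims, seed = sum(dims))
    patch <- c(4, 3, 5, dims[4])
    got <- center_crop(a, patch)
    expect_equal(got$origin[1:3], (dims[1:3] - patch[1:3]) %/% 2)
  }
})

test_that("center crop pads volumes smaller than the patch", {
  v <- tiny_volume(c(4, 3, 4, 2))
  p <- center_crop(v, c(6, 6, 6, 2))
  expect_equal(dim(p$data), c(6, 6, 6, 2))
  expect_equal(sum(p$data != 0), sum(v != 0))
})

test_that("random crop is uniform over valid origins and in bounds", {
  v <- tiny_volume(c(10, 10, 10, 2))
  set.seed(99)
  origins <- t(replicate(10000, random_crop(v, c(4, 4, 4, 2))$origin[1:3]))
  expect_true(all(origins >= 0) && all(origins <= 6))
  for (ax in 1:3) {
    tab <- tabulate(origins[, ax] + 1L, 7)
    expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  }
  set.seed(5)
  o1 <- replicate(5, random_crop(v, c(4, 4, 4, 2))$origin)
  set.seed(5)
  o2 <- replicate(5, random_crop(v, c(4, 4, 4, 2))$origin)
  expect_identical(o1, o2)
  expect_equal(random_crop(v, dim(v))$origin, rep(0L, 4))
})

test_that("subvolume grid covers every voxel with the predicted patch count", {
  for (dims in list(c(30, 13, 30, 2), c(50, 13, 50, 2), c(13, 13, 13, 2))) {
    v <- array(1, dims)
    patch <- c(13, 13, 13, 2)
    grid <- subvolume_grid(v, patch)
    expect_length(grid, traversal_patch_count(dims, patch))
    cover <- array(0, dims)
    for (g in grid) {
      idx <- Map(function(o, s) o + seq_len(s), as.list(g$origin), as.list(g$size))
      cover[idx[[1]], idx[[2]], idx[[3]], idx[[4]]] <-
        cover[idx[[1]], idx[[2]], idx[[3]], idx[[4]]] + 1
    }
    expect_true(all(cover >= 1))
  }
  one <- subvolume_grid(tiny_volume(c(8, 8, 8, 2)), c(8, 8, 8, 2))
  expect_length(one, 1)
  expect_equal(one[[1]]$origin, rep(0L, 4))
})

test_that("trilinear resize preserves identity, constants and the shape map", {
  v <- tiny_volume(c(7, 6, 5, 2))
  expect_equal(max(abs(resize_volume(v, dim(v)) - v)), 0)
  const <- array(0.42, c(9, 4, 7, 2))
  out <- resize_volume(const, c(5, 8, 3))
  expect_equal(dim(out), c(5, 8, 3, 2))
  expect_true(all(abs(out - 0.42) < 1e-12))
  # downscaled analogue of the nominal widefield compression
  big <- array(runif(84 * 23 * 84 * 2), c(84, 23, 84, 2))
  expect_equal(dim(resize_volume(big, c(23, 23, 23, 2))), c(23, 23, 23, 2))
  expect_error(resize_volume(v, c(5, 5, 5, 3)), "channel")
})

test_that("trilinear resize matches a brute-force oracle", {
  set.seed(8)
  a <- array(runif(4 * 3 * 5 * 1), c(4, 3, 5, 1))
  os <- c(7, 5, 4)
  out <- resize_volume(a, os)
  cg <- function(n_out, n_in) if (n_out == 1) 1 else
    1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  cx <- cg(os[1], 4); cy <- cg(os[2], 3); cz <- cg(os[3], 5)
  for (i in seq_len(os[1])) for (j in seq_len(os[2])) for (k in seq_len(os[3])) {
    x0 <- min(floor(cx[i]), 3); y0 <- min(floor(cy[j]), 2); z0 <- min(floor(cz[k]), 4)
    wx <- cx[i] - x0; wy <- cy[j] - y0; wz <- cz[k] - z0
    acc <- 0
    for (dx in 0:1) for (dyy in 0:1) for (dz in 0:1)
      acc <- acc + a[x0 + dx, y0 + dyy, z0 + dz, 1] *
        (if (dx) wx else 1 - wx) * (if (dyy) wy else 1 - wy) * (if (dz) wz else 1 - wz)
    expect_equal(out[i, j, k, 1], acc, tolerance = 1e-12)
  }
})

test_that("surface estimates stay within 2 voxels of ground truth", {
  set.seed(21)
  for (g in c(0L, 4L)) {
    latent <- octafusion:::eye_latent(g)
    v <- generate_raw_volume("hr6", g, scale = 0.1, latent = latent)
    surf <- segment_surfaces(v)
    expect_lte(mean(abs(surf$ilm - v$ilm)), 2)
    expect_lte(mean(abs(surf$rpe - v$rpe)), 2)
  }
})

test_that("flat-surface volumes give a constant ILM map", {
  set.seed(22)
  v <- generate_raw_volume("hr6", 0, scale = 0.06, flat_surfaces = TRUE,
                           noise_sd = 0)
  expect_equal(max(v$ilm) - min(v$ilm), 0)
  surf <- segment_surfaces(v)
  expect_equal(max(surf$ilm) - min(surf$ilm), 0)
})

test_that("degenerate volumes raise a surface-not-found error", {
  zero <- array(0, c(8, 20, 8, 2))
  expect_error(segment_surfaces(zero), "surface not found")
  flatline <- array(0.5, c(8, 20, 8, 2))
  expect_error(segment_surfaces(flatline), "surface not found")
})

test_that("flattening fixes the ILM at the first depth sample", {
  set.seed(23)
  v <- generate_raw_volume("hr6", 1, scale = 0.1)
  flat <- flatten_and_crop(v, v$ilm, v$rpe, d_target = 22)
  expect_equal(dim(flat$data), c(50, 22, 50, 2))
  # the first depth sample is taken exactly at the ILM of every A-scan:
  # compare against per-column linear interpolation (independent oracle)
  for (xz in list(c(1, 1), c(25, 40), c(50, 50), c(13, 31))) {
    x <- xz[1]; z <- xz[2]
    want <- approx(seq_len(dim(v$data)[2]), v$data[x, , z, 1],
                   xout = v$ilm[x, z])$y
    expect_equal(flat$data[x, 1, z, 1], want, tolerance = 1e-12)
  }
  # re-embed under synthetic vitreous and re-extract the surface: flat to
  # within the half-voxel quantization of the gradient detector
  d <- dim(flat$data)
  emb <- array(0.05, c(d[1], d[2] + 4, d[3], d[4]))
  emb[, 5:(d[2] + 4), , ] <- flat$data
  surf <- segment_surfaces(emb)
  expect_lte(max(surf$ilm) - min(surf$ilm), 1)
  expect_error(flatten_and_crop(v, v$ilm, v$rpe, d_target = 1), "at least 2")
})

test_that("flattening preserves an already-flat, correctly-sized band", {
  # band exactly d_target deep with flat surfaces passes through unchanged
  nd <- 40
  lat <- 8
  d_target <- 11
  a <- array(0, c(lat, nd, lat, 1))
  ilm <- matrix(10, lat, lat)
  rpe <- ilm + d_target - 1
  band_vals <- seq(0.1, 0.9, length.out = d_target)
  for (j in seq_len(d_target)) a[, 10 + j - 1, , 1] <- band_vals[j]
  flat <- flatten_and_crop(a, ilm, rpe, d_target)
  for (j in seq_len(d_target))
    expect_equal(unname(flat$data[1, j, 1, 1]), band_vals[j], tolerance = 1e-12)
})

test_that("quarter-scale raw volumes flatten to the 56-sample band", {
  set.seed(24)
  v <- generate_raw_volume("hr6", 0, scale = 0.25)
  expect_equal(dim(v$data), c(125, 384, 125, 2))
  out <- preprocess_volume(v, d_target = 56, use_truth = TRUE)
  expect_equal(dim(out$data), c(125, 56, 125, 2))
})
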
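# Synthetic OCTA cohort generator.
#
# Stands in for private clinical data: each eye gets a latent "physical"
# description in millimetres relative to the fovea (curved inner/outer
# retinal surfaces, a vascular texture, severity-dependent lesions), which is
# then rendered onto the voxel grid of each requested acquisition. Small
# central flow voids (grades >= 1) sit inside the high-resolution 6x6 mm
# field and are rendered at much lower contrast on the widefield grid
# (resolution loss); large peripheral non-perfusion patches (grades >= 3) sit
# outside the 6x6 mm field and are therefore only visible in the 15x15 mm
# acquisition. This encodes the clinical complementarity of the two
# acquisitions: early disease is a high-resolution signal, advanced disease a
# widefield one.

# counts of lesions injected per grade 0..5
central_lesion_count <- function(grade) c(0L, 2L, 4L, 4L, 4L, 4L)[grade + 1L]
peripheral_lesion_count <- function(grade) c(0L, 0L, 0L, 2L, 4L, 6L)[grade + 1L]

#' Describe a synthetic cohort
#'
#' @param n_patients Number of patients.
#' @param p_both_eyes Probability that a patient contributes both eyes.
#' @param p_both_acquisitions Probability that an eye has both the
#'   high-resolution (`hr6`) and ultra-widefield (`uwf15`) acquisitions.
#' @param severity_distribution Probability vector over the six severity
#'   grades. The default mirrors the class imbalance of a clinical DR cohort
#'   (moderate NPDR dominating, PDR rare).
#' @param volume_scale Factor in (0, 1] shrinking the nominal lateral/depth
#'   sizes (nominal: 500 and 834 lateral pixels, 1536/3072 raw depth
#'   samples) for desk-scale use.
#' @param seed Integer seed; cohorts are byte-identical under a fixed spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, p_both_eyes = 0.9, p_both_acquisitions = 0.9,
                        severity_distribution = c(127, 68, 321, 97, 20, 43) / 676,
                        volume_scale = 0.25, seed = 1L) {
  stopifnot(n_patients >= 1, p_both_eyes >= 0, p_both_eyes <= 1,
            p_both_acquisitions >= 0, p_both_acquisitions <= 1,
            volume_scale > 0, volume_scale <= 1)
  if (length(severity_distribution) != 6 || any(severity_distribution < 0) ||
      abs(sum(severity_distribution) - 1) > 1e-8)
    stop("'severity_distribution' must be a 6-vector on the probability simplex")
  structure(list(n_patients = as.integer(n_patients), p_both_eyes = p_both_eyes,
                 p_both_acquisitions = p_both_acquisitions,
                 severity_distribution = severity_distribution,
                 volume_scale = volume_scale, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Smooth zero-mean random field on a lateral grid (mm coordinates), built
# from a few random cosine products; returns a matrix.
smooth_field <- function(x_mm, z_mm, n_waves = 4, freq = c(0.15, 0.6)) {
  out <- matrix(0, length(x_mm), length(z_mm))
  for (i in seq_len(n_waves)) {
    fx <- runif(1, freq[1], freq[2]) * 2 * pi
    fz <- runif(1, freq[1], freq[2]) * 2 * pi
    px <- runif(1, 0, 2 * pi)
    pz <- runif(1, 0, 2 * pi)
    a <- rnorm(1, sd = 1 / sqrt(n_waves))
    out <- out + a * outer(cos(fx * x_mm + px), cos(fz * z_mm + pz))
  }
  out
}

# Latent description of one eye, independent of acquisition/grid.
eye_latent <- function(grade) {
  nc <- central_lesion_count(grade)
  np <- peripheral_lesion_count(grade)
  central <- if (nc > 0) {
    r <- runif(nc, 0, 1.5)        # inside the central 3 mm disc
    th <- runif(nc, 0, 2 * pi)
    data.frame(x = r * cos(th), z = r * sin(th),
               radius = runif(nc, 0.35, 0.55))
  } else NULL
  peripheral <- if (np > 0) {
    rad <- runif(np, 1.2, 2.0)
    # entire (truncated) footprint outside the jittered 6x6 mm field
    r <- runif(np, 3.5 + 1.5 * rad, 6.8)
    th <- runif(np, 0, 2 * pi)
    data.frame(x = r * cos(th), z = r * sin(th), radius = rad)
  } else NULL
  list(grade = grade, central = central, peripheral = peripheral,
       surface_seed = sample.int(.Machine$integer.max, 1L),
       vessel_seed = sample.int(.Machine$integer.max, 1L))
}

# Multiplicative flow deficit (0 = untouched) and ground-truth masks for a
# lesion table rendered on a lateral grid.
lesion_deficit <- function(lesions, x_mm, z_mm, amplitude) {
  lat_x <- length(x_mm)
  lat_z <- length(z_mm)
  deficit <- matrix(0, lat_x, lat_z)
  mask <- matrix(FALSE, lat_x, lat_z)
  if (is.null(lesions) || amplitude <= 0) return(list(deficit = deficit, mask = mask))
  for (i in seq_len(nrow(lesions))) {
    d2 <- outer((x_mm - lesions$x[i])^2, rep(1, lat_z)) +
      outer(rep(1, lat_x), (z_mm - lesions$z[i])^2)
    prof <- exp(-d2 / (2 * lesions$radius[i]^2))
    prof[d2 > (1.5 * lesions$radius[i])^2] <- 0   # compact support
    deficit <- pmax(deficit, amplitude * prof)
    mask <- mask | (prof > 0.5)
  }
  list(deficit = deficit, mask = mask)
}

#' Generate one raw synthetic OCTA volume
#'
#' Renders a rank-4 raw volume `(x, depth, z, channel)` with channels
#' `[structure, flow]`, curved ILM/RPE surfaces embedded in raw depth, a
#' layered structural profile, a filamentous flow texture, and
#' severity-dependent lesions. Uses the current RNG state; seed the session
#' (or use [generate_cohort()]) for reproducibility.
#'
#' @param acquisition `"hr6"` (6x6 mm high resolution) or `"uwf15"`
#'   (15x15 mm ultra widefield).
#' @param grade Severity grade 0..5.
#' @param scale Size factor in (0, 1] applied to the nominal grid.
#' @param latent Optional latent eye from a previous call, so the two
#'   acquisitions of one eye render the same underlying retina. Generated
#'   when `NULL`.
#' @param jitter_mm Lateral registration jitter range (acquisitions of one
#'   eye are deliberately unregistered).
#' @param flat_surfaces If `TRUE`, disables surface curvature (testing aid).
#' @param noise_sd Standard deviation of the additive Gaussian sensor noise.
#' @return An `octa_raw_volume`: list with `data` (rank-4 array in `[0, 1]`),
#'   `acquisition`, `grade`, ground-truth `ilm`/`rpe` surface maps
#'   (continuous 1-based depth positions per lateral location) and en-face
#'   `lesions$central`/`lesions$peripheral` masks.
#' @export
generate_raw_volume <- function(acquisition = c("hr6", "uwf15"), grade, scale = 0.25,
                                latent = NULL, jitter_mm = 0.3,
                                flat_surfaces = FALSE, noise_sd = 0.02) {
  acquisition <- match.arg(acquisition)
  grade <- validate_grade(grade)
  stopifnot(scale > 0, scale <= 1)
  if (is.null(latent)) latent <- eye_latent(grade)
  geom <- acq_geometry(acquisition)
  lat <- max(8L, as.integer(round(geom$lateral * scale)))
  nd <- max(16L, as.integer(round(geom$raw_depth * scale)))
  px_per_mm <- lat / geom$fov_mm
  jit <- runif(2, -jitter_mm, jitter_mm)
  x_mm <- (seq_len(lat) - (lat + 1) / 2) / px_per_mm + jit[1]
  z_mm <- (seq_len(lat) - (lat + 1) / 2) / px_per_mm + jit[2]

  # surfaces (continuous depth voxel positions, 1-based)
  rng_state <- .Random.seed
  set.seed(latent$surface_seed)
  f1 <- smooth_field(x_mm, z_mm)
  f2 <- smooth_field(x_mm, z_mm)
  assign(".Random.seed", rng_state, envir = globalenv())
  if (flat_surfaces) { f1[] <- 0; f2[] <- 0 }
  r2 <- outer(x_mm^2, rep(1, lat)) + outer(rep(1, lat), z_mm^2)
  bowl <- if (flat_surfaces) 0 else 0.10 * r2 / (7.5^2)
  ilm <- nd * (0.20 + bowl + 0.04 * f1)
  thick <- nd * (0.24 + 0.03 * f2)
  ilm <- pmin(pmax(ilm, 2), nd * 0.55)
  rpe <- pmin(ilm + pmax(thick, nd * 0.12), nd - 2)

  # relative depth within the retinal band, per voxel
  y_arr <- array(rep(seq_len(nd), each = lat), c(lat, nd, lat))
  ilm_arr <- aperm(array(ilm, c(lat, lat, nd)), c(1, 3, 2))
  th_arr <- aperm(array(rpe - ilm, c(lat, lat, nd)), c(1, 3, 2))
  rel <- (y_arr - ilm_arr) / th_arr

  # structure: vitreous / layered retina / bright RPE band / choroid decay
  st <- array(0.05, dim(rel))
  inner <- rel >= 0 & rel < 0.8
  st[inner] <- 0.55 + 0.12 * cos(2 * pi * 3 * rel[inner])
  band_rpe <- rel >= 0.8 & rel <= 1
  st[band_rpe] <- 0.95
  below <- rel > 1
  st[below] <- 0.15 * exp(-(rel[below] - 1) * 6)

  # flow: filamentous vessel texture in the inner vascular band
  set.seed(latent$vessel_seed)
  g <- smooth_field(x_mm, z_mm, n_waves = 8, freq = c(0.6, 2.0))
  assign(".Random.seed", rng_state, envir = globalenv())
  g <- g / max(stats::sd(g), 1e-9)
  vessels <- exp(-(g / 0.35)^2)
  flow_en <- 0.30 + 0.55 * vessels

  # severity-dependent lesions; contrast differs by acquisition
  amp_central <- if (acquisition == "hr6") 0.9 else 0.3
  les_c <- lesion_deficit(latent$central, x_mm, z_mm, amp_central)
  les_p <- lesion_deficit(latent$peripheral, x_mm, z_mm, 0.85)
  deficit <- pmax(les_c$deficit, les_p$deficit)
  flow_en <- flow_en * (1 - deficit)

  fl_arr <- aperm(array(flow_en, c(lat, lat, nd)), c(1, 3, 2))
  band_fl <- exp(-((rel - 0.25) / 0.15)^2)
  fl <- 0.04 + fl_arr * band_fl

  # matched structural dimming inside lesions
  dim_arr <- aperm(array(1 - 0.3 * deficit, c(lat, lat, nd)), c(1, 3, 2))
  st <- ifelse(rel >= 0 & rel <= 1, st * dim_arr, st)

  n <- length(st)
  data <- array(0, c(lat, nd, lat, 2L))
  data[, , , 1] <- if (noise_sd > 0) clamp01(st + rnorm(n, sd = noise_sd)) else clamp01(st)
  data[, , , 2] <- if (noise_sd > 0) clamp01(fl + rnorm(n, sd = noise_sd)) else clamp01(fl)

  structure(list(data = data, acquisition = acquisition, grade = grade,
                 ilm = ilm, rpe = rpe,
                 lesions = list(central = les_c$mask, peripheral = les_p$mask),
                 px_per_mm = px_per_mm, scale = scale, jitter_mm = jit,
                 latent = latent),
            class = "octa_raw_volume")
}

#' Generate one synthetic eye record
#'
#' @param grade Severity grade 0..5.
#' @param acquisitions Character subset of `c("hr6", "uwf15")`.
#' @param scale Size factor passed to [generate_raw_volume()].
#' @param patient_id,laterality Identifiers stored on the record.
#' @return An `octa_eye_record`: list with `patient_id`, `laterality`
#'   (`"OD"`/`"OS"`), `grade` and `volumes` (named list of raw volumes).
#' @export
generate_eye_record <- function(grade, acquisitions = c("hr6", "uwf15"),
                                scale = 0.25, patient_id = "P0001",
                                laterality = "OD") {
  grade <- validate_grade(grade)
  stopifnot(all(acquisitions %in% c("hr6", "uwf15")), length(acquisitions) >= 1)
  latent <- eye_latent(grade)
  volumes <- lapply(acquisitions, function(a)
    generate_raw_volume(a, grade, scale = scale, latent = latent))
  names(volumes) <- acquisitions
  structure(list(patient_id = patient_id, laterality = laterality,
                 grade = grade, volumes = volumes),
            class = "octa_eye_record")
}

#' Generate a seeded synthetic cohort
#'
#' Draws patients, eyes (1-2 per patient), acquisitions (1-2 per eye) and
#' severity grades according to the cohort spec, and renders every volume.
#' Identical specs produce byte-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param render Render the volumes (`FALSE` returns records with empty
#'   volume stubs, useful for split/manifest logic on large cohorts).
#' @return List of `octa_eye_record`s.
#' @examples
#' cohort <- generate_cohort(cohort_spec(2, volume_scale = 0.05, seed = 7))
#' cohort_manifest(cohort)
#' @export
generate_cohort <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  records <- list()
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%04d", i)
    both_eyes <- runif(1) < spec$p_both_eyes
    lats <- if (both_eyes) c("OD", "OS") else sample(c("OD", "OS"), 1)
    for (lt in lats) {
      grade <- sample(0:5, 1, prob = spec$severity_distribution)
      both_acq <- runif(1) < spec$p_both_acquisitions
      acqs <- if (both_acq) c("hr6", "uwf15") else sample(c("hr6", "uwf15"), 1)
      records[[length(records) + 1L]] <- if (render) {
        generate_eye_record(grade, acqs, scale = spec$volume_scale,
                            patient_id = pid, laterality = lt)
      } else {
        structure(list(patient_id = pid, laterality = lt, grade = grade,
                       volumes = stats::setNames(rep(list(list()), length(acqs)),
                                                 acqs)),
                  class = "octa_eye_record")
      }
    }
  }
  records
}

#' Generate a deliberately separable two-grade toy cohort
#'
#' A convergence smoke-test fixture: healthy eyes against eyes carrying many
#' large, strong flow voids spread over the field, so that (nearly) every
#' training crop carries the lesion signal and the two grades are separable
#' from single crops.
#'
#' @param n_eyes Number of eyes (grades alternate).
#' @param acquisition Which acquisition to render.
#' @param grades Two grades, the healthy one first.
#' @param scale Size factor as in [generate_raw_volume()].
#' @param seed Integer seed.
#' @return List of single-acquisition `octa_eye_record`s.
#' @export
generate_toy_cohort <- function(n_eyes = 20, acquisition = "hr6",
                                grades = c(0L, 2L), scale = 0.06, seed = 1L) {
  stopifnot(length(grades) == 2)
  set.seed(seed)
  lapply(seq_len(n_eyes), function(i) {
    g <- grades[(i - 1L) %% 2L + 1L]
    latent <- eye_latent(0L)
    if (g != grades[1]) {
      n <- 6L
      r <- runif(n, 0, 2.2)
      th <- runif(n, 0, 2 * pi)
      latent$central <- data.frame(x = r * cos(th), z = r * sin(th),
                                   radius = runif(n, 0.8, 1.2))
    }
    vol <- generate_raw_volume(acquisition, g, scale = scale, latent = latent)
    structure(list(patient_id = sprintf("T%04d", i), laterality = "OD",
                   grade = as.integer(g),
                   volumes = stats::setNames(list(vol), acquisition)),
              class = "octa_eye_record")
  })
}

#' Tabulate a cohort as a manifest tibble
#'
#' @param cohort List of eye records (raw or preprocessed).
#' @return Tibble with one row per (eye, acquisition): `patient_id`, `eye`,
#'   `acquisition`, `grade`.
#' @export
cohort_manifest <- function(cohort) {
  rows <- lapply(cohort, function(r) {
    tibble::tibble(patient_id = r$patient_id, eye = r$laterality,
                   acquisition = names(r$volumes), grade = r$grade)
  })
  do.call(rbind, rows)
}

#' @export
print.octa_raw_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<octa_raw_volume> %s grade %d, %d x %d x %d x %d\n",
              x$acquisition, x$grade, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' @export
print.octa_eye_record <- function(x, ...) {
  cat(sprintf("<octa_eye_record> %s %s grade %d [%s]\n", x$patient_id,
              x$laterality, x$grade, paste(names(x$volumes), collapse = ", ")))
  invisible(x)
}
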
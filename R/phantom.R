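# Synthetic head phantoms. Each subject is an ellipsoidal head containing
# two mirrored lateral-ventricle ellipsoids that enlarge with age, and a
# bilateral plexus-like curved tube hugging the posterior-medial ventricular
# wall whose volume follows a linear lifespan model
#   V = beta0 + beta_age * age + beta_male * 1[male] + eps,  eps ~ N(0, sigma^2)
# truncated below at a minimum volume. Modality-specific tissue intensities,
# a smooth multiplicative bias field, additive Gaussian noise and a rigid
# "native-space" jitter per subject complete the picture. Structure sizes
# are specified as fractions of the grid half-extent, so the same parameter
# set scales from small test grids to the 96^3 default.

#' Parameters of the phantom cohort generator
#'
#' @param grid_shape common-space grid (voxels), default `c(96, 96, 96)`.
#' @param spacing voxel spacing in mm, default 1 mm isotropic.
#' @param head_frac head ellipsoid semi-axes as fractions of the grid
#'   half-extent (x = left-right, y = anterior-posterior, z =
#'   inferior-superior).
#' @param vent_frac base (age 21) ventricle semi-axis fractions.
#' @param vent_offset_frac ventricle centre offset fractions; x is applied
#'   with both signs for the two hemispheres.
#' @param atrophy_rate fractional ventricular semi-axis growth per year of
#'   age beyond 21 (default 0.01/yr).
#' @param vol_beta0,vol_beta_age,vol_beta_male,vol_sigma plexus volume model
#'   in cm^3: intercept, slope per year, male offset, residual SD. Defaults
#'   `(0.62, 0.047, 0.30, 0.40)` put the cohort mean near 3.2 cm^3 over ages
#'   21-89 with a 0.047 cm^3/yr lifespan slope.
#' @param min_volume_cm3 lower truncation of the drawn target volume.
#' @param intensities 3x4 matrix (rows `t1`,`t2`,`flair`; columns
#'   `parenchyma`,`csf`,`plexus`,`background`). CSF is dark on T1/FLAIR and
#'   bright on T2; the plexus is brighter than CSF on FLAIR.
#' @param noise_sigma additive Gaussian noise SD.
#' @param bias_amplitude amplitude of the smooth low-order polynomial
#'   multiplicative bias field.
#' @param jitter_max_deg,jitter_max_mm limits of the rigid native-space
#'   jitter (per-axis rotation in degrees, translation in mm).
#' @param age_range modelled age range in years.
#' @param size_sd SD of the log-normal per-subject global size factor.
#' @return Object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(96, 96, 96),
                           spacing = c(1, 1, 1),
                           head_frac = c(0.82, 0.88, 0.76),
                           vent_frac = c(0.20, 0.41, 0.25),
                           vent_offset_frac = c(0.32, -0.05, 0.02),
                           atrophy_rate = 0.01,
                           vol_beta0 = 0.62,
                           vol_beta_age = 0.047,
                           vol_beta_male = 0.30,
                           vol_sigma = 0.40,
                           min_volume_cm3 = 0.5,
                           intensities = NULL,
                           noise_sigma = 0.03,
                           bias_amplitude = 0.1,
                           jitter_max_deg = 5,
                           jitter_max_mm = 3,
                           age_range = c(21, 89),
                           size_sd = 0.03) {
  if (is.null(intensities)) {
    intensities <- rbind(
      t1    = c(parenchyma = 0.60, csf = 0.15, plexus = 0.45, background = 0),
      t2    = c(parenchyma = 0.40, csf = 0.90, plexus = 0.60, background = 0),
      flair = c(parenchyma = 0.50, csf = 0.10, plexus = 0.70, background = 0))
  }
  p <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
            head_frac = head_frac, vent_frac = vent_frac,
            vent_offset_frac = vent_offset_frac, atrophy_rate = atrophy_rate,
            vol_beta0 = vol_beta0, vol_beta_age = vol_beta_age,
            vol_beta_male = vol_beta_male, vol_sigma = vol_sigma,
            min_volume_cm3 = min_volume_cm3, intensities = intensities,
            noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
            jitter_max_deg = jitter_max_deg, jitter_max_mm = jitter_max_mm,
            age_range = as.numeric(age_range), size_sd = size_sd)
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (length(p$grid_shape) != 3L || any(p$grid_shape < 16L)) {
    stopf("phantom grid must be 3-D with at least 16 voxels per axis")
  }
  gap <- abs(p$intensities[, "plexus"] - p$intensities[, "csf"])
  if (any(gap < 0.1)) {
    stopf("plexus/CSF intensity gap below 0.1 on: %s",
          paste(rownames(p$intensities)[gap < 0.1], collapse = ", "))
  }
  ages <- p$age_range
  ev <- p$vol_beta0 + p$vol_beta_age * ages
  if (any(ev <= 0)) stopf("plexus volume model is non-positive in age range")
  invisible(p)
}

# Ellipsoid indicator on the common grid; centre and semi-axes in mm.
ellipsoid_mask <- function(coords, center, semi) {
  ex <- ((coords$x - center[1]) / semi[1])^2
  ey <- ((coords$y - center[2]) / semi[2])^2
  ez <- ((coords$z - center[3]) / semi[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

grid_world_coords <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1 - (shape[1] - 1) / 2) * spacing[1],
       y = (seq_len(shape[2]) - 1 - (shape[2] - 1) / 2) * spacing[2],
       z = (seq_len(shape[3]) - 1 - (shape[3] - 1) / 2) * spacing[3])
}

# Sample points (mm) along one plexus-like arc hugging the posterior-medial
# wall of the ventricle on hemisphere `side` (+1 right, -1 left).
plexus_curve <- function(center, semi, side, n = 80) {
  theta <- seq(-1.15, 1.15, length.out = n)
  cbind(center[1] - side * 0.35 * semi[1],
        center[2] + 0.55 * semi[2] * sin(theta),
        center[3] + 0.55 * semi[3] * (cos(theta) - 0.15))
}

rigid_transform <- function(angles_deg, translation_mm) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  out <- diag(4)
  out[1:3, 1:3] <- Rz %*% Ry %*% Rx
  out[1:3, 4] <- translation_mm
  out
}

# Smooth multiplicative bias field: 1 + amplitude * (second-order polynomial
# in normalised coordinates, scaled to unit max absolute value).
bias_field <- function(shape, amplitude) {
  u <- seq(-1, 1, length.out = shape[1])
  v <- seq(-1, 1, length.out = shape[2])
  w <- seq(-1, 1, length.out = shape[3])
  cf <- runif(9, -1, 1)
  p <- outer(outer(cf[1] * u + cf[7] * u^2, cf[2] * v + cf[8] * v^2, "+"),
             cf[3] * w + cf[9] * w^2, "+") +
    outer(outer(cf[4] * u, v, "*"), rep(1, shape[3])) +
    outer(outer(cf[5] * u, rep(1, shape[2])), w) +
    outer(outer(rep(1, shape[1]), cf[6] * v), w)
  1 + amplitude * p / max(abs(p))
}

#' Generate one phantom subject
#'
#' Deterministic given `(params, age, sex, seed)`. Construction: head
#' ellipsoid; two mirrored ventricles scaled by `1 + atrophy_rate*(age-21)`;
#' a target plexus volume drawn from the linear lifespan model; a curved
#' tube per hemisphere whose radius is bisected until the rasterised volume
#' is within 5\% of target; modality intensities with bias field and noise;
#' and a rigid jitter defining the subject's native space.
#'
#' @param params [phantom_params()].
#' @param age age in years, inside `params$age_range`.
#' @param sex `"F"` or `"M"`.
#' @param seed integer seed.
#' @param detail `"full"` renders intensity volumes and native grids;
#'   `"masks"` stops after the common-space masks (for volumetry-only
#'   studies); `"metadata"` skips rasterisation entirely and reports the
#'   drawn target volume as achieved volume.
#' @param aniso_flair if `TRUE` the native FLAIR grid uses an anisotropic
#'   0.57 x 0.57 x 4.0 mm spacing.
#' @return Object of class `phantom_subject`: native-space contrast volumes
#'   (`$volumes`), common-space `truth_mask`/`ventricle_mask`/`head_mask`,
#'   native-space `truth_native`, the rigid `native_transform`
#'   (common world -> native world) and `$meta`.
#' @export
generate_subject <- function(params, age, sex = c("F", "M"), seed = 1L,
                             detail = c("full", "masks", "metadata"),
                             aniso_flair = FALSE) {
  sex <- match.arg(sex)
  detail <- match.arg(detail)
  if (age < params$age_range[1] || age > params$age_range[2]) {
    stopf("age %.1f outside modelled range [%g, %g]", age,
          params$age_range[1], params$age_range[2])
  }
  with_seed(seed, generate_subject_impl(params, age, sex, detail, aniso_flair))
}

generate_subject_impl <- function(params, age, sex, detail, aniso_flair) {
  shape <- params$grid_shape
  spacing <- params$spacing
  half_extent <- shape * spacing / 2
  vox_cm3 <- prod(spacing) / 1000

  size_factor <- exp(rnorm(1, 0, params$size_sd))
  target_volume <- params$vol_beta0 + params$vol_beta_age * age +
    params$vol_beta_male * (sex == "M") + rnorm(1, 0, params$vol_sigma)
  target_volume <- max(target_volume, params$min_volume_cm3)
  jitter_angles <- runif(3, -params$jitter_max_deg, params$jitter_max_deg)
  jitter_shift <- runif(3, -params$jitter_max_mm, params$jitter_max_mm)

  meta <- list(age = age, sex = sex, target_volume_cm3 = target_volume)
  native_transform <- rigid_transform(jitter_angles, jitter_shift)

  if (detail == "metadata") {
    meta$tiv_cm3 <- 4 / 3 * pi * prod(params$head_frac * half_extent) / 1000 *
      size_factor^3
    vent_scale <- 1 + params$atrophy_rate * (age - params$age_range[1])
    meta$lvv_cm3 <- 2 * 4 / 3 * pi *
      prod(params$vent_frac * half_extent * vent_scale) / 1000 * size_factor^3
    meta$achieved_volume_cm3 <- target_volume
    return(structure(list(volumes = NULL, truth_mask = NULL,
                          ventricle_mask = NULL, head_mask = NULL,
                          truth_native = NULL,
                          native_transform = native_transform, meta = meta,
                          grid_shape = shape, spacing = spacing),
                     class = "phantom_subject"))
  }

  coords <- grid_world_coords(shape, spacing)
  head_semi <- params$head_frac * half_extent * size_factor
  head <- ellipsoid_mask(coords, c(0, 0, 0), head_semi)

  vent_scale <- 1 + params$atrophy_rate * (age - params$age_range[1])
  vent_semi <- params$vent_frac * half_extent * vent_scale * size_factor
  vent_off <- params$vent_offset_frac * half_extent
  vent <- array(FALSE, shape)
  curves <- list()
  for (side in c(-1, 1)) {
    ctr <- c(side * vent_off[1], vent_off[2], vent_off[3])
    vent <- vent | ellipsoid_mask(coords, ctr, vent_semi)
    curves[[length(curves) + 1]] <- plexus_curve(ctr, vent_semi, side)
  }
  vent <- vent & head
  curve_pts <- do.call(rbind, curves)

  # distance from every ventricular voxel to the plexus arc; tube radius is
  # then bisected on this fixed field until the volume target is met
  vidx <- which(vent)
  ai <- arrayInd(vidx, shape)
  pts <- cbind(coords$x[ai[, 1]], coords$y[ai[, 2]], coords$z[ai[, 3]])
  dists <- nn_min_dists(pts, curve_pts)
  n_target <- target_volume / vox_cm3
  if (length(vidx) < 0.95 * n_target) {
    stopf(paste("target plexus volume %.2f cm^3 cannot fit inside the",
                "ventricles (%.2f cm^3); enlarge the ventricles or the grid"),
          target_volume, length(vidx) * vox_cm3)
  }
  lo <- 0
  hi <- 2 * max(vent_semi)
  best_r <- hi
  best_err <- Inf
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    n_mid <- sum(dists <= mid)
    err <- abs(n_mid - n_target)
    if (err < best_err) {
      best_err <- err
      best_r <- mid
    }
    if (n_mid < n_target) lo <- mid else hi <- mid
  }
  sel <- dists <= best_r
  achieved <- sum(sel) * vox_cm3
  if (abs(achieved - target_volume) / target_volume > 0.05) {
    stopf("plexus volume targeting failed: wanted %.3f cm^3, got %.3f",
          target_volume, achieved)
  }
  plexus <- array(FALSE, shape)
  plexus[vidx[sel]] <- TRUE

  affine <- centered_affine(shape, spacing)
  truth <- binary_mask3d(plexus, spacing, affine, space = "common")
  vent_mask <- binary_mask3d(vent, spacing, affine, space = "common")
  head_mask <- binary_mask3d(head, spacing, affine, space = "common")

  meta$tiv_cm3 <- sum(head) * vox_cm3
  meta$lvv_cm3 <- sum(vent) * vox_cm3
  meta$achieved_volume_cm3 <- achieved

  subject <- list(volumes = NULL, truth_mask = truth,
                  ventricle_mask = vent_mask, head_mask = head_mask,
                  truth_native = NULL, native_transform = native_transform,
                  meta = meta, grid_shape = shape, spacing = spacing)
  class(subject) <- "phantom_subject"
  if (detail == "masks") return(subject)

  common_geom <- list(shape = shape, spacing = spacing, affine = affine)
  tissue <- array(0L, shape)
  tissue[head] <- 1L
  tissue[vent] <- 2L
  tissue[plexus] <- 3L
  volumes <- list()
  for (mod in rownames(params$intensities)) {
    lut <- c(params$intensities[mod, "background"],
             params$intensities[mod, "parenchyma"],
             params$intensities[mod, "csf"],
             params$intensities[mod, "plexus"])
    img <- array(lut[tissue + 1L], shape)
    img <- img * bias_field(shape, params$bias_amplitude)
    img <- img + array(rnorm(prod(shape), 0, params$noise_sigma), shape)
    common_vol <- volume3d(img, spacing, affine, space = "common")
    tgt <- if (mod == "flair" && aniso_flair) {
      sp <- c(0.57, 0.57, 4.0)
      sh <- pmax(4L, as.integer(round(shape * spacing / sp)))
      list(shape = sh, spacing = sp, affine = centered_affine(sh, sp))
    } else {
      common_geom
    }
    volumes[[mod]] <- resample_with_affine(common_vol, native_transform, tgt,
                                           interp = "trilinear",
                                           space = "native")
  }
  subject$volumes <- volumes
  subject$truth_native <- resample_with_affine(truth, native_transform,
                                               common_geom,
                                               interp = "nearest",
                                               space = "native")
  subject
}

#' Generate a phantom cohort
#'
#' Ages are uniform over the modelled range and sexes balanced
#' Bernoulli(0.5). With `dir` given, writes per-subject NIfTI volumes,
#' native-space truth masks, transforms and a `manifest.csv` that
#' round-trips through [load_manifest()].
#'
#' @inheritParams generate_subject
#' @param n number of subjects (>= 2).
#' @param dir output directory (created if needed); `NULL` keeps the cohort
#'   in memory only.
#' @return list with `subjects` (named list of [generate_subject()] results)
#'   and `manifest` (data frame; includes an extra `plexus_cm3` column with
#'   the truth-mask volume).
#' @export
generate_cohort <- function(params, n, seed = 1L, dir = NULL,
                            detail = c("full", "masks", "metadata"),
                            aniso_flair = FALSE) {
  detail <- match.arg(detail)
  if (n < 2) stopf("cohort needs at least 2 subjects")
  draws <- with_seed(seed, list(
    ages = runif(n, params$age_range[1], params$age_range[2]),
    sexes = sample(c("F", "M"), n, replace = TRUE),
    seeds = sample.int(.Machine$integer.max - 1L, n)))
  ids <- sprintf("sub-%03d", seq_len(n))
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  subjects <- list()
  rows <- list()
  for (i in seq_len(n)) {
    s <- generate_subject(params, draws$ages[i], draws$sexes[i],
                          seed = draws$seeds[i], detail = detail,
                          aniso_flair = aniso_flair)
    s$id <- ids[i]
    subjects[[ids[i]]] <- s
    row <- data.frame(subject_id = ids[i], age = draws$ages[i],
                      sex = draws$sexes[i], diagnosis = "HC",
                      tiv_cm3 = s$meta$tiv_cm3, lvv_cm3 = s$meta$lvv_cm3,
                      t1_path = NA_character_, t2_path = NA_character_,
                      flair_path = NA_character_, mask_path = NA_character_,
                      transform_path = NA_character_,
                      plexus_cm3 = s$meta$achieved_volume_cm3,
                      stringsAsFactors = FALSE)
    if (!is.null(dir) && detail == "full") {
      for (mod in names(s$volumes)) {
        fn <- sprintf("%s_%s.nii.gz", ids[i], mod)
        write_volume(s$volumes[[mod]], file.path(dir, fn))
        row[[paste0(mod, "_path")]] <- fn
      }
      fn <- sprintf("%s_mask.nii.gz", ids[i])
      write_volume(s$truth_native, file.path(dir, fn))
      row$mask_path <- fn
      fn <- sprintf("%s_transform.txt", ids[i])
      write_affine(s$native_transform, file.path(dir, fn))
      row$transform_path <- fn
    }
    rows[[i]] <- row
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    if (detail == "full") {
      manifest <- load_manifest(file.path(dir, "manifest.csv"))
      manifest$plexus_cm3 <- vapply(subjects, function(s) {
        s$meta$achieved_volume_cm3
      }, numeric(1))
    }
  }
  list(subjects = subjects, manifest = manifest)
}
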
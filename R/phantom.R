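# Synthetic 3D head-phantom populations with known ground-truth warps.
#
# A phantom is a T1-like head volume rendered analytically from a smooth
# ellipsoidal anatomy: a head/brain ellipsoid with a gray-matter shell,
# central ventricle-like fluid, and bilateral deep gray structures
# (thalamus-, hippocampus-, parahippocampal-like) plus a cerebellum-like
# blob.  Subjects differ by a global sex/age scale and a random smooth
# diffeomorphic warp; the inverse warp (matching the direction of
# registration outputs, template grid -> subject coordinates) is stored as
# ground truth.

#' Specify a phantom population
#'
#' Defaults emulate the study conditions of an elderly East-Asian cohort:
#' five 5-year age strata with equal numbers of men and women per stratum,
#' brain extents near length 162, width 132, height 100 mm, a male/female
#' global size ratio of 1.04, and smooth zero-mean inter-subject warps with
#' 2 mm mean displacement.  The default grid is 64^3 at 3 mm spacing (a desk
#' scale suitable for tests and simulation studies); resolution is
#' configuration, not anatomy.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param spacing_mm Isotropic voxel size in mm.
#' @param brain_semi_axes_mm Semi-axes (width/2, length/2, height/2) in mm
#'   along grid axes 1 (right-left), 2 (anterior-posterior),
#'   3 (inferior-superior).
#' @param structure_size_scale Named multipliers on named-structure sizes
#'   (e.g. `c(parahippocampal = 1.3)`); the population mean-shape dial used
#'   for ethnicity-analogue experiments.
#' @param class_intensities Mean T1-like intensity per tissue class
#'   (`fluid`, `gm`, `wm`).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param bias_amplitude Log-scale amplitude of the multiplicative degree-2
#'   polynomial bias field (0 disables).
#' @param warp_sd_mm Target mean displacement magnitude of the random
#'   subject warp over the brain, in mm.
#' @param warp_smoothness_mm Gaussian scale of the random velocity field.
#' @param strata Data frame with columns `label`, `n_men`, `n_women`.
#' @param sex_size_factor Global isotropic male/female scale ratio (>= 1).
#' @param age_shrink Linear per-stratum shrink factor (0 disables).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing_mm = 3,
                         brain_semi_axes_mm = c(66, 81, 50),
                         structure_size_scale = numeric(),
                         class_intensities = c(fluid = 0.25, gm = 0.6, wm = 0.9),
                         noise_sd = 0.02,
                         bias_amplitude = 0.1,
                         warp_sd_mm = 2,
                         warp_smoothness_mm = 10,
                         strata = data.frame(
                           label = c("60-64", "65-69", "70-74", "75-79", "80+"),
                           n_men = 20L, n_women = 20L),
                         sex_size_factor = 1.04,
                         age_shrink = 0) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be 3 integers >= 8", call. = FALSE)
  if (spacing_mm <= 0) stop("spacing_mm must be positive", call. = FALSE)
  if (length(brain_semi_axes_mm) != 3L || any(brain_semi_axes_mm <= 0))
    stop("brain_semi_axes_mm must be 3 positive values", call. = FALSE)
  if (noise_sd < 0 || bias_amplitude < 0 || warp_sd_mm < 0)
    stop("noise_sd, bias_amplitude and warp_sd_mm must be >= 0", call. = FALSE)
  if (warp_smoothness_mm <= 0)
    stop("warp_smoothness_mm must be positive", call. = FALSE)
  strata <- as.data.frame(strata)
  if (!all(c("label", "n_men", "n_women") %in% names(strata)) ||
      nrow(strata) == 0)
    stop("strata must have columns label, n_men, n_women (>= 1 row)",
         call. = FALSE)
  if (any(strata$n_men < 0 | strata$n_women < 0) ||
      any(strata$n_men != round(strata$n_men)) ||
      any(strata$n_women != round(strata$n_women)))
    stop("strata counts must be nonnegative integers", call. = FALSE)
  if (sex_size_factor < 1)
    stop("sex_size_factor must be >= 1", call. = FALSE)
  structures <- default_structures(brain_semi_axes_mm)
  if (length(structure_size_scale)) {
    if (is.null(names(structure_size_scale)))
      stop("structure_size_scale must be named", call. = FALSE)
    for (nm in names(structure_size_scale)) {
      hit <- grepl(nm, vapply(structures, `[[`, "", "name"), fixed = TRUE)
      if (!any(hit))
        stop(sprintf("unknown structure in structure_size_scale: %s", nm),
             call. = FALSE)
      for (i in which(hit))
        structures[[i]]$size_scale <-
          structures[[i]]$size_scale * structure_size_scale[[nm]]
    }
  }
  structure(list(
    grid_shape = grid_shape, spacing_mm = spacing_mm,
    brain_semi_axes_mm = as.numeric(brain_semi_axes_mm),
    structures = structures,
    class_intensities = class_intensities,
    noise_sd = noise_sd, bias_amplitude = bias_amplitude,
    warp_sd_mm = warp_sd_mm, warp_smoothness_mm = warp_smoothness_mm,
    strata = strata, sex_size_factor = sex_size_factor,
    age_shrink = age_shrink
  ), class = "phantom_spec")
}

# Named deep structures: centres/semi-axes in mm on the unit-scale anatomy.
# Positions are fractions of the brain semi-axes so they stay inside the
# brain whatever the configured extents.
default_structures <- function(a) {
  rel <- function(cx, cy, cz, sx, sy, sz, name, tissue) {
    list(name = name, tissue = tissue,
         center = c(cx, cy, cz) * a, semi = c(sx, sy, sz) * a,
         size_scale = 1)
  }
  list(
    rel(0, 0.06, 0.20, 0.08, 0.22, 0.18, "ventricle", "fluid"),
    rel(-0.24, 0.02, 0.08, 0.10, 0.12, 0.13, "thalamus_left", "gm"),
    rel(0.24, 0.02, 0.08, 0.10, 0.12, 0.13, "thalamus_right", "gm"),
    rel(-0.36, -0.25, -0.22, 0.10, 0.18, 0.13, "hippocampus_left", "gm"),
    rel(0.36, -0.25, -0.22, 0.10, 0.18, 0.13, "hippocampus_right", "gm"),
    rel(-0.52, -0.30, -0.50, 0.09, 0.16, 0.10, "parahippocampal_left", "gm"),
    rel(0.52, -0.30, -0.50, 0.09, 0.16, 0.10, "parahippocampal_right", "gm"),
    rel(0, -0.57, -0.46, 0.48, 0.26, 0.32, "cerebellum", "gm")
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s grid @ %g mm, brain %g x %g x %g mm, %d strata\n",
    paste(x$grid_shape, collapse = "x"), x$spacing_mm,
    2 * x$brain_semi_axes_mm[1], 2 * x$brain_semi_axes_mm[2],
    2 * x$brain_semi_axes_mm[3], nrow(x$strata)))
  cat(sprintf("  warp_sd %g mm (smoothness %g mm), noise %g, bias %g\n",
              x$warp_sd_mm, x$warp_smoothness_mm, x$noise_sd,
              x$bias_amplitude))
  invisible(x)
}

# World coordinates (mm) of every voxel of the spec's grid.
spec_world_coords <- function(spec) {
  g <- grid_coords(spec$grid_shape)
  aff <- centered_affine(spec$grid_shape, rep(spec$spacing_mm, 3))
  list(x = g$x * aff[1, 1] + aff[1, 4],
       y = g$y * aff[2, 2] + aff[2, 4],
       z = g$z * aff[3, 3] + aff[3, 4],
       affine = aff)
}

# Soft ellipsoid membership: ~logistic edge of width `edge_mm`.
soft_ellipsoid <- function(px, py, pz, center, semi, edge_mm = 2) {
  rho <- sqrt(((px - center[1]) / semi[1])^2 +
                ((py - center[2]) / semi[2])^2 +
                ((pz - center[3]) / semi[3])^2)
  d_mm <- (1 - rho) * min(semi)
  1 / (1 + exp(-d_mm / (edge_mm / 4)))
}

# Analytic tissue fractions (fluid, gm, wm; background implied) at world
# points, for anatomy scaled globally by `scale`.
eval_anatomy <- function(spec, px, py, pz, scale = 1) {
  px <- px / scale; py <- py / scale; pz <- pz / scale
  a <- spec$brain_semi_axes_mm
  rho_h <- sqrt((px / a[1])^2 + (py / a[2])^2 + (pz / a[3])^2)
  head <- 1 / (1 + exp(-((1 - rho_h) * min(a)) / 0.5))
  shell <- 1 / (1 + exp(-((rho_h - 0.85) * min(a)) / 1.2))
  q_f <- 0; q_g <- shell
  for (s in spec$structures) {
    m <- soft_ellipsoid(px, py, pz, s$center, s$semi * s$size_scale)
    if (s$tissue == "fluid") q_f <- pmax(q_f, m) else q_g <- pmax(q_g, m)
  }
  q_g <- q_g * (1 - q_f)
  q_w <- 1 - q_f - q_g
  list(fluid = head * q_f, gm = head * q_g, wm = head * q_w, head = head)
}

render_t1 <- function(spec, frac) {
  ci <- spec$class_intensities
  frac$fluid * ci[["fluid"]] + frac$gm * ci[["gm"]] + frac$wm * ci[["wm"]]
}

#' Tissue probability maps
#'
#' Bundles one probability [volume()] per tissue class plus background; all
#' maps share one grid and sum to 1 per voxel (within 1e-6).
#'
#' @param maps Named list of probability volumes (tissue classes, e.g.
#'   `fluid`, `gm`, `wm`).
#' @param background Probability volume of the background class.
#' @return An object of class `tissue_maps`.
#' @export
tissue_maps <- function(maps, background) {
  if (!length(maps) || !all(vapply(maps, is_volume, TRUE)))
    stop("`maps` must be a list of volumes", call. = FALSE)
  for (m in maps) stopifnot_same_grid(m, background, "tissue maps")
  tot <- Reduce(`+`, lapply(maps, vol_values)) + vol_values(background)
  if (max(abs(tot - 1)) > 1e-6)
    stop("tissue class probabilities plus background must sum to 1",
         call. = FALSE)
  structure(list(maps = maps, background = background), class = "tissue_maps")
}

#' @export
print.tissue_maps <- function(x, ...) {
  cat(sprintf("<tissue_maps> classes: %s (+ background)\n",
              paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

# Run `expr` under a private RNG stream; the caller's RNG state is restored.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Zero-mean smooth random velocity with mean displacement `sd_mm` over the
# brain mask, in voxel units.  Drawn from smoothed white noise.
random_velocity <- function(spec, sd_mm, brain, amplitude_factor = 1) {
  dims <- spec$grid_shape
  sp <- rep(spec$spacing_mm, 3)
  v <- array(0, c(dims, 3L))
  for (i in 1:3) {
    w <- array(rnorm(prod(dims)), dims)
    v[, , , i] <- gaussian_smooth(w, spec$warp_smoothness_mm, spacing = sp)
  }
  mag_mm <- sqrt((v[, , , 1] * sp[1])^2 + (v[, , , 2] * sp[2])^2 +
                   (v[, , , 3] * sp[3])^2)
  # v is interpreted in voxel units; scale so the mean displacement
  # magnitude in mm over the brain hits the target
  cur <- mean(mag_mm[brain])
  target <- sd_mm * amplitude_factor
  if (cur > 0) v <- v * (target / cur)
  v
}

#' Generate one phantom subject
#'
#' Pipeline: population-mean anatomy -> per-population structure size
#' offsets (already in the spec) -> global sex/stratum scale -> random
#' smooth subject warp (smoothed white-noise velocity scaled to
#' `warp_sd_mm`, exponentiated) -> tissue-class intensity rendering ->
#' multiplicative smooth bias field -> additive noise.  The anatomy is
#' evaluated analytically at the warped coordinates, so rendering is exact.
#' The stored `true_warp` maps template-grid (population mean) coordinates
#' into the subject, matching the direction of registration outputs.
#'
#' @param spec A [phantom_spec()].
#' @param stratum Stratum label (must appear in `spec$strata$label`).
#' @param sex `"M"` or `"F"`.
#' @param seed Nonnegative integer seed; identical inputs give bit-identical
#'   subjects.
#' @param subject_id Optional id string.
#' @return An object of class `phantom_subject` with elements `t1`
#'   ([volume()]), `tissues` ([tissue_maps()]), `true_warp`
#'   ([deformation_field()]), `stratum`, `sex`, `subject_id`.
#' @export
generate_subject <- function(spec, stratum, sex = c("M", "F"), seed,
                             subject_id = NULL) {
  sex <- match.arg(sex)
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  si <- match(stratum, spec$strata$label)
  if (is.na(si)) stop(sprintf("unknown stratum: %s", stratum), call. = FALSE)
  if (seed < 0) stop("seed must be >= 0", call. = FALSE)
  scale <- (if (sex == "M") spec$sex_size_factor else 1) *
    (1 - spec$age_shrink * (si - 1))
  w <- spec_world_coords(spec)
  dims <- spec$grid_shape
  sp <- rep(spec$spacing_mm, 3)
  a <- spec$brain_semi_axes_mm * scale
  brain <- ((w$x / a[1])^2 + (w$y / a[2])^2 + (w$z / a[3])^2) <= 1
  with_seed(seed, {
    amp <- 1
    for (attempt in 1:5) {
      if (spec$warp_sd_mm == 0) {
        v <- array(0, c(dims, 3L))
      } else {
        v <- random_velocity(spec, spec$warp_sd_mm, brain, amp)
      }
      vf <- velocity_field(v, spacing = sp, affine = w$affine,
                           smoothness_mm = spec$warp_smoothness_mm)
      true_warp <- exp_velocity(negate_field(vf))
      jac_ok <- tryCatch({
        jm <- jacobian_map(true_warp)
        interior <- attr(jm, "interior")
        all(vol_values(jm)[interior] > 0)
      }, error = function(e) FALSE)
      if (jac_ok) break
      if (attempt == 5)
        stop("could not generate an invertible subject warp in 5 attempts",
             call. = FALSE)
      amp <- amp * 0.8
      message(sprintf(
        "generate_subject: non-diffeomorphic warp, retrying at %.2f amplitude",
        amp))
    }
    d <- exp_velocity(vf)
    u <- unclass(d)
    px <- w$x + u[, , , 1] * sp[1]
    py <- w$y + u[, , , 2] * sp[2]
    pz <- w$z + u[, , , 3] * sp[3]
    frac <- eval_anatomy(spec, px, py, pz, scale = scale)
    t1 <- render_t1(spec, frac)
    if (spec$bias_amplitude > 0) {
      nx <- w$x / max(abs(w$x)); ny <- w$y / max(abs(w$y))
      nz <- w$z / max(abs(w$z))
      terms <- list(nx, ny, nz, nx^2, ny^2, nz^2, nx * ny, nx * nz, ny * nz)
      cf <- rnorm(9)
      f <- Reduce(`+`, Map(`*`, terms, cf))
      f <- f / max(sd(f), 1e-12)
      t1 <- t1 * exp(spec$bias_amplitude * f)
    }
    if (spec$noise_sd > 0) t1 <- t1 + rnorm(length(t1), 0, spec$noise_sd)
    t1 <- array(t1, dims)
    mk <- function(x) volume(pmin(pmax(array(x, dims), 0), 1), spacing = sp,
                             affine = w$affine, kind = "probability")
    fl <- mk(frac$fluid); gm <- mk(frac$gm); wm <- mk(frac$wm)
    bg <- volume(array(pmax(1 - vol_values(fl) - vol_values(gm) -
                              vol_values(wm), 0), dims),
                 spacing = sp, affine = w$affine, kind = "probability")
    structure(list(
      t1 = volume(t1, spacing = sp, affine = w$affine, kind = "intensity"),
      tissues = tissue_maps(list(fluid = fl, gm = gm, wm = wm), bg),
      true_warp = true_warp,
      stratum = stratum, sex = sex,
      subject_id = subject_id %||%
        sprintf("%s_%s_seed%d", stratum, sex, as.integer(seed))
    ), class = "phantom_subject")
  })
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom_subject> %s  stratum %s, sex %s\n", x$subject_id,
              x$stratum, x$sex))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a phantom population
#'
#' One subject per (stratum, sex, replicate) slot, each with a distinct
#' derived seed, in deterministic order (strata in spec order; men then
#' women within a stratum).
#'
#' @param spec A [phantom_spec()].
#' @param seed Population seed (subject seeds are derived from it).
#' @param id_prefix Prefix for subject ids.
#' @return List of [generate_subject()] results.
#' @export
generate_population <- function(spec, seed, id_prefix = "S") {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  if (nrow(spec$strata) == 0) stop("empty strata list", call. = FALSE)
  subjects <- list()
  slot <- 0L
  for (si in seq_len(nrow(spec$strata))) {
    row <- spec$strata[si, ]
    for (sex in c("M", "F")) {
      n <- if (sex == "M") row$n_men else row$n_women
      for (r in seq_len(n)) {
        slot <- slot + 1L
        sseed <- (as.integer(seed) %% 59999) * 33013 + slot * 7919
        id <- sprintf("%s%03d_%s_%s%02d", id_prefix, slot, row$label, sex, r)
        subjects[[slot]] <- generate_subject(spec, row$label, sex,
                                             seed = sseed, subject_id = id)
      }
    }
  }
  subjects
}

#' Brain mask of the population-mean anatomy
#'
#' @param spec A [phantom_spec()].
#' @param scale Global scale factor (1 = population mean).
#' @return A logical 3D array marking voxels inside the brain ellipsoid.
#' @export
phantom_brain_mask <- function(spec, scale = 1) {
  w <- spec_world_coords(spec)
  a <- spec$brain_semi_axes_mm * scale
  ((w$x / a[1])^2 + (w$y / a[2])^2 + (w$z / a[3])^2) <= 1
}

#' Noiseless mean-anatomy phantom
#'
#' Renders the population-mean anatomy (no warp, no bias, no noise) as a
#' subject-like list; useful as a ground-truth reference.
#'
#' @inheritParams phantom_brain_mask
#' @return A `phantom_subject` whose `true_warp` is the zero field.
#' @export
mean_phantom <- function(spec, scale = 1) {
  w <- spec_world_coords(spec)
  dims <- spec$grid_shape
  sp <- rep(spec$spacing_mm, 3)
  frac <- eval_anatomy(spec, w$x, w$y, w$z, scale = scale)
  t1 <- array(render_t1(spec, frac), dims)
  mk <- function(x) volume(pmin(pmax(array(x, dims), 0), 1), spacing = sp,
                           affine = w$affine, kind = "probability")
  fl <- mk(frac$fluid); gm <- mk(frac$gm); wm <- mk(frac$wm)
  bg <- volume(array(pmax(1 - vol_values(fl) - vol_values(gm) -
                            vol_values(wm), 0), dims),
               spacing = sp, affine = w$affine, kind = "probability")
  structure(list(
    t1 = volume(t1, spacing = sp, affine = w$affine, kind = "intensity"),
    tissues = tissue_maps(list(fluid = fl, gm = gm, wm = wm), bg),
    true_warp = zero_field(dims, sp, w$affine),
    stratum = NA_character_, sex = NA_character_, subject_id = "mean"
  ), class = "phantom_subject")
}

#' Synthetic label atlas on the population-mean anatomy
#'
#' Deterministic parcellation standing in for an anatomical atlas: one label
#' per named structure plus an octant parcellation of the remaining brain
#' tissue (at least 12 regions in total).  Region volumes in the table equal
#' `voxel_count * spacing^3` exactly.
#'
#' @param spec A [phantom_spec()].
#' @param overlap_tolerance Maximum tolerated pairwise overlap fraction
#'   (relative to the smaller structure) before an error naming the pair.
#' @return A [label_atlas()].
#' @export
make_atlas <- function(spec, overlap_tolerance = 0.05) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  w <- spec_world_coords(spec)
  dims <- spec$grid_shape
  sp <- rep(spec$spacing_mm, 3)
  inside <- function(s) {
    semi <- s$semi * s$size_scale
    ((w$x - s$center[1]) / semi[1])^2 + ((w$y - s$center[2]) / semi[2])^2 +
      ((w$z - s$center[3]) / semi[3])^2 <= 1
  }
  masks <- lapply(spec$structures, inside)
  nms <- vapply(spec$structures, `[[`, "", "name")
  for (i in seq_along(masks)) for (j in seq_len(i - 1)) {
    ov <- sum(masks[[i]] & masks[[j]])
    if (ov > overlap_tolerance * min(sum(masks[[i]]), sum(masks[[j]])))
      stop(sprintf("structures overlap beyond tolerance: %s / %s",
                   nms[j], nms[i]), call. = FALSE)
  }
  a <- spec$brain_semi_axes_mm
  brain <- ((w$x / a[1])^2 + (w$y / a[2])^2 + (w$z / a[3])^2) <= 1
  lab <- array(0L, dims)
  n_struct <- length(masks)
  oct <- 1L + (w$x > 0) + 2L * (w$y > 0) + 4L * (w$z > 0)
  lab[brain] <- n_struct + oct[brain]
  for (i in seq_along(masks)) lab[masks[[i]] & brain] <- i
  region_names <- c(nms, sprintf("octant_%d", 1:8))
  names(region_names) <- as.character(seq_len(n_struct + 8L))
  label_atlas(volume(lab, spacing = sp, affine = w$affine, kind = "label"),
              region_names = region_names)
}
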
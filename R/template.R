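# Groupwise unbiased template construction: rigid/scale import to a common
# grid, then iterative mean-and-register with velocity-space recentring.

subject_channel_volumes <- function(s) {
  if (inherits(s, "phantom_subject"))
    c(list(t1 = s$t1), s$tissues$maps)
  else if (is.list(s) && all(vapply(s, is_volume, TRUE)))
    s
  else stop("subjects must be phantom_subject objects or lists of channel volumes",
            call. = FALSE)
}

subject_ident <- function(s, i) {
  if (inherits(s, "phantom_subject")) s$subject_id
  else attr(s, "subject_id") %||% sprintf("subject_%03d", i)
}

# Moments of a mask: centroid (voxel coords), principal axes, cube-root
# volume (for isotropic scale matching).
mask_moments <- function(a, threshold) {
  m <- a > threshold
  if (!any(m)) stop("empty mask in moments alignment", call. = FALSE)
  g <- grid_coords(dim(a))
  idx <- which(m)
  P <- cbind(g$x[idx], g$y[idx], g$z[idx])
  ctr <- colMeans(P)
  C <- crossprod(sweep(P, 2, ctr)) / nrow(P)
  list(centroid = ctr, cov = C, n = nrow(P))
}

#' Rigid + isotropic-scale import to a common grid
#'
#' Aligns every subject to the first subject's grid by moments: centroid
#' translation, principal-axis rotation (skipped when nearly degenerate),
#' and a global isotropic scale matching brain-mask volumes.  All channels
#' are resampled onto the common grid with linear interpolation.
#'
#' @param subjects List of [generate_subject()] results or lists of channel
#'   volumes (equal channel counts, T1 first).
#' @param mask_threshold Threshold defining the alignment mask on the first
#'   channel (default 10% of its 99th percentile).
#' @return List with `imported` (list of per-subject channel-volume lists on
#'   the common grid), `transforms` (per-subject 4x4 voxel-space affine,
#'   reference index -> subject index), and `ids`.
#' @export
initial_import <- function(subjects, mask_threshold = NULL) {
  if (length(subjects) == 0) stop("no subjects", call. = FALSE)
  chans <- lapply(subjects, subject_channel_volumes)
  nch <- length(chans[[1]])
  if (any(vapply(chans, length, 0L) != nch))
    stop("all subjects must have the same number of channels", call. = FALSE)
  ids <- vapply(seq_along(subjects),
                function(i) subject_ident(subjects[[i]], i), "")
  ref <- chans[[1]]
  ref_a <- vol_values(ref[[1]])
  thr <- mask_threshold %||% default_mask_threshold(ref[[1]])
  mom_r <- mask_moments(ref_a, thr)
  dims <- dim(ref[[1]])
  g <- grid_coords(dims)
  out <- vector("list", length(subjects))
  transforms <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    if (i == 1) {
      out[[i]] <- ref
      transforms[[i]] <- diag(4)
      next
    }
    sub <- chans[[i]]
    stopifnot_same_grid(sub[[1]], ref[[1]], "subject grids")
    mom_s <- mask_moments(vol_values(sub[[1]]),
                          mask_threshold %||%
                            default_mask_threshold(sub[[1]]))
    s <- (mom_s$n / mom_r$n)^(1 / 3)
    er <- eigen(mom_r$cov, symmetric = TRUE)
    es <- eigen(mom_s$cov, symmetric = TRUE)
    if (er$values[1] / er$values[3] < 1.05^2 ||
        es$values[1] / es$values[3] < 1.05^2) {
      R <- diag(3)
    } else {
      Vr <- er$vectors; Vs <- es$vectors
      for (k in 1:3) if (sum(Vs[, k] * Vr[, k]) < 0) Vs[, k] <- -Vs[, k]
      R <- Vs %*% t(Vr)
      if (det(R) < 0) {
        Vs[, 3] <- -Vs[, 3]
        R <- Vs %*% t(Vr)
      }
    }
    # reference voxel p -> subject voxel: c_s + s * R (p - c_r)
    A <- diag(4)
    A[1:3, 1:3] <- s * R
    A[1:3, 4] <- mom_s$centroid - s * R %*% mom_r$centroid
    transforms[[i]] <- A
    px <- A[1, 1] * g$x + A[1, 2] * g$y + A[1, 3] * g$z + A[1, 4]
    py <- A[2, 1] * g$x + A[2, 2] * g$y + A[2, 3] * g$z + A[2, 4]
    pz <- A[3, 1] * g$x + A[3, 2] * g$y + A[3, 3] * g$z + A[3, 4]
    out[[i]] <- lapply(sub, function(ch) {
      vals <- sample_at(vol_values(ch), px, py, pz)
      vol_like(vals, ref[[1]], kind = vol_kind(ch))
    })
    names(out[[i]]) <- names(sub)
  }
  list(imported = out, transforms = transforms, ids = ids)
}

#' Build a groupwise unbiased template
#'
#' Iterative mean-and-register construction: the initial template is the
#' voxelwise mean of the imported channels; each outer iteration registers
#' every subject to the current template (running `schedule[2]` demons
#' iterations per pyramid level as the inner loop), averages the warped
#' channels, and recentres by the inverse of the mean deformation --
#' implemented in velocity space: the mean subject velocity is subtracted
#' from every subject velocity and the template is warped by
#' `exp(-mean velocity)`, driving the average deformation toward zero.
#'
#' @param imported Result of [initial_import()], or a plain list of
#'   per-subject channel-volume lists on one grid.
#' @param schedule Integer pair `(outer, inner)`: outer iterations and
#'   demons iterations per pyramid level.  Default `c(6, 6)`.
#' @param params A [registration_params()]; its `iterations_per_level` is
#'   overridden by `schedule[2]`.
#' @param brain_mask Optional logical array on the template grid over which
#'   the history's mean displacement is computed; default: mask of the
#'   initial template's first channel.
#' @param keep_intermediate If `TRUE`, templates from every outer iteration
#'   are kept in the result's `intermediates`.
#' @param verbose Print per-iteration progress.
#' @return An object of class `brain_template`: `channels` (named volumes),
#'   `subject_velocities`, `subject_deformations` (template -> subject),
#'   `history` (tibble per outer iteration: `mean_displacement_mm`, the
#'   brain-mask mean magnitude of the mean pre-recentring subject
#'   deformation -- the template-position bias that recentring drives to
#'   zero; `mean_subject_displacement_mm`, the mean per-subject
#'   displacement magnitude; `mean_similarity`), `schedule`, `ids`.
#' @export
build_template <- function(imported, schedule = c(6L, 6L),
                           params = registration_params(),
                           brain_mask = NULL, keep_intermediate = FALSE,
                           verbose = FALSE) {
  if (is.list(imported) && !is.null(imported$imported))
    sets <- imported$imported
  else sets <- imported
  ids <- if (!is.null(imported$ids)) imported$ids
  else sprintf("subject_%03d", seq_along(sets))
  n <- length(sets)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  outer <- as.integer(schedule[1]); inner <- as.integer(schedule[2])
  if (outer < 1 || inner < 1) stop("schedule entries must be >= 1",
                                   call. = FALSE)
  params$iterations_per_level <- rep(inner, params$pyramid_levels)
  nch <- length(sets[[1]])
  ref <- sets[[1]][[1]]
  dims <- dim(ref)
  spacing <- vol_spacing(ref)
  affine <- vol_affine(ref)
  mean_channels <- function(chsets) {
    lapply(seq_len(nch), function(ch) {
      vals <- Reduce(`+`, lapply(chsets, function(s) vol_values(s[[ch]]))) / n
      vol_like(vals, ref, kind = vol_kind(sets[[1]][[ch]]))
    })
  }
  template <- mean_channels(sets)
  names(template) <- names(sets[[1]])
  if (is.null(brain_mask))
    brain_mask <- vol_values(template[[1]]) >
      default_mask_threshold(template[[1]])
  velocities <- vector("list", n)
  history <- list()
  intermediates <- if (keep_intermediate) list() else NULL
  # outer iteration 1 runs the full multiresolution pyramid; later outer
  # iterations refine the warm-started velocity at the finest level only,
  # so the mean-deformation trace reflects template change, not pyramid
  # round-trip churn
  fine_params <- params
  fine_params$pyramid_levels <- 1L
  fine_params$iterations_per_level <- inner
  for (k in seq_len(outer)) {
    p_k <- if (k == 1) params else fine_params
    regs <- vector("list", n)
    for (i in seq_len(n)) {
      regs[[i]] <- tryCatch(
        register_pair(sets[[i]], template, p_k,
                      init_velocity = velocities[[i]]),
        error = function(e) stop(sprintf(
          "registration failed for subject %s at outer iteration %d: %s",
          ids[i], k, conditionMessage(e)), call. = FALSE))
    }
    velocities <- lapply(regs, function(r) r$velocity)
    mean_v <- Reduce(`+`, lapply(velocities, unclass)) / n
    # convergence measure: magnitude of the mean (pre-recentring) subject
    # deformation over the brain mask -- the residual bias of the template
    # position that recentring drives toward zero
    mean_d_raw <- Reduce(`+`, lapply(regs, function(r)
      unclass(r$deformation))) / n
    bias_mag <- sqrt(mean_d_raw[, , , 1]^2 + mean_d_raw[, , , 2]^2 +
                       mean_d_raw[, , , 3]^2)
    mean_disp <- mean(bias_mag[brain_mask]) * spacing[1]
    # recentre in velocity space: subjects' mean velocity becomes zero
    velocities <- lapply(velocities, function(v) {
      out <- unclass(v) - mean_v
      velocity_field(out, spacing = spacing, affine = affine,
                     smoothness_mm = attr(v, "smoothness_mm"))
    })
    warped <- lapply(seq_len(n), function(i) {
      d <- regs[[i]]$deformation
      lapply(sets[[i]], warp_volume, d = d)
    })
    template <- mean_channels(warped)
    names(template) <- names(sets[[1]])
    recenter <- exp_velocity(velocity_field(-mean_v, spacing = spacing,
                                            affine = affine))
    template <- lapply(template, warp_volume, d = recenter)
    names(template) <- names(sets[[1]])
    deformations <- lapply(velocities, exp_velocity)
    mean_subj_disp <- mean(vapply(deformations, function(d) {
      m <- field_magnitude(d)
      mean(m[brain_mask]) * spacing[1]
    }, 0))
    mean_sim <- mean(vapply(regs, function(r)
      r$trace$similarity[nrow(r$trace)], 0))
    history[[k]] <- tibble::tibble(
      outer = k,
      mean_displacement_mm = mean_disp,
      mean_subject_displacement_mm = mean_subj_disp,
      mean_similarity = mean_sim)
    if (keep_intermediate) intermediates[[k]] <- template
    if (verbose)
      message(sprintf("outer %d/%d: mean displacement %.3f mm, ssd %.4g",
                      k, outer, mean_disp, mean_sim))
  }
  structure(list(channels = template,
                 subject_velocities = velocities,
                 subject_deformations = lapply(velocities, exp_velocity),
                 history = do.call(rbind, history),
                 schedule = c(outer = outer, inner = inner),
                 ids = ids,
                 brain_mask = brain_mask,
                 intermediates = intermediates),
            class = "brain_template")
}

#' @export
print.brain_template <- function(x, ...) {
  d <- dim(x$channels[[1]])
  h <- x$history
  cat(sprintf(
    "<brain_template> %d subjects, %d channels, %d x %d x %d grid\n",
    length(x$subject_deformations), length(x$channels), d[1], d[2], d[3]))
  cat(sprintf("  schedule (%d, %d); final mean displacement %.3f mm\n",
              x$schedule[1], x$schedule[2],
              h$mean_displacement_mm[nrow(h)]))
  invisible(x)
}

#' @importFrom stats var
template_sharpness <- function(template, mask = template$brain_mask) {
  a <- vol_values(template$channels[[1]])
  g <- sqrt(grad_axis(a, 1)^2 + grad_axis(a, 2)^2 + grad_axis(a, 3)^2)
  mean(g[mask])
}

#' Tidy a template's convergence history
#'
#' @param x A `brain_template`.
#' @param ... Unused.
#' @return The history tibble (one row per outer iteration).
#' @export
tidy.brain_template <- function(x, ...) x$history

#' One-row template summary
#'
#' @param x A `brain_template`.
#' @param ... Unused.
#' @return A one-row tibble: subjects, channels, schedule, final mean
#'   displacement, final similarity, sharpness of the T1 channel.
#' @export
glance.brain_template <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_subjects = length(x$subject_deformations),
    n_channels = length(x$channels),
    outer_iterations = x$schedule[["outer"]],
    inner_iterations = x$schedule[["inner"]],
    mean_displacement_mm = h$mean_displacement_mm[nrow(h)],
    mean_similarity = h$mean_similarity[nrow(h)],
    sharpness = template_sharpness(x)
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot a template's convergence history
#'
#' @param object A `brain_template`.
#' @param ... Unused.
#' @return A ggplot object (requires ggplot2).
#' @export
autoplot.brain_template <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for autoplot", call. = FALSE)
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$outer,
                                  y = .data$mean_displacement_mm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "outer iteration", y = "mean displacement (mm)",
                  title = "Template convergence")
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
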
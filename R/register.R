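# Pairwise diffeomorphic registration: greedy multiresolution demons
# optimization of a stationary velocity field under channel-weighted
# sum-of-squared-differences, with Gaussian regularization of both the
# update and the accumulated velocity.

#' Registration parameters
#'
#' @param pyramid_levels Number of resolution levels (>= 1); level 1 is the
#'   full resolution, each further level halves the grid.
#' @param iterations_per_level Iterations per level, coarsest first; length
#'   must equal `pyramid_levels`.
#' @param update_step Step length applied to the demons update (halved on
#'   steps that would increase the similarity).
#' @param velocity_smoothing_mm Gaussian scale for regularizing the demons
#'   update (every iteration) and the accumulated velocity (on entry to
#'   each pyramid level).  `NULL` = 2x the largest voxel spacing of the
#'   inputs.
#' @param squaring_steps Minimum scaling-and-squaring steps for
#'   exponentiation (auto-raised as needed).
#' @param similarity Similarity metric; only `"ssd"` is implemented.
#' @param channel_weights Nonnegative per-channel weights; `NULL` = equal.
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(pyramid_levels = 3L,
                                iterations_per_level = c(30L, 20L, 10L),
                                update_step = 1,
                                velocity_smoothing_mm = NULL,
                                squaring_steps = 0L,
                                similarity = "ssd",
                                channel_weights = NULL) {
  pyramid_levels <- as.integer(pyramid_levels)
  if (pyramid_levels < 1) stop("pyramid_levels must be >= 1", call. = FALSE)
  iterations_per_level <- as.integer(iterations_per_level)
  if (length(iterations_per_level) != pyramid_levels ||
      any(iterations_per_level < 1))
    stop("iterations_per_level must have one positive entry per level",
         call. = FALSE)
  if (update_step <= 0) stop("update_step must be positive", call. = FALSE)
  similarity <- match.arg(similarity, "ssd")
  structure(list(pyramid_levels = pyramid_levels,
                 iterations_per_level = iterations_per_level,
                 update_step = update_step,
                 velocity_smoothing_mm = velocity_smoothing_mm,
                 squaring_steps = as.integer(squaring_steps),
                 similarity = similarity,
                 channel_weights = channel_weights),
            class = "registration_params")
}

as_channel_list <- function(x) {
  if (is_volume(x)) list(x) else x
}

# Downsample a 3D array by an integer power of two with Gaussian
# anti-aliasing; grids are centre-aligned.
downsample_array <- function(a, spacing, factor) {
  if (factor == 1) return(a)
  dims <- dim(a)
  new_dims <- pmax(4L, as.integer(ceiling(dims / factor)))
  sm <- gaussian_smooth(a, 0.4 * spacing[1] * factor, spacing = spacing)
  g <- grid_coords(new_dims)
  x <- (g$x - (new_dims[1] - 1) / 2) * factor + (dims[1] - 1) / 2
  y <- (g$y - (new_dims[2] - 1) / 2) * factor + (dims[2] - 1) / 2
  z <- (g$z - (new_dims[3] - 1) / 2) * factor + (dims[3] - 1) / 2
  sample_at(sm, x, y, z)
}

# Resample a velocity array (voxel units) between centre-aligned grids,
# rescaling vectors for the change in voxel size.
resample_velocity <- function(v, from_dims, to_dims, factor_from, factor_to) {
  scale <- factor_from / factor_to
  out <- array(0, c(to_dims, 3L))
  g <- grid_coords(to_dims)
  x <- (g$x - (to_dims[1] - 1) / 2) / scale + (from_dims[1] - 1) / 2
  y <- (g$y - (to_dims[2] - 1) / 2) / scale + (from_dims[2] - 1) / 2
  z <- (g$z - (to_dims[3] - 1) / 2) / scale + (from_dims[3] - 1) / 2
  for (i in 1:3)
    out[, , , i] <- sample_at(array(v[, , , i], from_dims), x, y, z) * scale
  out
}

#' Diffeomorphic demons registration
#'
#' Registers `moving` to `fixed` (each a volume or a list of channel
#' volumes on one grid) by greedy multiresolution optimization of a
#' stationary velocity field: per iteration a demons update is computed
#' from the warped moving channels and Gaussian-smoothed, and steps that
#' would increase the similarity are rejected with the step size halved
#' (up to five times; a level stops when no step improves).  The
#' accumulated velocity is smoothed on entry to each pyramid level, so the
#' field is always a sum of smooth updates.  The reported similarity trace
#' is non-increasing within each level.
#'
#' @param moving,fixed A [volume()] or list of channel volumes (equal
#'   length, shared grid).
#' @param params A [registration_params()].
#' @param init_velocity Optional full-resolution [velocity_field()] used as
#'   warm start.
#' @return An object of class `registration`: list with `velocity`
#'   ([velocity_field()]), `deformation` ([deformation_field()], its
#'   exponential), and `trace` (tibble: level, iteration, similarity,
#'   step).
#' @export
register_pair <- function(moving, fixed, params = registration_params(),
                          init_velocity = NULL) {
  moving <- as_channel_list(moving)
  fixed <- as_channel_list(fixed)
  if (length(moving) != length(fixed))
    stop("moving and fixed must have the same number of channels",
         call. = FALSE)
  for (ch in seq_along(moving)) {
    stopifnot_same_grid(moving[[ch]], moving[[1]], "moving channels")
    stopifnot_same_grid(fixed[[ch]], moving[[1]], "fixed and moving channels")
  }
  nch <- length(moving)
  wts <- params$channel_weights %||% rep(1, nch)
  if (length(wts) != nch || any(wts < 0))
    stop("channel_weights must be nonnegative, one per channel",
         call. = FALSE)
  wts <- wts / sum(wts)
  # zero-weight channels contribute nothing to the similarity or the
  # update; drop them from the optimization
  keep <- wts > 0
  moving <- moving[keep]
  fixed <- fixed[keep]
  wts <- wts[keep]
  nch <- length(moving)
  dims <- dim(moving[[1]])
  spacing <- vol_spacing(moving[[1]])
  affine <- vol_affine(moving[[1]])
  sigma <- params$velocity_smoothing_mm %||% (2 * max(spacing))
  nlev <- params$pyramid_levels
  mov_a <- lapply(moving, vol_values)
  fix_a <- lapply(fixed, vol_values)
  trace <- list()
  v <- NULL
  prev_dims <- NULL
  prev_factor <- NULL
  for (lev in seq_len(nlev)) {
    factor <- 2^(nlev - lev)
    lsp <- spacing * factor
    mov_l <- lapply(mov_a, downsample_array, spacing = spacing,
                    factor = factor)
    fix_l <- lapply(fix_a, downsample_array, spacing = spacing,
                    factor = factor)
    ldims <- dim(mov_l[[1]])
    if (is.null(v)) {
      if (is.null(init_velocity)) {
        v <- array(0, c(ldims, 3L))
      } else {
        v <- resample_velocity(unclass(init_velocity), dims, ldims,
                               1, factor)
      }
    } else {
      v <- resample_velocity(v, prev_dims, ldims, prev_factor, factor)
    }
    step <- params$update_step
    eval_ssd <- function(vv) {
      d <- exp_velocity(velocity_field(vv, spacing = lsp),
                        params$squaring_steps)
      u <- as.double(unclass(d))
      warped <- lapply(mov_l, function(a)
        array(c_warp_scalar(as.double(a), u, as.integer(ldims)), ldims))
      ssd <- 0
      for (ch in seq_len(nch))
        ssd <- ssd + wts[ch] * mean((warped[[ch]] - fix_l[[ch]])^2)
      list(ssd = ssd, warped = warped)
    }
    cur <- eval_ssd(v)
    for (it in seq_len(params$iterations_per_level[lev])) {
      num1 <- num2 <- num3 <- den <- array(0, ldims)
      for (ch in seq_len(nch)) {
        diff <- cur$warped[[ch]] - fix_l[[ch]]
        g1 <- grad_axis(cur$warped[[ch]], 1)
        g2 <- grad_axis(cur$warped[[ch]], 2)
        g3 <- grad_axis(cur$warped[[ch]], 3)
        gsq <- g1^2 + g2^2 + g3^2
        num1 <- num1 - wts[ch] * diff * g1
        num2 <- num2 - wts[ch] * diff * g2
        num3 <- num3 - wts[ch] * diff * g3
        den <- den + wts[ch] * (gsq + diff^2)
      }
      den <- den + 1e-12
      upd <- array(0, c(ldims, 3L))
      upd[, , , 1] <- num1 / den
      upd[, , , 2] <- num2 / den
      upd[, , , 3] <- num3 / den
      for (i in 1:3)
        upd[, , , i] <- gaussian_smooth(array(upd[, , , i], ldims), sigma,
                                        spacing = lsp)
      accepted <- FALSE
      s <- step
      for (h in 0:5) {
        v_cand <- v + s * upd
        cand <- eval_ssd(v_cand)
        if (cand$ssd <= cur$ssd * (1 + 1e-8)) {
          v <- v_cand
          cur <- cand
          step <- s
          accepted <- TRUE
          break
        }
        s <- s / 2
      }
      trace[[length(trace) + 1L]] <- tibble::tibble(
        level = lev, iteration = it, similarity = cur$ssd, step = step,
        accepted = accepted)
      if (!accepted) {
        # no step of any tried size improves the similarity: the level has
        # converged (the candidate always includes the velocity
        # re-smoothing, which perturbs a converged field), so stop here
        # and keep the current velocity
        break
      }
    }
    prev_dims <- ldims
    prev_factor <- factor
  }
  if (!identical(dim(v)[1:3], dims))
    v <- resample_velocity(v, prev_dims, dims, prev_factor, 1)
  vf <- velocity_field(v, spacing = spacing, affine = affine,
                       smoothness_mm = sigma)
  structure(list(velocity = vf,
                 deformation = exp_velocity(vf, params$squaring_steps),
                 trace = do.call(rbind, trace)),
            class = "registration")
}

#' @export
print.registration <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("<registration> %d levels, %d iterations, final ssd %.4g\n",
              max(tr$level), nrow(tr), tr$similarity[nrow(tr)]))
  invisible(x)
}
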
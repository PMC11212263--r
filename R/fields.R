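# Stationary velocity fields and deformation fields.
#
# Both are stored as 4D arrays [n1, n2, n3, 3] of per-voxel 3-vectors in
# voxel units and index order, with `spacing` and `affine` attributes as for
# a volume.  Deformation fields use the backward (pull-back) convention:
# the warped image at voxel x samples the source at x + u(x).

new_field <- function(vectors, spacing, affine, class, smoothness_mm = NULL) {
  if (!is.array(vectors) || length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("field vectors must be an [n1, n2, n3, 3] array", call. = FALSE)
  storage.mode(vectors) <- "double"
  if (any(!is.finite(vectors)))
    stop("field components must all be finite", call. = FALSE)
  structure(vectors, spacing = as.numeric(spacing), affine = as.matrix(affine),
            smoothness_mm = smoothness_mm, class = class)
}

#' Construct a deformation field
#'
#' Per-voxel displacements `u(x)` in voxel units, backward convention: a
#' warped image's value at voxel `x` is sampled from the source at
#' `x + u(x)`.
#'
#' @param vectors `[n1, n2, n3, 3]` array of displacements in voxel units.
#' @param spacing Voxel spacing in mm (length 3).
#' @param affine 4x4 index-to-mm transform; defaults to a centred diagonal
#'   affine.
#' @return A `deformation_field`.
#' @export
deformation_field <- function(vectors, spacing = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- centered_affine(dim(vectors)[1:3], spacing)
  new_field(vectors, spacing, affine, "deformation_field")
}

#' Construct a stationary velocity field
#'
#' @inheritParams deformation_field
#' @param smoothness_mm Regularization scale (mm) used to produce the field,
#'   carried as metadata.
#' @return A `velocity_field`.
#' @export
velocity_field <- function(vectors, spacing = c(1, 1, 1), affine = NULL,
                           smoothness_mm = NULL) {
  if (is.null(affine)) affine <- centered_affine(dim(vectors)[1:3], spacing)
  new_field(vectors, spacing, affine, "velocity_field",
            smoothness_mm = smoothness_mm)
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x)
  m <- field_magnitude(x)
  cat(sprintf("<deformation_field> %d x %d x %d  mean |u| %.3f vox, max %.3f vox\n",
              d[1], d[2], d[3], mean(m), max(m)))
  invisible(x)
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x)
  m <- field_magnitude(x)
  cat(sprintf("<velocity_field> %d x %d x %d  mean |v| %.3f vox, max %.3f vox\n",
              d[1], d[2], d[3], mean(m), max(m)))
  invisible(x)
}

# Negate a field's vectors, preserving type and geometry.
negate_field <- function(f) {
  u <- unclass(f)
  v <- -u
  attributes(v) <- attributes(u)
  class(v) <- class(f)
  v
}

# Zero field helper
zero_field <- function(dims, spacing = c(1, 1, 1), affine = NULL,
                       type = c("deformation", "velocity")) {
  type <- match.arg(type)
  v <- array(0, c(dims, 3L))
  if (type == "deformation") deformation_field(v, spacing, affine)
  else velocity_field(v, spacing, affine)
}

field_component <- function(f, i) {
  d <- dim(f)[1:3]
  array(unclass(f)[(((i - 1) * prod(d)) + 1):(i * prod(d))], d)
}

# Per-voxel Euclidean norm in voxel units; returns a plain 3D array.
field_magnitude <- function(f) {
  u <- unclass(f)
  d <- dim(u)[1:3]
  array(sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2), d)
}

# Cached 0-based index coordinate arrays for a grid.
.grid_cache <- new.env(parent = emptyenv())
grid_coords <- function(dims) {
  key <- paste(dims, collapse = "x")
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    g <- list(
      x = array(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]), dims),
      y = array(rep(rep(seq_len(dims[2]) - 1, each = dims[1]), dims[3]), dims),
      z = array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]), dims)
    )
    .grid_cache[[key]] <- g
  }
  g
}

# Sample a 3D array at continuous 0-based voxel coordinates.
sample_at <- function(a, x, y, z, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  dims <- dim(a)
  f <- if (interp == "linear") c_trilinear else c_nearest
  out <- f(as.double(a), as.integer(dims), as.double(x), as.double(y),
           as.double(z))
  array(out, dim(x))
}

#' Exponentiate a stationary velocity field
#'
#' Computes the diffeomorphism `phi = exp(v)` by scaling and squaring:
#' `u0 = v / 2^N` followed by `N` self-compositions.  `N` is raised
#' automatically until the initial step's maximum displacement is at most
#' 0.5 voxel, so the per-step flow is well resolved.  Boundaries are handled
#' by edge clamping.
#'
#' @param v A [velocity_field()].
#' @param squaring_steps Minimum number of squarings; raised automatically
#'   (with a message) when the initial step would exceed 0.5 voxel.
#' @return A [deformation_field()].
#' @export
exp_velocity <- function(v, squaring_steps = 0L) {
  if (!inherits(v, "velocity_field"))
    stop("`v` must be a velocity_field", call. = FALSE)
  maxmag <- max(field_magnitude(v))
  n_req <- if (maxmag <= 0) 0L else max(0L, ceiling(log2(maxmag / 0.5)))
  n <- max(as.integer(squaring_steps), n_req)
  if (n > as.integer(squaring_steps) && squaring_steps > 0L)
    message(sprintf("exp_velocity: raising squaring steps %d -> %d",
                    as.integer(squaring_steps), n))
  u <- unclass(v) / 2^n
  dims <- dim(u)[1:3]
  for (s in seq_len(n))
    u <- array(c_field_compose(as.double(u), as.double(u),
                               as.integer(dims)), c(dims, 3L))
  deformation_field(u, spacing = attr(v, "spacing"), affine = attr(v, "affine"))
}

#' Compose two deformation fields
#'
#' Returns the deformation equivalent to warping first by `outer` and then
#' sampling through `inner`:
#' `u(x) = u_outer(x) + u_inner(x + u_outer(x))`, with `inner`'s displacement
#' interpolated linearly and edge-clamped.  With backward-convention fields
#' this is the displacement of the composite map
#' `phi_inner(phi_outer(x))`, i.e. `warp(warp(vol, inner), outer)` equals
#' `warp(vol, compose_fields(outer, inner))`.
#'
#' @param outer,inner [deformation_field()]s on the same grid.
#' @return A [deformation_field()].
#' @export
compose_fields <- function(outer, inner) {
  stopifnot_same_grid(outer, inner, "deformation fields")
  dims <- dim(outer)[1:3]
  u <- array(c_field_compose(as.double(unclass(outer)),
                             as.double(unclass(inner)),
                             as.integer(dims)), c(dims, 3L))
  deformation_field(u, spacing = attr(outer, "spacing"),
                    affine = attr(outer, "affine"))
}

#' Warp a volume through a deformation field
#'
#' Backward warping: `out(x) = vol(x + u(x))`.  Out-of-grid samples take the
#' nearest edge value and are flagged in a companion validity mask attached
#' as the `"validity"` attribute.
#'
#' @param vol A [volume()].
#' @param d A [deformation_field()] on the same grid.
#' @param interp `"linear"` or `"nearest"`.  Label volumes must use
#'   `"nearest"`.
#' @return A warped `volume` with a logical `"validity"` attribute.
#' @export
warp_volume <- function(vol, d, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  if (!is_volume(vol)) stop("`vol` must be a volume", call. = FALSE)
  stopifnot_same_grid(vol, d, "volume and deformation")
  if (vol_kind(vol) == "label" && interp != "nearest")
    stop("label volumes must be warped with nearest-neighbour interpolation",
         call. = FALSE)
  u <- unclass(d)
  dims <- dim(vol)
  g <- grid_coords(dims)
  x <- g$x + u[, , , 1]; y <- g$y + u[, , , 2]; z <- g$z + u[, , , 3]
  out <- sample_at(vol_values(vol), x, y, z, interp)
  valid <- x >= 0 & x <= dims[1] - 1 & y >= 0 & y <= dims[2] - 1 &
    z >= 0 & z <= dims[3] - 1
  res <- vol_like(out, vol)
  attr(res, "validity") <- valid
  res
}

#' Separable Gaussian smoothing of a 3D array or volume
#'
#' Boundary handled by kernel renormalization (equivalent to redistributing
#' truncated mass).  `sigma_mm = 0` returns the input unchanged.
#'
#' @param x A 3D array or [volume()].
#' @param sigma_mm Gaussian standard deviation in mm (scalar).
#' @param spacing Voxel spacing (taken from `x` when it is a volume).
#' @return Same type as `x`.
#' @export
gaussian_smooth <- function(x, sigma_mm, spacing = attr(x, "spacing")) {
  if (sigma_mm < 0) stop("sigma_mm must be >= 0", call. = FALSE)
  if (sigma_mm == 0) return(x)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  a <- if (is_volume(x)) vol_values(x) else x
  dims <- dim(a)
  for (ax in 1:3) {
    s_vox <- sigma_mm / spacing[ax]
    if (s_vox < 1e-8) next
    S <- smoothing_matrix(dims[ax], s_vox)
    a <- apply_axis_matrix(a, S, ax)
  }
  if (is_volume(x)) vol_like(a, x) else a
}

smooth_field_mm <- function(f, sigma_mm) {
  if (sigma_mm <= 0) return(f)
  u <- unclass(f)
  dims <- dim(u)[1:3]
  spacing <- attr(f, "spacing")
  for (i in 1:3) {
    u[, , , i] <- gaussian_smooth(array(u[, , , i], dims), sigma_mm,
                                  spacing = spacing)
  }
  attributes(u) <- attributes(unclass(f))
  class(u) <- class(f)
  u
}

# Dense 1D smoothing matrix (rows renormalized at the edges).
.smat_cache <- new.env(parent = emptyenv())
smoothing_matrix <- function(n, sigma_vox) {
  key <- sprintf("%d_%.6g", n, sigma_vox)
  S <- .smat_cache[[key]]
  if (!is.null(S)) return(S)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    S[i, j[ok]] <- k[ok]
    S[i, ] <- S[i, ] / sum(S[i, ])
  }
  .smat_cache[[key]] <- S
  S
}

apply_axis_matrix <- function(a, S, axis) {
  dims <- dim(a)
  if (axis == 1) {
    array(S %*% matrix(a, dims[1], dims[2] * dims[3]), dims)
  } else if (axis == 2) {
    b <- aperm(a, c(2, 1, 3))
    b <- array(S %*% matrix(b, dims[2], dims[1] * dims[3]),
               c(dims[2], dims[1], dims[3]))
    aperm(b, c(2, 1, 3))
  } else {
    array(matrix(a, dims[1] * dims[2], dims[3]) %*% t(S), dims)
  }
}
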
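# Deformation metrics: per-voxel displacement magnitude, (log) Jacobian
# determinant, transport of metric maps to a common reference space, and
# atlas-region summaries with a minimum-volume exclusion rule.

# Gradient of a 3D array along one axis in index space: central differences
# in the interior, one-sided at the two boundary slices.
grad_axis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  g <- array(0, d)
  idx <- function(i) switch(axis,
                            a[i, , , drop = FALSE],
                            a[, i, , drop = FALSE],
                            a[, , i, drop = FALSE])
  asn <- function(g, i, val) {
    switch(axis,
           g[i, , ] <- val,
           g[, i, ] <- val,
           g[, , i] <- val)
    g
  }
  if (n == 1) return(g)
  interior <- 2:(n - 1)
  if (n > 2) {
    val <- (idx(3:n) - idx(1:(n - 2))) / 2
    g <- asn(g, interior, val)
  }
  g <- asn(g, 1, idx(2) - idx(1))
  g <- asn(g, n, idx(n) - idx(n - 1))
  g
}

#' Displacement-magnitude map
#'
#' Per-voxel Euclidean distance, in mm, between a voxel's original position
#' and the position it samples through the deformation:
#' `sqrt(sum_i (u_i * spacing_i)^2)`.
#'
#' @param d A [deformation_field()].
#' @return A `volume` of kind `"metric"` (mm).
#' @export
displacement_map <- function(d) {
  if (!inherits(d, "deformation_field"))
    stop("`d` must be a deformation_field", call. = FALSE)
  u <- unclass(d)
  sp <- attr(d, "spacing")
  m <- sqrt((u[, , , 1] * sp[1])^2 + (u[, , , 2] * sp[2])^2 +
              (u[, , , 3] * sp[3])^2)
  volume(array(m, dim(u)[1:3]), spacing = sp, affine = attr(d, "affine"),
         kind = "metric")
}

#' Jacobian-determinant map of a deformation
#'
#' Computes `det(I + grad(u))` per voxel with central differences (one-sided
#' at the boundary).  The determinant is of the index-space map, so voxel
#' spacing cancels.  Voxels with determinant below `1e-6` are set to `NA`
#' (missing) and counted in the `"n_nonpositive"` attribute; if more than 1%
#' of interior voxels are nonpositive the field is rejected as
#' non-diffeomorphic.
#'
#' @param d A [deformation_field()].
#' @param log_output If `TRUE`, return the natural log of the determinant.
#' @return A `volume` of kind `"metric"` with attributes `"n_nonpositive"`
#'   and `"interior"` (logical mask of interior voxels).
#' @export
jacobian_map <- function(d, log_output = FALSE) {
  if (!inherits(d, "deformation_field"))
    stop("`d` must be a deformation_field", call. = FALSE)
  u <- unclass(d)
  dims <- dim(u)[1:3]
  J <- vector("list", 9)
  for (i in 1:3) {
    ui <- array(u[, , , i], dims)
    for (ax in 1:3) {
      g <- grad_axis(ui, ax)
      if (i == ax) g <- g + 1
      J[[(i - 1) * 3 + ax]] <- g
    }
  }
  # det of [ J[1] J[2] J[3] ; J[4] J[5] J[6] ; J[7] J[8] J[9] ]
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  interior <- array(FALSE, dims)
  interior[2:(dims[1] - 1), 2:(dims[2] - 1), 2:(dims[3] - 1)] <- TRUE
  bad <- det <= 1e-6
  n_bad_int <- sum(bad & interior)
  if (n_bad_int > 0.01 * sum(interior))
    stop(sprintf(
      "field is not diffeomorphic: %d of %d interior voxels (%.1f%%) have nonpositive Jacobian",
      n_bad_int, sum(interior), 100 * n_bad_int / sum(interior)),
      call. = FALSE)
  out <- if (log_output) {
    l <- det
    l[!bad] <- log(det[!bad])
    l
  } else det
  out[bad] <- 0  # placeholder; flagged missing below
  res <- volume(out, spacing = attr(d, "spacing"), affine = attr(d, "affine"),
                kind = "metric")
  miss <- bad
  attr(res, "missing") <- miss
  attr(res, "n_nonpositive") <- sum(bad)
  attr(res, "interior") <- interior
  res
}

#' Absolute log-Jacobian map
#'
#' Voxelwise absolute value of a log-Jacobian map, weighting volume expansion
#' and contraction equally so that region means cannot cancel.  Missingness
#' flags propagate.
#'
#' @param logj A log-Jacobian `volume` (kind `"metric"`), as returned by
#'   `jacobian_map(d, log_output = TRUE)`.
#' @return A `volume` of kind `"metric"`.
#' @export
abs_log_jacobian <- function(logj) {
  if (!is_volume(logj) || vol_kind(logj) != "metric")
    stop("`logj` must be a metric volume", call. = FALSE)
  res <- vol_like(abs(vol_values(logj)), logj)
  attr(res, "missing") <- attr(logj, "missing")
  attr(res, "interior") <- attr(logj, "interior")
  res
}

#' Resample a metric map into a common reference space
#'
#' Warps `map` onto the common reference grid through `bridge`, a deformation
#' defined on the reference grid that maps reference coordinates into the
#' map's native space (e.g. obtained by registering the map's template to the
#' reference template).  Linear interpolation; the validity mask is carried.
#'
#' @param map A metric `volume`.
#' @param bridge A [deformation_field()] on the reference grid.
#' @return A `volume` on the reference grid.
#' @export
to_common_space <- function(map, bridge) {
  if (!is_volume(map)) stop("`map` must be a volume", call. = FALSE)
  stopifnot_same_grid(map, bridge, "map and bridge")
  warp_volume(map, bridge, interp = "linear")
}

#' Atlas-region deformation summary
#'
#' Means of a displacement map and an absolute-log-Jacobian map over each
#' atlas region, excluding regions whose volume falls below
#' `min_volume_mm3` (default 500).  Voxels flagged missing in either map are
#' excluded from the means and counted.
#'
#' @param map_displacement Displacement `volume` (mm).
#' @param map_abslogj Absolute log-Jacobian `volume`.
#' @param atlas A [label_atlas()] sharing the maps' grid.
#' @param min_volume_mm3 Exclusion threshold in mm^3.
#' @return A tibble with one row per retained region: `region_id`, `name`,
#'   `volume_mm3`, `mean_displacement_mm`, `mean_abs_log_jacobian`,
#'   `n_voxels_used`.  The threshold and the excluded regions are attached
#'   as attributes.
#' @export
region_summary <- function(map_displacement, map_abslogj, atlas,
                           min_volume_mm3 = 500) {
  if (!inherits(atlas, "label_atlas"))
    stop("`atlas` must be a label_atlas", call. = FALSE)
  stopifnot_same_grid(map_displacement, atlas$labels, "maps and atlas")
  stopifnot_same_grid(map_abslogj, atlas$labels, "maps and atlas")
  keep <- atlas$regions$volume_mm3 >= min_volume_mm3
  if (!any(keep))
    stop(sprintf("no region survives the %g mm^3 volume filter",
                 min_volume_mm3), call. = FALSE)
  lab <- as.integer(vol_values(atlas$labels))
  disp <- as.double(vol_values(map_displacement))
  alj <- as.double(vol_values(map_abslogj))
  miss <- attr(map_displacement, "missing")
  miss2 <- attr(map_abslogj, "missing")
  bad <- rep(FALSE, length(lab))
  if (!is.null(miss)) bad <- bad | as.logical(miss)
  if (!is.null(miss2)) bad <- bad | as.logical(miss2)
  use <- lab > 0L & !bad
  ids <- atlas$regions$region_id[keep]
  f <- factor(lab[use], levels = ids)
  ok <- !is.na(f)
  mean_d <- tapply(disp[use][ok], f[ok], mean)
  mean_j <- tapply(alj[use][ok], f[ok], mean)
  n_used <- tapply(rep(1, sum(ok)), f[ok], sum)
  out <- tibble::tibble(
    region_id = ids,
    name = atlas$regions$name[keep],
    volume_mm3 = atlas$regions$volume_mm3[keep],
    mean_displacement_mm = as.numeric(mean_d),
    mean_abs_log_jacobian = as.numeric(mean_j),
    n_voxels_used = as.integer(ifelse(is.na(n_used), 0L, n_used))
  )
  attr(out, "min_volume_mm3") <- min_volume_mm3
  attr(out, "excluded_regions") <- atlas$regions$region_id[!keep]
  attr(out, "log_base") <- "natural"
  out
}
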
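#' @useDynLib tmplkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif sd pt qt kmeans quantile
NULL

#' Construct a 3D volume
#'
#' A `volume` is the package's basic image container: a 3D numeric array plus
#' voxel spacing in mm, a 4x4 world (index-to-mm) affine following the NIfTI
#' convention with 0-based voxel indices, and a `kind` tag describing the
#' values it holds.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, mm per voxel along each axis (all > 0).
#' @param affine 4x4 matrix mapping 0-based voxel indices to mm coordinates.
#'   Defaults to a diagonal affine with the grid centre at the world origin.
#' @param kind One of `"intensity"`, `"probability"`, `"label"`, `"metric"`.
#'
#' @return An object of class `volume`.
#' @export
volume <- function(values, spacing = c(1, 1, 1), affine = NULL,
                   kind = c("intensity", "probability", "label", "metric")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers", call. = FALSE)
  if (is.null(affine)) affine <- centered_affine(dim(values), spacing)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("volume values must all be finite", call. = FALSE)
  if (kind == "probability" && (min(values) < 0 || max(values) > 1))
    stop("probability volumes must have values in [0, 1]", call. = FALSE)
  if (kind == "label" && any(values < 0 | values != round(values)))
    stop("label volumes must contain nonnegative integers", call. = FALSE)
  structure(values, spacing = spacing, affine = affine, kind = kind,
            class = "volume")
}

# Diagonal index->mm affine putting the centre of the grid at the world origin.
centered_affine <- function(dims, spacing) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(spacing, 3)
  a[1:3, 4] <- -(dims - 1) / 2 * spacing
  a
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume> %s  %d x %d x %d voxels  spacing %s mm\n",
              attr(x, "kind"), d[1], d[2], d[3],
              paste(signif(attr(x, "spacing"), 4), collapse = " x ")))
  rng <- range(x)
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @rdname volume
#' @param x Object to test or coerce.
#' @export
is_volume <- function(x) inherits(x, "volume")

vol_spacing <- function(x) attr(x, "spacing")
vol_affine <- function(x) attr(x, "affine")
vol_kind <- function(x) attr(x, "kind")

vol_values <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x))
  a
}

# Rebuild a volume with new values but the geometry of `like`.
vol_like <- function(values, like, kind = vol_kind(like)) {
  volume(values, spacing = vol_spacing(like), affine = vol_affine(like),
         kind = kind)
}

stopifnot_same_grid <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:3], dim(b)[1:3]))
    stop(sprintf("%s must share one grid (dims %s vs %s)", what,
                 paste(dim(a)[1:3], collapse = "x"),
                 paste(dim(b)[1:3], collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Read a NIfTI image
#'
#' Reads a `.nii` or `.nii.gz` file.  3D images are returned as a [volume()];
#' 4D images (vector fields stored with the vector dimension last) are
#' returned as a raw 4D array with `spacing` and `affine` attributes, ready
#' for [deformation_field()] or [velocity_field()].  Values, spacing and the
#' world transform are taken from the header unmodified; nothing is resampled.
#'
#' @param path Path to a NIfTI file.
#' @param kind Kind tag for the returned volume (3D images only).
#' @return A `volume`, or a 4D array with geometry attributes.
#' @export
read_volume <- function(path, kind = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "not a readable NIfTI file: %s (%s)", path,
                    conditionMessage(e)), call. = FALSE))
  dims <- dim(img)
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dims)
  if (length(dims) == 3L) {
    if (is.null(kind)) {
      # heuristic default; callers that care should pass `kind`
      kind <- if (all(vals == round(vals)) && min(vals) >= 0 &&
                  max(vals) <= 65535) "label" else "intensity"
    }
    volume(vals, spacing = spacing, affine = affine, kind = kind)
  } else if (length(dims) == 4L) {
    structure(vals, spacing = spacing, affine = affine)
  } else {
    stop(sprintf("unsupported NIfTI dimensionality: %dD", length(dims)),
         call. = FALSE)
  }
}

#' Write a NIfTI image
#'
#' Writes a [volume()] (or a 4D vector-field array carrying `spacing`/`affine`
#' attributes) to NIfTI.  Scalar and metric volumes are stored as 32-bit
#' float, labels as the smallest sufficient unsigned integer, vector fields
#' as 32-bit float 4D images.  Values must be finite.
#'
#' @param vol A `volume`, `deformation_field`, `velocity_field`, or 4D array
#'   with geometry attributes.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vals <- unclass(vol)
  spacing <- attr(vol, "spacing")
  affine <- attr(vol, "affine")
  if (is.null(spacing) || is.null(affine))
    stop("`vol` must carry spacing and affine attributes", call. = FALSE)
  attributes(vals) <- list(dim = dim(vol))
  if (any(!is.finite(vals)))
    stop("refusing to write non-finite values", call. = FALSE)
  kind <- attr(vol, "kind")
  datatype <- if (identical(kind, "label")) {
    if (max(vals) <= 255) "uint8" else if (max(vals) <= 65535) "uint16"
    else "int32"
  } else "float"
  if (inherits(vol, "deformation_field") ||
      inherits(vol, "velocity_field")) {
    # record the field convention beside the image so the direction of a
    # stored field is never ambiguous
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (!identical(sidecar, path) &&
        requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(list(
        field_type = class(vol)[1],
        displacement_convention = "backward",
        units = "voxel",
        component_order = c("axis1", "axis2", "axis3")
      ), sidecar, auto_unbox = TRUE)
    }
  }
  attr(vals, "pixdim") <- c(spacing, rep(1, length(dim(vals)) - 3L))
  img <- RNifti::asNifti(vals, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
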
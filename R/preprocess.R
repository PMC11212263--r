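# Preprocessing chain: canonical reorientation by principal axes, isotropic
# reslicing, polynomial log-bias correction, Gaussian-mixture tissue
# segmentation, and whole-brain extent measurement with shape ratios.

default_mask_threshold <- function(vol) {
  0.10 * as.numeric(quantile(vol_values(vol), 0.99))
}

mask_from_threshold <- function(vol, mask_threshold) {
  if (is.null(mask_threshold)) mask_threshold <- default_mask_threshold(vol)
  m <- vol_values(vol) > mask_threshold
  if (!any(m)) stop("thresholded mask is empty", call. = FALSE)
  m
}

#' Reorient a volume along its principal axes
#'
#' Canonical-orientation surrogate for landmark-based reorientation:
#' the thresholded mask's principal axes are aligned with the grid axes
#' (largest spread -> length axis 2, second -> width axis 1, third ->
#' height axis 3) and its centroid is moved to the grid centre.  Nearly
#' spherical masks (largest/smallest axis spread ratio < 1.05) are left
#' unrotated with a warning.
#'
#' @param vol A [volume()].
#' @param mask_threshold Intensity threshold for the mask (default 10% of
#'   the 99th percentile).
#' @return List with `volume` (reoriented) and `transform` (4x4 rigid world
#'   transform applied, output world -> input world).
#' @export
reorient_principal_axes <- function(vol, mask_threshold = NULL) {
  m <- mask_from_threshold(vol, mask_threshold)
  dims <- dim(vol)
  aff <- vol_affine(vol)
  g <- grid_coords(dims)
  idx <- which(m)
  P <- cbind(g$x[idx], g$y[idx], g$z[idx])
  W <- P %*% t(aff[1:3, 1:3])
  W <- sweep(W, 2, -aff[1:3, 4], `-`)
  ctr <- colMeans(W)
  C <- crossprod(sweep(W, 2, ctr)) / nrow(W)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[1] / e$values[3] < 1.05^2) {
    warning("near-degenerate principal axes; applying identity rotation")
    R <- diag(3)
  } else {
    # eigenvectors by descending spread: 1st -> axis 2 (length),
    # 2nd -> axis 1 (width), 3rd -> axis 3 (height)
    V <- e$vectors[, c(2, 1, 3)]
    for (k in 1:3) if (V[k, k] < 0) V[, k] <- -V[, k]
    if (det(V) < 0) V[, 3] <- -V[, 3]
    R <- V  # columns: output axis directions in input world frame
  }
  out_aff <- centered_affine(dims, vol_spacing(vol))
  # output voxel x -> output world p -> input world ctr + R p -> input voxel
  p_out <- cbind(as.double(g$x), as.double(g$y), as.double(g$z)) %*%
    t(out_aff[1:3, 1:3])
  p_out <- sweep(p_out, 2, out_aff[1:3, 4], `+`)
  p_in <- sweep(p_out %*% t(R), 2, ctr, `+`)
  Ainv <- solve(aff)
  v_in <- sweep(p_in, 2, aff[1:3, 4]) %*% t(Ainv[1:3, 1:3])
  vals <- sample_at(vol_values(vol),
                    array(v_in[, 1], dims), array(v_in[, 2], dims),
                    array(v_in[, 3], dims),
                    interp = if (vol_kind(vol) == "label") "nearest"
                    else "linear")
  transform <- diag(4)
  transform[1:3, 1:3] <- R
  transform[1:3, 4] <- ctr
  list(volume = volume(vals, spacing = vol_spacing(vol), affine = out_aff,
                       kind = vol_kind(vol)),
       transform = transform)
}

#' Resample a volume to isotropic spacing
#'
#' The output grid covers the same world extent with `target_mm` isotropic
#' voxels; the world transform is updated so content keeps its world
#' coordinates.  When the input already has the requested spacing the values
#' are returned unchanged.
#'
#' @param vol A [volume()].
#' @param target_mm Target isotropic voxel size (> 0).
#' @param interp `"linear"` or `"nearest"`.
#' @return A resampled `volume`.
#' @export
resample_isotropic <- function(vol, target_mm,
                               interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  if (!is.numeric(target_mm) || target_mm <= 0)
    stop("target_mm must be positive", call. = FALSE)
  sp <- vol_spacing(vol)
  dims <- dim(vol)
  if (all(abs(sp - target_mm) < 1e-12)) return(vol)
  extent <- dims * sp
  new_dims <- pmax(1L, as.integer(round(extent / target_mm)))
  aff <- vol_affine(vol)
  dir <- aff[1:3, 1:3] %*% diag(1 / sp, 3)  # unit direction cosines
  new_aff <- diag(4)
  new_aff[1:3, 1:3] <- dir %*% diag(rep(target_mm, 3), 3)
  new_aff[1:3, 4] <- aff[1:3, 4]
  g <- grid_coords(new_dims)
  # new index -> world -> old index; with shared origin this reduces to a
  # per-axis scale of index coordinates
  scale <- target_mm / sp
  x <- g$x * scale[1]; y <- g$y * scale[2]; z <- g$z * scale[3]
  vals <- sample_at(vol_values(vol), x, y, z, interp)
  volume(vals, spacing = rep(target_mm, 3), affine = new_aff,
         kind = vol_kind(vol))
}

#' Polynomial bias-field correction
#'
#' Fits a degree-`degree` polynomial to log-intensities inside the mask and
#' divides it out: `corrected = vol / bias`, with the bias field normalized
#' to mean 1 inside the mask so the mean intensity is preserved.
#'
#' @param vol A strictly positive (inside the mask) intensity [volume()].
#' @param mask Logical array or mask `volume` on the same grid.
#' @param degree Polynomial degree (default 2).
#' @return List with `corrected` and `bias` volumes.
#' @export
bias_correct <- function(vol, mask, degree = 2L) {
  m <- if (is_volume(mask)) vol_values(mask) > 0 else as.logical(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  vals <- vol_values(vol)
  if (any(vals[m] <= 0))
    stop("intensities inside the mask must be strictly positive; mask out zeros first",
         call. = FALSE)
  dims <- dim(vol)
  g <- grid_coords(dims)
  nx <- 2 * g$x / max(dims[1] - 1, 1) - 1
  ny <- 2 * g$y / max(dims[2] - 1, 1) - 1
  nz <- 2 * g$z / max(dims[3] - 1, 1) - 1
  X <- poly_design(nx[m], ny[m], nz[m], degree)
  fit <- stats::lm.fit(X, log(vals[m]))
  Xall <- poly_design(as.double(nx), as.double(ny), as.double(nz), degree)
  f <- array(Xall %*% fit$coefficients, dims)
  b <- exp(f)
  b <- b / mean(b[m])
  corrected <- vals / b
  # restore the mask mean exactly (fold the factor into the bias so that
  # corrected * bias == vol still holds)
  s <- mean(vals[m]) / mean(corrected[m])
  corrected <- corrected * s
  b <- b / s
  list(corrected = vol_like(corrected, vol),
       bias = vol_like(b, vol, kind = "intensity"))
}

poly_design <- function(x, y, z, degree) {
  cols <- list(rep(1, length(x)))
  for (total in seq_len(degree)) {
    for (i in total:0) for (j in (total - i):0) {
      k <- total - i - j
      cols[[length(cols) + 1L]] <- x^i * y^j * z^k
    }
  }
  do.call(cbind, cols)
}

#' Gaussian-mixture tissue segmentation
#'
#' Fits an `n_classes` univariate Gaussian intensity mixture inside the mask
#' (k-means initialization, EM to a log-likelihood tolerance of 1e-6 or 200
#' iterations) and returns posterior probability maps ordered by ascending
#' class mean, plus `1 - mask` as background.  Per-voxel class sums plus
#' background equal 1 within 1e-6.
#'
#' @param vol Intensity [volume()].
#' @param mask Logical array or mask volume.
#' @param n_classes Number of tissue classes (>= 2).
#' @param seed Seed for the k-means initialization.
#' @return A [tissue_maps()] whose maps are named `class_1` (darkest) to
#'   `class_k` (brightest).
#' @export
segment_tissues <- function(vol, mask, n_classes = 3L, seed = 1L) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  m <- if (is_volume(mask)) vol_values(mask) > 0 else as.logical(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  x <- vol_values(vol)[m]
  if (sd(x) < 1e-12)
    stop("degenerate mixture: image is constant inside the mask",
         call. = FALSE)
  with_seed(seed, {
    km <- kmeans(x, centers = n_classes, nstart = 5, iter.max = 50)
    mu <- as.numeric(km$centers)
    sig <- vapply(seq_len(n_classes), function(k) {
      s <- sd(x[km$cluster == k])
      if (!is.finite(s) || s < 1e-8) 1e-3 * max(sd(x), 1e-6) else s
    }, 0)
    pi_k <- as.numeric(table(factor(km$cluster, seq_len(n_classes)))) /
      length(x)
    loglik <- -Inf
    converged <- FALSE
    for (it in seq_len(200)) {
      dens <- vapply(seq_len(n_classes), function(k)
        pi_k[k] * stats::dnorm(x, mu[k], sig[k]), numeric(length(x)))
      tot <- rowSums(dens)
      tot[tot < 1e-300] <- 1e-300
      ll <- sum(log(tot))
      resp <- dens / tot
      nk <- colSums(resp)
      pi_k <- nk / length(x)
      mu <- colSums(resp * x) / nk
      sig <- sqrt(colSums(resp * (x - rep(mu, each = length(x)))^2) / nk)
      sig <- pmax(sig, 1e-6 * max(sd(x), 1e-6))
      if (is.finite(loglik) && abs(ll - loglik) < 1e-6 * abs(ll)) {
        converged <- TRUE
        loglik <- ll
        break
      }
      loglik <- ll
    }
    if (!converged && it == 200)
      stop("EM did not converge within 200 iterations", call. = FALSE)
    ord <- order(mu)
    dens <- vapply(ord, function(k)
      pi_k[k] * stats::dnorm(x, mu[k], sig[k]), numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    resp <- dens / tot
    dims <- dim(vol)
    maps <- lapply(seq_len(n_classes), function(k) {
      p <- array(0, dims)
      p[m] <- resp[, k]
      vol_like(p, vol, kind = "probability")
    })
    names(maps) <- sprintf("class_%d", seq_len(n_classes))
    bg <- vol_like(array(as.numeric(!m), dims), vol, kind = "probability")
    res <- tissue_maps(maps, bg)
    attr(res, "means") <- mu[ord]
    attr(res, "sds") <- sig[ord]
    attr(res, "iterations") <- it
    res
  })
}

#' Bias-correct a phantom subject's T1 channel
#'
#' Applies [bias_correct()] to a subject's T1 before registration or
#' template construction, mirroring the usual preprocessing order (bias
#' correction precedes alignment).  The bias is estimated inside the
#' brightest intensity class only (found by k-means), where the true
#' intensity is approximately flat, so the fit captures the smooth
#' multiplicative inhomogeneity rather than genuine tissue contrast; the
#' estimated field is then divided out of the whole image.
#'
#' @param subject A [generate_subject()] result.
#' @param degree Polynomial degree of the log-bias model.
#' @param n_classes Number of intensity classes for the bright-class mask.
#' @return The subject with `t1` replaced by the corrected volume (clamped
#'   to be nonnegative) and the estimated bias attached as attribute
#'   `"bias"`.
#' @export
preprocess_phantom <- function(subject, degree = 2L, n_classes = 3L) {
  t1 <- subject$t1
  vals <- vol_values(t1)
  head_mask <- vals > default_mask_threshold(t1)
  km <- with_seed(1L, suppressWarnings(
    kmeans(vals[head_mask], centers = n_classes, nstart = 3,
           iter.max = 50)))
  bright <- which(head_mask)[km$cluster == which.max(km$centers)]
  m <- array(FALSE, dim(t1)); m[bright] <- TRUE
  floor_val <- 1e-3 * max(vals)
  safe <- vol_like(pmax(vals, floor_val), t1)
  bc <- bias_correct(safe, m, degree = degree)
  corrected <- vals / vol_values(bc$bias)
  subject$t1 <- vol_like(pmax(corrected, 0), t1)
  attr(subject, "bias") <- bc$bias
  subject
}

#' Default registration channel weights for phantom subjects
#'
#' Registration of phantom subjects uses the T1 plus the three tissue
#' probability channels.  By default the flow is driven by the tissue
#' channels alone (T1 weight 0): the greedy SSD demons treats any residual
#' intensity inhomogeneity in T1 as geometry, whereas the tissue
#' probability maps are intensity-calibrated by construction.  This mirrors
#' flow estimation from tissue classes in groupwise tissue-based template
#' pipelines; the T1 channel is still warped and averaged into templates.
#'
#' @param n_tissue Number of tissue channels following the T1 channel.
#' @param t1_weight Relative weight of the T1 channel.
#' @return A numeric weight vector (T1 first).
#' @export
phantom_channel_weights <- function(n_tissue = 3L, t1_weight = 0) {
  c(t1_weight, rep(1, n_tissue))
}

#' Measure whole-brain extents and shape ratios
#'
#' Height, length and width are the world-space distances spanned by the
#' thresholded mask along the height (axis 3), length (axis 2) and width
#' (axis 1) grid axes: `(max index - min index + 1) * spacing`.  The
#' width-to-length, height-to-length and height-to-width ratios follow.
#'
#' @param vol A [volume()] (canonically oriented; see
#'   [reorient_principal_axes()]).
#' @param mask_threshold Intensity threshold (default 10% of the 99th
#'   percentile).
#' @return A one-row tibble: `height_mm`, `length_mm`, `width_mm`,
#'   `wl_ratio`, `hl_ratio`, `hw_ratio`.
#' @export
measure_extent <- function(vol, mask_threshold = NULL) {
  m <- mask_from_threshold(vol, mask_threshold)
  sp <- vol_spacing(vol)
  rng <- function(ax) {
    pres <- apply(m, ax, any)
    w <- which(pres)
    (max(w) - min(w) + 1) * sp[ax]
  }
  width <- rng(1); length_ <- rng(2); height <- rng(3)
  tibble::tibble(
    height_mm = height, length_mm = length_, width_mm = width,
    wl_ratio = width / length_, hl_ratio = height / length_,
    hw_ratio = height / width
  )
}
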
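# Shared small fixtures, built in code.

# A tiny population spec on a coarse grid; fast enough for unit tests.
tiny_spec <- function(n_men = 1L, n_women = 1L, ...) {
  phantom_spec(strata = data.frame(label = "60-64", n_men = n_men,
                                   n_women = n_women), ...)
}

# Smooth random velocity array in voxel units (plain array).
smooth_random_velocity <- function(dims, sigma_vox = 4, max_vox = 2,
                                   seed = 1) {
  withr::with_seed(seed, {
    v <- array(rnorm(prod(dims) * 3), c(dims, 3L))
    for (i in 1:3)
      v[, , , i] <- gaussian_smooth(array(v[, , , i], dims), sigma_vox,
                                    spacing = c(1, 1, 1))
    mag <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
    v * (max_vox / max(mag))
  })
}

interior_idx <- function(dims, margin = 4) {
  lapply(dims, function(n) (margin + 1):(n - margin))
}

field_values <- function(f) unclass(f)

# Mean magnitude of a field over an optional mask.
mean_mag <- function(f, mask = NULL) {
  m <- sqrt(field_values(f)[, , , 1]^2 + field_values(f)[, , , 2]^2 +
              field_values(f)[, , , 3]^2)
  if (is.null(mask)) mean(m) else mean(m[mask])
}

# Brute-force 1024-step Euler integration of a stationary velocity field;
# the independent oracle for exp_velocity.
euler_flow <- function(v, n_steps = 1024L) {
  vv <- unclass(v)
  dims <- dim(vv)[1:3]
  u <- array(0, c(dims, 3L))
  g <- expand.grid(x = seq_len(dims[1]) - 1, y = seq_len(dims[2]) - 1,
                   z = seq_len(dims[3]) - 1)
  x <- array(g$x, dims); y <- array(g$y, dims); z <- array(g$z, dims)
  comp <- lapply(1:3, function(i) array(vv[, , , i], dims))
  tri <- function(a, cx, cy, cz) {
    tmplkit:::sample_at(a, cx, cy, cz)
  }
  for (s in seq_len(n_steps)) {
    cx <- x + u[, , , 1]; cy <- y + u[, , , 2]; cz <- z + u[, , , 3]
    for (i in 1:3)
      u[, , , i] <- u[, , , i] + tri(comp[[i]], cx, cy, cz) / n_steps
  }
  u
}
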
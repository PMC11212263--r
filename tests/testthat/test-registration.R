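test_that("exp_velocity handles degenerate and constant flows exactly", {
  dims <- c(16L, 16L, 16L)
  z <- exp_velocity(velocity_field(array(0, c(dims, 3))))
  expect_true(all(unclass(z) == 0))

  v <- array(0, c(dims, 3)); v[, , , 1] <- 3
  d <- exp_velocity(velocity_field(v))
  u <- unclass(d)
  int <- interior_idx(dims)
  expect_lt(max(abs(u[int[[1]], int[[2]], int[[3]], 1] - 3)), 1e-6)
  expect_lt(max(abs(u[int[[1]], int[[2]], int[[3]], 2:3])), 1e-6)
})

test_that("exp_velocity matches brute-force Euler integration", {
  dims <- c(24L, 24L, 24L)
  v <- velocity_field(smooth_random_velocity(dims, sigma_vox = 4,
                                             max_vox = 2, seed = 5))
  ue <- euler_flow(v, 1024L)
  ud <- unclass(exp_velocity(v))
  int <- interior_idx(dims)
  err <- sqrt((ue[int[[1]], int[[2]], int[[3]], 1] -
                 ud[int[[1]], int[[2]], int[[3]], 1])^2 +
              (ue[int[[1]], int[[2]], int[[3]], 2] -
                 ud[int[[1]], int[[2]], int[[3]], 2])^2 +
              (ue[int[[1]], int[[2]], int[[3]], 3] -
                 ud[int[[1]], int[[2]], int[[3]], 3])^2)
  expect_lt(max(err), 0.05)
})

test_that("exp(-v) numerically inverts exp(v)", {
  dims <- c(24L, 24L, 24L)
  for (seed in 1:3) {
    va <- smooth_random_velocity(dims, sigma_vox = 4, max_vox = 2,
                                 seed = seed)
    v <- velocity_field(va)
    res <- compose_fields(exp_velocity(v),
                          exp_velocity(velocity_field(-va)))
    expect_lt(mean_mag(res), 0.1)
  }
})

test_that("compose_fields is exact for identity and integer translations", {
  dims <- c(12L, 12L, 12L)
  withr::with_seed(2, {
    u <- array(rnorm(prod(dims) * 3, sd = 0.5), c(dims, 3))
  })
  d <- deformation_field(u)
  id <- deformation_field(array(0, c(dims, 3)))
  expect_equal(unclass(compose_fields(id, d)), unclass(d),
               ignore_attr = TRUE)

  t1 <- array(0, c(dims, 3)); t1[, , , 1] <- 2
  t2 <- array(0, c(dims, 3)); t2[, , , 2] <- 1
  comp <- unclass(compose_fields(deformation_field(t1),
                                 deformation_field(t2)))
  int <- interior_idx(dims, 3)
  expect_equal(max(abs(comp[int[[1]], int[[2]], int[[3]], 1] - 2)), 0)
  expect_equal(max(abs(comp[int[[1]], int[[2]], int[[3]], 2] - 1)), 0)
})

test_that("warp_volume is exact on identity and integer shifts and matches a pointwise oracle", {
  dims <- c(14L, 14L, 14L)
  withr::with_seed(4, {
    a <- array(runif(prod(dims)), dims)
  })
  v <- volume(a)
  id <- deformation_field(array(0, c(dims, 3)))
  expect_identical(as.numeric(warp_volume(v, id)), as.numeric(v))

  tr <- array(0, c(dims, 3)); tr[, , , 2] <- 2
  w <- warp_volume(v, deformation_field(tr))
  expect_equal(unname(unclass(w)[, 1:12, ]), a[, 3:14, ], ignore_attr = TRUE)

  # random field at random voxels vs an independent trilinear evaluation
  withr::with_seed(9, {
    u <- array(rnorm(prod(dims) * 3, sd = 1.5), c(dims, 3))
    pts <- cbind(sample(3:12, 50, TRUE), sample(3:12, 50, TRUE),
                 sample(3:12, 50, TRUE))
  })
  w2 <- warp_volume(v, deformation_field(u))
  for (r in seq_len(nrow(pts))) {
    i <- pts[r, 1]; j <- pts[r, 2]; k <- pts[r, 3]
    x <- i - 1 + u[i, j, k, 1]; y <- j - 1 + u[i, j, k, 2]
    z <- k - 1 + u[i, j, k, 3]
    x <- min(max(x, 0), dims[1] - 1); y <- min(max(y, 0), dims[2] - 1)
    z <- min(max(z, 0), dims[3] - 1)
    i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
    i1 <- min(i0 + 1, dims[1] - 1); j1 <- min(j0 + 1, dims[2] - 1)
    k1 <- min(k0 + 1, dims[3] - 1)
    fx <- x - i0; fy <- y - j0; fz <- z - k0
    gv <- function(ii, jj, kk) a[ii + 1, jj + 1, kk + 1]
    expected <-
      gv(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
      gv(i1, j0, k0) * fx * (1 - fy) * (1 - fz) +
      gv(i0, j1, k0) * (1 - fx) * fy * (1 - fz) +
      gv(i1, j1, k0) * fx * fy * (1 - fz) +
      gv(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
      gv(i1, j0, k1) * fx * (1 - fy) * fz +
      gv(i0, j1, k1) * (1 - fx) * fy * fz +
      gv(i1, j1, k1) * fx * fy * fz
    expect_equal(unclass(w2)[i, j, k], expected, tolerance = 1e-12)
  }
})

test_that("warp_volume guards label interpolation and preserves the label set", {
  dims <- c(12L, 12L, 12L)
  withr::with_seed(8, {
    lab <- volume(array(sample(0:4, prod(dims), TRUE), dims), kind = "label")
    u <- array(rnorm(prod(dims) * 3), c(dims, 3))
  })
  d <- deformation_field(u)
  expect_error(warp_volume(lab, d, interp = "linear"), "nearest")
  w <- warp_volume(lab, d, interp = "nearest")
  expect_true(all(unique(as.integer(w)) %in% unique(as.integer(lab))))
})

test_that("registering an image to itself recovers (almost) no deformation", {
  spec <- tiny_spec()
  mp <- mean_phantom(spec)
  reg <- register_pair(mp$t1, mp$t1)
  expect_lt(mean_mag(reg$deformation), 0.05)
})

test_that("registration recovers a known ground-truth warp", {
  spec <- tiny_spec(noise_sd = 0, bias_amplitude = 0)
  mp <- mean_phantom(spec)
  s <- generate_subject(spec, "60-64", "F", seed = 42)
  params <- registration_params(channel_weights = phantom_channel_weights())
  reg <- register_pair(c(list(s$t1), s$tissues$maps),
                       c(list(mp$t1), mp$tissues$maps), params)
  mask <- phantom_brain_mask(spec)
  du <- unclass(reg$deformation) - unclass(s$true_warp)
  epe <- sqrt(du[, , , 1]^2 + du[, , , 2]^2 + du[, , , 3]^2)
  expect_lt(mean(epe[mask]), 1)
  # and it must do a lot better than not registering at all
  expect_lt(mean(epe[mask]), mean_mag(s$true_warp, mask))
})

test_that("registration similarity trace is monotone non-increasing per level", {
  spec <- tiny_spec()
  mp <- mean_phantom(spec)
  s <- generate_subject(spec, "60-64", "M", seed = 3)
  reg <- register_pair(c(list(s$t1), s$tissues$maps),
                       c(list(mp$t1), mp$tissues$maps))
  for (lev in unique(reg$trace$level)) {
    ssd <- reg$trace$similarity[reg$trace$level == lev]
    expect_true(all(diff(ssd) <= 1e-8 * pmax(ssd[-length(ssd)], 1e-12)))
  }
})

test_that("channel mismatches are rejected", {
  spec <- tiny_spec()
  mp <- mean_phantom(spec)
  expect_error(register_pair(list(mp$t1, mp$t1), list(mp$t1)),
               "same number of channels")
  small <- volume(array(0.5, c(8, 8, 8)))
  expect_error(register_pair(mp$t1, small), "share one grid")
})

test_that("Jacobians of generated diffeomorphisms stay positive in the interior", {
  dims <- c(24L, 24L, 24L)
  for (seed in 1:3) {
    v <- velocity_field(smooth_random_velocity(dims, sigma_vox = 4,
                                               max_vox = 2, seed = seed))
    jm <- jacobian_map(exp_velocity(v))
    expect_true(all(unclass(jm)[attr(jm, "interior")] > 0))
  }
})
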
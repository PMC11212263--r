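test_that("displacement maps convert voxel displacements to mm", {
  dims <- c(16L, 16L, 16L)
  id <- deformation_field(array(0, c(dims, 3)), spacing = c(1, 1, 1))
  expect_true(all(as.numeric(displacement_map(id)) == 0))

  u <- array(0, c(dims, 3)); u[, , , 1] <- 3; u[, , , 2] <- 4
  d <- deformation_field(u, spacing = c(1, 1, 1))
  expect_true(all(abs(as.numeric(displacement_map(d)) - 5) == 0))

  withr::with_seed(6, {
    ur <- array(rnorm(prod(dims) * 3), c(dims, 3))
  })
  dr <- deformation_field(ur, spacing = c(2, 3, 1))
  m <- as.numeric(displacement_map(dr))
  oracle <- sqrt((ur[, , , 1] * 2)^2 + (ur[, , , 2] * 3)^2 +
                   (ur[, , , 3] * 1)^2)
  expect_equal(m, as.numeric(oracle), tolerance = 1e-12)
})

test_that("jacobian maps are exact on identity, scaling and affine fields", {
  dims <- c(20L, 20L, 20L)
  id <- deformation_field(array(0, c(dims, 3)))
  expect_true(all(as.numeric(jacobian_map(id)) == 1))
  expect_true(all(as.numeric(jacobian_map(id, log_output = TRUE)) == 0))

  g <- tmplkit:::grid_coords(dims)
  ctr <- (dims - 1) / 2
  mk_affine_field <- function(A) {
    u <- array(0, c(dims, 3))
    for (i in 1:3) {
      u[, , , i] <- (A[i, 1] * (g$x - ctr[1]) + A[i, 2] * (g$y - ctr[2]) +
                       A[i, 3] * (g$z - ctr[3])) -
        switch(i, g$x - ctr[1], g$y - ctr[2], g$z - ctr[3])
    }
    deformation_field(u)
  }
  scale11 <- mk_affine_field(diag(3) * 1.1)
  jm <- jacobian_map(scale11)
  int <- attr(jm, "interior")
  expect_lt(max(abs(as.numeric(jm)[int] - 1.331)), 1e-3)

  withr::with_seed(12, {
    for (r in 1:10) {
      repeat {
        A <- diag(3) + matrix(rnorm(9, sd = 0.15), 3)
        if (det(A) > 0.5 && det(A) < 2) break
      }
      jr <- jacobian_map(mk_affine_field(A))
      expect_lt(max(abs(as.numeric(jr)[attr(jr, "interior")] - det(A))),
                1e-6)
    }
  })
})

test_that("non-diffeomorphic fields are rejected", {
  dims <- c(12L, 12L, 12L)
  g <- tmplkit:::grid_coords(dims)
  u <- array(0, c(dims, 3))
  u[, , , 1] <- -1.5 * (g$x - (dims[1] - 1) / 2)  # folds the grid
  expect_error(jacobian_map(deformation_field(u)), "not diffeomorphic")
})

test_that("absolute log-Jacobian treats expansion and contraction equally", {
  dims <- c(8L, 8L, 8L)
  lj <- volume(array(log(2), dims), kind = "metric")
  expect_lt(max(abs(as.numeric(abs_log_jacobian(lj)) - 0.6931)), 1e-4)
  lj2 <- volume(array(log(0.5), dims), kind = "metric")
  expect_lt(max(abs(as.numeric(abs_log_jacobian(lj2)) - 0.6931)), 1e-4)
  withr::with_seed(14, {
    r <- array(rnorm(prod(dims)), dims)
  })
  expect_equal(as.numeric(abs_log_jacobian(volume(r, kind = "metric"))),
               abs(as.numeric(r)))
})

test_that("jacobians are approximately multiplicative under composition", {
  dims <- c(24L, 24L, 24L)
  va <- smooth_random_velocity(dims, sigma_vox = 4, max_vox = 1.5, seed = 31)
  vb <- smooth_random_velocity(dims, sigma_vox = 4, max_vox = 1.5, seed = 32)
  a <- exp_velocity(velocity_field(va))
  b <- exp_velocity(velocity_field(vb))
  ab <- compose_fields(a, b)
  j_ab <- as.numeric(jacobian_map(ab))
  j_a <- jacobian_map(a)
  j_b <- jacobian_map(b)
  j_b_at_a <- as.numeric(warp_volume(j_b, a))
  prod_j <- as.numeric(j_a) * j_b_at_a
  int <- array(FALSE, dims)
  idx <- interior_idx(dims, 5)
  int[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  rel <- abs(j_ab[int] - prod_j[int]) / prod_j[int]
  expect_lt(stats::quantile(rel, 0.99), 0.05)
})

test_that("summed Jacobians track the volume of the pushed-forward mask", {
  dims <- c(32L, 32L, 32L)
  g <- tmplkit:::grid_coords(dims)
  ctr <- (dims - 1) / 2
  mask <- ((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2) <= 10^2
  b <- volume(array(as.numeric(mask), dims))
  va <- smooth_random_velocity(dims, sigma_vox = 5, max_vox = 2, seed = 71)
  d <- exp_velocity(velocity_field(va))
  dinv <- exp_velocity(velocity_field(-va))
  # backward-warping through the inverse pushes the mask forward through d
  pushed <- as.numeric(warp_volume(b, dinv))
  jm <- as.numeric(jacobian_map(d))
  expect_lt(abs(sum(jm[mask]) - sum(pushed)) / sum(pushed), 0.02)
})

test_that("to_common_space transports maps through a bridge deformation", {
  dims <- c(16L, 16L, 16L)
  withr::with_seed(41, {
    m <- volume(array(runif(prod(dims)), dims), kind = "metric")
  })
  id <- deformation_field(array(0, c(dims, 3)))
  expect_identical(as.numeric(to_common_space(m, id)), as.numeric(m))

  cmap <- volume(array(0.42, dims), kind = "metric")
  withr::with_seed(42, {
    u <- array(rnorm(prod(dims) * 3), c(dims, 3))
  })
  br <- deformation_field(u)
  expect_lt(max(abs(as.numeric(to_common_space(cmap, br)) - 0.42)), 1e-12)

  # agreement with a direct pointwise resampling oracle at random voxels
  tm <- to_common_space(m, br)
  withr::with_seed(43, {
    pts <- cbind(sample(2:15, 200, TRUE), sample(2:15, 200, TRUE),
                 sample(2:15, 200, TRUE))
  })
  for (r in sample(nrow(pts), 50)) {
    i <- pts[r, 1]; j <- pts[r, 2]; k <- pts[r, 3]
    x <- i - 1 + u[i, j, k, 1]; y <- j - 1 + u[i, j, k, 2]
    z <- k - 1 + u[i, j, k, 3]
    oracle <- tmplkit:::sample_at(tmplkit:::vol_values(m),
                                  array(x, c(1, 1, 1)),
                                  array(y, c(1, 1, 1)),
                                  array(z, c(1, 1, 1)))
    expect_equal(unclass(tm)[i, j, k], as.numeric(oracle), tolerance = 1e-12)
  }
})

test_that("region summaries apply the volume filter and match brute force", {
  dims <- c(16L, 16L, 16L)
  lab <- array(0L, dims)
  lab[2:13, 2:9, 2:9] <- 1L            # large region
  lab[2:9, 11:15, 2:13] <- 2L          # large region
  lab[12:15, 12:15, 12:14] <- 3L       # 4*4*3 = 48 voxels = 480 mm3 at 10 mm3
  atlas <- label_atlas(volume(lab, spacing = c(1, 1, 10), kind = "label"))
  # spacing 1x1x10 gives 10 mm3 per voxel: region 3 has 480 mm3
  withr::with_seed(51, {
    md <- volume(array(runif(prod(dims)), dims), spacing = c(1, 1, 10),
                 kind = "metric")
    mj <- volume(array(runif(prod(dims)), dims), spacing = c(1, 1, 10),
                 kind = "metric")
  })
  rs <- region_summary(md, mj, atlas, min_volume_mm3 = 500)
  expect_false(3 %in% rs$region_id)
  expect_true(all(c(1, 2) %in% rs$region_id))
  for (id in c(1, 2)) {
    expect_equal(rs$mean_displacement_mm[rs$region_id == id],
                 mean(as.numeric(md)[lab == id]))
    expect_equal(rs$mean_abs_log_jacobian[rs$region_id == id],
                 mean(as.numeric(mj)[lab == id]))
  }
  # constant map: every retained region mean equals the constant exactly
  cst <- volume(array(2.5, dims), spacing = c(1, 1, 10), kind = "metric")
  rs2 <- region_summary(cst, cst, atlas, min_volume_mm3 = 500)
  expect_true(all(rs2$mean_displacement_mm == 2.5))
  # a 520 mm3 region is retained at the 500 mm3 threshold
  lab52 <- array(0L, dims); lab52[1:4, 1:13, 1] <- 3L  # 52 voxels = 520 mm3
  lab52[lab > 0] <- lab[lab > 0]
  lab52[lab == 3L] <- 0L
  atlas52 <- label_atlas(volume(lab52, spacing = c(1, 1, 10),
                                kind = "label"))
  rs3 <- region_summary(md, mj, atlas52, min_volume_mm3 = 500)
  expect_true(3 %in% rs3$region_id)
  expect_error(region_summary(md, mj, atlas, min_volume_mm3 = 1e9),
               "no region")
})

test_that("a single-region atlas reproduces the whole-mask mean", {
  dims <- c(12L, 12L, 12L)
  lab <- array(1L, dims)
  atlas <- label_atlas(volume(lab, spacing = c(2, 2, 2), kind = "label"))
  withr::with_seed(52, {
    m <- volume(array(runif(prod(dims)), dims), spacing = c(2, 2, 2),
                kind = "metric")
  })
  rs <- region_summary(m, m, atlas, min_volume_mm3 = 500)
  expect_equal(rs$mean_displacement_mm, mean(as.numeric(m)))
})

test_that("whole-grid displacement means are axis-permutation invariant", {
  dims <- c(14L, 14L, 14L)
  withr::with_seed(61, {
    u <- array(rnorm(prod(dims) * 3), c(dims, 3))
  })
  d1 <- deformation_field(u, spacing = c(2, 2, 2))
  up <- aperm(u, c(2, 3, 1, 4))[, , , c(2, 3, 1)]
  d2 <- deformation_field(array(up, c(dims, 3)), spacing = c(2, 2, 2))
  expect_equal(mean(as.numeric(displacement_map(d1))),
               mean(as.numeric(displacement_map(d2))), tolerance = 1e-12)
})
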
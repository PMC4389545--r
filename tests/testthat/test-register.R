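test_that("rigid transforms are orthonormal and preserve world distances", {
  expect_error(affine_transform(diag(c(2, 1, 1, 1)), "rigid6"), "orthonormal")
  p <- c(0.1, -0.05, 0.2, 3, -2, 1)
  m <- agetpl:::rigid_matrix(p, c(5, 5, 5))
  xf <- affine_transform(m, "rigid6")
  set.seed(1)
  pts <- matrix(rnorm(30, sd = 40), ncol = 3)
  tp <- sweep(pts %*% t(m[1:3, 1:3]), 2, m[1:3, 4], `+`)
  expect_equal(as.numeric(dist(tp)), as.numeric(dist(pts)), tolerance = 1e-6)
  back <- invert_affine(xf)
  expect_equal(back$matrix %*% m, diag(4), tolerance = 1e-9)
})

test_that("self-registration returns the identity transform", {
  ph <- phantom32(age = 40, seed = 17)
  xf <- register_rigid(ph$head, ph$head)
  R <- xf$matrix[1:3, 1:3]
  ang <- acos(pmin(1, (sum(diag(R)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.1)                         # degrees
  expect_lt(max(abs(xf$matrix[1:3, 4])), 0.1) # mm
})

test_that("known translations and rotations are recovered", {
  ph <- phantom32(age = 40, seed = 17)
  fixed <- ph$head
  # translate the moving image by +3 mm along x (world)
  aff <- fixed$affine
  aff[1, 4] <- aff[1, 4] + 3
  moving <- as_volume(fixed$data, aff)
  xf <- register_rigid(moving, fixed)
  expect_lt(max(abs(xf$matrix[1:3, 4] - c(3, 0, 0))), 0.2)

  # rotate by 5 degrees about z around the volume center, encoded in the
  # affine (no resampling, so the experiment is not biased by interpolation
  # smoothing of a near-spherical object)
  th <- 5 * pi / 180
  Rz <- agetpl:::rigid_matrix(c(0, 0, th, 0, 0, 0),
                              agetpl:::volume_center_world(fixed))
  moving2 <- as_volume(fixed$data, Rz %*% fixed$affine)
  # moving2 is the anatomy rotated by Rz in world space; the pullback
  # transform mapping fixed world to moving world is Rz itself
  xf2 <- register_rigid(moving2, fixed)
  Rrec <- xf2$matrix[1:3, 1:3] %*% t(Rz[1:3, 1:3])
  ang <- acos(pmin(1, (sum(diag(Rrec)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.5)
  expect_error(register_rigid(as_volume(array(1, c(8, 8, 8))),
                              as_volume(array(1, c(8, 8, 8)))),
               "constant")
})

test_that("deformable self-registration produces a negligible field", {
  ph <- phantom32(age = 30, seed = 23)
  f <- register_deformable(ph$head, ph$head, c(10, 10, 5))
  mx <- max(sqrt(rowSums(agetpl:::field_as_matrix(f$forward)^2)))
  expect_lt(mx / VX32, 0.1)
})

test_that("deformable registration improves the metric, finer schedules win,
           and ventricle boundaries align", {
  a <- phantom32(age = 25, seed = 41, noise_sigma = 0)
  b <- phantom32(age = 80, seed = 42, noise_sigma = 0)
  fine <- register_deformable(a$head, b$head, c(15, 10, 5))
  expect_lt(fine$metrics$final, fine$metrics$affine)
  coarse <- register_deformable(a$head, b$head, c(15, 0, 0))
  expect_lte(fine$metrics$final, coarse$metrics$final)
  # warped young ventricle boundary approaches the aged one: compare warped
  # truth OM (ventricle+CSF) maps
  wa <- apply_transform(a$truth_pve, fine, grid_of(b$head))
  sd_before <- soft_dice(a$truth_pve$wm, b$truth_pve$wm)
  sd_after <- soft_dice(wa$wm, b$truth_pve$wm)
  expect_gt(sd_after, sd_before)
  expect_gt(sd_after, 0.9)
})

test_that("forward/inverse displacement fields compose to identity within tolerance", {
  a <- phantom32(age = 35, seed = 51)
  b <- phantom32(age = 60, seed = 52)
  f <- register_deformable(a$brain, b$brain, c(10, 10, 5))
  g <- f$grid
  xyz <- agetpl:::grid_world_coords(g)
  fwd <- agetpl:::sample_field(f$forward, g, xyz)
  back <- agetpl:::sample_field(f$inverse, g, xyz + fwd)
  res <- sqrt(rowSums((fwd + back)^2)) / VX32
  expect_lt(max(res), 0.2)
  # double inversion returns the original forward field
  f2 <- invert_deformation(invert_deformation(f))
  expect_identical(f2$forward, f$forward)
})

test_that("analytic inverses: zero field and constant translations", {
  g <- list(dim = c(12L, 12L, 12L), affine = centered_affine(c(12, 12, 12), 4))
  zero <- array(0, c(g$dim, 3L))
  expect_equal(agetpl:::invert_disp(zero, g), zero)
  const <- zero
  const[, , , 1] <- 5
  inv <- agetpl:::invert_disp(const, g)
  expect_equal(as.numeric(inv[, , , 1]), rep(-5, prod(g$dim)), tolerance = 1e-9)
  expect_true(all(inv[, , , 2:3] == 0))
})

test_that("random smooth small-amplitude fields invert below 0.2 voxel residual", {
  set.seed(7)
  g <- list(dim = c(16L, 16L, 16L), affine = centered_affine(c(16, 16, 16), 4))
  raw <- array(rnorm(prod(g$dim) * 3, sd = 3), c(g$dim, 3L))
  for (c_ in 1:3) raw[, , , c_] <- agetpl:::gauss_smooth(raw[, , , c_], 2)
  inv <- agetpl:::invert_disp(raw, g, tol = 0.2)
  xyz <- agetpl:::grid_world_coords(g)
  fwd <- agetpl:::field_as_matrix(raw)
  back <- agetpl:::sample_field(inv, g, xyz + fwd)
  expect_lt(max(sqrt(rowSums((fwd + back)^2))) / 4, 0.2)
})

test_that("apply_transform honors identity, integer shifts, and round-trips", {
  ph <- phantom32(age = 45, seed = 61)
  idt <- apply_transform(ph$head, agetpl:::identity_affine(), grid_of(ph$head))
  expect_equal(idt$data, ph$head$data, tolerance = 1e-12)

  shift <- diag(4); shift[2, 4] <- VX32   # one voxel along y
  sh <- apply_transform(ph$head, affine_transform(shift, "rigid6"),
                        grid_of(ph$head), "nearest")
  d <- dim(ph$head$data)
  expect_equal(sh$data[, 1:(d[2] - 1), ], ph$head$data[, 2:d[2], ])
  expect_error(apply_transform(ph$head, agetpl:::identity_affine(),
                               grid_of(ph$head), "cubic"))

  # round trip on noise-free anatomy (interpolation cannot and should not
  # reproduce per-voxel noise)
  a2 <- phantom32(age = 45, seed = 61, noise_sigma = 0)
  b2 <- phantom32(age = 65, seed = 62, noise_sigma = 0)
  f <- register_deformable(a2$head, b2$head, c(10, 10, 5))
  there <- apply_transform(a2$head, f, grid_of(b2$head))
  back <- apply_transform(there, invert_deformation(f), grid_of(a2$head))
  rng <- diff(range(a2$head$data))
  expect_lt(mean(abs(back$data - a2$head$data)) / rng, 0.02)
})

test_that("PVE maps stay normalized through warps", {
  a <- phantom32(age = 35, seed = 71)
  b <- phantom32(age = 70, seed = 72)
  f <- register_deformable(a$brain, b$brain, c(10, 5, 0))
  w <- apply_transform(a$truth_pve, f, grid_of(b$brain))
  s <- w$om$data + w$gm$data + w$wm$data
  m <- w$mask$data > 0
  expect_true(all(abs(s[m] - 1) < 1e-6))
  expect_true(all(s[!m] == 0))
})
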
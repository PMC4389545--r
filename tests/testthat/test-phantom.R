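test_that("identical spec and seed reproduce the phantom bit for bit", {
  sp <- spec32(age = 44, seed = 7, noise_sigma = 8, bias_amplitude = 0.2)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$head$data, b$head$data)
  expect_identical(a$truth_pve$gm$data, b$truth_pve$gm$data)
  expect_identical(a$bias_field$data, b$bias_field$data)
})

test_that("truth PVEs are conserved and masks are nested", {
  ph <- phantom32(age = 61, seed = 3)
  s <- ph$truth_pve$om$data + ph$truth_pve$gm$data + ph$truth_pve$wm$data
  m <- ph$brain_mask$data > 0
  expect_true(all(abs(s[m] - 1) < 1e-6))
  # zero outside the head support
  outside <- ph$inner_skull_mask$data == 0 & s < 0.5
  expect_true(all(s[ph$head$data == 0 & ph$brain_mask$data == 0] < 1 + 1e-6))
  expect_true(all(ph$brain_mask$data <= ph$inner_skull_mask$data))
  # brain volume zero outside mask
  expect_true(all(ph$brain$data[!m] == 0))
})

test_that("noise-free, bias-free phantom has exact pure-class intensities", {
  ph <- phantom32(age = 30, seed = 5, noise_sigma = 0, bias_amplitude = 0)
  ints <- ph$spec$intensities
  for (cl in c("om", "gm", "wm")) {
    key <- c(om = "csf", gm = "gm", wm = "wm")[[cl]]
    pure <- ph$truth_pve[[cl]]$data >= 1
    expect_true(any(pure))
    expect_true(all(ph$brain$data[pure] == ints[[key]]))
  }
})

test_that("aging model: GM shrinks, OM grows, WM peaks at wm_peak_age", {
  vv <- VX32^3
  gm_vol <- function(age) {
    ph <- phantom32(age = age, seed = 11, noise_sigma = 0, shape_jitter = 0)
    sum(ph$truth_pve$gm$data) * vv
  }
  om_vol <- function(age) {
    ph <- phantom32(age = age, seed = 11, noise_sigma = 0, shape_jitter = 0)
    sum(ph$truth_pve$om$data) * vv
  }
  expect_gt(gm_vol(25), gm_vol(85))
  expect_gt(om_vol(85), om_vol(25))
  ages <- c(25, 40, 55, 70, 85)
  gms <- vapply(ages, gm_vol, numeric(1))
  expect_true(all(diff(gms) < 0))          # strictly decreasing
  oms <- vapply(c(55, 70, 85), om_vol, numeric(1))
  expect_true(all(diff(oms) >= 0))         # non-decreasing after the WM peak

  sp <- phantom_spec()
  fr <- vapply(20:89, function(a) expected_class_fractions(a, sp), numeric(3))
  expect_true(all(abs(colSums(fr) - 1) < 1e-12))
  expect_equal((20:89)[which.max(fr["wm", ])], sp$wm_peak_age)
  expect_gt(expected_class_fractions(30, sp)[["gm"]],
            expected_class_fractions(70, sp)[["gm"]])
})

test_that("jitter-free compartment volumes match the analytic shapes within 2%", {
  # at the production voxel size (2 mm); 4 mm voxels leave >2% discretization
  # error in the thin subarachnoid OM shell
  for (age in c(25, 50, 85)) {
    sp <- phantom_spec(age = age, seed = 2, noise_sigma = 0, shape_jitter = 0,
                       grid_shape = c(64L, 64L, 64L), voxel_size = 2)
    ph <- make_phantom(sp)
    av <- phantom_analytic_volumes(sp)
    for (cl in c("om", "gm", "wm")) {
      measured <- sum(ph$truth_pve[[cl]]$data) * 8
      expect_lt(abs(measured - av[[cl]]) / av[[cl]], 0.02)
    }
  }
})

test_that("invalid specs and infeasible grids error", {
  expect_error(phantom_spec(age = 19), "age")
  expect_error(phantom_spec(age = 95), "age")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(voxel_size = 0), "voxel_size")
  expect_error(make_phantom(phantom_spec(grid_shape = c(16L, 16L, 16L),
                                         voxel_size = 2)),
               "too small")
})

test_that("make_cohort is deterministic, honors the group design, and errors on bad input", {
  groups5 <- make_age_groups("five_year")
  expect_equal(nrow(groups5), 14L)
  expect_equal(groups5$label[1], "20-24")
  expect_equal(nrow(make_age_groups("ten_year")), 7L)
  expect_equal(make_age_groups("multi_year")$label, c("25-39", "40-59", "60-89"))

  co <- make_cohort(list(c(20, 24), c(85, 89)), 2, seed = 9,
                    grid_shape = GS32, voxel_size = VX32)
  expect_length(co, 4L)
  ages <- vapply(co, function(x) x$spec$age, numeric(1))
  expect_true(all(ages[1:2] >= 20 & ages[1:2] <= 24))
  expect_true(all(ages[3:4] >= 85 & ages[3:4] <= 89))
  co2 <- make_cohort(list(c(20, 24), c(85, 89)), 2, seed = 9,
                     grid_shape = GS32, voxel_size = VX32)
  expect_identical(co[[3]]$head$data, co2[[3]]$head$data)

  single <- make_cohort(list(c(40, 44)), 1, seed = 1,
                        grid_shape = GS32, voxel_size = VX32)
  expect_length(single, 1L)
  expect_error(make_cohort(list(), 2), "empty")
  expect_error(make_cohort(list(c(20, 24)), 0), "n_per_group")
})

test_that("the 14 x 4 design yields 56 cases", {
  # counting contract only; cases are light stand-ins with ages
  fy <- make_age_groups("five_year")
  cases <- unlist(lapply(seq_len(nrow(fy)), function(g)
    lapply(1:5, function(i) list(age = fy$low[g] + i %% 5, id = paste(g, i)))),
    recursive = FALSE)
  picked <- sample_offset_cases(cases, n_per_group = 4, seed = 1)
  expect_length(picked, 56L)
})

test_that("phantom cases round-trip to NIfTI with a JSON sidecar", {
  ph <- phantom32(age = 33, seed = 21)
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  expect_true(all(file.exists(file.path(dir,
    c("head.nii.gz", "brain.nii.gz", "brain_mask.nii.gz",
      "pve_gm.nii.gz", "spec.json")))))
  head2 <- read_volume(file.path(dir, "head.nii.gz"))
  expect_equal(head2$data, ph$head$data, tolerance = 1e-5)
  sidecar <- jsonlite::read_json(file.path(dir, "spec.json"))
  expect_equal(sidecar$age, ph$spec$age)
  expect_equal(sidecar$seed, ph$spec$seed)
})
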
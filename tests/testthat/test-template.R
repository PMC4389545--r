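test_that("compute_rms matches hand calculations", {
  d <- c(2L, 1L, 1L)
  af <- centered_affine(d, 1)
  a <- as_volume(array(c(1, 2), d), af)
  expect_equal(compute_rms(a, a, as_volume(array(1, d), af)), 0)
  b <- as_volume(a$data + 3, af)
  expect_equal(compute_rms(a, b, as_volume(array(1, d), af)), 3)
  # two-voxel mask with differences (0, 4): sqrt(mean(0, 16)) = sqrt(8)
  cvol <- as_volume(array(c(1, 6), d), af)
  expect_equal(compute_rms(a, cvol, as_volume(array(1, d), af)), sqrt(8))
  expect_error(compute_rms(a, b, as_volume(array(0, d), af)), "empty")
})

test_that("a single volume templates to its rigidly aligned self", {
  ph <- phantom32(age = 40, seed = 301)
  tpl <- build_template(list(ph$brain), ph$brain, TEST_PLAN)
  expect_equal(nrow(tpl$iterations), 1L)
  expect_true(tpl$converged)
  rng <- diff(range(ph$brain$data))
  expect_lt(max(abs(tpl$template$data - ph$brain$data)) / rng, 0.01)
})

test_that("identical volumes converge exactly at the first iteration", {
  ph <- phantom32(age = 40, seed = 302)
  tpl <- build_template(list(ph$brain, ph$brain, ph$brain), ph$brain, TEST_PLAN)
  rng <- diff(range(ph$brain$data))
  expect_lt(max(abs(tpl$template$data - ph$brain$data)) / rng, 0.01)
  expect_equal(nrow(tpl$iterations), 1L)
  expect_lt(tpl$iterations$rms[1], 1e-6 * rng)
  expect_true(tpl$converged)
  expect_error(build_template(list(), ph$brain), "at least one")
})

test_that("a jittered one-group cohort yields a non-increasing RMS trace and
           a template with cohort-mean GM volume", {
  cases <- group_phantoms("70-74", 6, 4242)
  tpl <- build_template(lapply(cases, `[[`, "brain"), cases[[1]]$brain,
                        TEST_PLAN, max_iter = 3L)
  rms <- tpl$iterations$rms
  if (length(rms) > 1) {
    # tolerance: one non-monotone step allowed
    expect_lte(sum(diff(rms) > 0), 1L)
  }
  # measure the template's GM compartment by the pipeline's own procedure:
  # segment it with the cohort's image-based priors applied a posteriori
  # (prior-free EM on a blurred average inflates GM through the
  # variance-absorption pathology; see the methods vignette)
  pves <- lapply(cases, function(x) segment_em(x$brain, x$brain_mask)$pve)
  pri <- build_priors(pves, tpl$subject_transforms, grid_of(tpl$template),
                      "70-74")
  mask <- as_volume(array(as.numeric(tpl$template$data > 15),
                          dim(tpl$template$data)), tpl$template$affine)
  seg <- suppressMessages(
    segment_em(tpl$template, mask, agetpl:::priors_as_pve(pri),
               seg_config("a_posteriori")))
  hard_gm <- sum(classify_hard(seg$pve)$data == 2L) * VX32^3
  truth_gm <- mean(vapply(cases, function(x)
    sum(x$truth_pve$gm$data) * VX32^3, numeric(1)))
  expect_lt(abs(hard_gm - truth_gm) / truth_gm, 0.05)
})

test_that("build_priors averages forward-transformed PVEs and keeps mass", {
  ph <- phantom32(age = 40, seed = 305)
  idt <- agetpl:::identity_deformation(grid_of(ph$brain))
  pr <- build_priors(list(ph$truth_pve), list(idt), grid_of(ph$brain),
                     age_group = "40-44")
  for (cl in c("om", "gm", "wm"))
    expect_equal(pr[[cl]]$data, ph$truth_pve[[cl]]$data, tolerance = 1e-6)
  # identical PVEs from several subjects leave the prior unchanged
  pr2 <- build_priors(list(ph$truth_pve, ph$truth_pve), list(idt, idt),
                      grid_of(ph$brain))
  expect_equal(pr2$gm$data, ph$truth_pve$gm$data, tolerance = 1e-6)
  s <- pr2$om$data + pr2$gm$data + pr2$wm$data
  expect_true(all(s <= 1 + 1e-6))
  expect_error(build_priors(list(ph$truth_pve), list(idt, idt),
                            grid_of(ph$brain)), "one transform per")
})

test_that("prior construction from a warped cohort conserves class mass within
           interpolation tolerance", {
  lib <- fx_library14()
  ent <- lib$library$five_year[["70-74"]]
  cases <- fx_cohort14()
  ages <- vapply(cases, function(x) x$age, numeric(1))
  sel <- which(ages >= 70 & ages <= 74)
  truth_gm <- mean(vapply(cases[sel], function(x)
    sum(x$truth_pve$gm$data) * VX32^3, numeric(1)))
  prior_gm <- sum(ent$priors_image$gm$data) * VX32^3
  expect_lt(abs(prior_gm - truth_gm) / truth_gm, 0.10)
})

test_that("the prior library covers the group schemes and records provenance", {
  lib <- fx_library14()
  expect_length(lib$library$five_year, 14L)
  expect_setequal(names(lib$library$five_year), make_age_groups("five_year")$label)
  for (entry in lib$library$five_year) {
    pr <- entry$priors_image
    expect_s3_class(pr, "agetpl_priors")
    expect_equal(pr$base_reference, "image")
    s <- pr$om$data + pr$gm$data + pr$wm$data
    expect_true(all(s <= 1 + 1e-6))
    expect_true(all(pr$gm$data >= 0 & pr$gm$data <= 1))
  }
  # two-group library: young-adult reference present, both base references
  lib2 <- fx_ordering_library()
  expect_setequal(names(lib2$library$five_year), c("20-24", "85-89"))
  expect_setequal(names(lib2$library$ten_year), c("20-29", "80-89"))
  expect_equal(lib2$young_adult_label, "20-24")
  expect_false(is.null(lib2$reference))
  for (scheme in names(lib2$library))
    for (entry in lib2$library[[scheme]])
      expect_equal(entry$priors_reference$base_reference, "reference")
  # empty groups are skipped with a warning
  one <- group_phantoms("20-24", 1, 88)
  w <- capture_warnings(
    lib1 <- build_prior_library(one, schemes = "five_year",
                                schedule_plan = TEST_PLAN,
                                include_reference = FALSE))
  expect_true(any(grepl("no cases", w)))
  expect_length(lib1$library$five_year, 1L)
})

test_that("library age groups reject out-of-range cohorts", {
  ph <- phantom32(age = 40, seed = 1)
  ph$age <- 95
  expect_error(build_prior_library(list(ph), schemes = "five_year"),
               "20, 89")
})
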
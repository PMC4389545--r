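mask_of <- function(v, d = c(4L, 4L, 1L)) as_volume(array(v, d), centered_affine(d, 1))

test_that("dice follows its definition and is symmetric", {
  a <- mask_of(c(rep(1, 2), rep(0, 14)))
  b <- mask_of(c(rep(1, 4), rep(0, 12)))
  expect_equal(dice(a, a), 1.0)
  disjoint <- mask_of(c(rep(0, 4), rep(1, 4), rep(0, 8)))
  expect_equal(dice(a, disjoint), 0.0)
  # |A| = 2, |B| = 4, |A ∩ B| = 2 -> 2*2/(2+4)
  expect_equal(dice(a, b), 2 * 2 / (2 + 4))
  expect_equal(dice(b, a), dice(a, b))
  expect_message(both_empty <- dice(mask_of(rep(0, 16)), mask_of(rep(0, 16))),
                 "both masks empty")
  expect_equal(both_empty, 1.0)
  expect_error(dice(a, mask_of(rep(1, 8), c(2L, 4L, 1L))), "grid")
  set.seed(2)
  for (i in 1:5) {
    x <- mask_of(rbinom(16, 1, 0.5)); y <- mask_of(rbinom(16, 1, 0.5))
    expect_equal(dice(x, y), dice(y, x))
    expect_gte(dice(x, y), 0); expect_lte(dice(x, y), 1)
  }
})

test_that("soft dice agrees with hard dice on binary maps", {
  a <- mask_of(c(rep(1, 2), rep(0, 14)))
  b <- mask_of(c(rep(1, 4), rep(0, 12)))
  expect_equal(soft_dice(a, b), dice(a, b))
})

test_that("one-way ANOVA matches hand computations", {
  # groups {1,2,3} and {4,5,6}: SSB = 13.5, SSW = 4 -> F = 13.5, df (1, 4)
  res <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 13.5)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE))

  same <- anova_oneway(c(2, 2, 2, 5, 5, 5, 5), rep(c("a", "b"), c(3, 4)))
  expect_equal(same$F, Inf)
  flat <- anova_oneway(rep(c(3, 3, 3, 3), 2), rep(c("a", "b"), 4))
  expect_equal(flat$F, 0)

  # permuting observations within groups leaves F unchanged
  set.seed(3)
  vals <- rnorm(12); gr <- rep(c("a", "b", "c"), each = 4)
  perm <- unlist(tapply(vals, gr, sample))
  expect_equal(anova_oneway(perm, sort(gr))$F, anova_oneway(vals, gr)$F)

  expect_error(anova_oneway(1:3, rep("a", 3)), "2 groups")
  expect_error(anova_oneway(1:2, factor(c("a", "b"), levels = c("a", "b", "c"))),
               "zero observations")
})

test_that("tissue volumes integrate PVEs times voxel volume", {
  d <- c(10L, 10L, 10L)
  af <- centered_affine(d, 1)
  one <- as_volume(array(1, d), af)
  zero <- as_volume(array(0, d), af)
  half <- as_volume(array(0.5, d), af)
  tv <- tissue_volumes(pve_map(zero, one, zero, one))
  expect_equal(tv[["gm"]], 1000)
  tv2 <- tissue_volumes(pve_map(half, half, zero, one))
  expect_equal(tv2[["gm"]], 500)
  expect_equal(tv2[["gm_wm"]], 500)
  sp <- phantom_spec(age = 40, seed = 2, noise_sigma = 0, shape_jitter = 0,
                     grid_shape = c(64L, 64L, 64L), voxel_size = 2)
  ph <- make_phantom(sp)
  tvp <- tissue_volumes(ph$truth_pve)
  av <- phantom_analytic_volumes(sp)
  expect_lt(abs(tvp[["gm"]] - av[["gm"]]) / av[["gm"]], 0.02)
})

test_that("demographics summary reproduces the printed totals", {
  counts <- demographics_table()
  recs <- expand_demographics(counts)
  tab <- summarize_cohort(recs)
  total_row <- tab[tab$age_group == "Total", ]
  expect_equal(total_row$total, 1162L)
  expect_equal(total_row$pct_female, 60)
  expect_equal(tab$total[tab$age_group == "20-24"], 244L)
  # 20-24 per-source counts (42, 88, 26, 88, 0) sum to the row total
  r2024 <- counts[counts$age_group == "20-24", ]
  expect_equal(r2024$ixi + r2024$mcbi + r2024$nihpd + r2024$oasis_cs +
                 r2024$oasis_long, 244)
  expect_equal(sum(tab$female[tab$age_group != "Total"]), 693L)

  empty <- summarize_cohort(data.frame(age = numeric(0), sex = character(0)))
  expect_true(all(empty$total == 0))
  expect_error(summarize_cohort(data.frame(age = 19, sex = "F")), "outside")
})

test_that("the variant harness emits exactly the closed eleven-variant set", {
  labels <- variant_labels()
  expect_length(labels, 11L)
  lib <- fx_ordering_library()
  case <- group_phantoms("85-89", 1, 7777)[[1]]
  case$reference <- case$truth_pve
  recs <- suppressMessages(run_variant_harness(list(case), lib, backend = "rigid"))
  expect_equal(nrow(recs), 22L)              # 11 variants x GM/WM
  expect_setequal(unique(recs$config_label), labels)
  expect_equal(as.integer(table(recs$tissue)[c("GM", "WM")]), c(11L, 11L))
  expect_true(all(recs$dice >= 0 & recs$dice <= 1))
  # a reference equal to a variant's own output scores dice 1
  seg <- segment_em(case$brain, case$brain_mask)
  case2 <- case
  case2$reference <- seg$pve
  recs2 <- suppressMessages(run_variant_harness(list(case2), lib, backend = "rigid"))
  expect_equal(recs2$dice[recs2$config_label == "image"], c(1, 1))
  # a missing age-group entry is reported by name
  case3 <- group_phantoms("50-54", 1, 31)[[1]]
  case3$reference <- case3$truth_pve
  expect_error(suppressMessages(run_variant_harness(list(case3), lib)),
               "missing prior library entry")
})

test_that("offset records: zero offset is perfect, boundary groups are one-sided", {
  lib <- fx_library14()
  case <- fx_cohort14()[[1]]                   # a 20-24 case
  recs <- suppressMessages(
    age_offset_analysis(list(case), lib, backend = "rigid", include_zero = TRUE))
  expect_true(all(recs$dice[recs$template_offset == 0] == 1.0))
  expect_true(all(recs$template_offset[recs$template_offset != 0] > 0))
  expect_setequal(unique(recs$template_offset), 0:13)
})

test_that("volumetric trend report recovers the generator's aging trends", {
  cases <- fx_cohort14()
  vols <- do.call(rbind, lapply(cases, function(ph) {
    tv <- tissue_volumes(ph$truth_pve)
    vv <- VX32^3
    data.frame(age = ph$age, gm = tv[["gm"]], wm = tv[["wm"]], om = tv[["om"]],
               gm_wm = tv[["gm_wm"]],
               inner_skull = sum(ph$inner_skull_mask$data > 0) * vv)
  }))
  rep <- volumetric_trend_report(vols)
  expect_equal(nrow(rep$table), 14L)
  expect_true(all(c("gm_mean", "gm_se", "inner_skull_mean") %in% names(rep$table)))
  # implied GM slope: gm_slope fraction/year x intracranial volume
  sp <- spec32()
  implied <- sp$gm_slope * 4 / 3 * pi * 52^3
  expect_gt(implied, rep$gm_slope_ci[1])
  expect_lt(implied, rep$gm_slope_ci[2])
  expect_lt(abs(rep$wm_vertex_age - sp$wm_peak_age), 5)
  # brain never exceeds the skull
  expect_true(all(vols$gm_wm <= vols$inner_skull))
})
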
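# Shared fixtures, built lazily and cached for the whole test run.
#
# Scale note: the heavy template/evaluation fixtures run on 32^3 grids at
# 4 mm with shortened demons schedules (the production defaults are 64^3 at
# 2 mm with 50x50x50); this keeps the whole suite inside its time budget
# without changing any generator default that defines the phantom world.

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

GS32 <- c(32L, 32L, 32L)
VX32 <- 4

spec32 <- function(age = 30, seed = 1, noise_sigma = 8, bias_amplitude = 0,
                   shape_jitter = 1.5, ...) {
  phantom_spec(age = age, seed = seed, noise_sigma = noise_sigma,
               bias_amplitude = bias_amplitude, shape_jitter = shape_jitter,
               grid_shape = GS32, voxel_size = VX32, ...)
}

phantom32 <- function(...) make_phantom(spec32(...))

# deterministic mini-cohort for one age-group label, ages uniform in group
group_phantoms <- function(label, n, seed0, ...) {
  lo <- as.numeric(sub("-.*", "", label))
  hi <- as.numeric(sub(".*-", "", label))
  lapply(seq_len(n), function(i) {
    s <- derive_seed(seed0, label, i)
    set.seed(s)
    ph <- make_phantom(spec32(age = runif(1, lo, hi), seed = s, ...))
    ph$age <- ph$spec$age
    ph$id <- sprintf("%s_%d", label, i)
    ph
  })
}

TEST_PLAN <- list(c(10, 0, 0), c(10, 10, 0), c(10, 10, 5))

# two-group library (young adult + aged), both base references, five- and
# ten-year schemes: backs the harness-closure and headline-ordering tests
fx_ordering_library <- function() fixture("ordering_library", function() {
  cases <- c(group_phantoms("20-24", 4, 101), group_phantoms("85-89", 4, 202))
  suppressWarnings(
    build_prior_library(cases, schemes = c("five_year", "ten_year"),
                        schedule_plan = TEST_PLAN, max_iter = 3L,
                        include_reference = TRUE))
})

# 20 held-out aged phantoms segmented under the three headline prior modes
fx_ordering_dice <- function() fixture("ordering_dice", function() {
  lib <- fx_ordering_library()
  ent_aged <- lib$library$five_year[["85-89"]]
  ent_young <- lib$library$five_year[["20-24"]]
  test <- group_phantoms("85-89", 20, 909)
  rows <- lapply(test, function(ph) {
    truth <- classify_hard(ph$truth_pve)
    gm_dice <- function(seg)
      dice(classify_hard(seg$pve)$data == 2L, truth$data == 2L)
    wa <- warp_priors_to_subject(ent_aged$priors_image, ent_aged$template,
                                 ph$brain, "rigid")
    wy <- warp_priors_to_subject(ent_young$priors_image, ent_young$template,
                                 ph$brain, "rigid")
    seg <- function(pri, usage) suppressMessages(
      segment_em(ph$brain, ph$brain_mask, agetpl:::priors_as_pve(pri),
                 seg_config(usage)))
    data.frame(
      id = ph$id,
      appropriate = gm_dice(seg(wa, "a_posteriori")),
      young = gm_dice(seg(wy, "a_posteriori")),
      reference_only = gm_dice(seg(wy, "a_priori")))
  })
  do.call(rbind, rows)
})

# all 14 five-year groups, 2 phantoms each, image priors only: backs the
# age-offset and volumetric-trend tests
fx_cohort14 <- function() fixture("cohort14", function() {
  fy <- make_age_groups("five_year")
  unlist(lapply(seq_len(nrow(fy)), function(g)
    group_phantoms(fy$label[g], 2, 3000 + g)), recursive = FALSE)
})

fx_library14 <- function() fixture("library14", function() {
  suppressWarnings(
    build_prior_library(fx_cohort14(), schemes = "five_year",
                        schedule_plan = list(c(8, 0, 0), c(8, 4, 0)),
                        max_iter = 2L, include_reference = FALSE))
})

fx_offset_records <- function() fixture("offset_records", function() {
  cases <- fx_cohort14()[seq(1, 27, by = 2)]   # one per five-year group
  suppressMessages(age_offset_analysis(cases, fx_library14(), backend = "rigid"))
})
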
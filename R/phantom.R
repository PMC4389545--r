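#' Specification of a synthetic head phantom
#'
#' The phantom is a set of concentric smooth shells (scalp, skull, intracranial
#' CSF, GM ribbon, WM core, central ventricle) whose radii are driven by an
#' aging model: the GM fraction of the intracranial volume declines linearly
#' with age, the WM fraction follows a quadratic with its vertex at
#' `wm_peak_age`, and the remaining "other matter" (CSF-like) fraction grows
#' accordingly. All geometry is defined in world mm, so the same anatomy can be
#' rendered on any grid/voxel size.
#'
#' @param age age in years, in \[20, 89\].
#' @param gm_slope decline in GM intracranial fraction per year (negative).
#'   Default loses ~15% of the age-20 GM fraction by age 89.
#' @param wm_peak_age age (years) at which the WM fraction peaks.
#' @param wm_curv quadratic coefficient of the WM fraction trend (fraction per
#'   year^2).
#' @param noise_sigma additive Gaussian intensity noise SD (intensity units,
#'   on the pre-normalization scale where GM = 70). The default 8 stands in
#'   for all within-class intensity variability of real T1 data (scanner
#'   noise, biological heterogeneity, residual partial voluming), not just
#'   thermal noise.
#' @param bias_amplitude bound on the multiplicative bias field dynamic range:
#'   the field lies within \[1/(1+a), 1+a\].
#' @param shape_jitter RMS random radial perturbation of the tissue boundaries
#'   in mm.
#' @param seed integer seed; identical spec + seed reproduces identical output.
#' @param grid_shape grid dimensions in voxels.
#' @param voxel_size isotropic voxel edge in mm.
#' @param gm_frac0 GM intracranial fraction at age 20.
#' @param wm_peak_frac WM intracranial fraction at `wm_peak_age`.
#' @param deep_gm_thickness thickness (mm) of the deep-GM ring lining the
#'   ventricle (caudate/thalamus stand-in); part of the GM budget.
#' @param intensities named pure-class mean intensities (csf, gm, wm) plus
#'   skull and scalp; arbitrary units, T1-like ordering WM > GM > CSF.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(age = 30,
                         gm_slope = -0.15 * 0.50 / 69,
                         wm_peak_age = 50,
                         wm_curv = 2e-5,
                         noise_sigma = 8,
                         bias_amplitude = 0.2,
                         shape_jitter = 1.5,
                         seed = 1L,
                         grid_shape = c(64L, 64L, 64L),
                         voxel_size = 2,
                         gm_frac0 = 0.50,
                         wm_peak_frac = 0.35,
                         deep_gm_thickness = 3,
                         intensities = c(csf = 30, gm = 70, wm = 110,
                                         skull = 20, scalp = 90)) {
  if (age < 20 || age > 89) stop("age must be in [20, 89]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  if (bias_amplitude < 0) stop("bias_amplitude must be >= 0")
  structure(list(age = age, gm_slope = gm_slope, wm_peak_age = wm_peak_age,
                 wm_curv = wm_curv, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude, shape_jitter = shape_jitter,
                 seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, gm_frac0 = gm_frac0,
                 wm_peak_frac = wm_peak_frac,
                 deep_gm_thickness = deep_gm_thickness,
                 intensities = intensities),
            class = "phantom_spec")
}

#' Target tissue fractions of the intracranial volume at a given age
#'
#' The generator's aging model: GM fraction linear in age, WM fraction
#' quadratic with vertex at `wm_peak_age`, OM the remainder. Fractions sum
#' to 1 by construction.
#'
#' @param age age in years, in \[20, 89\].
#' @param spec a [phantom_spec()] supplying the trend coefficients.
#' @return named numeric vector `c(om, gm, wm)` summing to 1.
#' @export
expected_class_fractions <- function(age, spec = phantom_spec()) {
  if (any(age < 20 | age > 89)) stop("age must be in [20, 89]")
  gm <- spec$gm_frac0 + spec$gm_slope * (age - 20)
  wm <- spec$wm_peak_frac - spec$wm_curv * (age - spec$wm_peak_age)^2
  om <- 1 - gm - wm
  if (any(c(gm, wm, om) <= 0)) stop("trend coefficients give non-positive fractions")
  c(om = unname(om), gm = unname(gm), wm = unname(wm))
}

# outer radii of the fixed (non-aging) head shells, mm
PHANTOM_RADII <- c(scalp = 60, skull = 56, inner_skull = 52)

# analytic radii (mm) of the aging tissue boundaries at a given age; the
# ventricle is lined by a deep-GM ring (caudate/thalamus-like), so the GM
# budget is split between the ring and the cortical ribbon
phantom_radii <- function(spec) {
  fr <- expected_class_fractions(spec$age, spec)
  R_in <- PHANTOM_RADII[["inner_skull"]]
  ball <- function(x) 4 / 3 * pi * x^3
  inv_ball <- function(v) (3 * v / (4 * pi))^(1 / 3)
  # ventricular share of OM grows with age (0.30 at 20 -> 0.50 at 89)
  vshare <- 0.30 + 0.20 * (spec$age - 20) / 69
  V <- ball(R_in)
  r_v <- R_in * (fr[["om"]] * vshare)^(1 / 3)
  r_dg <- r_v + spec$deep_gm_thickness
  v_deep <- ball(r_dg) - ball(r_v)
  if (v_deep >= V * fr[["gm"]])
    stop("deep GM ring exhausts the GM budget; reduce deep_gm_thickness")
  r_w <- inv_ball(ball(r_dg) + V * fr[["wm"]])
  r_g <- inv_ball(ball(r_w) + V * fr[["gm"]] - v_deep)
  c(vent = r_v, deep_gm = r_dg, wm = r_w, gm = r_g, inner_skull = R_in,
    skull = PHANTOM_RADII[["skull"]], scalp = PHANTOM_RADII[["scalp"]])
}

#' Analytic compartment volumes of the generating shapes (mm^3)
#' @param spec a [phantom_spec()].
#' @return named vector of OM/GM/WM (and inner skull) volumes for the
#'   unjittered geometry.
#' @export
phantom_analytic_volumes <- function(spec) {
  r <- phantom_radii(spec)
  ball <- function(x) 4 / 3 * pi * x^3
  c(om = ball(r[["vent"]]) + ball(r[["inner_skull"]]) - ball(r[["gm"]]),
    gm = (ball(r[["deep_gm"]]) - ball(r[["vent"]])) +
      (ball(r[["gm"]]) - ball(r[["wm"]])),
    wm = ball(r[["wm"]]) - ball(r[["deep_gm"]]),
    inner_skull = ball(r[["inner_skull"]]))
}

# smooth random directional field on the unit sphere: linear + quadratic
# monomials of the direction cosines with seeded coefficients, normalized to
# approximately unit RMS over the sphere.
jitter_field <- function(nhat, coef) {
  b <- cbind(nhat,
             nhat[, 1] * nhat[, 2], nhat[, 1] * nhat[, 3], nhat[, 2] * nhat[, 3],
             nhat[, 1]^2 - nhat[, 2]^2, 2 * nhat[, 3]^2 - nhat[, 1]^2 - nhat[, 2]^2)
  # RMS over the sphere of each basis function (analytic moments)
  norms <- sqrt(c(1 / 3, 1 / 3, 1 / 3, 1 / 15, 1 / 15, 1 / 15, 4 / 15, 4 / 5))
  drop(b %*% (coef * norms / sqrt(sum(coef^2 * norms^2) + 1e-12)))
}

#' Generate a synthetic head phantom with ground-truth tissue maps
#'
#' Renders the shell geometry of a [phantom_spec()] onto its grid: partial
#' volume ground truth for OM/GM/WM inside the skull (a linear one-voxel ramp
#' across each boundary), a T1-like head image (WM > GM > CSF), a smooth
#' multiplicative bias field (exponential of a seeded quadratic polynomial),
#' and additive Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_case` list with fields `head`, `brain` (head masked to
#'   the intracranial cavity), `truth_pve` (a [pve_map()]), `brain_mask`,
#'   `inner_skull_mask`, `bias_field`, and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vs <- spec$voxel_size
  half_fov <- min(d) * vs / 2
  if (half_fov < PHANTOM_RADII[["scalp"]] + vs / 2)
    stop("grid too small to contain the head shells at this voxel size")
  affine <- centered_affine(d, vs)
  xyz <- grid_world_coords(list(dim = d, affine = affine))
  r <- sqrt(rowSums(xyz^2))
  nhat <- xyz / pmax(r, 1e-9)
  radii <- phantom_radii(spec)

  set.seed(derive_seed(spec$seed, "phantom-shape"))
  jit <- function(scale) {
    if (spec$shape_jitter <= 0) return(0)
    spec$shape_jitter * scale * jitter_field(nhat, rnorm(8))
  }
  # independent smooth perturbations per aging boundary; skull/scalp fixed
  ramp <- function(R) pmin(1, pmax(0, (R - r) / vs + 0.5))
  vent_jit <- jit(0.5)
  in_vent <- ramp(radii[["vent"]] + vent_jit)
  in_dgm <- ramp(radii[["deep_gm"]] + vent_jit)   # ring rides on the ventricle
  in_wm <- ramp(radii[["wm"]] + jit(1))
  in_gm <- ramp(radii[["gm"]] + jit(1))
  in_icc <- ramp(radii[["inner_skull"]])
  in_skull <- ramp(radii[["skull"]])
  in_scalp <- ramp(radii[["scalp"]])
  # enforce nesting (jitter could cross boundaries)
  in_vent <- pmin(in_vent, in_dgm)
  in_dgm <- pmin(in_dgm, in_wm)
  in_wm <- pmin(in_wm, in_gm)
  in_gm <- pmin(in_gm, in_icc)

  pve_wm <- in_wm - in_dgm
  pve_gm <- (in_dgm - in_vent) + (in_gm - in_wm)
  pve_om <- in_vent + (in_icc - in_gm)

  # renormalize so the per-voxel class sum is exactly 1 inside the brain mask
  # (= intracranial indicator at the 0.5 level) and 0 outside; sub-voxel
  # boundary mass is redistributed symmetrically, so compartment volumes stay
  # within discretization tolerance of the analytic shapes
  s <- pve_om + pve_gm + pve_wm        # equals in_icc by construction
  mask_bin <- s >= 0.5
  norm <- ifelse(mask_bin, pmax(s, 1e-12), Inf)
  om_n <- pve_om / norm
  gm_n <- pve_gm / norm
  wm_n <- pve_wm / norm

  ints <- spec$intensities
  img <- (in_scalp - in_skull) * ints[["scalp"]] +
    (in_skull - in_icc) * ints[["skull"]] +
    pve_om * ints[["csf"]] + pve_gm * ints[["gm"]] + pve_wm * ints[["wm"]]
  # inside the brain mask, rebuild intensities from the renormalized PVEs so
  # that "pure" voxels carry exactly their pure intensity
  img[mask_bin] <- (om_n * ints[["csf"]] + gm_n * ints[["gm"]] +
                      wm_n * ints[["wm"]])[mask_bin]

  head_support <- in_scalp > 0
  bias <- rep(1, length(img))
  if (spec$bias_amplitude > 0) {
    set.seed(derive_seed(spec$seed, "phantom-bias"))
    u <- xyz / half_fov
    basis <- cbind(u, u^2, u[, 1] * u[, 2], u[, 1] * u[, 3], u[, 2] * u[, 3])
    g <- drop(basis %*% rnorm(9))
    g <- g - mean(g[head_support])
    g <- g * log1p(spec$bias_amplitude) / max(abs(g[head_support]))
    g <- g - mean(g[head_support])          # unit geometric mean in the head
    bias <- exp(g)
  }
  img <- img * bias
  if (spec$noise_sigma > 0) {
    set.seed(derive_seed(spec$seed, "phantom-noise"))
    img <- img + rnorm(length(img), 0, spec$noise_sigma)
  }

  arr <- function(x) { dim(x) <- d; x }
  head <- as_volume(arr(img), affine)
  brain_mask <- as_volume(arr(as.numeric(mask_bin)), affine)
  inner_skull_mask <- brain_mask
  brain <- as_volume(arr(img * mask_bin), affine)
  truth <- pve_map(om = as_volume(arr(om_n), affine),
                   gm = as_volume(arr(gm_n), affine),
                   wm = as_volume(arr(wm_n), affine),
                   mask = brain_mask)
  structure(list(head = head, brain = brain, truth_pve = truth,
                 brain_mask = brain_mask, inner_skull_mask = inner_skull_mask,
                 bias_field = as_volume(arr(bias), affine), spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> age %.1f y, grid %s @ %.3g mm, seed %d\n",
              x$spec$age, paste(x$spec$grid_shape, collapse = "x"),
              x$spec$voxel_size, x$spec$seed))
  invisible(x)
}

#' Generate a seeded cohort of phantoms over age groups
#'
#' Ages are sampled uniformly within each group; per-case seeds are derived
#' deterministically from the root seed, so the same arguments always yield
#' the identical cohort.
#'
#' @param age_groups a list/data.frame of age groups (see [make_age_groups()]),
#'   or a character scheme name (`"five_year"`, `"ten_year"`, `"multi_year"`).
#' @param n_per_group number of phantoms per group (>= 1).
#' @param seed root integer seed.
#' @param ... further arguments passed to [phantom_spec()] (e.g. `grid_shape`,
#'   `noise_sigma`).
#' @return list of `phantom_case` objects; each carries `$age_group_label` and
#'   `$id`.
#' @export
make_cohort <- function(age_groups, n_per_group, seed = 1L, ...) {
  if (is.character(age_groups) && length(age_groups) == 1L)
    age_groups <- make_age_groups(age_groups)
  groups <- as_age_group_df(age_groups)
  if (nrow(groups) == 0L) stop("age_groups must not be empty")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  cases <- list()
  for (gi in seq_len(nrow(groups))) {
    for (ci in seq_len(n_per_group)) {
      case_seed <- derive_seed(seed, "cohort", groups$label[gi], ci)
      set.seed(case_seed)
      age <- runif(1, groups$low[gi], groups$high[gi])
      sp <- phantom_spec(age = age, seed = case_seed, ...)
      case <- make_phantom(sp)
      case$age <- age
      case$age_group_label <- groups$label[gi]
      case$id <- sprintf("%s_%02d", groups$label[gi], ci)
      cases[[length(cases) + 1L]] <- case
    }
  }
  cases
}

as_age_group_df <- function(age_groups) {
  if (is.data.frame(age_groups)) return(age_groups)
  if (is.list(age_groups)) {
    lows <- vapply(age_groups, function(g) g[[1]], numeric(1))
    highs <- vapply(age_groups, function(g) g[[2]], numeric(1))
    return(data.frame(label = sprintf("%d-%d", as.integer(lows), as.integer(highs)),
                      low = lows, high = highs, stringsAsFactors = FALSE))
  }
  stop("age_groups must be a data.frame, list of ranges, or scheme name")
}

#' Write a phantom case to a directory as NIfTI files + JSON sidecar
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$head, file.path(dir, "head.nii.gz"))
  write_volume(case$brain, file.path(dir, "brain.nii.gz"))
  write_volume(case$brain_mask, file.path(dir, "brain_mask.nii.gz"), "uint8")
  write_volume(case$inner_skull_mask, file.path(dir, "inner_skull_mask.nii.gz"), "uint8")
  for (cl in c("om", "gm", "wm"))
    write_volume(case$truth_pve[[cl]], file.path(dir, sprintf("pve_%s.nii.gz", cl)))
  sp <- case$spec
  sp$intensities <- as.list(sp$intensities)
  jsonlite::write_json(unclass(sp), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
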
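#' Age group definitions
#'
#' Three grouping schemes over the adult range 20-89: `five_year` tiles it
#' into 14 bins (20-24, 25-29, ..., 85-89), `ten_year` into 7 bins, and
#' `multi_year` uses the three broad bins 25-39, 40-59, 60-89 (which do not
#' cover 20-24).
#'
#' @param scheme `"five_year"`, `"ten_year"` or `"multi_year"`.
#' @return data.frame with `label`, `low`, `high`, `scheme`.
#' @export
make_age_groups <- function(scheme = c("five_year", "ten_year", "multi_year")) {
  scheme <- match.arg(scheme)
  bounds <- switch(scheme,
    five_year = cbind(seq(20, 85, 5), seq(24, 89, 5)),
    ten_year = cbind(seq(20, 80, 10), seq(29, 89, 10)),
    multi_year = cbind(c(25, 40, 60), c(39, 59, 89)))
  data.frame(label = sprintf("%d-%d", bounds[, 1], bounds[, 2]),
             low = bounds[, 1], high = bounds[, 2], scheme = scheme,
             stringsAsFactors = FALSE)
}

#' Locate the age group containing an age
#' @param age age in years.
#' @param groups data.frame from [make_age_groups()].
#' @return row index into `groups` (NA if none contains the age).
#' @export
age_group_index <- function(age, groups) {
  hit <- which(groups$low <= age & age <= groups$high)
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

#' RMS intensity difference between two volumes inside a mask
#' @param a,b `agetpl_volume`s on the same grid.
#' @param mask binary `agetpl_volume`.
#' @return square root of the mean squared intensity difference over the mask.
#' @export
compute_rms <- function(a, b, mask) {
  stopifnot_same_grid(a, b)
  stopifnot_same_grid(a, mask)
  m <- mask$data > 0
  if (!any(m)) stop("mask is empty")
  sqrt(mean((a$data[m] - b$data[m])^2))
}

#' Iterative average-template construction
#'
#' The classic register-transform-average loop: every input volume is first
#' rigidly aligned to `init_reference` and averaged into a tentative template
#' A0; each subsequent iteration deformably registers every volume to the
#' current average (coarse resolution schedules first, fine thereafter),
#' transforms it into template space, and re-averages. The loop stops when
#' the RMS difference between successive averages levels off (relative change
#' below `rms_tol`) or after `max_iter` iterations.
#'
#' @param volumes list of `agetpl_volume`s, consistently preprocessed
#'   (brain-extracted or whole-head throughout, GM peak at 100).
#' @param init_reference `agetpl_volume` defining the template grid and
#'   initial orientation.
#' @param schedule_plan list of per-iteration pyramid schedules; iteration n
#'   uses `schedule_plan[[min(n, length(schedule_plan))]]`. The default
#'   mirrors the coarse/medium/fine progression 50x0x0, 50x50x0, 50x50x50.
#' @param rms_tol relative RMS change defining "leveling" (default 5%).
#' @param max_iter maximum deformable iterations.
#' @param verbose log RMS per iteration via `message()`.
#' @return a `template_result`: `template` (A_n), `subject_transforms`
#'   (final-iteration `agetpl_deform` per subject), `iterations`
#'   (data.frame n/rms), `converged`, `mask`.
#' @export
build_template <- function(volumes, init_reference,
                           schedule_plan = list(c(50, 0, 0), c(50, 50, 0), c(50, 50, 50)),
                           rms_tol = 0.05, max_iter = 6L, verbose = FALSE) {
  if (length(volumes) == 0L) stop("need at least one volume")
  grid <- grid_of(init_reference)
  aligned <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    xf <- tryCatch(register_rigid(volumes[[i]], init_reference),
                   error = function(e) stop(sprintf("rigid registration failed for subject %d: %s",
                                                    i, conditionMessage(e))))
    aligned[[i]] <- apply_transform(volumes[[i]], xf, grid, "linear")
  }
  average <- function(vols) {
    acc <- Reduce(`+`, lapply(vols, function(v) v$data)) / length(vols)
    as_volume(acc, grid$affine)
  }
  A <- average(aligned)
  rng <- diff(range(A$data))
  mask <- as_volume(array(as.numeric(A$data > 0.05 * max(A$data)), grid$dim),
                    grid$affine)
  iterations <- data.frame(n = integer(0), rms = numeric(0))
  transforms <- replicate(length(volumes),
                          identity_deformation(grid), simplify = FALSE)
  converged <- FALSE
  prev_rms <- NA_real_
  if (length(volumes) > 1L) {
    for (n in seq_len(max_iter)) {
      sched <- schedule_plan[[min(n, length(schedule_plan))]]
      warped <- vector("list", length(volumes))
      for (i in seq_along(volumes)) {
        transforms[[i]] <- tryCatch(
          register_deformable(volumes[[i]], A, sched),
          error = function(e) stop(sprintf("deformable registration failed for subject %d: %s",
                                           i, conditionMessage(e))))
        warped[[i]] <- apply_transform(volumes[[i]], transforms[[i]], grid, "linear")
      }
      A_new <- average(warped)
      rms <- compute_rms(A_new, A, mask)
      iterations <- rbind(iterations, data.frame(n = n, rms = rms))
      if (verbose) message(sprintf("template iteration %d: RMS %.4f", n, rms))
      A <- A_new
      if (rms < 1e-6 * rng) { converged <- TRUE; break }
      if (!is.na(prev_rms) && abs(rms - prev_rms) < rms_tol * prev_rms) {
        converged <- TRUE; break
      }
      prev_rms <- rms
    }
  } else {
    # single volume: the template is its rigidly aligned self
    iterations <- data.frame(n = 1L, rms = 0)
    converged <- TRUE
  }
  structure(list(template = A, subject_transforms = transforms,
                 iterations = iterations, converged = converged, mask = mask),
            class = "template_result")
}

identity_deformation <- function(grid) {
  z <- array(0, c(grid$dim, 3L))
  deformation_field(z, z, grid)
}

#' @export
print.template_result <- function(x, ...) {
  cat(sprintf("<template_result> %d subjects, %d iterations (%s), final RMS %.4g\n",
              length(x$subject_transforms), nrow(x$iterations),
              if (x$converged) "converged" else "max_iter",
              tail(x$iterations$rms, 1)))
  invisible(x)
}

#' Age-specific tissue priors in template space
#'
#' @param om,gm,wm per-class probability `agetpl_volume`s (values in \[0,1\],
#'   per-voxel sum at most 1).
#' @param age_group one-row data.frame (label/low/high/scheme) or label string.
#' @param base_reference `"image"` when the source PVEs came from prior-free
#'   segmentation, `"reference"` when they came from reference-prior
#'   segmentation.
#' @param mask binary support mask.
#' @return an `agetpl_priors`.
#' @export
tissue_priors <- function(om, gm, wm, mask, age_group, base_reference = c("image", "reference")) {
  base_reference <- match.arg(base_reference)
  s <- om$data + gm$data + wm$data
  over <- s > 1
  if (any(over)) {
    om$data[over] <- om$data[over] / s[over]
    gm$data[over] <- gm$data[over] / s[over]
    wm$data[over] <- wm$data[over] / s[over]
  }
  structure(list(om = om, gm = gm, wm = wm, mask = mask,
                 age_group = age_group, base_reference = base_reference),
            class = "agetpl_priors")
}

#' @export
print.agetpl_priors <- function(x, ...) {
  lab <- if (is.data.frame(x$age_group)) x$age_group$label else as.character(x$age_group)
  cat(sprintf("<agetpl_priors> age group %s, base %s\n", lab, x$base_reference))
  invisible(x)
}

priors_as_pve <- function(pr) pve_map(pr$om, pr$gm, pr$wm, pr$mask)

#' Average forward-transformed subject PVEs into template-space priors
#'
#' Each subject's PVE map is forward-transformed into template space with the
#' final-iteration subject transform and the per-class arithmetic mean is
#' taken, then renormalized so that the per-voxel class sum does not exceed 1.
#'
#' @param pves list of `agetpl_pve` (one per subject, subject space).
#' @param transforms list of `agetpl_deform` from [build_template()] (same
#'   length/order).
#' @param template_grid grid list or `agetpl_volume` of the template.
#' @param age_group,base_reference provenance, see [tissue_priors()].
#' @return an `agetpl_priors`.
#' @export
build_priors <- function(pves, transforms, template_grid,
                         age_group = "unspecified",
                         base_reference = c("image", "reference")) {
  base_reference <- match.arg(base_reference)
  if (length(pves) != length(transforms))
    stop("need exactly one transform per PVE map")
  if (is_volume(template_grid)) template_grid <- grid_of(template_grid)
  warped <- vector("list", length(pves))
  for (i in seq_along(pves))
    warped[[i]] <- apply_transform(pves[[i]], transforms[[i]], template_grid, "linear")
  avg_class <- function(cl) {
    acc <- Reduce(`+`, lapply(warped, function(w) w[[cl]]$data)) / length(warped)
    as_volume(acc, template_grid$affine)
  }
  mask_any <- Reduce(`|`, lapply(warped, function(w) w$mask$data > 0))
  mask <- as_volume(array(as.numeric(mask_any), template_grid$dim),
                    template_grid$affine)
  tissue_priors(avg_class("om"), avg_class("gm"), avg_class("wm"), mask,
                age_group, base_reference)
}

#' Build a library of age-specific templates and tissue priors
#'
#' For every grouping scheme and every age group with at least one case,
#' builds an average template from the group's brains and constructs two
#' prior sets: "image" priors from prior-free segmentations, and (optionally)
#' "reference" priors from segmentations guided by the young-adult reference
#' prior set. The young-adult (20-24 five-year) entry doubles as the internal
#' reference set playing the role of an external standard-space prior atlas.
#'
#' @param cases list of cases; each needs `$brain` (preprocessed
#'   `agetpl_volume`), `$age`, and optionally `$mask` and `$id`.
#' @param schemes subset of `c("five_year","ten_year","multi_year")`.
#' @param schedule_plan,rms_tol,max_iter passed to [build_template()].
#' @param include_reference also build reference-based priors (doubles the
#'   per-subject segmentation and registration work).
#' @param verbose log progress.
#' @return an `agetpl_library`: nested list `lib[[scheme]][[label]]` with
#'   `template`, `priors_image`, `priors_reference` (or NULL), `transforms`,
#'   `ages`; plus `$reference` (the young-adult entry) and `$groups`.
#' @export
build_prior_library <- function(cases,
                                schemes = c("five_year", "ten_year", "multi_year"),
                                schedule_plan = list(c(50, 0, 0), c(50, 50, 0), c(50, 50, 50)),
                                rms_tol = 0.05, max_iter = 6L,
                                include_reference = TRUE, verbose = FALSE) {
  ages <- vapply(cases, function(x) x[["age"]] %||% x$spec$age, numeric(1))
  if (any(ages < 20 | ages > 89)) stop("all case ages must be in [20, 89]")
  brains <- lapply(cases, `[[`, "brain")
  masks <- lapply(cases, function(x) x$mask %||% x$brain_mask %||% {
    as_volume(array(as.numeric(x$brain$data > 0), dim(x$brain$data)), x$brain$affine)
  })
  # prior-free ("image") segmentations, shared across schemes
  if (verbose) message("segmenting ", length(cases), " cases (prior-free)")
  pve_image <- lapply(seq_along(cases), function(i)
    segment_em(brains[[i]], masks[[i]], NULL, seg_config())$pve)

  build_group <- function(sel, label, scheme, reference) {
    init <- brains[[sel[1]]]
    tpl <- build_template(brains[sel], init, schedule_plan, rms_tol, max_iter,
                          verbose = verbose)
    pr_img <- build_priors(pve_image[sel], tpl$subject_transforms,
                           grid_of(tpl$template), label, "image")
    pr_ref <- NULL
    if (!is.null(reference)) {
      pve_ref <- lapply(sel, function(i) {
        pri <- warp_priors_to_subject(reference$priors_image, reference$template,
                                      brains[[i]], backend = "rigid")
        segment_em(brains[[i]], masks[[i]], priors_as_pve(pri),
                   seg_config("a_priori"))$pve
      })
      pr_ref <- build_priors(pve_ref, tpl$subject_transforms,
                             grid_of(tpl$template), label, "reference")
    }
    list(template = tpl$template, result = tpl, priors_image = pr_img,
         priors_reference = pr_ref, transforms = tpl$subject_transforms,
         ages = ages[sel], ids = vapply(sel, function(i) cases[[i]]$id %||% as.character(i), character(1)))
  }

  # the internal young-adult reference: 20-24 five-year group, image priors
  fy <- make_age_groups("five_year")
  sel_ref <- which(ages >= fy$low[1] & ages <= fy$high[1])
  reference <- NULL
  if (length(sel_ref) > 0) {
    if (verbose) message("building young-adult reference (20-24)")
    reference <- build_group(sel_ref, fy$label[1], "five_year", reference = NULL)
  } else if (include_reference) {
    warning("no 20-24 cases: reference-based priors unavailable")
    include_reference <- FALSE
  }

  lib <- list()
  for (scheme in schemes) {
    groups <- make_age_groups(scheme)
    entries <- list()
    for (g in seq_len(nrow(groups))) {
      sel <- which(ages >= groups$low[g] & ages <= groups$high[g])
      if (length(sel) == 0L) {
        warning(sprintf("age group %s (%s) has no cases; skipped",
                        groups$label[g], scheme))
        next
      }
      if (scheme == "five_year" && g == 1L && !is.null(reference)) {
        entry <- reference
        if (include_reference && is.null(entry$priors_reference)) {
          pve_ref <- lapply(sel, function(i) {
            pri <- warp_priors_to_subject(reference$priors_image, reference$template,
                                          brains[[i]], backend = "rigid")
            segment_em(brains[[i]], masks[[i]], priors_as_pve(pri),
                       seg_config("a_priori"))$pve
          })
          entry$priors_reference <- build_priors(pve_ref, entry$transforms,
                                                 grid_of(entry$template),
                                                 groups$label[g], "reference")
        }
      } else {
        if (verbose) message(sprintf("building %s template %s (n=%d)",
                                     scheme, groups$label[g], length(sel)))
        entry <- build_group(sel, groups$label[g], scheme,
                             reference = if (include_reference) reference else NULL)
      }
      entries[[groups$label[g]]] <- entry
    }
    lib[[scheme]] <- entries
  }
  structure(list(library = lib, reference = reference,
                 young_adult_label = fy$label[1], ages = ages),
            class = "agetpl_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.agetpl_library <- function(x, ...) {
  for (scheme in names(x$library))
    cat(sprintf("%s: %s\n", scheme, paste(names(x$library[[scheme]]), collapse = ", ")))
  invisible(x)
}

#' Warp template-space priors into a subject's space
#'
#' Registers the subject to the template (rigid or deformable backend),
#' inverts the transform, and resamples the prior maps onto the subject grid.
#'
#' @param priors an `agetpl_priors` in template space.
#' @param template the template `agetpl_volume` the priors live in.
#' @param subject the subject `agetpl_volume`.
#' @param backend `"rigid"` or `"deformable"`.
#' @param schedule pyramid schedule for the deformable backend.
#' @param rigid_quality precision of the rigid backend (see
#'   [register_rigid()]); the coarse default is adequate for mapping smooth
#'   probability maps.
#' @return an `agetpl_priors` on the subject grid.
#' @export
warp_priors_to_subject <- function(priors, template, subject,
                                   backend = c("rigid", "deformable"),
                                   schedule = c(20, 10, 0),
                                   rigid_quality = "coarse") {
  backend <- match.arg(backend)
  if (backend == "rigid") {
    # register_rigid maps template(fixed) world -> subject(moving) world
    xf <- register_rigid(subject, template, quality = rigid_quality)
    # resampling priors (template space) onto the subject grid needs
    # subject world -> template world
    inv <- invert_affine(xf)
    warp <- function(v, itp) apply_transform(v, inv, grid_of(subject), itp)
  } else {
    field <- register_deformable(subject, template, schedule)
    inv <- invert_deformation(field)
    warp <- function(v, itp) apply_transform(v, inv, grid_of(subject), itp)
  }
  pve <- warp(priors_as_pve(priors), "linear")
  tissue_priors(pve$om, pve$gm, pve$wm, pve$mask,
                priors$age_group, priors$base_reference)
}
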
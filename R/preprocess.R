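#' Estimate a smooth multiplicative bias field
#'
#' Simplified N4-style scheme working entirely in the log domain: iterate
#' \{classify the bias-corrected intensities into three tissue classes by a
#' 1D k-means-style split, form the residual log-intensity against the class
#' log-means, least-squares fit a low-order 3D polynomial basis to the
#' residual\} until the field changes by less than 0.1%. The polynomial degree
#' is derived from `control_spacing` (roughly one degree per control spacing
#' across the field of view, capped at 4). The full N4 histogram sharpening is
#' deliberately not reproduced; only smooth-multiplicative-correction behavior
#' matters downstream.
#'
#' @param volume an `agetpl_volume` with non-negative intensities.
#' @param mask binary `agetpl_volume`; the fit uses in-mask voxels.
#' @param control_spacing smoothness scale in mm (larger = smoother field).
#' @param max_iter outer iteration cap.
#' @return an `agetpl_bias` list: `field` (an `agetpl_volume`, strictly
#'   positive, unit geometric mean inside the mask), `degree`, `n_iter`.
#' @export
estimate_bias_field <- function(volume, mask, control_spacing = 60, max_iter = 20L) {
  stopifnot_same_grid(volume, mask)
  idx <- which(mask$data > 0)
  if (length(idx) == 0L) stop("mask is empty")
  v <- volume$data[idx]
  if (all(v <= 0)) stop("volume is zero inside the mask")
  if (any(v < 0)) stop("bias estimation requires non-negative intensities")
  pos <- v > max(v) * 1e-4            # log domain needs positive values
  fov <- max(grid_dim(volume) * voxel_size(volume))
  degree <- max(1L, min(4L, as.integer(round(fov / control_spacing))))

  xyz <- grid_world_coords(grid_of(volume))[idx[pos], , drop = FALSE]
  u <- sweep(xyz, 2, colMeans(xyz))
  u <- sweep(u, 2, pmax(apply(abs(u), 2, max), 1e-9), `/`)
  B <- poly_basis(u, degree)
  logv <- log(v[pos])

  logfield <- rep(0, sum(pos))
  for (it in seq_len(max_iter)) {
    corrected <- logv - logfield
    centers <- kmeans1d(corrected, 3L)
    cls <- apply(outer(corrected, centers, function(a, b) abs(a - b)), 1, which.min)
    resid <- corrected - centers[cls]
    # trim partial-volume voxels (large within-class residuals) from the fit
    keep <- abs(resid) <= quantile(abs(resid), 0.7)
    target <- logfield + resid          # total smooth component of log intensity
    fit <- stats::lm.fit(B[keep, , drop = FALSE], target[keep])
    new_logfield <- drop(B %*% fit$coefficients)
    new_logfield <- new_logfield - mean(new_logfield)   # unit geometric mean
    delta <- max(abs(new_logfield - logfield))
    logfield <- new_logfield
    if (delta < 1e-3) break
  }

  # evaluate the fitted polynomial over the whole grid
  all_xyz <- grid_world_coords(grid_of(volume))
  au <- sweep(all_xyz, 2, colMeans(xyz))
  au <- sweep(au, 2, pmax(apply(abs(sweep(xyz, 2, colMeans(xyz))), 2, max), 1e-9), `/`)
  lf_all <- drop(poly_basis(au, degree) %*% fit$coefficients)
  lf_all <- lf_all - mean(lf_all[idx][pos])
  field <- exp(pmin(pmax(lf_all, -3), 3))
  dim(field) <- grid_dim(volume)
  structure(list(field = as_volume(field, volume$affine), degree = degree,
                 n_iter = it), class = "agetpl_bias")
}

poly_basis <- function(u, degree) {
  cols <- list(rep(1, nrow(u)))
  for (dx in 0:degree) for (dy in 0:degree) for (dz in 0:degree) {
    if (dx + dy + dz == 0 || dx + dy + dz > degree) next
    cols[[length(cols) + 1L]] <- u[, 1]^dx * u[, 2]^dy * u[, 3]^dz
  }
  do.call(cbind, cols)
}

# deterministic 1D k-means (quantile init, Lloyd iterations)
kmeans1d <- function(x, k, iter = 30L) {
  centers <- as.numeric(quantile(x, (seq_len(k) - 0.5) / k, names = FALSE))
  for (i in seq_len(iter)) {
    cls <- apply(outer(x, centers, function(a, b) abs(a - b)), 1, which.min)
    new <- vapply(seq_len(k), function(j)
      if (any(cls == j)) mean(x[cls == j]) else centers[j], numeric(1))
    if (max(abs(new - centers)) < 1e-10) break
    centers <- sort(new)
  }
  centers
}

#' Divide out a multiplicative bias field
#' @param volume an `agetpl_volume`.
#' @param field an `agetpl_bias` (or an `agetpl_volume` holding the field).
#' @return the corrected `agetpl_volume`.
#' @export
correct_bias <- function(volume, field) {
  f <- if (inherits(field, "agetpl_bias")) field$field else field
  stopifnot_same_grid(volume, f, "volume and bias field")
  if (any(f$data <= 0)) stop("bias field must be strictly positive")
  as_volume(volume$data / f$data, volume$affine)
}

#' Standardize intensities so that the mean pure-GM intensity is 100
#'
#' Voxels whose GM partial volume estimate is effectively 1 (>= the pure-voxel
#' threshold) are averaged; the whole volume is rescaled by `100 / mean` so
#' that the GM histogram peak lands at 100. The operation is a single global
#' scaling, so intensity ratios are preserved and applying it twice is a
#' no-op.
#'
#' @param volume an `agetpl_volume`.
#' @param pve an `agetpl_pve` on the same grid (typically from prior-free
#'   [segment_em()]).
#' @param pure_threshold PVE counted as "1.0" (float tolerance), default 0.999.
#' @return list with `volume` (rescaled) and `scale`.
#' @export
normalize_gm_peak <- function(volume, pve, pure_threshold = 0.999) {
  stopifnot_same_grid(volume, pve$gm)
  pure <- pve$gm$data >= pure_threshold
  if (!any(pure)) stop("no pure GM voxels; segmentation unusable for norming")
  scale <- 100 / mean(volume$data[pure])
  list(volume = as_volume(volume$data * scale, volume$affine), scale = scale)
}

# binary morphological closing with a 1-voxel ball (6-connectivity),
# implemented with array shifts
morph_close <- function(mask_arr) {
  dilate <- function(m) {
    out <- m
    d <- dim(m)
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    out
  }
  erode <- function(m) !dilate(!m)
  erode(dilate(mask_arr > 0))
}

#' Brain extraction by atlas-mask propagation
#'
#' Registers the head to an atlas head, propagates the atlas brain mask back
#' through the inverse transform (nearest neighbour), applies a 1-voxel
#' morphological closing, and masks the head. This is the single-pass
#' simplification of the usual register / inverse-transform-mask / refine
#' chain; no surface-based refinement is attempted.
#'
#' @param head an `agetpl_volume`.
#' @param atlas_head atlas `agetpl_volume`.
#' @param atlas_brain_mask binary `agetpl_volume` on the atlas grid.
#' @param deformable if TRUE, refines the rigid registration with a coarse
#'   deformable pass before propagating the mask.
#' @param schedule pyramid schedule for the deformable refinement.
#' @return list with `brain` (head zeroed outside the mask) and `mask`
#'   (binary `agetpl_volume`).
#' @export
extract_brain <- function(head, atlas_head, atlas_brain_mask,
                          deformable = FALSE, schedule = c(20, 10, 0)) {
  if (!any(atlas_brain_mask$data > 0)) stop("atlas brain mask is empty")
  if (deformable) {
    xf <- register_deformable(head, atlas_head, schedule)
    inv <- invert_deformation(xf)
    mask_v <- apply_transform(atlas_brain_mask, inv, grid_of(head), "nearest")
  } else {
    # register_rigid(moving = head, fixed = atlas) maps atlas world to head
    # world; resampling the atlas mask onto the head grid needs the inverse.
    xf <- register_rigid(head, atlas_head)
    mask_v <- apply_transform(atlas_brain_mask, invert_affine(xf),
                              grid_of(head), "nearest")
  }
  m <- morph_close(mask_v$data > 0.5)
  mask <- as_volume(array(as.numeric(m), dim(head$data)), head$affine)
  brain <- as_volume(head$data * as.numeric(m), head$affine)
  list(brain = brain, mask = mask)
}

#' Full file-preparation chain for one subject
#'
#' Order fixed as: extract brain, estimate/correct bias, provisional
#' prior-free segmentation, GM-peak norming to 100.
#'
#' @param head an `agetpl_volume`.
#' @param atlas list with `head` and `brain_mask` volumes (e.g. from a
#'   phantom atlas case), or NULL to skip extraction when `head` is already
#'   brain-extracted (then `mask` is taken as `head > 0`).
#' @param control_spacing bias-field smoothness scale in mm.
#' @param correct_bias_field set FALSE to skip bias correction (e.g. for
#'   bias-free phantoms).
#' @return list with `brain`, `mask`, `bias`, `normalized`, `scale`, `pve`
#'   (the provisional prior-free segmentation of the normalized brain).
#' @export
preprocess_subject <- function(head, atlas = NULL, control_spacing = 60,
                               correct_bias_field = TRUE) {
  if (!is.null(atlas)) {
    ex <- extract_brain(head, atlas$head, atlas$brain_mask)
  } else {
    m <- head$data > 0
    ex <- list(brain = head,
               mask = as_volume(array(as.numeric(m), dim(head$data)), head$affine))
  }
  bias <- NULL
  brain <- ex$brain
  if (correct_bias_field) {
    bias <- estimate_bias_field(brain, ex$mask, control_spacing)
    brain <- correct_bias(brain, bias)
    brain$data <- brain$data * (ex$mask$data > 0)
  }
  seg <- segment_em(brain, ex$mask, priors = NULL, seg_config())
  nrm <- normalize_gm_peak(brain, seg$pve)
  list(brain = brain, mask = ex$mask, bias = bias,
       normalized = nrm$volume, scale = nrm$scale, pve = seg$pve)
}
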
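#' Affine (rigid) world-space transform
#'
#' Transforms are stored in the resampling (pullback) convention: the matrix
#' maps points in the *fixed* image's world space to the corresponding points
#' in the *moving* image's world space, so that warping the moving image onto
#' the fixed grid is a single interpolation.
#'
#' @param matrix 4x4 world-mm map.
#' @param dof_tag `"rigid6"` or `"affine12"`.
#' @return an `agetpl_affine`.
#' @export
affine_transform <- function(matrix, dof_tag = c("rigid6", "affine12")) {
  dof_tag <- match.arg(dof_tag)
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (abs(det(matrix[1:3, 1:3])) < 1e-12) stop("transform is not invertible")
  if (dof_tag == "rigid6") {
    R <- matrix[1:3, 1:3]
    if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || det(R) < 0)
      stop("rigid6 requires an orthonormal rotation block with det +1")
  }
  structure(list(matrix = matrix, dof_tag = dof_tag), class = "agetpl_affine")
}

#' @export
print.agetpl_affine <- function(x, ...) {
  cat(sprintf("<agetpl_affine> %s\n", x$dof_tag))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Invert an affine transform
#' @param xf an `agetpl_affine`.
#' @return the inverse `agetpl_affine`.
#' @export
invert_affine <- function(xf) affine_transform(solve(xf$matrix), xf$dof_tag)

identity_affine <- function() affine_transform(diag(4))

# 6-parameter rigid matrix: rotations (rad, Rz Ry Rx) about `center`, then
# translation (mm)
rigid_matrix <- function(p, center) {
  cx <- cos(p[1]); sx <- sin(p[1])
  cy <- cos(p[2]); sy <- sin(p[2])
  cz <- cos(p[3]); sz <- sin(p[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center + p[4:6]
  m
}

volume_center_world <- function(vol) {
  drop(vox_to_world(vol, matrix((grid_dim(vol) - 1) / 2, 1)))
}

#' Rigid (6-DOF) intensity-based registration
#'
#' Minimizes the sum-of-squared-differences between the fixed image and the
#' moving image resampled through the candidate transform, by Nelder-Mead
#' over rotations and translations at two resolutions (coarse smoothed,
#' then full). Deterministic given its inputs.
#'
#' @param moving,fixed `agetpl_volume`s with overlapping fields of view.
#' @param max_iter optimizer iteration cap per stage.
#' @param quality `"full"` (coarse + full-resolution refinement) or
#'   `"coarse"` (smoothed, strided stage only; used for bulk prior mapping
#'   where sub-voxel precision is not needed).
#' @return an `agetpl_affine` (tag `rigid6`) mapping fixed world coordinates
#'   to moving world coordinates.
#' @export
register_rigid <- function(moving, fixed, max_iter = 300L,
                           quality = c("full", "coarse")) {
  quality <- match.arg(quality)
  if (sd(moving$data) == 0 || sd(fixed$data) == 0)
    stop("cannot register constant images")
  center <- volume_center_world(fixed)
  stages <- list(list(smooth = 2, stride = 2L, scale = c(0.02, 2)),
                 list(smooth = 0, stride = 1L, scale = c(0.005, 0.5)))
  if (quality == "coarse") stages <- stages[1]
  p <- rep(0, 6)
  for (st in stages) {
    fdat <- if (st$smooth > 0) {
      a <- gauss_smooth(fixed$data, st$smooth); dim(a) <- dim(fixed$data); a
    } else fixed$data
    mdat <- if (st$smooth > 0) {
      a <- gauss_smooth(moving$data, st$smooth); dim(a) <- dim(moving$data); a
    } else moving$data
    mvol <- as_volume(mdat, moving$affine)
    d <- dim(fdat)
    sub <- as.logical(array(0, d))
    ii <- seq(1, d[1], by = st$stride)
    jj <- seq(1, d[2], by = st$stride)
    kk <- seq(1, d[3], by = st$stride)
    sel <- array(FALSE, d); sel[ii, jj, kk] <- TRUE
    idx <- which(sel)
    pts <- grid_world_coords(list(dim = d, affine = fixed$affine))[idx, , drop = FALSE]
    fvals <- fdat[idx]
    cost <- function(q) {
      m <- rigid_matrix(q, center)
      xy <- sweep(pts %*% t(m[1:3, 1:3]), 2, m[1:3, 4], `+`)
      w <- sample_at(mvol, xy, "linear", outside = 0)
      mean((w - fvals)^2)
    }
    opt <- optim(p, cost, method = "Nelder-Mead",
                 control = list(maxit = max_iter, reltol = 1e-10,
                                parscale = rep(st$scale, each = 3)))
    if (!is.finite(opt$value)) stop("registration failed: non-finite metric")
    p <- opt$par
  }
  affine_transform(rigid_matrix(p, center), "rigid6")
}

#' Deformation field with forward and inverse displacements
#'
#' The forward field gives, at each voxel of its grid (the fixed/template
#' grid), the world-mm displacement such that `x + forward(x)` is the
#' corresponding point in the moving image's world space; the rigid
#' pre-alignment is folded into the field (and recorded in `pre_affine` for
#' provenance). The inverse field realizes the opposite mapping on the same
#' grid and satisfies the composition tolerance `inv_tol` (voxels).
#'
#' @param forward,inverse 4D arrays (nx, ny, nz, 3) of mm displacements.
#' @param grid grid list (`dim`, `affine`) the fields live on.
#' @param pre_affine `agetpl_affine` used for pre-alignment.
#' @param inv_tol inverse-consistency tolerance in voxels.
#' @param metrics optional named list of similarity metric values.
#' @return an `agetpl_deform`.
#' @export
deformation_field <- function(forward, inverse, grid, pre_affine = identity_affine(),
                              inv_tol = 0.2, metrics = list()) {
  stopifnot(length(dim(forward)) == 4L, dim(forward)[4] == 3L)
  if (!all(is.finite(forward)) || !all(is.finite(inverse)))
    stop("deformation fields must be finite")
  structure(list(forward = forward, inverse = inverse, grid = grid,
                 pre_affine = pre_affine, inv_tol = inv_tol, metrics = metrics),
            class = "agetpl_deform")
}

#' @export
print.agetpl_deform <- function(x, ...) {
  mx <- max(sqrt(rowSums(field_as_matrix(x$forward)^2)))
  cat(sprintf("<agetpl_deform> grid %s, max |forward| %.2f mm\n",
              paste(x$grid$dim, collapse = "x"), mx))
  invisible(x)
}

# sample a displacement field (nvox x 3 mm) at arbitrary world points
sample_field <- function(field_array, grid, xyz) {
  v <- world_to_vox(list(affine = grid$affine), xyz)
  d <- grid$dim
  out <- matrix(0, nrow(v), 3)
  for (c_ in 1:3) {
    comp <- field_array[, , , c_]
    out[, c_] <- cpp_sample3(as.numeric(comp), d, v[, 1], v[, 2], v[, 3],
                             0L, 0, TRUE)
  }
  out
}

field_as_matrix <- function(field_array) {
  d <- dim(field_array)
  matrix(field_array, prod(d[1:3]), 3)
}

matrix_as_field <- function(m, d) array(m, c(d, 3L))

downsample_grid <- function(arr, affine, factor) {
  if (factor == 1) return(list(data = arr, affine = affine))
  sm <- gauss_smooth(arr, factor / 2)
  dim(sm) <- dim(arr)
  ii <- seq(1, dim(arr)[1], by = factor)
  jj <- seq(1, dim(arr)[2], by = factor)
  kk <- seq(1, dim(arr)[3], by = factor)
  a2 <- affine
  a2[1:3, 1:3] <- affine[1:3, 1:3] * factor
  list(data = sm[ii, jj, kk, drop = FALSE], affine = a2)
}

# resample a (nvox x 3) field from grid `from` onto grid `to` (both lists)
resample_field_matrix <- function(U, from, to) {
  xyz <- grid_world_coords(to)
  sample_field(matrix_as_field(U, from$dim), from, xyz)
}

#' Multi-resolution deformable registration (diffeomorphic demons backend)
#'
#' Rigid pre-alignment followed by demons refinement over a 3-level pyramid
#' (4x / 2x / 1x downsampling). At each iteration the demons force is
#' smoothed with a fluid-like Gaussian, integrated by scaling-and-squaring
#' (so each increment is a small diffeomorphism), composed with the current
#' field, and regularized with a diffusion-like Gaussian. The returned field
#' folds the pre-alignment in and carries a fixed-point inverse.
#'
#' @param moving,fixed `agetpl_volume`s on comparable intensity scales
#'   (GM peak ~100 in the template pipeline).
#' @param schedule iterations per pyramid level, coarse to fine, e.g.
#'   `c(50, 50, 50)`; `c(50, 0, 0)` runs only the coarsest level.
#' @param pre_align run rigid pre-registration first (default TRUE).
#' @param sigma_fluid,sigma_diff Gaussian sigmas (voxels) for the update and
#'   the accumulated field.
#' @param inv_tol inverse-consistency tolerance in voxels of the fixed grid.
#' @return an `agetpl_deform` on the fixed grid.
#' @export
register_deformable <- function(moving, fixed, schedule = c(50, 50, 50),
                                pre_align = TRUE, sigma_fluid = 1,
                                sigma_diff = 0.7, inv_tol = 0.2) {
  stopifnot(length(schedule) == 3L, all(schedule >= 0))
  A <- if (pre_align) register_rigid(moving, fixed) else identity_affine()
  fgrid <- grid_of(fixed)
  # resample moving through the affine once
  xyz_f <- grid_world_coords(fgrid)
  m0 <- sample_at(moving, sweep(xyz_f %*% t(A$matrix[1:3, 1:3]), 2,
                                A$matrix[1:3, 4], `+`), "linear", 0)
  dim(m0) <- fgrid$dim
  metric0 <- mean((m0 - fixed$data)^2)
  if (!is.finite(metric0)) stop("registration failed: non-finite metric")

  factors <- c(4L, 2L, 1L)
  U <- NULL   # nvox x 3 at current level
  level_metrics <- numeric(0)
  prev_grid <- NULL
  for (lev in 1:3) {
    f <- factors[lev]
    fx <- downsample_grid(fixed$data, fixed$affine, f)
    mv <- downsample_grid(m0, fixed$affine, f)
    lgrid <- list(dim = dim(fx$data), affine = fx$affine)
    U <- if (is.null(U)) matrix(0, prod(lgrid$dim), 3)
         else resample_field_matrix(U, prev_grid, lgrid)
    if (schedule[lev] > 0)
      U <- demons_level(mv$data, fx$data, lgrid, U, schedule[lev],
                        sigma_fluid, sigma_diff)
    prev_grid <- lgrid
    wl <- warp_array(mv$data, lgrid, lgrid, U)
    level_metrics <- c(level_metrics, mean((wl - fx$data)^2))
  }
  U <- resample_field_matrix(U, prev_grid, fgrid)
  # guarantee the field does not do worse than affine-only at full resolution
  warped <- warp_array(m0, fgrid, fgrid, U)
  metric_def <- mean((warped - fixed$data)^2)
  if (metric_def > metric0) {
    U <- matrix(0, prod(fgrid$dim), 3)
    metric_def <- metric0
  }
  # total forward displacement: x -> A(x + u(x)) expressed as x + U_tot(x)
  pts <- xyz_f + U
  tot <- sweep(pts %*% t(A$matrix[1:3, 1:3]), 2, A$matrix[1:3, 4], `+`) - xyz_f
  fwd <- matrix_as_field(tot, fgrid$dim)
  # The affine part must not enter the fixed-point inversion (a large
  # rotation field is not contractive): invert only the small demons
  # displacement u, then compose analytically with the exact affine inverse:
  # phi^-1(y) = (id + v)(A^-1 y), whose residual equals the fixed-point
  # residual of v.
  v <- invert_disp(matrix_as_field(U, fgrid$dim), fgrid, inv_tol)
  Ainv <- solve(A$matrix)
  z <- sweep(xyz_f %*% t(Ainv[1:3, 1:3]), 2, Ainv[1:3, 4], `+`)
  v_at_z <- sample_field(v, fgrid, z)
  inv <- matrix_as_field(z + v_at_z - xyz_f, fgrid$dim)
  deformation_field(fwd, inv, fgrid, pre_affine = A, inv_tol = inv_tol,
                    metrics = list(affine = metric0, final = metric_def,
                                   levels = level_metrics))
}

# warp an array defined on grid `src` onto grid `dst` through displacement U
# (nvox x 3, on dst grid)
warp_array <- function(arr, src, dst, U) {
  xyz <- grid_world_coords(dst) + U
  v <- world_to_vox(list(affine = src$affine), xyz)
  out <- cpp_sample3(as.numeric(arr), src$dim, v[, 1], v[, 2], v[, 3], 0L, 0, FALSE)
  dim(out) <- dst$dim
  out
}

demons_level <- function(mov, fix, lgrid, U, n_iter, sigma_fluid, sigma_diff) {
  d <- lgrid$dim
  sp <- voxel_size(lgrid$affine)
  spm <- mean(sp)
  xyz <- grid_world_coords(lgrid)
  best <- list(U = U, metric = Inf)
  for (it in seq_len(n_iter)) {
    w <- warp_array(mov, lgrid, lgrid, U)
    diffi <- w - fix
    metric <- mean(diffi^2)
    if (metric < best$metric) best <- list(U = U, metric = metric)
    g <- cpp_grad3(as.numeric(w), d, sp)
    nvox <- prod(d)
    gx <- g[1:nvox]; gy <- g[nvox + 1:nvox]; gz <- g[2 * nvox + 1:nvox]
    g2 <- gx^2 + gy^2 + gz^2
    den <- g2 + (diffi / spm)^2
    s <- ifelse(den > 1e-12, -as.numeric(diffi) / den, 0)
    delta <- cbind(s * gx, s * gy, s * gz)
    # cap the raw step at one voxel
    mag <- sqrt(rowSums(delta^2))
    cap <- mag > spm
    if (any(cap)) delta[cap, ] <- delta[cap, ] * (spm / mag[cap])
    for (c_ in 1:3) {
      a <- array(delta[, c_], d)
      delta[, c_] <- gauss_smooth(a, sigma_fluid)
    }
    delta <- exp_field(delta, lgrid, spm)
    # compose: U <- delta o U, i.e. U_new(x) = delta(x) + U(x + delta(x))
    U <- delta + sample_field(matrix_as_field(U, d), lgrid, xyz + delta)
    for (c_ in 1:3) {
      a <- array(U[, c_], d)
      U[, c_] <- gauss_smooth(a, sigma_diff)
    }
  }
  w <- warp_array(mov, lgrid, lgrid, U)
  if (mean((w - fix)^2) > best$metric) U <- best$U
  U
}

# scaling-and-squaring exponential of a velocity field (nvox x 3, mm)
exp_field <- function(vel, lgrid, spacing) {
  mx <- sqrt(max(rowSums(vel^2)))
  n <- 0L
  if (mx > 0.25 * spacing)
    n <- min(8L, max(0L, ceiling(log2(mx / (0.25 * spacing)))))
  psi <- vel / 2^n
  if (n > 0) {
    xyz <- grid_world_coords(lgrid)
    d <- lgrid$dim
    for (i in seq_len(n))
      psi <- psi + sample_field(matrix_as_field(psi, d), lgrid, xyz + psi)
  }
  psi
}

# fixed-point inversion of a displacement field; error if the residual does
# not meet tol (in voxels) after max_iter sweeps
invert_disp <- function(fwd, grid, tol = 0.2, max_iter = 20L) {
  d <- grid$dim
  spm <- mean(voxel_size(grid$affine))
  xyz <- grid_world_coords(grid)
  V <- -field_as_matrix(fwd)
  worst <- Inf
  for (it in seq_len(max_iter)) {
    V <- -sample_field(fwd, grid, xyz + V)
    res <- V + sample_field(fwd, grid, xyz + V)
    worst <- max(sqrt(rowSums(res^2))) / spm
    if (worst <= tol) break
  }
  if (worst > tol)
    stop(sprintf("deformation inversion did not converge: worst residual %.3f voxels", worst))
  matrix_as_field(V, d)
}

#' Invert a deformation field
#'
#' Swaps the forward and inverse displacement fields (recomputing the inverse
#' by fixed-point iteration if absent) and inverts the recorded pre-affine.
#'
#' @param field an `agetpl_deform`.
#' @param max_iter fixed-point iteration cap.
#' @return an `agetpl_deform` realizing the inverse mapping.
#' @export
invert_deformation <- function(field, max_iter = 20L) {
  inv <- field$inverse
  if (is.null(inv)) inv <- invert_disp(field$forward, field$grid,
                                       field$inv_tol, max_iter)
  deformation_field(inv, field$forward, field$grid,
                    pre_affine = invert_affine(field$pre_affine),
                    inv_tol = field$inv_tol, metrics = field$metrics)
}

#' Resample an image or PVE map through a transform
#'
#' Maps every voxel of `target_grid` to world coordinates, displaces it
#' through the transform (affine matrix or forward displacement field), and
#' samples the input there. PVE maps are interpolated per class, their mask
#' is warped, and the classes are renormalized to sum to 1 inside the warped
#' mask.
#'
#' @param image an `agetpl_volume` or `agetpl_pve`.
#' @param xf an `agetpl_affine` or `agetpl_deform`. Use
#'   [invert_deformation()] / [invert_affine()] to resample in the opposite
#'   direction.
#' @param target_grid a grid list ([grid_of()]) or `agetpl_volume`.
#' @param interp `"linear"` or `"nearest"`.
#' @return object of the same kind as `image`, on `target_grid`.
#' @export
apply_transform <- function(image, xf, target_grid, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  if (is_volume(target_grid)) target_grid <- grid_of(target_grid)
  xyz <- grid_world_coords(target_grid)
  if (inherits(xf, "agetpl_affine")) {
    pts <- sweep(xyz %*% t(xf$matrix[1:3, 1:3]), 2, xf$matrix[1:3, 4], `+`)
  } else if (inherits(xf, "agetpl_deform")) {
    pts <- xyz + sample_field(xf$forward, xf$grid, xyz)
  } else stop("xf must be an agetpl_affine or agetpl_deform")

  resamp <- function(vol, itp, outside = 0) {
    out <- sample_at(vol, pts, itp, outside)
    dim(out) <- target_grid$dim
    as_volume(out, target_grid$affine)
  }
  if (is_volume(image)) return(resamp(image, interp))
  if (inherits(image, "agetpl_pve")) {
    mask_w <- resamp(image$mask, "linear")
    mask_w$data <- as.numeric(mask_w$data >= 0.5)
    dim(mask_w$data) <- target_grid$dim
    cls <- lapply(PVE_CLASSES, function(cl) resamp(image[[cl]], interp))
    names(cls) <- PVE_CLASSES
    return(pve_map(cls$om, cls$gm, cls$wm, mask_w, normalize = TRUE))
  }
  stop("image must be an agetpl_volume or agetpl_pve")
}

# identity resampling of priors onto another grid
resample_pve <- function(pve, grid) apply_transform(pve, identity_affine(), grid)
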
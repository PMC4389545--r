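#' @useDynLib agetpl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif quantile sd lm coef confint pf approx
#'   median cor.test dnorm aggregate t.test
#' @importFrom utils head tail read.delim write.table
NULL

#' 3D scalar volume with a voxel-to-world affine
#'
#' The basic spatial container of the package: a 3D numeric array plus a 4x4
#' affine mapping 0-based voxel indices (i, j, k, 1) to world coordinates in
#' mm (RAS). All geometry in the package is expressed in world mm, so grids
#' and voxel sizes can change without changing anatomy.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-index-to-world matrix. Defaults to an isotropic
#'   grid of `voxel_size` mm centered on the world origin.
#' @param voxel_size isotropic voxel edge in mm, used when `affine` is NULL.
#' @return an object of class `agetpl_volume` with fields `data` and `affine`.
#' @export
as_volume <- function(data, affine = NULL, voxel_size = 1) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (is.null(affine)) affine <- centered_affine(dim(data), voxel_size)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine is not invertible")
  if (!all(is.finite(data))) stop("volume data must be finite")
  structure(list(data = data, affine = affine), class = "agetpl_volume")
}

#' @export
print.agetpl_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<agetpl_volume> %dx%dx%d, voxel %.3gx%.3gx%.3g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3],
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "agetpl_volume")

#' Affine for a grid centered on the world origin
#' @param dim grid dimensions (3 integers).
#' @param voxel_size voxel edge(s) in mm (scalar or length 3).
#' @return 4x4 affine.
#' @export
centered_affine <- function(dim, voxel_size = 1) {
  vs <- rep_len(voxel_size, 3L)
  a <- diag(4)
  a[1:3, 1:3] <- diag(vs, 3L)
  a[1:3, 4] <- -(dim - 1) / 2 * vs
  a
}

#' Per-axis voxel size in mm
#' @param vol an `agetpl_volume` or 4x4 affine.
#' @return length-3 numeric vector.
#' @export
voxel_size <- function(vol) {
  a <- if (is_volume(vol)) vol$affine else vol
  sqrt(colSums(a[1:3, 1:3]^2))
}

#' Convert 0-based voxel indices to world mm (and back)
#'
#' @param vol an `agetpl_volume` (or a grid list with `$affine`).
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates.
#' @export
vox_to_world <- function(vol, ijk) {
  a <- grid_affine(vol)
  ijk <- matrix_3(ijk)
  sweep(ijk %*% t(a[1:3, 1:3]), 2, a[1:3, 4], `+`)
}

#' @rdname vox_to_world
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @export
world_to_vox <- function(vol, xyz) {
  a <- grid_affine(vol)
  inv <- solve(a)
  xyz <- matrix_3(xyz)
  sweep(xyz, 2, a[1:3, 4], `-`) %*% t(inv[1:3, 1:3])
}

matrix_3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  x
}

grid_affine <- function(x) {
  if (is_volume(x)) x$affine else x$affine
}

grid_dim <- function(x) {
  if (is_volume(x)) dim(x$data) else x$dim
}

#' Grid geometry of a volume
#'
#' A lightweight description (dims + affine) of a sampling grid, used as the
#' `target_grid` of [apply_transform()].
#' @param vol an `agetpl_volume`.
#' @return list with `dim` and `affine`.
#' @export
grid_of <- function(vol) list(dim = dim(vol$data), affine = vol$affine)

same_grid <- function(a, b, tol = 1e-6) {
  all(grid_dim(a) == grid_dim(b)) &&
    max(abs(grid_affine(a) - grid_affine(b))) < tol
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(sprintf("%s are not on the same grid", what))
}

#' World coordinates of every voxel of a grid
#' @param grid a volume or grid list.
#' @return nvox x 3 matrix, voxels in array (column-major) order.
#' @keywords internal
grid_world_coords <- function(grid) {
  d <- grid_dim(grid)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
  vox_to_world(list(affine = grid_affine(grid)), ijk)
}

#' Sample a volume at world coordinates
#' @param vol an `agetpl_volume`.
#' @param xyz n x 3 world coordinates (mm).
#' @param interp "linear" or "nearest".
#' @param outside value returned outside the grid.
#' @return numeric vector of samples.
#' @export
sample_at <- function(vol, xyz, interp = c("linear", "nearest"), outside = 0) {
  interp <- match.arg(interp)
  v <- world_to_vox(vol, xyz)
  cpp_sample3(as.numeric(vol$data), dim(vol$data),
              v[, 1], v[, 2], v[, 3],
              if (interp == "linear") 0L else 1L, outside, FALSE)
}

gauss_smooth <- function(arr, sigma_vox) {
  cpp_gauss3(as.numeric(arr), dim(arr), rep_len(sigma_vox, 3L))
}

#' Deterministic seed derivation
#'
#' Derives a child seed below 2^31 from a root seed and a label, so that every
#' stage/subject gets an independent but reproducible stream.
#' @param root integer root seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return integer seed.
#' @export
derive_seed <- function(root, ...) {
  lab <- paste(c(root, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h + 1)
}
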
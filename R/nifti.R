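# Minimal NIfTI-1 codec. The pipeline only needs single-frame scalar volumes
# and 3-component displacement fields, stored uncompressed (.nii) or gzipped
# (.nii.gz); the affine is carried in the sform rows. No R NIfTI package is
# assumed to be available.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)
NIFTI_BITPIX <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L, float64 = 64L)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_nifti <- function(data, affine, path, datatype = "float32") {
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  d <- dim(data)
  ndim <- length(d)
  if (!ndim %in% c(3L, 4L)) stop("only 3D volumes and 4D fields are written")
  dimv <- rep.int(1L, 8L)
  if (ndim == 3L) {
    dimv[1:4] <- c(3L, d)
    intent <- 0L
  } else {
    # vector field: store components in the 5th dimension (NIfTI convention)
    dimv[1:6] <- c(5L, d[1:3], 1L, d[4])
    intent <- 1007L
  }
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size)
  wf <- function(x) writeBin(as.numeric(x), con, size = 4)
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                      # sizeof_hdr
  wc(36)                           # data_type..dim_info
  wi(dimv, 2)                      # dim[8]
  wf(c(0, 0, 0)); wi(intent, 2)    # intent_p1-3, intent_code
  wi(dt, 2); wi(NIFTI_BITPIX[[datatype]], 2); wi(0L, 2)
  wf(c(1, vs, 1, 1, 1, 1))         # pixdim (qfac = 1)
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2); wc(2)                 # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  desc <- charToRaw("agetpl"); wc0 <- raw(80); wc0[seq_along(desc)] <- desc
  writeBin(wc0, con)               # descrip
  wc(24)                           # aux_file
  wi(0L, 2); wi(2L, 2)             # qform_code = 0, sform_code = 2
  wf(rep(0, 6))                    # quaternions + qoffsets
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])
  wc(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  wc(4)                            # extension flag
  x <- as.numeric(data)
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(x)), con, size = NIFTI_BITPIX[[datatype]] / 8)
  } else {
    writeBin(x, con, size = NIFTI_BITPIX[[datatype]] / 8)
  }
  invisible(path)
}

read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (short header): ", path)
  endian <- .Platform$endian
  geti <- function(off, size, n = 1, e = endian)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size, endian = e)
  if (geti(0, 4) != 348L) {
    endian <- if (endian == "little") "big" else "little"
    if (geti(0, 4) != 348L) stop("not a NIfTI-1 file: ", path)
  }
  getf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4, endian = endian)
  dimv <- geti(40, 2, 8)
  ndim <- dimv[1]
  datatype <- geti(70, 2)
  pixdim <- getf(76, 8)
  vox_offset <- getf(108)
  scl_slope <- getf(112); scl_inter <- getf(116)
  sform_code <- geti(254, 2)
  qform_code <- geti(252, 2)
  dt_name <- names(NIFTI_DT)[match(datatype, unlist(NIFTI_DT))]
  if (is.na(dt_name)) stop("unsupported NIfTI datatype code ", datatype)
  nd <- dimv[2:(ndim + 1)]
  nvox <- prod(nd)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  size <- NIFTI_BITPIX[[dt_name]] / 8
  what <- if (dt_name %in% c("float32", "float64")) "numeric" else "integer"
  data <- readBin(con, what, n = nvox, size = size, endian = endian,
                  signed = dt_name != "uint8")
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  if (ndim == 5L && nd[4] == 1L) {        # vector field stored in dim 5
    nd <- nd[c(1:3, 5)]
    ndim <- 4L
  } else {
    while (ndim > 3L && nd[ndim] == 1L) ndim <- ndim - 1L  # squeeze singletons
    nd <- nd[1:ndim]
  }
  dim(data) <- nd
  affine <- NULL
  if (sform_code > 0) {
    affine <- rbind(getf(280, 4), getf(296, 4), getf(312, 4), c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    b <- getf(256); cc <- getf(260); dd <- getf(264)
    a2 <- max(0, 1 - b^2 - cc^2 - dd^2); a <- sqrt(a2)
    R <- rbind(
      c(a^2 + b^2 - cc^2 - dd^2, 2 * (b * cc - a * dd), 2 * (b * dd + a * cc)),
      c(2 * (b * cc + a * dd), a^2 + cc^2 - b^2 - dd^2, 2 * (cc * dd - a * b)),
      c(2 * (b * dd - a * cc), 2 * (cc * dd + a * b), a^2 + dd^2 - b^2 - cc^2))
    qfac <- if (pixdim[1] == 0) 1 else pixdim[1]
    S <- R %*% diag(c(pixdim[2:3], qfac * pixdim[4]))
    affine <- rbind(cbind(S, getf(268, 3)), c(0, 0, 0, 1))
  } else {
    affine <- diag(4); diag(affine)[1:3] <- pmax(pixdim[2:4], 1e-6)
  }
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("non-invertible affine in ", path)
  list(data = data, affine = affine, ndim = ndim)
}

#' Read / write a 3D volume as NIfTI-1
#'
#' `write_volume()` stores the volume as float32 with the affine in the sform
#' rows; `read_volume()` accepts uint8/int16/int32/float32/float64 data with
#' either byte order and reconstructs the affine from the sform (or qform)
#' fields. Paths ending in `.gz` are transparently (de)compressed.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol an `agetpl_volume`.
#' @param datatype storage type for writing, default `"float32"`.
#' @return `read_volume()` returns an `agetpl_volume`; `write_volume()` the
#'   path, invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- read_nifti(path)
  if (nf$ndim != 3L)
    stop(sprintf("expected a 3D volume, got %dD: %s", nf$ndim, path))
  as_volume(nf$data, nf$affine)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, datatype = "float32") {
  stopifnot(is_volume(vol))
  invisible(write_nifti(vol$data, vol$affine, path, datatype))
}

# displacement fields: 4D (x,y,z,3) arrays of mm displacements
write_field_nifti <- function(field_array, affine, path) {
  write_nifti(field_array, affine, path, "float32")
}

read_field_nifti <- function(path) {
  nf <- read_nifti(path)
  if (length(dim(nf$data)) != 4L) stop("expected a 4D displacement field: ", path)
  nf
}
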
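# Minimal NIfTI-1 I/O.
#
# No NIfTI reader ships with the supported package set, so the single-file
# .nii / .nii.gz layout (348-byte header + voxel payload) is read and written
# directly. Only what segmentation masks need is supported: 3D grids, the
# common integer/float datatypes, spacing from the sform affine (column
# norms) falling back to pixdim. Orientation is deliberately ignored: every
# quantity computed downstream (areas, volumes, component counts) is
# intrinsic to the grid.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

read_nifti_header <- function(raw348, endian) {
  con <- rawConnection(raw348)
  on.exit(close(con))
  h <- list()
  h$sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  readBin(con, "raw", 36)                      # unused historical fields
  h$dim <- readBin(con, "integer", 8, 2, endian = endian)
  readBin(con, "double", 3, 4, endian = endian)  # intent_p1..p3
  readBin(con, "integer", 1, 2, endian = endian) # intent_code
  h$datatype <- readBin(con, "integer", 1, 2, endian = endian)
  h$bitpix <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 1, 2, endian = endian) # slice_start
  h$pixdim <- readBin(con, "double", 8, 4, endian = endian)
  h$vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  h$scl_slope <- readBin(con, "double", 1, 4, endian = endian)
  h$scl_inter <- readBin(con, "double", 1, 4, endian = endian)
  readBin(con, "raw", 132)                     # slice_end .. aux_file
  h$qform_code <- readBin(con, "integer", 1, 2, endian = endian)
  h$sform_code <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "double", 6, 4, endian = endian)  # quaternion fields
  h$srow <- matrix(readBin(con, "double", 12, 4, endian = endian),
                   nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)                      # intent_name
  h$magic <- rawToChar(readBin(con, "raw", 4))
  h
}

#' Read a segmentation mask from a NIfTI file
#'
#' Reads a 3D volume from `.nii` or `.nii.gz`, binarizes it (any nonzero
#' voxel becomes foreground) and derives voxel spacing from the sform
#' affine's column norms when an sform is present, else from `pixdim`.
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @param role stored on the mask; see [segmentation_mask()]
#' @param verbose log dimensions and spacing via `message()`
#' @param binarize map any nonzero voxel to 1 (default). With FALSE the
#'   raw integer labels are kept as attribute `"labels"` on the mask
#'   (used for multi-label inputs such as per-voxel contact labels)
#' @return a [segmentation_mask()]
#' @export
read_mask <- function(path, role = c("tumor_pre", "tumor_post", "brain"),
                      verbose = FALSE, binarize = TRUE) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("read_mask: file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw348 <- readBin(con, "raw", 348L)
  if (length(raw348) < 348L) stop("read_mask: truncated NIfTI header in ", path)
  endian <- "little"
  h <- read_nifti_header(raw348, endian)
  if (h$sizeof_hdr != 348L) {
    endian <- "big"
    h <- read_nifti_header(raw348, endian)
    if (h$sizeof_hdr != 348L) {
      stop("read_mask: not a NIfTI-1 file (sizeof_hdr != 348): ", path)
    }
  }
  ndim <- h$dim[1]
  dims <- h$dim[2:(1 + max(ndim, 1))]
  if (ndim > 3L) {
    if (all(dims[4:ndim] == 1L)) dims <- dims[1:3] else
      stop("read_mask: expected a 3D volume, dim field reports ", ndim, "D data")
  }
  if (ndim < 3L || length(dims) != 3L || any(dims < 1L)) {
    stop("read_mask: expected a 3D volume, dim field is invalid")
  }
  dt <- NIFTI_DTYPES[[as.character(h$datatype)]]
  if (is.null(dt)) stop("read_mask: unsupported datatype code ", h$datatype)
  if (h$sform_code > 0) {
    spacing <- sqrt(colSums(h$srow[, 1:3, drop = FALSE]^2))
    origin <- h$srow[, 4]
    spacing_src <- "sform"
  } else {
    spacing <- h$pixdim[2:4]
    origin <- c(0, 0, 0)
    spacing_src <- "pixdim"
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop(sprintf("read_mask: non-finite or zero spacing in %s field of %s",
                 spacing_src, path))
  }
  # skip bytes between header end and vox_offset, then read the payload
  skip <- as.integer(round(h$vox_offset)) - 348L
  if (skip < 0L) skip <- 4L   # default single-file offset is 352
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  signed <- !(dt$size <= 2L && !dt$signed)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = if (dt$what == "integer") signed else TRUE)
  if (length(vals) < n) stop("read_mask: truncated voxel payload in ", path)
  vox <- array(vals, dim = dims)
  m <- segmentation_mask(vox, spacing, origin_offset = origin, role = role)
  if (!binarize) attr(m, "labels") <- array(as.integer(round(vals)), dims)
  if (verbose) {
    message(sprintf("read_mask: %s dims=%s spacing=%s mm (%s)", basename(path),
                    paste(dims, collapse = "x"),
                    paste(format(spacing, digits = 4), collapse = "x"),
                    spacing_src))
  }
  m
}

#' Write a segmentation mask to a NIfTI file
#'
#' Writes uint8 voxel data with spacing in both `pixdim` and a diagonal
#' sform affine, so that [read_mask()] round-trips voxels, spacing and
#' origin exactly. Compression follows the file extension (`.nii.gz`).
#'
#' @param mask a [segmentation_mask()]
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  dims <- dim(mask$voxels)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(348L, 4L)                                   # sizeof_hdr
  wb(raw(36), 1L)                                # data_type..dim_info
  wb(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  wb(numeric(3), 4L)                             # intent_p1..p3
  wb(0L, 2L)                                     # intent_code
  wb(2L, 2L)                                     # datatype uint8
  wb(8L, 2L)                                     # bitpix
  wb(0L, 2L)                                     # slice_start
  wb(c(1, mask$spacing, 1, 1, 1, 1), 4L)         # pixdim[8]
  wb(352, 4L)                                    # vox_offset
  wb(c(1, 0), 4L)                                # scl_slope, scl_inter
  wb(0L, 2L); wb(raw(2), 1L)                     # slice_end, slice_code, xyzt_units
  wb(numeric(4), 4L)                             # cal_max..toffset
  wb(integer(2), 4L)                             # glmax, glmin
  wb(raw(104), 1L)                               # descrip + aux_file
  wb(0L, 2L); wb(1L, 2L)                         # qform_code=0, sform_code=1
  wb(numeric(6), 4L)                             # quaternion fields
  srow <- cbind(diag(mask$spacing), mask$origin_offset)
  wb(as.numeric(t(srow)), 4L)                    # srow_x, srow_y, srow_z
  wb(raw(16), 1L)                                # intent_name
  writeBin(charToRaw("n+1"), con); wb(raw(1), 1L)  # magic "n+1\0"
  wb(raw(4), 1L)                                 # extension indicator
  writeBin(as.raw(mask$voxels != 0), con)
  invisible(path)
}
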
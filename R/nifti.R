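# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# The installed R stack carries no NIfTI package, so the small subset of the
# format this pipeline needs is implemented directly: 3D volumes, float32 or
# uint8 storage, voxel spacing in pixdim, vox_offset 352, no extensions, no
# orientation math (the analysis only ever uses header spacing).

#' Write a 3D array as a NIfTI-1 file
#'
#' @param a 3D numeric array.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param datatype `"float32"` for images, `"uint8"` for masks.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(a, path, spacing, datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(a)) == 3L, length(spacing) == 3L, all(spacing > 0))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  dt_code <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L

  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(36), con)                                    # unused
  writeBin(c(3L, dim(a), 1L, 1L, 1L, 1L), con, size = 2, endian = "little")  # dim[8]
  writeBin(raw(14), con)                                    # intent_p*, intent_code
  writeBin(c(dt_code, bitpix, 0L), con, size = 2, endian = "little")
  writeBin(c(0, spacing, 0, 0, 0, 0), con, size = 4, endian = "little")  # pixdim[8]
  writeBin(352, con, size = 4, endian = "little")           # vox_offset (float)
  writeBin(c(1, 0), con, size = 4, endian = "little")       # scl_slope, scl_inter
  writeBin(raw(4), con)                                     # slice_end..xyzt_units
  writeBin(c(0, 0), con, size = 4, endian = "little")       # cal_max, cal_min
  writeBin(raw(16), con)                                    # slice_duration..glmin
  desc <- charToRaw("renalrad phantom volume")
  writeBin(c(desc, raw(80L - length(desc))), con)           # descrip
  writeBin(raw(24), con)                                    # aux_file
  writeBin(c(0L, 0L), con, size = 2, endian = "little")     # qform, sform = 0
  writeBin(rep(0, 18), con, size = 4, endian = "little")    # quatern/srow
  writeBin(raw(16), con)                                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)             # magic
  writeBin(raw(4), con)                                     # extension flag

  if (datatype == "float32") {
    writeBin(as.numeric(a), con, size = 4, endian = "little")
  } else {
    v <- as.integer(a)
    if (any(v < 0 | v > 255)) stop("uint8 overflow when writing mask")
    writeBin(as.raw(v), con)
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or any plain 3D NIfTI-1)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array) and `spacing` (length-3 mm).
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  if (length(hdr) < 352) stop("truncated NIfTI header: ", path)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = "little")
  }
  sizeof <- rd(0, "integer", 1, 4)
  if (sizeof != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  dims <- rd(40, "integer", 8, 2)
  if (dims[1] != 3L) stop("only 3D volumes are supported, got ndim=", dims[1])
  shape <- dims[2:4]
  dt_code <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  nvox <- prod(shape)
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- switch(as.character(dt_code),
    "2"  = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = nvox, size = 2, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n = nvox, size = 4, endian = "little")),
    "16" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = nvox, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", dt_code))
  if (length(data) != nvox) stop("truncated NIfTI data: ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  list(data = array(data, shape), spacing = pixdim[2:4])
}
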
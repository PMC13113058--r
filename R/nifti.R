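# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O, little-endian, RAS
# orientation encoded in the sform (diagonal spacing affine, zero origin).
# Covers exactly what the package emits: float32 CT grids and uint8 masks.

.nifti_dtypes <- list(uint8 = list(code = 2L, bitpix = 8L),
                      int16 = list(code = 4L, bitpix = 16L),
                      float32 = list(code = 16L, bitpix = 32L),
                      float64 = list(code = 64L, bitpix = 64L))

#' Write a 3D array as a NIfTI-1 volume
#'
#' @param arr 3D numeric array.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param spacing voxel spacing (sx, sy, sz) in mm, stored both in `pixdim`
#'   and the sform affine.
#' @param datatype `"float32"` (CT) or `"uint8"` (masks).
#' @export
write_nifti <- function(arr, path, spacing = c(1, 1, 1),
                        datatype = c("float32", "uint8", "int16", "float64")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(arr)) == 3, length(spacing) == 3, all(spacing > 0))
  dt <- .nifti_dtypes[[datatype]]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }
  wi(348L, 4)                                  # sizeof_hdr
  wc("", 10); wc("", 18)                       # data_type, db_name
  wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(c(3L, dim(arr), 1L, 1L, 1L, 1L), 2)       # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                    # intent_p1-3, intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wf(c(1, spacing, 1, 1, 1, 1))                # pixdim (qfac = 1)
  wf(352); wf(1); wf(0)                        # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc("", 1)                         # slice_end, slice_code
  writeBin(as.raw(2L), con)                    # xyzt_units: mm
  wf(c(0, 0, 0, 0))                            # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4)                             # glmax, glmin
  wc("pvlnet synthetic aortic-root volume", 80)
  wc("", 24)                                   # aux_file
  wi(0L, 2); wi(1L, 2)                         # qform_code 0, sform_code 1
  wf(c(0, 0, 0, 0, 0, 0))                      # quatern b,c,d + qoffset
  wf(c(spacing[1], 0, 0, 0))                   # srow_x
  wf(c(0, spacing[2], 0, 0))                   # srow_y
  wf(c(0, 0, spacing[3], 0))                   # srow_z
  wc("", 16)                                   # intent_name
  wc("n+1", 4)                                 # magic
  writeBin(raw(4), con)                        # no extensions
  v <- as.vector(arr)
  if (datatype %in% c("uint8", "int16")) {
    storage <- as.integer(round(v))
    if (datatype == "uint8" && (any(storage < 0) || any(storage > 255))) {
      stop("uint8 volume has values outside [0, 255]")
    }
    writeBin(storage, con, size = dt$bitpix / 8, endian = "little")
  } else {
    writeBin(v, con, size = dt$bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()] (or any little-endian
#' single-file NIfTI-1 with datatype uint8/int16/float32/float64)
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return list with `data` (3D array), `spacing`, `datatype`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file")
  invisible(readBin(con, "raw", n = 36))       # skip to dim
  dims <- ri(8, 2)
  ndim <- dims[1]
  shape <- dims[2:(1 + max(ndim, 3))]
  invisible(rf(3)); invisible(ri(1, 2))        # intent_p, intent_code
  dtype_code <- ri(1, 2)
  bitpix <- ri(1, 2)
  invisible(ri(1, 2))                          # slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  invisible(readBin(con, "raw", n = 240))      # rest of header + extension flag
  to_skip <- vox_offset - 352
  if (to_skip > 0) invisible(readBin(con, "raw", n = to_skip))
  n <- prod(shape[1:3])
  dt_name <- names(Filter(function(d) d$code == dtype_code, .nifti_dtypes))
  if (length(dt_name) != 1) stop("unsupported NIfTI datatype code ", dtype_code)
  data <- switch(dt_name,
                 uint8 = as.numeric(readBin(con, "integer", n = n, size = 1,
                                            signed = FALSE)),
                 int16 = as.numeric(readBin(con, "integer", n = n, size = 2,
                                            endian = "little")),
                 float32 = readBin(con, "numeric", n = n, size = 4,
                                   endian = "little"),
                 float64 = readBin(con, "numeric", n = n, size = 8,
                                   endian = "little"))
  arr <- array(data, dim = shape[1:3])
  list(data = arr, spacing = pixdim[2:4], datatype = dt_name)
}
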
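## Minimal NIfTI-1 reader/writer. No NIfTI-capable R package is
## available in the target environment, so the small subset needed here
## (single-file .nii/.nii.gz, little-endian, datatypes uint8/int16/
## int32/float32/float64, scl_slope/scl_inter honoured) is implemented
## directly. Acquisition metadata that the NIfTI header cannot carry
## (TR lists, gas schedules, units) lives in a JSON sidecar; see
## read_series()/write_series().

nifti_datatypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4` = list(what = "integer", size = 2L, signed = TRUE, bitpix = 16L),
  `8` = list(what = "integer", size = 4L, signed = TRUE, bitpix = 32L),
  `16` = list(what = "double", size = 4L, signed = TRUE, bitpix = 32L),
  `64` = list(what = "double", size = 8L, signed = TRUE, bitpix = 64L))

#' Write a numeric array as a NIfTI-1 image
#'
#' Single-file little-endian NIfTI-1 with time (or the TR step) as the
#' 4th dimension. Data are stored as float64 so values round-trip
#' exactly. Paths ending in `.gz` are gzip-compressed.
#'
#' @param x numeric array (2-4 dimensions).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim grid spacings, one per dimension (default 1).
#' @param description free-text header description (<= 79 chars).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = NULL, description = "") {
  x <- as.array(x)
  nd <- length(dim(x))
  if (nd < 2 || nd > 4) stop("only 2-4 dimensional images are supported")
  if (is.null(pixdim)) pixdim <- rep(1, nd)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else
    file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                                endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                                endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4L,
                                endian = "little")
  w_chr <- function(s, n) {
    r <- charToRaw(substr(s, 1, n - 1))
    writeBin(c(r, raw(n - length(r))), con)
  }
  w_i32(348)                               # sizeof_hdr
  w_chr("", 10); w_chr("", 18)             # data_type, db_name
  w_i32(0); w_i16(0); w_chr("r", 1)        # extents, session_error, regular
  writeBin(raw(1), con)                    # dim_info
  w_i16(c(nd, dim(x), rep(1L, 7 - nd)))    # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)              # intent_p1-3, intent_code
  w_i16(64); w_i16(64L); w_i16(0)          # datatype, bitpix, slice_start
  w_f32(c(1, pixdim, rep(1, 7 - nd)))      # pixdim[8] (qfac = 1)
  w_f32(352)                               # vox_offset
  w_f32(1); w_f32(0)                       # scl_slope, scl_inter
  w_i16(0); writeBin(raw(2), con)          # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                     # cal_max/min, slice_duration, toffset
  w_i32(c(0, 0))                           # glmax, glmin
  w_chr(description, 80); w_chr("", 24)    # descrip, aux_file
  w_i16(c(0, 0))                           # qform_code, sform_code
  w_f32(rep(0, 6))                         # quatern, qoffset
  w_f32(c(pixdim[1], 0, 0, 0))             # srow_x
  w_f32(c(0, pixdim[2], 0, 0))             # srow_y
  w_f32(c(0, 0, if (nd >= 3) pixdim[3] else 1, 0))  # srow_z
  w_chr("", 16)                            # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)                    # extension flag (none)
  vals <- as.numeric(x)
  vals[is.na(vals)] <- NaN
  writeBin(vals, con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return A numeric array with attribute `"pixdim"`.
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")   # gzfile also reads plain files
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header")
  r_i32 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)],
                                        "integer", n, 4L,
                                        endian = "little")
  endian <- "little"
  if (r_i32(0) != 348) {
    endian <- "big"
    r_i32 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)],
                                          "integer", n, 4L, endian = "big")
    if (r_i32(0) != 348) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  r_i16 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 2 * n)],
                                        "integer", n, 2L, endian = endian)
  r_f32 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)],
                                        "double", n, 4L, endian = endian)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
  dims <- r_i16(40, 8)
  nd <- dims[1]
  if (nd < 1 || nd > 7) stop("bad NIfTI dimension count")
  shape <- dims[2:(1 + nd)]
  dtcode <- as.character(r_i16(70))
  dt <- nifti_datatypes[[dtcode]]
  if (is.null(dt))
    stop(sprintf("unsupported NIfTI datatype code %s", dtcode))
  pixdim <- r_f32(76, 8)[2:(1 + nd)]
  vox_offset <- r_f32(108)
  scl_slope <- r_f32(112); scl_inter <- r_f32(116)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data section")
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  out <- array(vals, shape)
  attr(out, "pixdim") <- pixdim
  out
}
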
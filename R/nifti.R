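#' Minimal NIfTI-1 input/output for label and scalar volumes
#'
#' Reads and writes single-file NIfTI-1 (`.nii`, optionally gzipped to
#' `.nii.gz`) volumes: 3-D integer label grids (written as int16) and 3-D
#' real-valued grids such as ground-truth thickness maps (written as
#' float32). Voxel spacing travels in `pixdim` (and a diagonal sform).
#' This is deliberately a minimal subset of the format: single-file, no
#' header extensions, little-endian writing, datatypes
#' uint8/int16/int32/float32/float64 on read.
#'
#' @param path file path; a `.gz` suffix selects gzip compression.
#' @param data 3-D array to write.
#' @param spacing_mm numeric length-3 voxel size in mm.
#' @param datatype `"int16"` or `"float32"`; integer arrays default to int16.
#' @return `read_nifti()` returns a list with `data` (3-D numeric array) and
#'   `spacing_mm`; `write_nifti()` returns `path` invisibly.
#' @examples
#' arr <- array(0L, c(4, 3, 2)); arr[2, 2, 1] <- 7L
#' f <- tempfile(fileext = ".nii")
#' write_nifti(arr, f, spacing_mm = c(0.5, 0.5, 3))
#' v <- read_nifti(f)
#' stopifnot(v$data[2, 2, 1] == 7, all(v$spacing_mm == c(0.5, 0.5, 3)))
#' @export
write_nifti <- function(data, path, spacing_mm,
                        datatype = if (is.integer(data)) "int16" else "float32") {
  stopifnot(length(dim(data)) == 3, length(spacing_mm) == 3)
  if (datatype == "int16" && any(abs(data) > 32767))
    stop("label values exceed int16 range")
  dtcode <- switch(datatype, int16 = 4L, float32 = 16L,
                   stop("unsupported datatype '", datatype, "'"))
  bitpix <- switch(datatype, int16 = 16L, float32 = 32L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wr <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                                   # sizeof_hdr
  wr(36)                                        # data_type..dim_info (unused)
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), 2)       # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1..3, intent_code
  wi(dtcode, 2); wi(bitpix, 2); wi(0L, 2)       # datatype, bitpix, slice_start
  wf(c(1, spacing_mm, 1, 1, 1, 1))              # pixdim[8]
  wf(352); wf(1); wf(0)                         # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wr(1)                              # slice_end, slice_code
  writeBin(as.raw(2L), con)                     # xyzt_units = mm
  wf(c(0, 0, 0, 0))                             # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  wr(80); wr(24)                                # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code, sform_code
  wf(rep(0, 6))                                 # quatern b/c/d, qoffset x/y/z
  wf(c(spacing_mm[1], 0, 0, 0))                 # srow_x
  wf(c(0, spacing_mm[2], 0, 0))                 # srow_y
  wf(c(0, 0, spacing_mm[3], 0))                 # srow_z
  wr(16)                                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  wr(4)                                         # extension indicator = none
  if (datatype == "int16") {
    writeBin(as.integer(data), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file: truncated header")
  ri <- function(off, size, n = 1, endian)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  rf <- function(off, n = 1, endian)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = endian)
  endian <- "little"
  if (ri(0, 4, endian = "little") != 348L) {
    if (ri(0, 4, endian = "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file: sizeof_hdr != 348")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file: bad magic '", magic, "'")
  dims <- ri(40, 2, n = 8, endian = endian)
  ndim <- dims[1]
  if (ndim < 3) stop("expected a 3-D volume, got ", ndim, "-D")
  if (ndim > 3 && any(dims[5:(ndim + 1)] > 1))
    stop("only single-frame 3-D volumes are supported")
  shape <- dims[2:4]
  dtcode <- ri(70, 2, endian = endian)
  pixdim <- rf(76, n = 8, endian = endian)
  vox_offset <- rf(108, endian = endian)
  scl_slope <- rf(112, endian = endian)
  scl_inter <- rf(116, endian = endian)
  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  nvox <- prod(shape)
  vals <- switch(as.character(dtcode),
    "2"  = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                              signed = FALSE, endian = endian)),
    "4"  = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                              endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n = nvox, size = 4,
                              endian = endian)),
    "16" = readBin(con, "double", n = nvox, size = 4, endian = endian),
    "64" = readBin(con, "double", n = nvox, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code ", dtcode))
  if (length(vals) < nvox) stop("truncated NIfTI data section")
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, shape), spacing_mm = abs(pixdim[2:4]))
}

#' Read or write a `label_volume` as NIfTI-1 plus a JSON code table
#'
#' The integer grid goes into a `.nii` file; the structure-name to
#' label-code mapping goes into a JSON sidecar (`<path>.json` by default).
#'
#' @param volume a [label_volume()].
#' @param path `.nii` / `.nii.gz` path.
#' @param json_path path of the JSON code-table sidecar.
#' @param codes named integer code table used (on read) when no sidecar
#'   exists; defaults to [knee_codes].
#' @return `read_label_volume()` returns a [label_volume()];
#'   `write_label_volume()` returns `path` invisibly.
#' @export
write_label_volume <- function(volume, path,
                               json_path = paste0(path, ".json")) {
  stopifnot(inherits(volume, "label_volume"))
  write_nifti(volume$data, path, volume$spacing_mm, datatype = "int16")
  jsonlite::write_json(as.list(volume$codes), json_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path, json_path = paste0(path, ".json"),
                              codes = knee_codes) {
  v <- read_nifti(path)
  if (file.exists(json_path)) {
    lst <- jsonlite::read_json(json_path)
    codes <- setNames(as.integer(unlist(lst)), names(lst))
  }
  dat <- v$data
  storage.mode(dat) <- "integer"
  label_volume(dat, v$spacing_mm, codes)
}
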
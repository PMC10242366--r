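# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz).
#
# Supports the datatypes this package emits and consumes: uint8 (2),
# int16 (4), int32 (8), float32 (16), float64 (64). Data are returned with
# scl_slope/scl_inter applied when set. Only little-endian files are
# written; reading detects byte order from sizeof_hdr.

nifti_datatypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),
  `4` = list(what = "integer", size = 2L, signed = TRUE),
  `8` = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double", size = 4L, signed = TRUE),
  `64` = list(what = "double", size = 8L, signed = TRUE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A numeric or integer array with the header dims, with attributes
#'   `pixdim` (spatial steps, mm) and `datatype`.
#' @export
read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file (short header)",
                                   call. = FALSE)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)",
                                 call. = FALSE)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)",
                                        call. = FALSE)
  rint <- function(off, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], "integer", n, size,
            endian = endian)
  }
  rflt <- function(off, n) {
    readBin(hdr_raw[(off + 1):(off + n * 4)], "double", n, 4L, endian = endian)
  }
  dim_field <- rint(40L, 8L, 2L)
  ndim <- dim_field[1]
  dims <- dim_field[1 + seq_len(ndim)]
  dims[dims == 0L] <- 1L
  datatype <- rint(70L, 1L, 2L)
  pixdim <- rflt(76L, 8L)[1 + seq_len(ndim)]
  vox_offset <- rflt(108L, 1L)
  scl_slope <- rflt(112L, 1L)
  scl_inter <- rflt(116L, 1L)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype %d", datatype),
                        call. = FALSE)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(dims)
  x <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(x) < n) stop("truncated NIfTI data section", call. = FALSE)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    x <- x * scl_slope + scl_inter
  }
  dim(x) <- dims
  attr(x, "pixdim") <- pixdim
  attr(x, "datatype") <- datatype
  x
}

#' Write a NIfTI-1 volume
#'
#' @param x A numeric or integer array (rank 2 to 4).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32) or 64 (float64).
#' @param pixdim Spatial step sizes in mm, recycled to the array rank.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, datatype = 16L, pixdim = 1) {
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype %d", datatype),
                        call. = FALSE)
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  ndim <- length(dims)
  if (ndim > 7L) stop("too many dimensions for NIfTI-1", call. = FALSE)
  pixdim <- rep_len(as.numeric(pixdim), ndim)
  hdr <- raw(348L)
  put <- function(off, values, size, type = "integer") {
    b <- writeBin(if (type == "integer") as.integer(values)
                  else as.numeric(values),
                  raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
    invisible(NULL)
  }
  put(0L, 348L, 4L)                               # sizeof_hdr
  dim_field <- integer(8L)
  dim_field[1] <- ndim
  dim_field[1 + seq_len(ndim)] <- dims
  put(40L, dim_field, 2L)                         # dim
  put(70L, datatype, 2L)                          # datatype
  put(72L, dt$size * 8L, 2L)                      # bitpix
  pd <- numeric(8L)
  pd[1] <- 1
  pd[1 + seq_len(ndim)] <- pixdim
  put(76L, pd, 4L, "double")                      # pixdim
  put(108L, 352, 4L, "double")                    # vox_offset
  put(112L, 1, 4L, "double")                      # scl_slope
  put(116L, 0, 4L, "double")                      # scl_inter
  put(252L, 1L, 2L)                               # qform_code (scanner)
  put(264L, c(0, 0, 0), 4L, "double")             # quaternions b,c,d
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L)) # magic
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con) # extension flag
  if (dt$what == "integer") {
    storage.mode(x) <- "integer"
    if (datatype == 2L) {
      if (any(x < 0 | x > 255)) stop("values out of uint8 range", call. = FALSE)
      writeBin(as.raw(x), con)
    } else {
      writeBin(as.vector(x), con, size = dt$size, endian = "little")
    }
  } else {
    writeBin(as.vector(as.numeric(x)), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
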
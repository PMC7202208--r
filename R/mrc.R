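#' Read an MRC2014 volume
#'
#' Reads a cubic mode-2 (32-bit float) MRC2014 file into a
#' [density_volume()]. The voxel size is taken as `cella / mx` and the
#' header origin (words 50-52) is respected. Files in other data modes or
#' truncated files raise an error without returning a partial volume.
#'
#' @param path Path to an `.mrc` file.
#' @return A `density_volume`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (is.na(mode) || mode != 2L)
    stop("unsupported MRC mode ", mode, " (only mode 2, 32-bit float)",
         call. = FALSE)
  if (file.size(path) < 1024 + hdr_int[24] + 4 * nx * ny * nz)
    stop("truncated MRC file: ", path, call. = FALSE)
  seek(con, 0)
  invisible(readBin(con, "integer", n = 7, size = 4, endian = "little"))
  mx <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 4 * 49)
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  nsymbt <- hdr_int[24]
  seek(con, 1024 + nsymbt)
  data <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
                  endian = "little")
  voxel <- if (mx[1] > 0 && cella[1] > 0) cella[1] / mx[1] else 1
  density_volume(array(data, c(nx, ny, nz)), voxel, origin)
}

#' Write an MRC2014 volume
#'
#' Writes a `density_volume` as a mode-2 (32-bit float) MRC2014 file with
#' the voxel size encoded in `cella/mx` and the origin in header words
#' 50-52. The write -> read round trip preserves the data array bit-exactly
#' at float32 precision.
#'
#' @param vol A `density_volume`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(is_density_volume(vol))
  n <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n)                       # nx ny nz
  wi(2L)                      # mode 2: float32
  wi(c(0L, 0L, 0L))           # nxstart nystart nzstart
  wi(n)                       # mx my mz
  wf(n * vol$voxel_size)      # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))  # dmin dmax dmean
  wi(c(1L, 0L))               # ispg, nsymbt
  wi(rep(0L, 25))             # extra (words 26-50 region up to word 49)
  wf(vol$origin)              # origin x y z (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(vol$data))     # rms
  wi(0L)                      # nlabl
  writeBin(raw(800), con)     # labels
  writeBin(as.vector(vol$data), con, size = 4, endian = "little")
  invisible(path)
}
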
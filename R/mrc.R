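#' @name mrc_io
#' @title Minimal MRC2014 map I/O
#' @description
#' Reads and writes MRC/CCP4 density maps in mode 2 (32-bit float),
#' little-endian, with the MRC2014 ORIGIN record carrying the position of
#' the first voxel centre and MAPC/MAPR/MAPS = 1/2/3 (x fastest). Values
#' round-trip exactly at 32-bit float precision.
NULL

#' Write a density grid as an MRC2014 map
#'
#' @param grid a `density_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- grid$dim
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                 # NX NY NZ
  wi(2L)                # MODE 2 = float32
  wi(c(0L, 0L, 0L))     # NXSTART NYSTART NZSTART
  wi(d)                 # MX MY MZ
  wf(d * grid$spacing)  # CELLA
  wf(c(90, 90, 90))     # CELLB
  wi(c(1L, 2L, 3L))     # MAPC MAPR MAPS
  v <- grid$values
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(1L)                # ISPG
  wi(0L)                # NSYMBT
  wi(rep(0L, 25))       # EXTRA (words 25-49)
  wf(grid$origin)       # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)              # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(as.numeric(v)))  # RMS
  wi(0L)                # NLABL
  writeBin(raw(800L), con)  # 10 empty labels
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC2014 map into a density grid
#'
#' Supports mode 2 (float32) maps with axis order x,y,z (MAPC/MAPR/MAPS =
#' 1/2/3). The voxel origin is taken from the ORIGIN record when nonzero,
#' else from NXSTART * spacing.
#'
#' @param path MRC/CCP4 file.
#' @param species species label to attach.
#' @return a `density_grid`.
#' @export
read_mrc <- function(path, species = "total") {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2, float32)")
  nstart <- ri(3)
  m <- ri(3)
  cella <- rf(3)
  rf(3)                 # CELLB
  mapcrs <- ri(3)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order: ", paste(mapcrs, collapse = ","))
  rf(3)                 # DMIN DMAX DMEAN
  ri(1)                 # ISPG
  nsymbt <- ri(1)
  ri(25)                # EXTRA
  origin <- rf(3)
  seek(con, 1024 + nsymbt)
  spacing <- cella / m
  if (all(origin == 0) && any(nstart != 0)) origin <- nstart * spacing
  v <- readBin(con, "numeric", prod(d), size = 4L, endian = "little")
  density_grid(origin, spacing, d, array(v, d), species)
}
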
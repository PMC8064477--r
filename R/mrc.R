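## Minimal MRC2014 volume I/O (modes 0, 1, 2), x fastest.
##
## No MRC reader exists in the R stack this package builds on, so the
## format is read and written directly: 1024-byte header, little-endian,
## data in x-fastest order.  Only the fields this package relies on are
## interpreted; the voxel size is cella/mx and the MRC2014 origin words
## (50-52) are honoured.

#' 3D density volume container
#'
#' @param grid 3D numeric array (x fastest, i.e. dim 1 = x).
#' @param voxel_size cubic voxel edge, Angstrom.
#' @param origin physical coordinate of the centre of voxel (1,1,1).
#' @return object of class \code{volume_density}.
#' @export
volume_density <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  if (voxel_size <= 0) stop_param("voxel_size must be positive")
  stopifnot(length(dim(grid)) == 3)
  structure(list(grid = grid, voxel_size = voxel_size, origin = origin),
            class = "volume_density")
}

#' @export
print.volume_density <- function(x, ...) {
  d <- dim(x$grid)
  cat("Density volume ", d[1], "x", d[2], "x", d[3], " voxels at ",
      x$voxel_size, " A/voxel\n", sep = "")
  invisible(x)
}

#' Write a volume as an MRC file
#'
#' Mode 2 (32-bit float) MRC2014; voxel size is stored in cella/mx and the
#' physical origin in the origin header words.
#'
#' @param volume a \code{\link{volume_density}}.
#' @param path output file.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_density"))
  d <- dim(volume$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2)                                   # mode 2: float32
  wi(c(0, 0, 0))                          # nxstart..
  wi(d)                                   # mx my mz
  wf(d * volume$voxel_size)               # cella
  wf(c(90, 90, 90))                       # cellb
  wi(c(1, 2, 3))                          # mapc mapr maps
  wf(c(min(volume$grid), max(volume$grid), mean(volume$grid)))
  wi(c(0, 0))                             # ispg, nsymbt
  wi(rep(0, 25))                          # extra
  wf(volume$origin)                       # origin (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.integer(c(0x44, 0x44, 0, 0)), con, size = 1)  # machst LE
  wf(stats::sd(as.numeric(volume$grid)))  # rms
  wi(0)                                   # nlabl
  writeBin(raw(800), con)                 # labels
  writeBin(as.numeric(volume$grid), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC volume
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32).  Corrupt or
#' truncated files raise a format error naming the offending field.
#'
#' @param path MRC file path.
#' @return a \code{\link{volume_density}}.
#' @export
read_volume <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop("MRC format error: file shorter than the 1024-byte header",
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  if (any(d <= 0) || any(d > 1e5))
    stop("MRC format error: implausible dimensions (nx/ny/nz)", call. = FALSE)
  mode <- ri(1)
  if (!mode %in% c(0, 1, 2))
    stop("MRC format error: unsupported mode ", mode, call. = FALSE)
  ri(3)                                   # nxstart
  m <- ri(3)                              # mx my mz
  cella <- rf(3)
  rf(3)                                   # cellb
  ri(3)                                   # mapc mapr maps
  rf(3)                                   # dmin dmax dmean
  ri(2)                                   # ispg nsymbt
  nsymbt <- 0
  ri(25)                                  # extra
  origin <- rf(3)
  seek(con, 1024 + nsymbt)
  n <- prod(d)
  bytes <- c(`0` = 1, `1` = 2, `2` = 4)[as.character(mode)]
  if (sz < 1024 + n * bytes)
    stop("MRC format error: data section truncated (expected ",
         n * bytes, " bytes)", call. = FALSE)
  data <- if (mode == 2) readBin(con, "numeric", n, size = 4,
                                 endian = "little")
          else readBin(con, "integer", n, size = bytes, signed = TRUE,
                       endian = "little")
  voxel <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else 1
  volume_density(array(as.numeric(data), dim = d), voxel, origin)
}

#' Write a 2D density image as a single-section MRC file
#'
#' @param image a \code{\link{density_image}}.
#' @param path output file.
#' @export
write_image_mrc <- function(image, path) {
  stopifnot(inherits(image, "density_image"))
  vol <- volume_density(array(image$grid, dim = c(dim(image$grid), 1)),
                        image$pixel_size,
                        origin = c(image$origin, 0))
  write_volume(vol, path)
}

#' Read a single-section MRC file as a 2D density image
#'
#' @param path MRC file path.
#' @return a \code{\link{density_image}}.
#' @export
read_image_mrc <- function(path) {
  vol <- read_volume(path)
  if (dim(vol$grid)[3] != 1)
    stop("MRC format error: expected a single-section (nz = 1) file",
         call. = FALSE)
  density_image(vol$grid[, , 1], vol$voxel_size, vol$origin[1:2])
}
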
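# MRC2014 volume I/O.
#
# No CRAN/Bioconductor package reads the MRC map format, so the (simple,
# fully specified) 1024-byte header + raster layout is implemented here
# directly.  Written files are little-endian mode 2 (float32) with the voxel
# size carried in cella/mx; the reader additionally accepts modes 0 (int8),
# 1 (int16) and 6 (uint16) and big-endian files.

.mrc_modes <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Read an MRC2014 density map
#'
#' @param path path to an existing MRC file holding a cubic volume.
#' @return a [voxel_grid]; the pixel size is taken from the header
#'   (`cella/mx`), defaulting to 1 A if the header cell is unset.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_map: file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  read_header <- function(endian) {
    seek(con, 0)
    h <- list()
    h$nxyz <- readBin(con, "integer", 3, size = 4, endian = endian)
    h$mode <- readBin(con, "integer", 1, size = 4, endian = endian)
    h$nstart <- readBin(con, "integer", 3, size = 4, endian = endian)
    h$mxyz <- readBin(con, "integer", 3, size = 4, endian = endian)
    h$cella <- readBin(con, "numeric", 3, size = 4, endian = endian)
    h$cellb <- readBin(con, "numeric", 3, size = 4, endian = endian)
    h$mapcrs <- readBin(con, "integer", 3, size = 4, endian = endian)
    h$dstats <- readBin(con, "numeric", 3, size = 4, endian = endian)
    h$ispg <- readBin(con, "integer", 1, size = 4, endian = endian)
    h$nsymbt <- readBin(con, "integer", 1, size = 4, endian = endian)
    h
  }
  plausible <- function(h) {
    !anyNA(h$nxyz) && !is.na(h$mode) &&
      as.character(h$mode) %in% names(.mrc_modes) &&
      all(h$nxyz >= 1) && all(h$nxyz <= 100000L)
  }
  endian <- "little"
  h <- read_header(endian)
  if (!plausible(h)) {
    endian <- "big"
    h <- read_header(endian)
    if (!plausible(h))
      stop(sprintf("read_map: corrupt or unsupported MRC header in %s", path))
  }
  n <- h$nxyz
  if (n[1] != n[2] || n[1] != n[3])
    stop(sprintf("read_map: non-cubic volume (%d x %d x %d) in %s",
                 n[1], n[2], n[3], path))
  seek(con, 1024 + max(h$nsymbt, 0L))
  nv <- prod(as.numeric(n))
  vals <- switch(as.character(h$mode),
    `0` = as.numeric(readBin(con, "integer", nv, size = 1, signed = TRUE)),
    `1` = as.numeric(readBin(con, "integer", nv, size = 2, signed = TRUE,
                             endian = endian)),
    `2` = readBin(con, "numeric", nv, size = 4, endian = endian),
    `6` = as.numeric(readBin(con, "integer", nv, size = 2, signed = FALSE,
                             endian = endian)))
  if (length(vals) != nv)
    stop(sprintf("read_map: truncated data section in %s", path))
  ps <- if (h$mxyz[1] > 0 && is.finite(h$cella[1]) && h$cella[1] > 0)
    h$cella[1] / h$mxyz[1] else 1
  voxel_grid(array(vals, dim = n), ps, name = basename(path))
}

#' Write a map as MRC2014 (mode 2, float32)
#'
#' @param grid a [voxel_grid].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_map <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e)
                    stop(sprintf("write_map: cannot open '%s' for writing",
                                 path)))
  on.exit(close(con))
  n <- dim(grid$data)[1]
  x <- as.vector(grid$data)
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(c(n, n, n))                       # nx ny nz
  wi(2L)                               # mode 2 = float32
  wi(c(0L, 0L, 0L))                    # nxstart
  wi(c(n, n, n))                       # mx my mz
  wf(rep(n * grid$pixel_size, 3))      # cella
  wf(c(90, 90, 90))                    # cellb
  wi(c(1L, 2L, 3L))                    # mapc mapr maps
  wf(c(min(x), max(x), mean(x)))       # dmin dmax dmean
  wi(1L)                               # ispg (volume)
  wi(0L)                               # nsymbt
  wi(rep(0L, 25))                      # extra (words 25-49)
  wf(c(0, 0, 0))                       # origin
  writeBin(charToRaw("MAP "), con)     # map id
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(x) * sqrt((length(x) - 1) / length(x)))  # rms about mean
  wi(1L)                               # nlabl
  lab <- charToRaw(formatC("ardecon volume", width = -80))
  writeBin(lab, con)
  writeBin(raw(800 - length(lab)), con)
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}
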
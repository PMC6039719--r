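# Minimal MRC2014 map I/O (mode 2, 32-bit float voxels). The origin is
# stored in the ORIGIN header words (Angstrom); axes are written in x, y, z
# order (MAPC/MAPR/MAPS = 1, 2, 3). No installed R package reads MRC, so
# the format is implemented here with readBin/writeBin.

#' Write a density map to an MRC file
#'
#' @param map a `density_map`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mrc <- function(map, file) {
  stopifnot(inherits(map, "density_map"))
  dm <- dim(map$data)
  con <- file(file, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(dm)                      # NX NY NZ
  wi(2)                       # MODE 2: float32
  wi(c(0, 0, 0))              # NXSTART..
  wi(dm)                      # MX MY MZ
  wf(dm * map$voxel_size)     # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(c(1, 2, 3))              # MAPC MAPR MAPS
  v <- as.numeric(map$data)
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(1)                       # ISPG
  wi(0)                       # NSYMBT
  wi(rep(0, 25))              # EXTRA (word 27 could carry resolution; 0)
  wf(map$origin)              # ORIGIN (words 50-52)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(v))                   # RMS
  wi(1)                       # NLABL
  lab <- sprintf("%-80s", sprintf("xlscore simulated map, resolution %s A",
                                  format(map$resolution)))
  writeChar(substr(lab, 1, 80), con, 80, eos = NULL)
  writeChar(paste(rep(" ", 80 * 9), collapse = ""), con, 80 * 9,
            eos = NULL)
  wf(v)
  invisible(file)
}

#' Read a density map from an MRC file
#'
#' Supports mode-2 (float32) maps with axes in x, y, z order.
#'
#' @param file path to an MRC file.
#' @param resolution optional nominal resolution label to attach.
#' @return a `density_map`.
#' @export
read_mrc <- function(file, resolution = NA_real_) {
  con <- file(file, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4,
                            endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4,
                            endian = "little")
  dm <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) MRC maps are supported")
  ri(3)                       # NXSTART
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3)                       # CELLB
  mapc <- ri(3)
  if (!all(mapc == c(1, 2, 3)))
    stop("only MAPC/MAPR/MAPS = 1/2/3 axis order is supported")
  rf(3)                       # DMIN DMAX DMEAN
  ri(1)                       # ISPG
  nsymbt <- ri(1)
  ri(25)                      # EXTRA
  origin <- rf(3)
  seek(con, 1024 + nsymbt)
  v <- rf(prod(dm))
  voxel <- cella[1] / mxyz[1]
  density_map(array(v, dm), origin, voxel, resolution)
}
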
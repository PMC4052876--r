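## Minimal MRC2014 mode-2 (32-bit float) stack reader/writer — enough to
## round-trip image/pattern stacks produced by the forge and to ingest plain
## externally produced stacks.  Little-endian, no extended header.

#' Write an image stack to an MRC/MRCS file
#'
#' @param images numeric array `side x side x n` (a single matrix is treated
#'   as n = 1), written as MRC mode 2 (float32).
#' @param path output file path.
#' @param pixel_size pixel size in Angstrom (stored in the cell dimensions).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(images, path, pixel_size = 1) {
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1))
  stopifnot(length(dim(images)) == 3, dim(images)[1] == dim(images)[2])
  nx <- dim(images)[1]; ny <- dim(images)[2]; nz <- dim(images)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz, 2L))                     # NX NY NZ MODE
  wi(c(0L, 0L, 0L))                         # NXSTART..NZSTART
  wi(c(nx, ny, nz))                         # MX MY MZ
  wf(c(nx, ny, nz) * pixel_size)            # CELLA
  wf(c(90, 90, 90))                         # CELLB
  wi(c(1L, 2L, 3L))                         # MAPC MAPR MAPS
  wf(c(min(images), max(images), mean(images)))  # DMIN DMAX DMEAN
  wi(c(0L, 0L))                             # ISPG NSYMBT
  wi(rep(0L, 25))                           # EXTRA
  wf(c(0, 0, 0))                            # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # little-endian stamp
  wf(sd(as.vector(images)))                 # RMS
  wi(0L)                                    # NLABL
  writeBin(raw(800), con)                   # empty labels
  wf(as.vector(images))
  invisible(path)
}

#' Read an MRC/MRCS stack
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32), 6 (uint16),
#' little-endian.
#'
#' @param path MRC file path.
#' @return list with `images` (`nx x ny x nz` array) and `pixel_size`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop_confmap("MRC file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 4, size = 4, endian = "little")
  nx <- hdr_i[1]; ny <- hdr_i[2]; nz <- hdr_i[3]; mode <- hdr_i[4]
  readBin(con, "integer", n = 6, size = 4, endian = "little")   # starts, M*
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  npx <- nx * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = npx, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = npx, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = npx, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = npx, size = 2, signed = FALSE,
                  endian = "little"),
    stop_confmap("unsupported MRC mode %d", mode))
  if (length(data) < npx) stop_confmap("truncated MRC file: %s", path)
  list(images = array(as.numeric(data), dim = c(nx, ny, nz)),
       pixel_size = if (nx > 0 && cella[1] > 0) cella[1] / nx else 1)
}
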
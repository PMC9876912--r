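# MRC2014 mode-2 (float32) volume / image-stack I/O, little-endian.
# Header layout follows the MRC2014 standard: 1024-byte fixed header,
# "MAP " magic at word 53, machine stamp 0x44 0x44 0x00 0x00.

#' Write a volume or image stack as MRC/MRCS (mode 2, float32)
#'
#' Writes an MRC2014 file with correct dimension and cell (voxel size)
#' header fields. A 3-D array is written as-is (for a stack, the third
#' axis is the particle index, as in `.mrcs`); a matrix is written as a
#' single-section file; a `particle_stack` or `volume_grid` supplies its
#' own pixel size. Output is deterministic: identical input yields
#' byte-identical files.
#'
#' @param x array `c(nx, ny, nz)`, matrix, [render_volume()] result, or
#'   [generate_dataset()] stack.
#' @param path output file path.
#' @param pixel_size voxel/pixel edge in Angstrom (ignored when `x` knows
#'   its own).
#' @return `path`, invisibly.
#' @export
write_mrcs <- function(x, path, pixel_size = 1.0) {
  if (inherits(x, "particle_stack")) {
    pixel_size <- x$pixel_size
    x <- x$images
  } else if (inherits(x, "volume_grid")) {
    pixel_size <- x$voxel_size
    x <- x$data
  }
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3)
  if (any(!is.finite(x))) stop("cannot write non-finite values")
  d <- dim(x)
  v <- as.numeric(x)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(i) writeBin(as.integer(i), con, size = 4L,
                             endian = "little")
  wf <- function(f) writeBin(as.numeric(f), con, size = 4L,
                             endian = "little")
  wi(d)                         # nx, ny, nz
  wi(2L)                        # mode 2: float32
  wi(c(0L, 0L, 0L))             # nxstart, nystart, nzstart
  wi(d)                         # mx, my, mz
  wf(d * pixel_size)            # cella (Angstrom)
  wf(c(90, 90, 90))             # cellb
  wi(c(1L, 2L, 3L))             # mapc, mapr, maps
  wf(c(min(v), max(v), mean(v)))  # dmin, dmax, dmean
  wi(c(0L, 0L))                 # ispg (0: stack/image), nsymbt
  wi(c(0L, 0L))                 # extra words 25-26
  writeBin(raw(4), con)         # word 27: exttyp (unset)
  wi(20140L)                    # word 28: nversion (MRC2014)
  wi(rep(0L, 21))               # extra words 29-49
  wf(c(0, 0, 0))                # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v) * sqrt((length(v) - 1) / length(v)))  # rms
  wi(0L)                        # nlabl
  writeBin(raw(800), con)       # labels
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC/MRCS file (mode 2, float32)
#'
#' @param path MRC or MRCS file.
#' @return list with `data` (array `c(nx, ny, nz)`), `pixel_size`
#'   (Angstrom, from cella/mx) and `dim`.
#' @export
read_mrcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  ri <- function(n) readBin(con, "integer", n = n, size = 4L,
                            endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L,
                            endian = "little")
  d <- ri(3)
  if (length(d) < 3 || any(d <= 0) || any(d > 1e5))
    stop("malformed MRC header: bad dimensions at offset 0")
  mode <- ri(1)
  if (!identical(mode, 2L))
    stop("unsupported MRC mode ", mode, " at offset 12 (only mode 2)")
  ri(3)                 # nxstart..
  m <- ri(3)            # mx, my, mz
  cella <- rf(3)
  seek(con, 208)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MAP "))
    stop("malformed MRC header: missing 'MAP ' magic at offset 208")
  seek(con, 1024)
  v <- rf(prod(d))
  if (length(v) != prod(d))
    stop("truncated MRC data: expected ", prod(d), " voxels")
  pixel_size <- if (m[1] > 0) cella[1] / m[1] else 1.0
  list(data = array(v, dim = d), pixel_size = pixel_size, dim = d)
}
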
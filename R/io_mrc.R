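# Minimal MRC2014 reader/writer (mode 2, 32-bit float, little endian).
# Maps are written column-fastest with origin fields zeroed; the voxel grid
# is right-handed and the reader never reorders or flips axes (axis flips
# during format conversion are a classic way to silently change hand), it
# only checks that MAPC/MAPR/MAPS is the identity order.

#' Write a 3D map or image stack as MRC2014
#'
#' Mode 2 (32-bit float), column-fastest, pixel size stored in the cell
#' dimensions, origin zeroed.  `ispg = 1` marks a volume, `ispg = 0` an
#' image stack (used by [write_mrc_stack()]).
#'
#' @param path output file.
#' @param grid real 3D array (or matrix for a single image).
#' @param pixel_size voxel size, Angstrom.
#' @param ispg space-group field (1 volume, 0 stack).
#' @return invisibly, `path`.
#' @export
write_mrc_volume <- function(path, grid, pixel_size, ispg = 1L) {
  if (is.matrix(grid)) grid <- array(grid, c(dim(grid), 1L))
  d <- dim(grid)
  if (length(d) != 3L) stop("grid must be a 3D array")
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.numeric(grid)
  wi(c(d, 2L)); wi(c(0L, 0L, 0L)); wi(d)
  wf(d * pixel_size); wf(c(90, 90, 90)); wi(c(1L, 2L, 3L))
  wf(c(min(v), max(v), mean(v)))
  wi(c(as.integer(ispg), 0L))
  wi(rep(0L, 25L))                         # EXTRA block (words 25-49)
  wf(c(0, 0, 0))                           # ORIGIN
  writeBin(charToRaw("MAP "), con)         # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little endian
  wf(sd(v))                                # RMS
  wi(0L)                                   # NLABL
  writeBin(raw(800), con)                  # labels
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_mrc_volume
#' @param images box x box x P array of particle images.
#' @export
write_mrc_stack <- function(path, images, pixel_size) {
  write_mrc_volume(path, images, pixel_size, ispg = 0L)
}

#' Read an MRC2014 map or stack
#'
#' Supports mode 2 (float32) and mode 0/1 integer data; checks the
#' header/data size and the axis order (must be the identity — this reader
#' refuses to reorder axes because axis flips silently change hand).
#'
#' @param path MRC file.
#' @return list with `data` (3D array), `pixel_size` (Angstrom, from
#'   CELLA/MX), `ispg`, `mode`.
#' @export
read_mrc_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3); mode <- ri(1)
  ri(3)                    # nxstart
  mxyz <- ri(3)
  cella <- rf(3); rf(3)    # cellb
  mapcrs <- ri(3)
  rf(3)                    # dmin dmax dmean
  ispg <- ri(1); nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  if (any(dims <= 0)) stop("invalid MRC dimensions")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("MRC axis order is not the identity (refusing to silently permute axes)")
  n <- prod(dims)
  data <- switch(as.character(mode),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "1" = readBin(con, "integer", n, size = 2, endian = "little"),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    stop(sprintf("unsupported MRC mode %d", mode)))
  if (length(data) != n) stop("MRC header/data size mismatch")
  px <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  list(data = array(as.numeric(data), dims), pixel_size = px,
       ispg = ispg, mode = mode)
}

#' Write an FSC curve as a plain-text table
#'
#' Tab-separated columns: resolution (Angstrom), shell centre (1/Angstrom),
#' correlation value, voxel count.
#'
#' @param curve an `fsc_curve`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fsc_table <- function(curve, path) {
  df <- data.frame(resolution_A = sprintf("%.4f", curve$resolution),
                   shell_center_invA = sprintf("%.6f", curve$freq),
                   fsc = sprintf("%.6f", curve$value),
                   n_voxels = curve$n_voxels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
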
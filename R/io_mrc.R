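# Minimal MRC/CCP4 map IO (mode 2, float32, orthogonal cells, axis order
# x fastest) — enough to exchange half-maps with standard cryo-EM software.

#' Write a density map in MRC format
#'
#' @param map Numeric 3D array (x fastest, matching R's array layout).
#' @param voxel Voxel size in Angstrom (scalar or length-3).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_mrc <- function(map, voxel, path) {
  stopifnot(length(dim(map)) == 3)
  dims <- dim(map)
  voxel <- rep_len(voxel, 3)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4)
  wf <- function(x) writeBin(as.numeric(x), con, size = 4)
  wi(dims)                       # nx ny nz
  wi(2)                          # mode 2: float32
  wi(c(0, 0, 0))                 # nstart
  wi(dims)                       # mx my mz
  wf(dims * voxel)               # cell lengths
  wf(c(90, 90, 90))              # cell angles
  wi(c(1, 2, 3))                 # axis order
  wf(c(min(map), max(map), mean(map)))
  wi(1)                          # ispg
  wi(0)                          # nsymbt
  wi(integer(25))                # extra
  wf(c(0, 0, 0))                 # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  wf(stats::sd(as.vector(map)))
  wi(0)                          # nlabl
  writeBin(raw(800), con)        # labels
  writeBin(as.numeric(as.vector(map)), con, size = 4)
  invisible(path)
}

#' Read an MRC density map
#'
#' @param path MRC file (mode 2, axis order 1,2,3).
#' @return List with `map` (3D array), `voxel` (length-3, Angstrom) and
#'   `cell` (box edge lengths, Angstrom).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4)
  rf <- function(n) readBin(con, "numeric", n, size = 4)
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) MRC maps are supported")
  ri(3)                          # nstart
  m <- ri(3)                     # mx my mz
  cell <- rf(3)
  rf(3)                          # angles
  axes <- ri(3)
  if (!all(axes == c(1, 2, 3))) stop("only axis order 1,2,3 is supported")
  rf(3); ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  vals <- rf(prod(dims))
  list(map = array(vals, dim = dims), voxel = cell / m, cell = cell)
}
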
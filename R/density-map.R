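#' Density maps
#'
#' A density map is a 3D scalar grid with cubic voxels and a physical voxel
#' size, used for synthetic tomograms, references, subvolumes and averages.
#' The array is indexed \code{values[ix, iy, iz]}; the center of voxel
#' \code{(i, j, k)} sits at \code{origin + (c(i, j, k) - 0.5) * voxel_size}
#' nm, so the first array index runs along x.
#'
#' @param values numeric 3D array.
#' @param voxel_size voxel edge length in nm (> 0).
#' @param origin nm offset of the grid corner (length-3).
#' @return an object of class \code{density_map}.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (any(dim(values) < 1)) stop("grid dimensions must be >= 1")
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map:", paste(dim(x$values), collapse = " x "),
      "voxels,", x$voxel_size, "nm/voxel\n")
  invisible(x)
}

# coordinates (nm) of voxel centers along each axis
map_axes <- function(map) {
  lapply(seq_along(dim(map$values)), function(a)
    map$origin[a] + (seq_len(dim(map$values)[a]) - 0.5) * map$voxel_size)
}

#' Write a density map as MRC (mode 2, 32-bit float)
#'
#' Minimal MRC2014 writer: voxel size is stored via the cell dimensions
#' (Angstrom) over the grid sampling, axes in x-fastest order.
#'
#' @param map a \code{density_map}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_mrc <- function(map, path) {
  dm <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dm)                        # NX NY NZ
  wi(2L)                        # MODE 2 = float32
  wi(c(0L, 0L, 0L))             # NXSTART..
  wi(dm)                        # MX MY MZ
  wf(dm * map$voxel_size * 10)  # CELLA (Angstrom)
  wf(c(90, 90, 90))             # CELLB
  wi(c(1L, 2L, 3L))             # MAPC MAPR MAPS
  v <- map$values
  wf(c(min(v), max(v), mean(v)))
  wi(c(1L, 0L))                 # ISPG, NSYMBT
  wi(rep(0L, 25))               # EXTRA
  wf(map$origin * 10)           # ORIGIN (Angstrom)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(as.numeric(v)))
  wi(0L)                        # NLABL
  writeBin(raw(800), con)       # labels
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC density map (modes 0, 1, 2, 6)
#' @param path MRC file.
#' @return a \code{density_map} (values as double; voxel size in nm).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dm <- ri(3)
  mode <- ri(1)
  ri(3)                  # nstart
  mx <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3); ri(2); ri(25)
  origin <- rf(3) / 10
  readBin(con, "raw", 4 + 4)   # MAP, MACHST
  rf(1); nlabl <- ri(1)
  readBin(con, "raw", 800)
  n <- prod(dm)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                             endian = "little")),
    stop("unsupported MRC mode: ", mode))
  voxel <- if (mx[1] > 0 && cella[1] > 0) cella[1] / mx[1] / 10 else 1
  density_map(array(vals, dm), voxel, origin)
}
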
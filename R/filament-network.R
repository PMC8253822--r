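#' Filament networks
#'
#' A filament network is the common currency of the pipeline: a set of typed,
#' ordered 3D centerlines with optional polarity labels. It is stored as a
#' data frame with one row per centerline point and columns
#' \code{filament_id} (integer), \code{type} ("thin" or "thick"),
#' \code{polarity} (+1 if the pointed end of the filament is at the last
#' point of its centerline, -1 if at the first, NA if unknown),
#' \code{point_index} (1-based order along the centerline) and
#' \code{x, y, z} coordinates in nm.
#'
#' @param points data frame with the columns above (\code{polarity} may be
#'   omitted and defaults to NA).
#' @return an object of class \code{filament_network}.
#' @export
filament_network <- function(points) {
  req <- c("filament_id", "type", "point_index", "x", "y", "z")
  miss <- setdiff(req, names(points))
  if (length(miss))
    stop("missing network columns: ", paste(miss, collapse = ", "))
  if (is.null(points$polarity)) points$polarity <- NA_integer_
  if (!all(points$type %in% c("thin", "thick")))
    stop("filament type must be 'thin' or 'thick'")
  points <- points[order(points$filament_id, points$point_index), , drop = FALSE]
  npts <- table(points$filament_id)
  if (any(npts < 2)) stop("every filament needs >= 2 centerline points")
  rownames(points) <- NULL
  structure(points, class = c("filament_network", "data.frame"))
}

#' @export
print.filament_network <- function(x, ...) {
  ids <- unique(x$filament_id)
  ty <- x$type[!duplicated(x$filament_id)]
  cat("filament_network:", length(ids), "filaments (",
      sum(ty == "thin"), "thin /", sum(ty == "thick"), "thick ),",
      nrow(x), "points\n")
  invisible(x)
}

# split a network into per-filament data frames, preserving order
split_filaments <- function(network) {
  split(as.data.frame(network), network$filament_id)
}

# per-filament summary: one row per filament with type, polarity, endpoints
filament_summary <- function(network) {
  first <- !duplicated(network$filament_id)
  lastv <- !duplicated(network$filament_id, fromLast = TRUE)
  data.frame(
    filament_id = network$filament_id[first],
    type = network$type[first],
    polarity = network$polarity[first],
    x0 = network$x[first], y0 = network$y[first], z0 = network$z[first],
    x1 = network$x[lastv], y1 = network$y[lastv], z1 = network$z[lastv]
  )
}

#' Number of filaments and type counts
#' @param network a \code{filament_network}.
#' @return named integer vector with elements \code{thin}, \code{thick} and
#'   \code{total}.
#' @export
filament_counts <- function(network) {
  ty <- network$type[!duplicated(network$filament_id)]
  c(thin = sum(ty == "thin"), thick = sum(ty == "thick"), total = length(ty))
}

#' Thin-to-thick filament count ratio
#'
#' The thin:thick ratio of a network or of explicit segmentation totals, as
#' reported for myofibril cross-sections (adult vertebrate striated muscle
#' has ~2:1; neonatal cardiomyocytes ~3:1).
#'
#' @param n_thin,n_thick filament counts; alternatively pass a
#'   \code{filament_network} as \code{n_thin}.
#' @return list with \code{ratio} (numeric) and \code{rounded} (integer).
#' @export
filament_type_ratio <- function(n_thin, n_thick = NULL) {
  if (inherits(n_thin, "filament_network")) {
    cnt <- filament_counts(n_thin)
    n_thin <- cnt[["thin"]]; n_thick <- cnt[["thick"]]
  }
  if (n_thick <= 0) stop("n_thick must be positive")
  r <- n_thin / n_thick
  list(ratio = r, rounded = as.integer(round(r)))
}

#' Read / write filament networks as CSV
#'
#' The CSV dialect has columns \code{filament_id, type, polarity,
#' point_index, x_nm, y_nm, z_nm}, mirroring centerline tables exported from
#' filament-tracing software.
#'
#' @param network a \code{filament_network}.
#' @param path file path.
#' @return \code{read_network_csv} returns a \code{filament_network};
#'   \code{write_network_csv} returns \code{path} invisibly.
#' @export
write_network_csv <- function(network, path) {
  df <- data.frame(
    filament_id = network$filament_id, type = network$type,
    polarity = network$polarity, point_index = network$point_index,
    x_nm = network$x, y_nm = network$y, z_nm = network$z
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  df <- read.csv(path)
  filament_network(data.frame(
    filament_id = df$filament_id, type = df$type,
    polarity = df$polarity, point_index = df$point_index,
    x = df$x_nm, y = df$y_nm, z = df$z_nm
  ))
}

#' Unit direction of the pointed end per labeled filament
#'
#' @param network a \code{filament_network} with polarity labels.
#' @return data frame (filament_id, dx, dy, dz) for labeled filaments; the
#'   direction is the end-to-end unit vector times the polarity sign.
#' @export
pointed_directions <- function(network) {
  fs <- filament_summary(network)
  fs <- fs[!is.na(fs$polarity), , drop = FALSE]
  d <- cbind(fs$x1 - fs$x0, fs$y1 - fs$y0, fs$z1 - fs$z0)
  d <- d / sqrt(rowSums(d^2)) * fs$polarity
  data.frame(filament_id = fs$filament_id, dx = d[, 1], dy = d[, 2], dz = d[, 3])
}
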
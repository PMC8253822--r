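#' Resample a filament centerline at a fixed arc-length step
#'
#' Points are placed every \code{step} nm along the polyline arc length
#' starting from the first point, preserving direction and order; a trailing
#' remainder shorter than \code{step} is dropped. The packing analysis uses
#' a 3 nm step (equal weight per unit filament length); subtomogram sampling
#' uses 1.38 nm, half the axial rise per actin subunit.
#'
#' @param filament data frame of one filament's rows (a subset of a
#'   \code{\link{filament_network}}), points in order.
#' @param step arc-length step in nm; must be positive and no longer than
#'   the filament arc length.
#' @return the filament with resampled points (same columns,
#'   \code{point_index} renumbered).
#' @export
resample_centerline <- function(filament, step) {
  xyz <- as.matrix(filament[, c("x", "y", "z")])
  seg <- sqrt(rowSums(diff(xyz)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    xyz <- xyz[keep, , drop = FALSE]
    seg <- seg[seg > 0]
  }
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total <= 0) stop("degenerate filament: arc length is zero")
  if (step <= 0 || step > total + 1e-9)
    stop("step must be > 0 and <= the filament arc length")
  s <- seq(0, total, by = step)
  new <- vapply(1:3, function(a) approx(arc, xyz[, a], xout = s)$y,
                numeric(length(s)))
  out <- filament[rep(1, length(s)), , drop = FALSE]
  out$point_index <- seq_along(s)
  out$x <- new[, 1]; out$y <- new[, 2]; out$z <- new[, 3]
  rownames(out) <- NULL
  out
}

#' @describeIn resample_centerline resample every filament of a network.
#' @param network a \code{filament_network}.
#' @export
resample_network <- function(network, step) {
  out <- do.call(rbind, lapply(split_filaments(network),
                               resample_centerline, step = step))
  filament_network(out)
}

#' Local tangent unit vectors along a filament
#'
#' The local direction at each point is the local tangent of the centerline:
#' central differences at interior points, one-sided differences at the two
#' endpoints, normalized to unit length.
#'
#' @param filament data frame of one filament's points in order.
#' @return an n x 3 matrix of unit tangents.
#' @export
local_tangents <- function(filament) {
  xyz <- as.matrix(filament[, c("x", "y", "z")])
  n <- nrow(xyz)
  tg <- matrix(0, n, 3)
  if (n == 2) {
    tg[1, ] <- tg[2, ] <- xyz[2, ] - xyz[1, ]
  } else {
    tg[1, ] <- xyz[2, ] - xyz[1, ]
    tg[n, ] <- xyz[n, ] - xyz[n - 1, ]
    tg[2:(n - 1), ] <- xyz[3:n, ] - xyz[1:(n - 2), ]
  }
  tg / sqrt(rowSums(tg^2))
}

# principal axis (unit vector) of a set of direction vectors, computed from
# the orientation tensor so that the sign ambiguity of tangents is immaterial
principal_axis <- function(dirs) {
  m <- crossprod(dirs) / nrow(dirs)
  ax <- eigen(m, symmetric = TRUE)$vectors[, 1]
  s <- sum(dirs %*% ax)
  if (abs(s) > 1e-12) ax <- ax * sign(s)
  else {
    nz <- which(abs(ax) > 1e-12)[1]
    ax <- ax * sign(ax[nz])
  }
  ax
}

#' Unify filament directions along the network's principal axis
#'
#' Reorders filament points where needed so that every filament's
#' end-to-end direction has a non-negative dot product with the first
#' principal axis of all local tangent directions (the common direction of
#' the network). Order-relative polarity labels are flipped together with
#' the point order, so the physical pointed-end direction is preserved.
#' Applying the operation twice equals applying it once.
#'
#' @param network a \code{filament_network}.
#' @return the network with unified point order.
#' @export
unify_directions <- function(network) {
  fils <- split_filaments(network)
  tangents <- do.call(rbind, lapply(fils, local_tangents))
  ax <- principal_axis(tangents)
  out <- lapply(fils, function(f) {
    e <- as.numeric(f[nrow(f), c("x", "y", "z")] - f[1, c("x", "y", "z")])
    d <- sum(e * ax)
    flip <- if (d < 0) TRUE else if (d > 0) FALSE else {
      # tie: orient so the first endpoint precedes the last lexicographically
      a <- as.numeric(f[1, c("x", "y", "z")])
      b <- as.numeric(f[nrow(f), c("x", "y", "z")])
      cmp <- c(a - b)[which(abs(a - b) > 1e-12)[1]]
      !is.na(cmp) && cmp > 0
    }
    if (flip) {
      f <- f[rev(seq_len(nrow(f))), , drop = FALSE]
      f$point_index <- seq_len(nrow(f))
      f$polarity <- -f$polarity
    }
    f
  })
  filament_network(do.call(rbind, out))
}

#' Initial subtomogram poses along a filament
#'
#' One pose per centerline point: (theta, psi) are set from the local
#' tangent so the zxz rotation carries the unit z axis onto it (the
#' filament centerline is aligned with z in the subvolume frame), and the
#' in-plane angle phi — which cannot be determined from the tomogram — is
#' randomized on a regular grid, by default every 30 degrees, independently
#' per pose.
#'
#' @param filament data frame of one (resampled) filament's points.
#' @param phi_step grid spacing for the randomized in-plane angle, degrees;
#'   must divide 360.
#' @param seed RNG seed (NULL to use the current RNG state).
#' @return a pose table: data frame with columns \code{filament_id},
#'   \code{subunit_index}, \code{x, y, z} (nm) and \code{phi, theta, psi}
#'   (degrees, zxz).
#' @export
init_poses <- function(filament, phi_step = 30, seed = NULL) {
  if (360 %% phi_step != 0) stop("phi_step must divide 360")
  tg <- local_tangents(filament)
  tp <- t(apply(tg, 1, tangent_to_euler))
  n <- nrow(filament)
  with_seed(seed, {
    phi <- sample(seq(0, 360 - phi_step, by = phi_step), n, replace = TRUE)
    data.frame(filament_id = filament$filament_id[1],
               subunit_index = seq_len(n),
               x = filament$x, y = filament$y, z = filament$z,
               phi = phi, theta = tp[, "theta"], psi = tp[, "psi"])
  })
}

#' @describeIn init_poses initial poses for every filament of a network
#'   (optionally restricted by filament type).
#' @param network a \code{filament_network}.
#' @param type optional filament type filter ("thin" or "thick").
#' @export
init_network_poses <- function(network, phi_step = 30, seed = NULL,
                               type = "thin") {
  if (!is.null(type)) {
    ids <- unique(network$filament_id[network$type %in% type])
    network <- filament_network(network[network$filament_id %in% ids, ])
  }
  with_seed(seed, {
    do.call(rbind, lapply(split_filaments(network), init_poses,
                          phi_step = phi_step, seed = NULL))
  })
}

#' Read / write pose tables as CSV
#'
#' Columns: \code{filament_id, subunit_index, x_nm, y_nm, z_nm, phi_deg,
#' theta_deg, psi_deg} plus any extra columns present (e.g. \code{score},
#' \code{half_set}).
#'
#' @param poses a pose table.
#' @param path file path.
#' @export
write_poses_csv <- function(poses, path) {
  df <- poses
  names(df)[match(c("x", "y", "z", "phi", "theta", "psi"), names(df))] <-
    c("x_nm", "y_nm", "z_nm", "phi_deg", "theta_deg", "psi_deg")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_poses_csv
#' @export
read_poses_csv <- function(path) {
  df <- read.csv(path)
  names(df)[match(c("x_nm", "y_nm", "z_nm", "phi_deg", "theta_deg", "psi_deg"),
                  names(df))] <- c("x", "y", "z", "phi", "theta", "psi")
  df
}
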
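#' Helical parameters of the thin filament
#'
#' Canonical F-actin geometry: a left-handed single-start helix with a rise
#' of 2.76 nm per subunit and a signed twist of -167.0 degrees per molecule,
#' giving a full repeat of 13 x 2.76 = 35.88 nm. Two tropomyosin strands,
#' related by 180 degrees of azimuthal symmetry, run along the filament
#' surface at \code{tpm_radius} following the long-pitch twist
#' (\code{twist + 180} degrees per rise).
#'
#' @param rise axial rise per subunit, nm (> 0).
#' @param twist signed angular twist per subunit, degrees (|twist| in
#'   (0, 360), negative = left-handed).
#' @param subunits_per_repeat subunits per full helical repeat.
#' @param actin_radius radial distance of subunit density centers from the
#'   filament axis, nm.
#' @param tpm_radius radius of the tropomyosin strands, nm.
#' @param tpm_azimuth azimuthal offset (degrees) of the tropomyosin strands,
#'   measured from the line through the center of subunit 0. The default 60
#'   places the strands in the groove off the subunit line; with the strands
#'   exactly on the subunit line (azimuth 0 or 90) the rendered map acquires
#'   a spurious mirror symmetry and filament polarity becomes undetectable —
#'   as in real thin filaments, polarity is read from the position of the
#'   actin subunits relative to the two Tpm strands.
#' @return an object of class \code{helical_params}.
#' @export
helical_params <- function(rise = 2.76, twist = -167.0,
                           subunits_per_repeat = 13, actin_radius = 2.0,
                           tpm_radius = 3.9, tpm_azimuth = 60) {
  stopifnot(rise > 0, abs(twist) > 0, abs(twist) < 360,
            subunits_per_repeat >= 1 || twist == 0)
  structure(list(rise = rise, twist = twist,
                 subunits_per_repeat = subunits_per_repeat,
                 actin_radius = actin_radius, tpm_radius = tpm_radius,
                 tpm_azimuth = tpm_azimuth),
            class = "helical_params")
}

#' Imaging conditions for synthetic volumes
#'
#' @param snr signal variance / noise variance; \code{Inf} = noise-free.
#' @param wedge_half_angle half-angle (degrees, in (0, 90)) of the missing
#'   wedge about the tilt axis, or NULL for complete sampling (the default:
#'   wedge effects are not analyzed quantitatively here).
#' @param seed RNG seed for the noise realisation.
#' @return an object of class \code{imaging_spec}.
#' @export
imaging_spec <- function(snr = Inf, wedge_half_angle = NULL, seed = 1) {
  stopifnot(snr > 0,
            is.null(wedge_half_angle) ||
              (wedge_half_angle > 0 && wedge_half_angle < 90))
  structure(list(snr = snr, wedge_half_angle = wedge_half_angle, seed = seed),
            class = "imaging_spec")
}

#' Ideal helical subunit poses along filament centerlines
#'
#' Places one pose per actin subunit every \code{rise} nm along each thin
#' filament centerline (in point order, i.e. barbed to pointed for polarity
#' +1 filaments), with the in-plane angle advancing by \code{twist} per
#' subunit from a per-filament starting angle.
#'
#' @param network a \code{filament_network} (thin filaments are used).
#' @param helix a \code{\link{helical_params}}.
#' @param phi0 starting in-plane angle(s), degrees: a single value recycled
#'   over filaments, or "random" to draw one uniform start per filament.
#' @param seed RNG seed used when \code{phi0 = "random"}.
#' @return a pose table (see \code{\link{init_poses}}).
#' @export
helical_poses <- function(network, helix, phi0 = 0, seed = NULL) {
  fils <- split_filaments(network)
  fils <- Filter(function(f) f$type[1] == "thin", fils)
  with_seed(seed, {
    starts <- if (identical(phi0, "random"))
      runif(length(fils), 0, 360) else rep_len(phi0, length(fils))
    out <- Map(function(f, p0) {
      rs <- resample_centerline(f, helix$rise)
      tg <- local_tangents(rs)
      tp <- t(apply(tg, 1, tangent_to_euler))
      n <- nrow(rs)
      data.frame(filament_id = f$filament_id[1], subunit_index = seq_len(n),
                 x = rs$x, y = rs$y, z = rs$z,
                 phi = (p0 + (seq_len(n) - 1) * helix$twist) %% 360,
                 theta = tp[, "theta"], psi = tp[, "psi"])
    }, fils, starts)
    do.call(rbind, out)
  })
}

# add a Gaussian blob (sd sigma nm, peak amp) into map values at center nm
add_blob <- function(vals, dim3, voxel, origin, center, sigma, amp) {
  ctr <- (center - origin) / voxel + 0.5  # 1-based fractional voxel index
  r <- ceiling(4 * sigma / voxel)
  lo <- pmax(1, floor(ctr - r)); hi <- pmin(dim3, ceiling(ctr + r))
  if (any(lo > hi)) return(vals)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  gx <- exp(-((ix - ctr[1]) * voxel)^2 / (2 * sigma^2))
  gy <- exp(-((iy - ctr[2]) * voxel)^2 / (2 * sigma^2))
  gz <- exp(-((iz - ctr[3]) * voxel)^2 / (2 * sigma^2))
  vals[ix, iy, iz] <- vals[ix, iy, iz] + amp * (gx %o% gy %o% gz)
  vals
}

#' Render thin-filament density from subunit poses
#'
#' Forward model standing in for the tomogram: each subunit pose contributes
#' a soft-sphere (Gaussian) actin density at its helical position, and each
#' filament carries two continuous tropomyosin tubes at
#' \code{helix$tpm_radius}, offset azimuthally by \code{helix$tpm_azimuth}
#' and 180 degrees apart, following the long-pitch twist. Additive Gaussian
#' noise brings the volume to the requested SNR; an optional missing-wedge
#' filter is applied in the frequency domain. Deterministic given the
#' imaging seed. Rendering is linear in the poses: the density of two
#' filaments is the sum of their individual densities (noise-free).
#'
#' @param poses pose table (see \code{\link{helical_poses}}).
#' @param helix a \code{\link{helical_params}}.
#' @param voxel_size voxel edge, nm.
#' @param box integer grid dimensions (length 3, voxels).
#' @param imaging an \code{\link{imaging_spec}}.
#' @param origin nm offset of the grid corner.
#' @param sigma_actin,sigma_tpm Gaussian blob widths, nm.
#' @param tpm_amp tropomyosin amplitude relative to actin subunits.
#' @param tube_step arc step used to rasterize the tropomyosin tubes, nm.
#' @return a \code{density_map}.
#' @export
render_filament_density <- function(poses, helix, voxel_size, box,
                                    imaging = imaging_spec(),
                                    origin = c(0, 0, 0), sigma_actin = 1.2,
                                    sigma_tpm = 0.8, tpm_amp = 0.6,
                                    tube_step = 0.7) {
  box <- as.integer(rep_len(box, 3))
  upper <- origin + box * voxel_size
  if (any(poses$x < origin[1] | poses$x > upper[1] |
          poses$y < origin[2] | poses$y > upper[2] |
          poses$z < origin[3] | poses$z > upper[3]))
    stop("box too small: poses lie outside the rendering box")
  vals <- array(0, box)
  for (f in split(poses, poses$filament_id)) {
    f <- f[order(f$subunit_index), , drop = FALSE]
    n <- nrow(f)
    # actin subunits
    for (i in seq_len(n)) {
      R <- euler_to_matrix(f$phi[i], f$theta[i], f$psi[i])
      ctr <- c(f$x[i], f$y[i], f$z[i]) + R %*% c(helix$actin_radius, 0, 0)
      vals <- add_blob(vals, box, voxel_size, origin, as.numeric(ctr),
                       sigma_actin, 1)
    }
    # tropomyosin tubes: continuous long-pitch continuation from pose 1
    if (n >= 2) {
      tt <- seq(1, n, by = tube_step / helix$rise)
      px <- approx(seq_len(n), f$x, xout = tt)$y
      py <- approx(seq_len(n), f$y, xout = tt)$y
      pz <- approx(seq_len(n), f$z, xout = tt)$y
      az <- f$phi[1] + helix$tpm_azimuth + (tt - 1) * (helix$twist + 180)
      for (s in seq_along(tt)) {
        i0 <- min(floor(tt[s]), n - 1)
        tg <- c(f$x[i0 + 1] - f$x[i0], f$y[i0 + 1] - f$y[i0],
                f$z[i0 + 1] - f$z[i0])
        tp <- tangent_to_euler(tg)
        for (strand in c(0, 180)) {
          R <- euler_to_matrix(az[s] + strand, tp["theta"], tp["psi"])
          ctr <- c(px[s], py[s], pz[s]) + R %*% c(helix$tpm_radius, 0, 0)
          vals <- add_blob(vals, box, voxel_size, origin, as.numeric(ctr),
                           sigma_tpm, tpm_amp * tube_step / helix$rise)
        }
      }
    }
  }
  map <- density_map(vals, voxel_size, origin)
  if (!is.null(imaging$wedge_half_angle))
    map <- apply_missing_wedge(map, imaging$wedge_half_angle)
  if (is.finite(imaging$snr)) {
    sig_var <- stats::var(as.numeric(map$values))
    map$values <- map$values + with_seed(imaging$seed,
      array(rnorm(prod(box), 0, sqrt(sig_var / imaging$snr)), box))
  }
  map
}

#' Apply a missing-wedge filter in the frequency domain
#'
#' Zeroes Fourier components inside the double wedge about the tilt axis
#' (+y): components whose (kx, kz) direction lies within
#' \code{half_angle} of the kz (beam) axis are removed, emulating a tilt
#' range of +/-(90 - half_angle) degrees.
#'
#' @param map a \code{density_map}.
#' @param half_angle wedge half-angle, degrees in (0, 90).
#' @return the filtered \code{density_map}.
#' @export
apply_missing_wedge <- function(map, half_angle) {
  dm <- dim(map$values)
  freq_idx <- function(n) { k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n; k }
  kx <- freq_idx(dm[1]) / dm[1]
  kz <- freq_idx(dm[3]) / dm[3]
  ang <- atan2(abs(outer(kx, rep(1, dm[3]))),
               abs(outer(rep(1, dm[1]), kz))) * 180 / pi
  keep <- ang >= half_angle
  keep[1, 1] <- TRUE  # keep the mean
  ft <- fft(map$values)
  mask <- aperm(array(rep(keep, dm[2]), c(dm[1], dm[3], dm[2])), c(1, 3, 2))
  map$values <- Re(fft(ft * mask, inverse = TRUE)) / prod(dm)
  map
}

#' Build a polarity reference pair
#'
#' Renders a noise-free thin-filament reference centered in the box with its
#' axis along +z, and a second reference of opposite polarity obtained by
#' rotating the first by 180 degrees about the x axis (an exact grid
#' operation for even box dimensions). The two are not related by any pure
#' translation: polarity is only reversed by the out-of-plane rotation.
#'
#' @param helix a \code{\link{helical_params}}.
#' @param voxel_size voxel edge, nm.
#' @param box integer grid dimensions (length 3 or scalar).
#' @param phi0 in-plane angle of the reference helix, degrees.
#' @return list with elements \code{A} and \code{B} (\code{density_map}s).
#' @export
make_reference_pair <- function(helix, voxel_size, box, phi0 = 0) {
  box <- as.integer(rep_len(box, 3))
  pad <- 8L
  padbox <- box + c(0L, 0L, 2L * pad)
  zlen <- padbox[3] * voxel_size
  # odd subunit count, spanning the padded box, middle subunit at the center
  n_sub <- max(3, floor((zlen - 2) / helix$rise))
  if (n_sub %% 2 == 0) n_sub <- n_sub - 1
  zc <- (n_sub - 1) * helix$rise / 2
  ctr <- padbox * voxel_size / 2
  fil <- filament_network(data.frame(
    filament_id = 1L, type = "thin", polarity = 1L, point_index = 1:2,
    x = c(ctr[1], ctr[1]), y = c(ctr[2], ctr[2]),
    z = ctr[3] + c(-zc, zc + helix$rise * 0.999)))
  # phase the helix so the middle subunit sits at azimuth phi0
  start <- phi0 - (n_sub - 1) / 2 * helix$twist
  poses <- helical_poses(fil, helix, phi0 = start)
  A <- render_filament_density(poses, helix, voxel_size, padbox)
  A$values <- A$values[, , (pad + 1):(pad + box[3])]
  A$origin <- c(0, 0, 0)
  B <- A
  B$values <- A$values[, rev(seq_len(box[2])), rev(seq_len(box[3]))]
  list(A = A, B = B)
}

#' Rotate a density map by 180 degrees about a box axis
#'
#' Exact grid flip about the box center (even dimensions assumed on the two
#' flipped axes).
#'
#' @param map a \code{density_map}.
#' @param axis "x", "y" or "z": the rotation axis.
#' @return the rotated map.
#' @export
rotate180 <- function(map, axis = "x") {
  d <- dim(map$values)
  map$values <- switch(axis,
    x = map$values[, rev(seq_len(d[2])), rev(seq_len(d[3]))],
    y = map$values[rev(seq_len(d[1])), , rev(seq_len(d[3]))],
    z = map$values[rev(seq_len(d[1])), rev(seq_len(d[2])), ],
    stop("axis must be x, y or z"))
  map
}
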
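# Polarity-derived sarcomere metrics: Z-disk / M-line location, overlap
# lengths and fractions, helical rise/twist, tropomyosin azimuthal shift.

# 1D single-linkage clustering: split sorted positions at gaps > gap
cluster_1d <- function(xs, gap) {
  if (!length(xs)) return(list())
  o <- order(xs)
  xs <- xs[o]
  br <- c(0, which(diff(xs) > gap), length(xs))
  lapply(seq_len(length(br) - 1), function(i) xs[(br[i] + 1):br[i + 1]])
}

#' Annotate Z-disks, M-lines and sarcomere lengths from filament polarity
#'
#' Projects thin-filament endpoints on the myofibril axis and reads the
#' sarcomere register off the polarity pattern: gaps where thin filaments
#' face each other with their barbed ends locate Z-disks (gap midpoints);
#' encounters of pointed ends of opposite-polarity filaments locate M-lines
#' (midpoint of the overlap interval, or of the gap when the filaments do
#' not touch). Sarcomere length is the distance between consecutive
#' Z-disks.
#'
#' @param network a \code{filament_network} whose thin filaments carry
#'   polarity labels (at least 60\% of them).
#' @param axis myofibril axis (unit 3-vector); default: first principal
#'   axis of all local tangents.
#' @param cluster_gap 1D clustering gap for endpoint groups, nm.
#' @param pair_tol maximum distance between paired endpoint clusters, nm.
#' @return an object of class \code{sarcomere_annotation}: list with
#'   \code{z_disks}, \code{m_lines} (positions along the axis, nm),
#'   \code{sarcomere_lengths}, \code{overlaps} (data frame m_line,
#'   overlap_nm, fraction_pct, n_pairs) and \code{axis}.
#' @export
annotate_sarcomeres <- function(network, axis = NULL, cluster_gap = 150,
                                pair_tol = 400) {
  fs <- filament_summary(network)
  thin <- fs[fs$type == "thin", , drop = FALSE]
  frac <- mean(!is.na(thin$polarity))
  if (frac < 0.6)
    stop("need confident polarity for >= 60% of thin filaments (have ",
         round(100 * frac), "%)")
  if (is.null(axis)) {
    tangents <- do.call(rbind, lapply(split_filaments(network),
                                      local_tangents))
    axis <- principal_axis(tangents)
  }
  axis <- axis / sqrt(sum(axis^2))
  thin <- thin[!is.na(thin$polarity), , drop = FALSE]
  p0 <- cbind(thin$x0, thin$y0, thin$z0) %*% axis
  p1 <- cbind(thin$x1, thin$y1, thin$z1) %*% axis
  barbed <- ifelse(thin$polarity > 0, p0, p1)
  pointed <- ifelse(thin$polarity > 0, p1, p0)
  dirp <- sign(pointed - barbed)
  if (all(dirp > 0) || all(dirp < 0)) {
    warning("uniform polarity: no Z-disk or M-line found")
    return(structure(list(z_disks = numeric(0), m_lines = numeric(0),
                          sarcomere_lengths = numeric(0),
                          overlaps = data.frame(), axis = axis),
                     class = "sarcomere_annotation"))
  }
  # Pair a cluster of below-feature endpoints with one of above-feature
  # endpoints; the feature sits at the pair midpoint. When correct_edges,
  # unpaired clusters (network edges) are shifted by half the mean signed
  # gap of the paired ones (the barbed-end gap straddling a Z-disk).
  pair_clusters <- function(lo_vals, hi_vals, correct_edges) {
    mlo <- vapply(cluster_1d(lo_vals, cluster_gap), mean, numeric(1))
    mhi <- vapply(cluster_1d(hi_vals, cluster_gap), mean, numeric(1))
    pos <- numeric(0)
    lone_lo <- numeric(0)
    gaps <- numeric(0)
    used <- logical(length(mhi))
    for (i in seq_along(mlo)) {
      d <- abs(mhi - mlo[i])
      j <- which.min(replace(d, used, Inf))
      if (length(j) && is.finite(d[j]) && d[j] <= pair_tol) {
        pos <- c(pos, (mlo[i] + mhi[j]) / 2)
        gaps <- c(gaps, mhi[j] - mlo[i])
        used[j] <- TRUE
      } else lone_lo <- c(lone_lo, mlo[i])
    }
    half <- if (correct_edges && length(gaps)) mean(gaps) / 2 else 0
    sort(c(pos, lone_lo + half, mhi[!used] - half))
  }
  # Z-disks: barbed ends of down-pointing filaments just below the disk,
  # barbed ends of up-pointing filaments just above
  z_disks <- pair_clusters(barbed[dirp < 0], barbed[dirp > 0], TRUE)
  # M-lines: pointed ends of up-pointing filaments meet pointed ends of
  # down-pointing filaments
  m_lines <- pair_clusters(pointed[dirp > 0], pointed[dirp < 0], FALSE)
  # keep only M-lines that fall between Z-disks when both exist
  sarc_len <- diff(z_disks)
  overlaps <- do.call(rbind, lapply(m_lines, function(m) {
    below <- z_disks[z_disks < m]
    above <- z_disks[z_disks > m]
    L <- if (length(below) && length(above))
      min(above) - max(below) else NA_real_
    ov <- measure_overlap(network, m, axis, sarcomere_length = L)
    data.frame(m_line = m, overlap_nm = ov$overlap,
               fraction_pct = if (is.null(ov$fraction)) NA_real_ else
                 ov$fraction,
               n_pairs = ov$n_pairs)
  }))
  structure(list(z_disks = z_disks, m_lines = m_lines,
                 sarcomere_lengths = sarc_len,
                 overlaps = if (is.null(overlaps)) data.frame() else overlaps,
                 axis = axis),
            class = "sarcomere_annotation")
}

#' @export
print.sarcomere_annotation <- function(x, ...) {
  cat("sarcomere_annotation:", length(x$z_disks), "Z-disks,",
      length(x$m_lines), "M-lines\n")
  if (length(x$sarcomere_lengths))
    cat("  sarcomere lengths (nm):",
        paste(round(x$sarcomere_lengths), collapse = ", "), "\n")
  if (NROW(x$overlaps))
    for (i in seq_len(nrow(x$overlaps)))
      cat(sprintf("  M-line at %.0f nm: overlap %.0f nm (%s%%)\n",
                  x$overlaps$m_line[i], x$overlaps$overlap_nm[i],
                  ifelse(is.na(x$overlaps$fraction_pct[i]), "NA",
                         round(x$overlaps$fraction_pct[i]))))
  invisible(x)
}

#' Thin-filament overlap length and fraction at an M-line
#'
#' The overlap is the maximum, over pairs of opposite-polarity thin
#' filaments bridging the M-line, of the axial interpenetration of their
#' pointed-end extents, clipped at zero. The fraction is relative to the
#' flanking sarcomere length (absent when unknown). The full distribution
#' of positive pair interpenetrations is also returned.
#'
#' @param network a \code{filament_network} with thin-filament polarity.
#' @param m_line_position M-line position along the axis, nm.
#' @param axis unit 3-vector.
#' @param sarcomere_length flanking sarcomere length, nm, or NULL.
#' @param window half-width of the axial window around the M-line within
#'   which pointed ends participate, nm.
#' @return list with \code{overlap} (nm), \code{fraction} (percent of
#'   sarcomere length, NULL if unknown), \code{n_pairs} (bridging pairs
#'   with positive interpenetration) and \code{pair_overlaps}.
#' @export
measure_overlap <- function(network, m_line_position, axis = c(1, 0, 0),
                            sarcomere_length = NULL, window = 500) {
  axis <- axis / sqrt(sum(axis^2))
  fs <- filament_summary(network)
  thin <- fs[fs$type == "thin" & !is.na(fs$polarity), , drop = FALSE]
  p0 <- cbind(thin$x0, thin$y0, thin$z0) %*% axis
  p1 <- cbind(thin$x1, thin$y1, thin$z1) %*% axis
  barbed <- ifelse(thin$polarity > 0, p0, p1)
  pointed <- ifelse(thin$polarity > 0, p1, p0)
  dirp <- sign(pointed - barbed)
  sel <- abs(pointed - m_line_position) <= window
  up <- pointed[sel & dirp > 0]
  dn <- pointed[sel & dirp < 0]
  if (!length(up) || !length(dn))
    return(list(overlap = 0, fraction = if (is.null(sarcomere_length))
      NULL else 0, n_pairs = 0L, pair_overlaps = numeric(0)))
  pair <- outer(up, dn, "-")
  pos <- pair[pair > 0]
  overlap <- max(0, max(pair))
  list(overlap = overlap,
       fraction = if (is.null(sarcomere_length) || is.na(sarcomere_length))
         NULL else 100 * overlap / sarcomere_length,
       n_pairs = length(pos), pair_overlaps = as.numeric(pos))
}

#' Helical rise and twist from refined subunit poses
#'
#' Rise is the mean spacing between consecutive subunit poses along each
#' filament; twist is the signed circular mean of consecutive in-plane
#' rotation (phi) differences, wrapped to (-180, 180]. The number of
#' subunits per repeat is the smallest n (up to \code{n_max}) whose helical
#' closure residual |wrap(n * twist)| is within \code{closure_tol} degrees
#' (falling back to the overall argmin); the repeat distance is n x rise.
#'
#' @param poses pose table of deduplicated refined poses (one per subunit),
#'   with at least one filament of >= 3 subunits.
#' @param n_max largest subunits-per-repeat considered.
#' @param closure_tol closure residual tolerance, degrees.
#' @return an object of class \code{helical_estimate}: list with
#'   \code{rise} (nm), \code{twist} (degrees, signed),
#'   \code{subunits_per_repeat}, \code{repeat_nm} and \code{n_pairs}.
#' @export
estimate_helix <- function(poses, n_max = 28, closure_tol = 15) {
  fils <- split(poses, poses$filament_id)
  fils <- Filter(function(f) nrow(f) >= 3, fils)
  if (!length(fils)) stop("need >= 3 subunits on at least one filament")
  d <- dphi <- numeric(0)
  for (f in fils) {
    f <- f[order(f$subunit_index), , drop = FALSE]
    xyz <- as.matrix(f[, c("x", "y", "z")])
    d <- c(d, sqrt(rowSums(diff(xyz)^2)))
    dphi <- c(dphi, wrap180(diff(f$phi)))
  }
  rise <- mean(d)
  rad <- dphi * pi / 180
  twist <- wrap180(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
  resid <- abs(wrap180(seq_len(n_max) * twist))
  ok <- which(resid <= closure_tol)
  n_rep <- if (length(ok)) ok[1] else which.min(resid)
  structure(list(rise = rise, twist = twist, subunits_per_repeat = n_rep,
                 repeat_nm = n_rep * rise, n_pairs = length(d)),
            class = "helical_estimate")
}

#' @export
print.helical_estimate <- function(x, ...) {
  cat(sprintf(
    "helix: rise %.3f nm, twist %.1f deg, repeat %.3g nm (%d subunits, n = %d)\n",
    x$rise, x$twist, x$repeat_nm, x$subunits_per_repeat, x$n_pairs))
  invisible(x)
}

# trilinear interpolation of a density map at nm coordinates (n x 3)
interp_map <- function(map, pts) {
  f <- sweep(pts, 2, map$origin) / map$voxel_size + 0.5
  dm <- dim(map$values)
  f <- pmin(pmax(f, 1), matrix(rep(dm, each = nrow(f)), ncol = 3))
  i0 <- pmin(floor(f), matrix(rep(dm - 1, each = nrow(f)), ncol = 3))
  fr <- f - i0
  v <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (ifelse(dx == 1, fr[, 1], 1 - fr[, 1]) *
          ifelse(dy == 1, fr[, 2], 1 - fr[, 2]) *
          ifelse(dz == 1, fr[, 3], 1 - fr[, 3]))
    v <- v + w * map$values[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  v
}

#' Azimuthal shift of the tropomyosin density between two maps
#'
#' Extracts azimuthal intensity profiles on a cylindrical annulus at the
#' tropomyosin radius from two maps aligned to a common filament axis and
#' register. Because the strands are helical, the sampling azimuth is
#' unwound along the axis at the long-pitch rate
#' \code{(twist + 180) / rise} so that each strand contributes at a fixed
#' profile angle. The two profiles are cross-correlated over rotation
#' about the axis and the shift maximizing the correlation is returned,
#' wrapped to (-180, 180]; because the two tropomyosin strands are related
#' by 180-degree azimuthal symmetry, the shift is defined modulo 180 and
#' is resolved to the smaller absolute value.
#'
#' @param map_a,map_b \code{density_map}s with identical box and voxel
#'   size (register mismatch is an error).
#' @param axis filament axis: "z" (default), "x" or "y" (box axes).
#' @param helix \code{\link{helical_params}} of the filament (for the
#'   tropomyosin radius and the long-pitch unwinding rate).
#' @param radius annulus center radius, nm.
#' @param width annulus half-width, nm.
#' @param z_frac fraction of the box length along the axis used (interior
#'   region).
#' @param phi_step azimuthal sampling, degrees.
#' @return shift in degrees, in (-90, 90].
#' @export
tpm_azimuth_shift <- function(map_a, map_b, axis = "z",
                              helix = helical_params(),
                              radius = helix$tpm_radius,
                              width = 1, z_frac = 0.6, phi_step = 1) {
  if (!all(dim(map_a$values) == dim(map_b$values)) ||
      !isTRUE(all.equal(map_a$voxel_size, map_b$voxel_size)))
    stop("register mismatch between the two maps")
  perm <- switch(axis, z = 1:3, x = c(2, 3, 1), y = c(3, 1, 2),
                 stop("axis must be x, y or z"))
  dm <- dim(map_a$values)
  ctr <- map_a$origin + dm * map_a$voxel_size / 2
  zlen <- dm[perm[3]] * map_a$voxel_size * z_frac
  zs <- seq(-zlen / 2, zlen / 2, by = map_a$voxel_size)
  # sample from the strand radius outward: inner radii pick up actin
  # density common to both maps, which biases the correlation toward zero
  rs <- radius + seq(0, width, length.out = 3)
  phis <- seq(0, 360 - phi_step, by = phi_step)
  pitch_rate <- (helix$twist + 180) / helix$rise   # deg per nm along axis
  profile <- function(map) {
    vapply(phis, function(ph) {
      g <- expand.grid(r = rs, z = zs)
      a <- (ph + pitch_rate * g$z) * pi / 180
      pts <- matrix(0, nrow(g), 3)
      pts[, perm[1]] <- ctr[perm[1]] + g$r * cos(a)
      pts[, perm[2]] <- ctr[perm[2]] + g$r * sin(a)
      pts[, perm[3]] <- ctr[perm[3]] + g$z
      mean(interp_map(map, pts))
    }, numeric(1))
  }
  pa <- profile(map_a); pa <- pa - mean(pa)
  pb <- profile(map_b); pb <- pb - mean(pb)
  n <- length(phis)
  cc <- vapply(seq_len(n) - 1, function(s)
    sum(pa * pb[(seq_len(n) - 1 + s) %% n + 1]), numeric(1))
  best <- which.max(cc) - 1
  # parabolic sub-bin refinement
  y0 <- cc[(best - 1) %% n + 1]; y1 <- cc[best + 1]
  y2 <- cc[(best + 1) %% n + 1]
  den <- y0 - 2 * y1 + y2
  frac <- if (abs(den) > 1e-12) 0.5 * (y0 - y2) / den else 0
  shift <- wrap180((best + frac) * phi_step)
  if (shift > 90) shift <- shift - 180
  if (shift <= -90) shift <- shift + 180
  shift
}

#' Export polarity arrows for 3D visualization
#'
#' Writes one arrow per polarity-labeled filament, from the barbed-side
#' endpoint toward the pointed end, as a plain-text segment table loadable
#' in common 3D viewers (columns: filament id, start xyz, end xyz, color by
#' pointed-end direction). Unlabeled filaments are written to a separate
#' \code{*_unassigned.csv} segment table.
#'
#' @param network a \code{filament_network} with polarity labels on the
#'   filaments to draw.
#' @param path output CSV path.
#' @return list with \code{n_arrows} and \code{n_unassigned}, invisibly.
#' @export
export_polarity_arrows <- function(network, path) {
  fs <- filament_summary(network)
  lab <- !is.na(fs$polarity)
  arrows <- fs[lab, , drop = FALSE]
  swap <- arrows$polarity < 0
  tmp <- arrows[swap, c("x0", "y0", "z0")]
  arrows[swap, c("x0", "y0", "z0")] <- arrows[swap, c("x1", "y1", "z1")]
  arrows[swap, c("x1", "y1", "z1")] <- tmp
  dirx <- sign(arrows$x1 - arrows$x0)
  out <- data.frame(filament_id = arrows$filament_id,
                    start_x = arrows$x0, start_y = arrows$y0,
                    start_z = arrows$z0, end_x = arrows$x1,
                    end_y = arrows$y1, end_z = arrows$z1,
                    color = ifelse(dirx >= 0, "orange", "blue"))
  write.csv(out, path, row.names = FALSE)
  un <- fs[!lab, , drop = FALSE]
  un_path <- sub("\\.csv$", "", path)
  un_path <- paste0(un_path, "_unassigned.csv")
  write.csv(data.frame(filament_id = un$filament_id,
                       start_x = un$x0, start_y = un$y0, start_z = un$z0,
                       end_x = un$x1, end_y = un$y1, end_z = un$z1),
            un_path, row.names = FALSE)
  invisible(list(n_arrows = nrow(out), n_unassigned = nrow(un)))
}

#' Serialize a sarcomere annotation
#'
#' @param annotation a \code{sarcomere_annotation}.
#' @param path output path without extension; writes \code{<path>.json}
#'   and \code{<path>_overlaps.csv}.
#' @export
write_annotation <- function(annotation, path) {
  jsonlite::write_json(list(z_disks = annotation$z_disks,
                            m_lines = annotation$m_lines,
                            sarcomere_lengths = annotation$sarcomere_lengths,
                            axis = annotation$axis),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  write.csv(annotation$overlaps, paste0(path, "_overlaps.csv"),
            row.names = FALSE)
  invisible(path)
}
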
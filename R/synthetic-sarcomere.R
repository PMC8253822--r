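#' Sarcomere geometry specification
#'
#' Longitudinal layout of synthetic polarity-segmented sarcomeres along the
#' +x axis. Each sarcomere of length \code{sarcomere_length} is bounded by
#' Z-disks; no filament density exists within \code{z_disk_width / 2} of a
#' Z-disk position (the dense Z-disk structure masks filament ends there).
#' Thin filaments emanate from both Z-disk faces with their barbed ends at
#' the Z-disk and pointed ends toward the sarcomere center; thin filaments
#' of the two half-sarcomeres interpenetrate the M-region by exactly
#' \code{overlap_length}. Thick filaments span the A-band, centered on the
#' M-line, and are absent from the I-band.
#'
#' Defaults follow measurements in contracting neonatal rat cardiomyocytes:
#' sarcomere length 1800 nm (1.8 +/- 0.2 um), Z-disk widths 100-140 nm,
#' I-band widths 240-300 nm, bare-zone (M-region) length 140 nm.
#'
#' @param sarcomere_length sarcomere length in nm.
#' @param z_disk_width width of the filament-free Z-disk gap in nm.
#' @param i_band_width thick-filament-free I-band width (spanning a Z-disk)
#'   in nm; sets the default thick filament length
#'   \code{sarcomere_length - i_band_width}.
#' @param bare_zone_length myosin bare-zone length in nm (metadata; no
#'   thick-filament density model is attached to it).
#' @param overlap_length planted tip-to-tip interpenetration of
#'   opposite-polarity thin filaments at the M-line, in nm (>= 0; 0 means
#'   the pointed ends meet but do not cross).
#' @param thin_length_mean,thin_length_sd thin filament length distribution
#'   in nm (Gaussian, truncated above at the M-region reach). The default
#'   mean is the maximal reach \code{sarcomere_length/2 - z_disk_width/2 +
#'   overlap_length/2}, so about half of the filaments attain it.
#' @param thick_length thick filament length in nm.
#' @param n_sarcomeres number of sarcomeres in series.
#' @param seed RNG seed.
#' @return an object of class \code{sarcomere_spec}.
#' @export
sarcomere_spec <- function(sarcomere_length = 1800, z_disk_width = 120,
                           i_band_width = 270, bare_zone_length = 140,
                           overlap_length = 0, thin_length_mean = NULL,
                           thin_length_sd = 50, thick_length = NULL,
                           n_sarcomeres = 1, seed = 1) {
  stopifnot(sarcomere_length > 0, z_disk_width >= 0, i_band_width >= 0,
            bare_zone_length >= 0, overlap_length >= 0, thin_length_sd >= 0,
            n_sarcomeres >= 1)
  reach <- sarcomere_length / 2 - z_disk_width / 2 + overlap_length / 2
  if (is.null(thin_length_mean)) thin_length_mean <- reach
  if (is.null(thick_length)) thick_length <- sarcomere_length - i_band_width
  if (reach <= 0 || overlap_length / 2 > sarcomere_length / 2 - z_disk_width / 2)
    stop("inconsistent sarcomere geometry: thin lengths + overlap + I-band ",
         "do not fit within the sarcomere length")
  if (thick_length > sarcomere_length - z_disk_width)
    stop("thick filaments would enter the Z-disk gap")
  structure(list(sarcomere_length = sarcomere_length,
                 z_disk_width = z_disk_width, i_band_width = i_band_width,
                 bare_zone_length = bare_zone_length,
                 overlap_length = overlap_length,
                 thin_length_mean = thin_length_mean,
                 thin_length_sd = thin_length_sd, thick_length = thick_length,
                 n_sarcomeres = n_sarcomeres, seed = seed),
            class = "sarcomere_spec")
}

#' Build a synthetic polarity-segmented sarcomere network
#'
#' Combines the longitudinal layout of a \code{\link{sarcomere_spec}} with
#' the lateral lattice of a \code{\link{lattice_spec}}. Thin filament
#' centerlines are stored barbed end first (so every thin filament has
#' polarity label +1: pointed end at the last point); filaments of the two
#' half-sarcomeres therefore have opposite pointed-end directions along x.
#' Thin lengths are Gaussian with the spec mean/sd, truncated above at the
#' M-region reach; one filament per half-sarcomere is pinned to the maximal
#' reach so that the planted \code{overlap_length} is realised exactly.
#'
#' @param sspec a \code{\link{sarcomere_spec}}.
#' @param lspec a \code{\link{lattice_spec}} supplying the lateral lattice
#'   (its \code{filament_length} and pairing/interstitial settings are not
#'   used here).
#' @return a \code{filament_network}.
#' @export
build_sarcomere <- function(sspec, lspec = lattice_spec()) {
  stopifnot(inherits(sspec, "sarcomere_spec"), inherits(lspec, "lattice_spec"))
  L <- sspec$sarcomere_length
  wz <- sspec$z_disk_width
  ov <- sspec$overlap_length
  reach <- L / 2 - wz / 2 + ov / 2
  with_seed(sspec$seed, {
    sites <- hex_sites(lspec)
    rows <- list()
    fid <- 0L
    add <- function(type, polarity, xs, yz) {
      fid <<- fid + 1L
      data.frame(filament_id = fid, type = type, polarity = polarity,
                 point_index = seq_along(xs), x = xs,
                 y = yz[1], z = yz[2])
    }
    jit <- function(p) {
      if (lspec$jitter_sd > 0) p + rnorm(2, 0, lspec$jitter_sd) else p
    }
    trig <- sites$trigonal
    if (is.null(trig)) stop("lattice too small for trigonal thin filaments")
    for (s in seq_len(sspec$n_sarcomeres) - 1) {
      xz0 <- s * L          # left Z-disk
      xz1 <- (s + 1) * L    # right Z-disk
      xm <- xz0 + L / 2     # M-line
      # thick filaments across the A-band
      for (i in seq_len(nrow(sites$thick))) {
        p <- jit(sites$thick[i, ])
        rows[[length(rows) + 1L]] <-
          add("thick", NA_integer_,
              c(xm - sspec$thick_length / 2, xm + sspec$thick_length / 2), p)
      }
      # thin filaments of both half-sarcomeres
      for (half in c(+1, -1)) {
        zb <- if (half > 0) xz0 + wz / 2 else xz1 - wz / 2
        keep <- which(runif(nrow(trig)) < lspec$trigonal_occupancy)
        if (!length(keep)) keep <- 1L
        first <- TRUE
        for (i in keep) {
          p <- jit(trig[i, ])
          len <- if (first) reach else
            min(reach, rnorm(1, sspec$thin_length_mean, sspec$thin_length_sd))
          first <- FALSE
          len <- max(len, wz / 2 + 10)  # keep filaments non-degenerate
          rows[[length(rows) + 1L]] <-
            add("thin", 1L, c(zb, zb + half * len), p)
        }
      }
    }
    filament_network(do.call(rbind, rows))
  })
}

#' Directly measure the planted M-line interpenetration of a network
#'
#' Geometric measurement on the generated network (before any analysis
#' stage): the maximal axial interpenetration, clipped at zero, of
#' pointed-end extents of opposite-direction thin filaments around a given
#' M-line position.
#'
#' @param network a \code{filament_network} with thin-filament polarity.
#' @param m_line_x M-line position along x in nm.
#' @param window half-width (nm) of the axial window around the M-line in
#'   which pointed ends are considered.
#' @return interpenetration in nm (>= 0).
#' @export
planted_overlap <- function(network, m_line_x, window = 500) {
  fs <- filament_summary(network)
  fs <- fs[fs$type == "thin" & !is.na(fs$polarity), , drop = FALSE]
  dirx <- sign((fs$x1 - fs$x0) * fs$polarity)
  pointed <- ifelse(fs$polarity > 0, fs$x1, fs$x0)
  sel <- abs(pointed - m_line_x) <= window
  up <- pointed[sel & dirx > 0]
  dn <- pointed[sel & dirx < 0]
  if (!length(up) || !length(dn)) return(0)
  max(0, max(up) - min(dn))
}
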
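# Desk-scale subtomogram extraction, constrained alignment, averaging and
# two-reference polarity assignment.

#' Soft cylindrical mask
#'
#' A soft-edged cylindrical mask about an axis through the box center, used
#' to restrict alignment scoring to the filament region.
#'
#' @param box integer box dimensions (scalar or length 3), voxels.
#' @param voxel_size voxel edge, nm.
#' @param radius cylinder radius, nm.
#' @param axis unit 3-vector, lab frame.
#' @param soft Gaussian edge width, nm.
#' @return a 3D array of weights in [0, 1].
#' @export
cylinder_mask <- function(box, voxel_size, radius, axis = c(0, 0, 1),
                          soft = 1) {
  box <- as.integer(rep_len(box, 3))
  axis <- axis / sqrt(sum(axis^2))
  ctr <- (box - 1) / 2
  ix <- (0:(box[1] - 1) - ctr[1]) * voxel_size
  iy <- (0:(box[2] - 1) - ctr[2]) * voxel_size
  iz <- (0:(box[3] - 1) - ctr[3]) * voxel_size
  g <- expand.grid(x = ix, y = iy, z = iz)
  proj <- g$x * axis[1] + g$y * axis[2] + g$z * axis[3]
  r2 <- g$x^2 + g$y^2 + g$z^2 - proj^2
  d <- sqrt(pmax(0, r2)) - radius
  w <- ifelse(d <= 0, 1, exp(-d^2 / (2 * soft^2)))
  array(w, box)
}

#' Extract cubic subvolumes at pose positions
#'
#' Axis-aligned cubic crops of the map centered at each pose position
#' (nearest-voxel centering); poses are carried through. Poses whose box
#' does not fit inside the map are skipped and counted, not an error.
#'
#' @param map a \code{density_map}.
#' @param poses pose table.
#' @param box cubic box size in voxels (scalar).
#' @return list with \code{subvolumes} (list of \code{subvolume} objects:
#'   values, voxel_size, center_nm, pose), \code{poses} (rows kept) and
#'   \code{skipped} (count).
#' @export
extract_subvolumes <- function(map, poses, box) {
  box <- as.integer(box)
  dm <- dim(map$values)
  half_lo <- floor((box - 1) / 2)
  half_hi <- box - 1 - half_lo
  subs <- list()
  kept <- logical(nrow(poses))
  for (k in seq_len(nrow(poses))) {
    p <- c(poses$x[k], poses$y[k], poses$z[k])
    idx <- round((p - map$origin) / map$voxel_size + 0.5)
    lo <- idx - half_lo
    hi <- idx + half_hi
    if (any(lo < 1) || any(hi > dm)) next
    kept[k] <- TRUE
    ctr <- map$origin + (idx - 0.5) * map$voxel_size
    subs[[length(subs) + 1L]] <- structure(
      list(values = map$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                               drop = FALSE],
           voxel_size = map$voxel_size, center_nm = ctr,
           pose = poses[k, , drop = FALSE]),
      class = "subvolume")
  }
  list(subvolumes = subs, poses = poses[kept, , drop = FALSE],
       skipped = sum(!kept))
}

# candidate rotation matrices around a starting pose
search_rotations <- function(phi, theta, psi, angular_search) {
  if (angular_search$type == "global_phi") {
    step <- angular_search$step
    phis <- seq(0, 360 - step, by = step)
    lapply(phis, function(p) euler_to_matrix(p, theta, psi))
  } else if (angular_search$type == "local") {
    d <- seq(-angular_search$range, angular_search$range,
             by = angular_search$step)
    grid <- expand.grid(dphi = d, dtheta = d, dpsi = d)
    lapply(seq_len(nrow(grid)), function(i)
      euler_to_matrix(phi + grid$dphi[i], theta + grid$dtheta[i],
                      psi + grid$dpsi[i]))
  } else stop("unknown angular search type: ", angular_search$type)
}

# integer-voxel shift candidates: axial component (along `axis`, lab frame)
# limited to shift_limit nm, transverse norm limited to trans_limit voxels
search_shifts <- function(axis, voxel_size, shift_limit, trans_limit) {
  m <- ceiling(max(shift_limit / voxel_size, trans_limit))
  g <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
  ax <- g %*% axis
  perp2 <- rowSums(g^2) - ax^2
  keep <- abs(ax) * voxel_size <= shift_limit + 1e-9 &
    sqrt(pmax(0, perp2)) <= trans_limit + 1e-9
  t(g[keep, , drop = FALSE])
}

#' Align a subvolume against a reference
#'
#' Maximizes the masked normalized cross-correlation over a rotation grid
#' around the subvolume's pose (global in-plane search or local refinement
#' of all three Euler angles) and over integer-voxel translations. Shifts
#' are constrained along the filament axis (the pose's z direction) to
#' \code{shift_limit} (default 1.38 nm, half the actin rise) and
#' transversally to \code{trans_limit} voxels.
#'
#' @param sub a \code{subvolume} (see \code{\link{extract_subvolumes}}).
#' @param ref a \code{density_map} reference with the same box and voxel
#'   size.
#' @param angular_search list: \code{list(type = "global_phi", step = 10)}
#'   or \code{list(type = "local", range = 10, step = 2)}.
#' @param shift_limit axial shift bound, nm.
#' @param trans_limit transverse shift bound, voxels.
#' @param mask scoring mask array (default: soft cylinder of radius 40\%
#'   of the box along the pose axis).
#' @return list with \code{pose} (refined pose row: updated angles,
#'   position and \code{score}) and \code{score} (best masked NCC).
#' @export
align_subvolume <- function(sub, ref, angular_search = list(type = "global_phi",
                                                            step = 10),
                            shift_limit = 1.38, trans_limit = 2,
                            mask = NULL) {
  stopifnot(all(dim(sub$values) == dim(ref$values)),
            isTRUE(all.equal(sub$voxel_size, ref$voxel_size)))
  p <- sub$pose
  R0 <- euler_to_matrix(p$phi, p$theta, p$psi)
  axis <- as.numeric(R0 %*% c(0, 0, 1))
  if (is.null(mask))
    mask <- cylinder_mask(dim(sub$values), sub$voxel_size,
                          min(8, 0.4 * dim(sub$values)[1] * sub$voxel_size),
                          axis = axis)
  rots <- search_rotations(p$phi, p$theta, p$psi, angular_search)
  if (!length(rots)) stop("empty angular search grid")
  shifts <- search_shifts(axis, sub$voxel_size, shift_limit, trans_limit)
  Ms <- do.call(rbind, lapply(rots, t))
  sc <- cpp_score_grid(sub$values, ref$values, mask, Ms, shifts)
  best <- arrayInd(which.max(sc), dim(sc))
  R <- rots[[best[1]]]
  ang <- matrix_to_euler(R)
  tvox <- shifts[, best[2]]
  out <- p
  out$phi <- ang["phi"]; out$theta <- ang["theta"]; out$psi <- ang["psi"]
  # shifts are scored as absolute offsets from the subvolume box center,
  # so the refined position is center + shift (not an increment on the
  # previous pose -- increments would accumulate across rounds)
  ctr <- if (!is.null(sub$center_nm)) sub$center_nm else c(p$x, p$y, p$z)
  out$x <- ctr[1] + tvox[1] * sub$voxel_size
  out$y <- ctr[2] + tvox[2] * sub$voxel_size
  out$z <- ctr[3] + tvox[3] * sub$voxel_size
  out$score <- max(sc)
  list(pose = out, score = max(sc),
       shift_vox = tvox, rotation = R)
}

#' Average subvolumes in the reference frame
#'
#' Each subvolume is inverse-transformed to the reference frame using its
#' pose (rotation plus the constrained shift, taken as the pose position
#' relative to the subvolume's box center) and the transformed volumes are
#' averaged voxel-wise with uniform weights.
#'
#' @param subs list of \code{subvolume}s.
#' @param poses pose table with one row per subvolume (defaults to the
#'   poses stored in the subvolumes).
#' @return a \code{density_map}.
#' @export
average_subvolumes <- function(subs, poses = NULL) {
  if (!length(subs)) stop("need at least one subvolume")
  if (is.null(poses)) poses <- do.call(rbind, lapply(subs, `[[`, "pose"))
  vx <- subs[[1]]$voxel_size
  dm <- dim(subs[[1]]$values)
  acc <- array(0, dm)
  for (k in seq_along(subs)) {
    R <- euler_to_matrix(poses$phi[k], poses$theta[k], poses$psi[k])
    tvox <- (c(poses$x[k], poses$y[k], poses$z[k]) - subs[[k]]$center_nm) / vx
    acc <- acc + cpp_resample(subs[[k]]$values, R, c(0, 0, 0), tvox, dm)
  }
  density_map(acc / length(subs), vx)
}

#' Low-pass filter a density map
#'
#' Sharp spherical cutoff in the frequency domain at the requested
#' resolution.
#'
#' @param map a \code{density_map}.
#' @param resolution_nm cutoff resolution in nm (features finer than this
#'   are removed).
#' @return the filtered \code{density_map}.
#' @export
lowpass_map <- function(map, resolution_nm) {
  dm <- dim(map$values)
  freq_idx <- function(n) { k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n; k }
  kx <- freq_idx(dm[1]) / (dm[1] * map$voxel_size)
  ky <- freq_idx(dm[2]) / (dm[2] * map$voxel_size)
  kz <- freq_idx(dm[3]) / (dm[3] * map$voxel_size)
  r <- sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
  ft <- fft(map$values)
  ft[r > 1 / resolution_nm] <- 0
  map$values <- Re(fft(ft, inverse = TRUE)) / prod(dm)
  map
}

#' Iterative constrained alignment and averaging
#'
#' Alternates alignment of all subvolumes against the current reference and
#' re-averaging, following a schedule of rounds (global in-plane search
#' and/or local refinement of all Euler angles), emitting the mean
#' alignment score per round. Errors out if the mean score decreases for
#' three consecutive rounds (divergence guard).
#'
#' @param subs list of \code{subvolume}s.
#' @param ref0 starting reference (\code{density_map}).
#' @param schedule list of rounds, each an \code{angular_search} list for
#'   \code{\link{align_subvolume}}, optionally carrying its own
#'   \code{shift_limit} / \code{trans_limit} override. Tightening the shift
#'   bounds in late local-refinement rounds prevents subvolumes from
#'   hopping to the half-rise helical register (an axial shift of 1.38 nm
#'   plus a compensating in-plane rotation), which would smear the
#'   polarity signal out of the average.
#' @param shift_limit,trans_limit shift constraints, as in
#'   \code{\link{align_subvolume}}.
#' @param divergence_tol a round counts as a decrease only when the mean
#'   score drops by more than this amount; small dips are expected when the
#'   reference sharpens between rounds (a sharper average correlates less
#'   with each noisy subvolume even as the structure improves).
#' @param lowpass resolution (nm) of the low-pass filter applied to each
#'   new average before it is reused as the alignment reference (default
#'   2.5 nm); NULL disables. Filtering the working reference suppresses
#'   interpolation artifacts that would otherwise feed back into the
#'   alignment. The returned map is the unfiltered final average.
#' @return list with \code{map} (final average), \code{poses} (refined pose
#'   table with scores) and \code{mean_scores} (per round).
#' @export
iterate_alignment <- function(subs, ref0, schedule, shift_limit = 1.38,
                              trans_limit = 2, divergence_tol = 0.02,
                              lowpass = 2.5) {
  ref <- ref0
  poses <- do.call(rbind, lapply(subs, `[[`, "pose"))
  if (is.null(poses$score)) poses$score <- NA_real_
  mean_scores <- numeric(0)
  drops <- 0
  for (round in seq_along(schedule)) {
    rd <- schedule[[round]]
    sl <- if (!is.null(rd$shift_limit)) rd$shift_limit else shift_limit
    tl <- if (!is.null(rd$trans_limit)) rd$trans_limit else trans_limit
    for (k in seq_along(subs)) {
      subs[[k]]$pose <- poses[k, , drop = FALSE]
      al <- align_subvolume(subs[[k]], ref, rd,
                            shift_limit = sl, trans_limit = tl)
      poses[k, names(al$pose)] <- al$pose
    }
    ms <- mean(poses$score)
    if (length(mean_scores) && ms < tail(mean_scores, 1) - divergence_tol) {
      drops <- drops + 1
      if (drops >= 3) stop("alignment diverged: mean score decreased for ",
                           "3 consecutive rounds")
    } else drops <- 0
    mean_scores <- c(mean_scores, ms)
    avg <- average_subvolumes(subs, poses)
    ref <- if (is.null(lowpass)) avg else lowpass_map(avg, lowpass)
  }
  list(map = avg, poses = poses, mean_scores = mean_scores)
}

#' Remove oversampled positions, one subtomogram per actin subunit
#'
#' Greedy selection per filament in descending score order: a pose closer
#' than \code{min_distance} (default 2.76 nm, the axial rise) to an
#' already-kept pose on the same filament is dropped. The kept set is
#' maximal: every dropped pose is within \code{min_distance} of a kept one.
#'
#' @param poses pose table with refined positions (and optionally a
#'   \code{score} column; equal or missing scores fall back to table
#'   order).
#' @param min_distance nm.
#' @return the kept pose rows.
#' @export
dedupe_positions <- function(poses, min_distance = 2.76) {
  keep_all <- lapply(split(poses, poses$filament_id), function(f) {
    ord <- if (!is.null(f$score) && !anyNA(f$score))
      order(-f$score) else seq_len(nrow(f))
    xyz <- as.matrix(f[, c("x", "y", "z")])
    kept <- integer(0)
    for (i in ord) {
      # strict "closer than" with a float tolerance: poses at exactly the
      # threshold spacing (one per subunit) are kept
      if (!length(kept) ||
          all(sqrt(colSums((t(xyz[kept, , drop = FALSE]) - xyz[i, ])^2)) >=
              min_distance - 1e-6))
        kept <- c(kept, i)
    }
    f[sort(kept), , drop = FALSE]
  })
  out <- do.call(rbind, keep_all)
  rownames(out) <- NULL
  out
}

#' Fourier shell correlation of two maps
#'
#' Correlation of Fourier coefficients per spherical frequency shell; the
#' reported resolution is 1/frequency at the first downward 0.143 crossing
#' (linear interpolation between shells). A map against itself gives FSC
#' identically 1 and a resolution of twice the voxel size (Nyquist).
#'
#' @param map_a,map_b \code{density_map}s with identical box and voxel
#'   size.
#' @return an object of class \code{fsc_curve}: list with \code{freq}
#'   (1/nm), \code{fsc}, \code{resolution_nm} and \code{resolution_A}.
#' @export
fsc <- function(map_a, map_b) {
  if (!all(dim(map_a$values) == dim(map_b$values)) ||
      !isTRUE(all.equal(map_a$voxel_size, map_b$voxel_size)))
    stop("FSC requires identical box and voxel size")
  dm <- dim(map_a$values)
  fa <- fft(map_a$values)
  fb <- fft(map_b$values)
  freq_idx <- function(n) { k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n; k }
  kx <- freq_idx(dm[1]); ky <- freq_idx(dm[2]); kz <- freq_idx(dm[3])
  r <- sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
  shell <- round(r)
  smax <- floor(min(dm) / 2)
  num <- re_den_a <- den_b <- numeric(smax)
  sel <- shell >= 1 & shell <= smax
  s <- shell[sel]
  num <- as.numeric(tapply(Re(fa[sel] * Conj(fb[sel])), s, sum))
  da <- as.numeric(tapply(abs(fa[sel])^2, s, sum))
  db <- as.numeric(tapply(abs(fb[sel])^2, s, sum))
  corr <- num / sqrt(da * db)
  corr[!is.finite(corr)] <- 0
  nvox <- dm[1] * map_a$voxel_size
  freq <- seq_len(smax) / nvox
  cross <- which(corr < 0.143)
  if (!length(cross)) {
    res <- 2 * map_a$voxel_size
  } else {
    i <- cross[1]
    if (i == 1) res <- 1 / freq[1]
    else {
      f <- freq[i - 1] + (0.143 - corr[i - 1]) / (corr[i] - corr[i - 1]) *
        (freq[i] - freq[i - 1])
      res <- 1 / f
    }
  }
  structure(list(freq = freq, fsc = corr, resolution_nm = res,
                 resolution_A = res * 10),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("FSC: %d shells, resolution (0.143) = %.2f nm (%.1f A)\n",
              length(x$freq), x$resolution_nm, x$resolution_A))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, ...) {
  graphics::plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/nm)",
                 ylab = "FSC", ylim = c(-0.2, 1), ...)
  graphics::abline(h = 0.143, lty = 2)
  invisible(x)
}

#' Two-reference statistical polarity assignment
#'
#' Every subvolume is aligned against both polarity references
#' independently with identical search settings; the two score samples of
#' each filament are compared with a two-sided unpaired Student's t-test
#' (pooled variance by default, Welch optionally). Filaments with
#' p < \code{alpha} are called for the higher-scoring reference; others
#' remain unassigned. Filaments with fewer than two subvolumes are
#' unassigned with p = 1.
#'
#' @param subs list of \code{subvolume}s (their poses carry filament ids).
#' @param ref_a,ref_b polarity references (\code{density_map}s), typically
#'   from \code{\link{make_reference_pair}}.
#' @param alpha significance level.
#' @param angular_search,shift_limit,trans_limit search settings, as in
#'   \code{\link{align_subvolume}}.
#' @param welch use Welch's t-test instead of the pooled-variance test.
#' @param split if FALSE (default) every subvolume is scored against both
#'   references; the two score samples of a filament then share the same
#'   noise realisations, which makes the unpaired t-test conservative
#'   (realised false-call rate below alpha on polarity-free input). If
#'   TRUE, the subvolumes of each filament are split into two disjoint
#'   halves scored against A and B respectively, so the two samples are
#'   statistically independent and the test realises its nominal size
#'   alpha exactly.
#' @return a data frame of class \code{polarity_calls} with one row per
#'   filament: \code{filament_id, n_subvolumes, mean_score_A,
#'   mean_score_B, p_value, call} (call in "A", "B", "unassigned"). The
#'   per-subvolume scores are attached as attribute \code{"scores"}.
#' @export
assign_polarity <- function(subs, ref_a, ref_b, alpha = 0.05,
                            angular_search = list(type = "global_phi",
                                                  step = 30),
                            shift_limit = 1.38, trans_limit = 1,
                            welch = FALSE, split = FALSE) {
  n <- length(subs)
  fid <- vapply(subs, function(s) s$pose$filament_id[1], numeric(1))
  sa <- sb <- rep(NA_real_, n)
  vs_a <- rep(TRUE, n)
  if (split)
    for (ix in split(seq_len(n), fid))
      vs_a[ix] <- seq_along(ix) %% 2 == 1
  for (k in seq_len(n)) {
    if (!split || vs_a[k])
      sa[k] <- align_subvolume(subs[[k]], ref_a, angular_search,
                               shift_limit, trans_limit)$score
    if (!split || !vs_a[k])
      sb[k] <- align_subvolume(subs[[k]], ref_b, angular_search,
                               shift_limit, trans_limit)$score
  }
  res <- lapply(split(seq_len(n), fid), function(ix) {
    a <- sa[ix][!is.na(sa[ix])]; b <- sb[ix][!is.na(sb[ix])]
    if (length(a) < 2 || length(b) < 2) {
      warning("filament ", fid[ix[1]], " has < 2 subvolumes; unassigned")
      p <- 1
    } else if (sd(a) == 0 && sd(b) == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      p <- tryCatch(t.test(a, b, var.equal = !welch)$p.value,
                    error = function(e) 1)
      if (!is.finite(p)) p <- 1
    }
    data.frame(filament_id = fid[ix[1]], n_subvolumes = length(ix),
               mean_score_A = mean(a), mean_score_B = mean(b), p_value = p,
               call = if (p < alpha) {
                 if (mean(a) >= mean(b)) "A" else "B"
               } else "unassigned")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "scores") <- data.frame(filament_id = fid, score_A = sa,
                                    score_B = sb)
  class(out) <- c("polarity_calls", "data.frame")
  out
}

#' Read / write polarity call tables as CSV
#' @param calls a \code{polarity_calls} data frame.
#' @param path file path.
#' @export
write_calls_csv <- function(calls, path) {
  write.csv(as.data.frame(calls)[, c("filament_id", "n_subvolumes",
                                     "mean_score_A", "mean_score_B",
                                     "p_value", "call")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_csv
#' @export
read_calls_csv <- function(path) {
  out <- read.csv(path)
  class(out) <- c("polarity_calls", "data.frame")
  out
}
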
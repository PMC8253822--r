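# shared builders for the test suite: straight filaments, small bundles and
# desk-scale rendering settings

straight_filament <- function(id, from, to, type = "thin", polarity = 1L,
                              n = 2) {
  s <- seq(0, 1, length.out = n)
  data.frame(filament_id = id, type = type, polarity = polarity,
             point_index = seq_len(n),
             x = from[1] + s * (to[1] - from[1]),
             y = from[2] + s * (to[2] - from[2]),
             z = from[3] + s * (to[3] - from[3]))
}

# parallel thin filaments along +z spread along x inside a rendering box;
# ids in `reversed` are traced in the opposite direction (opposite polarity
# in the lab frame)
test_bundle <- function(n = 4, box_nm = c(72, 44, 88), spacing = 15,
                        reversed = integer(0), margin = 14) {
  rows <- lapply(seq_len(n), function(i) {
    f <- straight_filament(i, c(margin + (i - 1) * spacing, box_nm[2] / 2,
                                margin),
                           c(margin + (i - 1) * spacing, box_nm[2] / 2,
                             box_nm[3] - margin))
    if (i %in% reversed) {
      f <- f[rev(seq_len(nrow(f))), ]
      f$point_index <- seq_len(nrow(f))
    }
    f
  })
  filament_network(do.call(rbind, rows))
}

# brute-force closest-point neighbor observations (independent oracle for
# neighbor_observations): exhaustive all-pairs distance search
brute_neighbor_obs <- function(network, ref_type, nbr_type, d_max) {
  fils <- split(as.data.frame(network), network$filament_id)
  out <- list()
  for (f in fils) {
    if (f$type[1] != ref_type) next
    tf <- local_tangents(f)
    for (g in fils) {
      if (g$type[1] != nbr_type || g$filament_id[1] == f$filament_id[1]) next
      tg <- local_tangents(g)
      for (i in seq_len(nrow(f))) {
        dd <- sqrt((g$x - f$x[i])^2 + (g$y - f$y[i])^2 + (g$z - f$z[i])^2)
        j <- which.min(dd)
        if (dd[j] <= d_max) {
          th <- acos(min(1, abs(sum(tf[i, ] * tg[j, ])))) * 180 / pi
          out[[length(out) + 1L]] <- data.frame(
            ref_id = f$filament_id[1], ref_point = i,
            nbr_id = g$filament_id[1], d = dd[j], theta = th)
        }
      }
    }
  }
  do.call(rbind, out)
}

# noise subvolume with a minimal pose, for polarity null simulations
noise_subvolume <- function(fid, box, voxel_size, phi = 0) {
  structure(list(values = array(rnorm(box^3), c(box, box, box)),
                 voxel_size = voxel_size, center_nm = c(0, 0, 0),
                 pose = data.frame(filament_id = fid, subunit_index = 1,
                                   x = 0, y = 0, z = 0, phi = phi,
                                   theta = 0, psi = 0)),
            class = "subvolume")
}
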
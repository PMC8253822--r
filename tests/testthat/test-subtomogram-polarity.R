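vx <- 0.684

test_that("subvolume extraction crops exactly and skips boundary poses", {
  set.seed(41)
  m <- density_map(array(rnorm(24^3), c(24, 24, 24)), vx)
  ctr <- 24 * vx / 2
  poses <- data.frame(filament_id = 1, subunit_index = 1:3,
                      x = c(ctr, ctr, 0.4), y = ctr, z = ctr,
                      phi = 0, theta = 0, psi = 0)
  ex <- extract_subvolumes(m, poses, 24)
  # a pose at the center with box = map size returns the whole map
  expect_equal(ex$subvolumes[[1]]$values, m$values)
  # a pose within half a box of the boundary is skipped, with a count
  expect_equal(ex$skipped, 1)
  expect_equal(length(ex$subvolumes), 2)
  # crop values equal the corresponding source region exactly
  p2 <- data.frame(filament_id = 1, subunit_index = 1,
                   x = 8 * vx, y = 10 * vx, z = 12 * vx,
                   phi = 0, theta = 0, psi = 0)
  ex2 <- extract_subvolumes(m, p2, 8)
  expect_equal(ex2$subvolumes[[1]]$values, m$values[5:12, 7:14, 9:16])
})

test_that("alignment recovers identity, planted shifts, and matches an
           exhaustive grid search", {
  hx <- helical_params()
  refs <- make_reference_pair(hx, vx, 24)
  sub <- structure(list(values = refs$A$values, voxel_size = vx,
                        center_nm = c(0, 0, 0),
                        pose = data.frame(filament_id = 1, subunit_index = 1,
                                          x = 0, y = 0, z = 0, phi = 0,
                                          theta = 0, psi = 0)),
                   class = "subvolume")
  al <- align_subvolume(sub, refs$A, list(type = "local", range = 0, step = 1),
                        trans_limit = 0, shift_limit = 0)
  expect_equal(al$score, 1, tolerance = 1e-6)
  expect_equal(unlist(al$pose[c("phi", "theta", "psi")]),
               c(phi = 0, theta = 0, psi = 0))
  # planted axial shift of 1.0 nm recovered within half a voxel
  shifted <- sarcopack:::cpp_resample(refs$A$values, diag(3), c(0, 0, 0),
                                      c(0, 0, -1.0 / vx), dim(refs$A$values))
  sub2 <- sub
  sub2$values <- shifted   # filament displaced +1 nm along z
  al2 <- align_subvolume(sub2, refs$A, list(type = "local", range = 0,
                                            step = 1), shift_limit = 1.38)
  # 1.0 nm is 1.46 voxels: both neighboring integer shifts are legitimate
  # candidates, so allow up to 0.6 voxel of rounding
  expect_lt(abs(al2$pose$z - 1.0), vx * 0.6)
  # exhaustive-search oracle on a coarse grid: the returned maximum equals
  # a brute-force evaluation over the same candidates
  search <- list(type = "global_phi", step = 45)
  mask <- cylinder_mask(dim(sub2$values), vx, 8, axis = c(0, 0, 1))
  al3 <- align_subvolume(sub2, refs$A, search, shift_limit = 1.38,
                         trans_limit = 1, mask = mask)
  w <- as.numeric(mask > 1e-3) * mask
  brute_best <- -2
  for (ph in seq(0, 315, 45)) {
    R <- euler_to_matrix(ph, 0, 0)
    for (sx in -1:1) for (sy in -1:1) for (sz in -2:2) {
      if (sqrt(sx^2 + sy^2) > 1 + 1e-9 || abs(sz) * vx > 1.38 + 1e-9) next
      if (sqrt(sx^2 + sy^2 + 0) > 0 && sqrt(sx^2 + sy^2) > 1) next
      b <- sarcopack:::cpp_resample(refs$A$values, t(R), c(sx, sy, sz),
                                    c(0, 0, 0), dim(refs$A$values))
      a <- as.numeric(sub2$values)
      bv <- as.numeric(b)
      wm <- as.numeric(mask)
      sel <- wm > 1e-3
      a <- a[sel]; bv <- bv[sel]; wv <- wm[sel]
      am <- sum(wv * a) / sum(wv); bm <- sum(wv * bv) / sum(wv)
      sc <- sum(wv * (a - am) * (bv - bm)) /
        sqrt(sum(wv * (a - am)^2) * sum(wv * (bv - bm)^2))
      brute_best <- max(brute_best, sc)
    }
  }
  expect_equal(al3$score, brute_best, tolerance = 1e-9)
  expect_error(align_subvolume(sub, refs$A, list(type = "nope")), "search")
})

test_that("alignment score is invariant under joint rotation of sub and ref", {
  hx <- helical_params()
  refs <- make_reference_pair(hx, vx, 24)
  set.seed(43)
  vals <- refs$A$values + array(rnorm(24^3, 0, 0.1), c(24, 24, 24))
  rot90 <- function(v) aperm(v, c(2, 1, 3))[24:1, , ]   # 90 deg about z
  sub <- structure(list(values = vals, voxel_size = vx, center_nm = c(0, 0, 0),
                        pose = data.frame(filament_id = 1, subunit_index = 1,
                                          x = 0, y = 0, z = 0, phi = 0,
                                          theta = 0, psi = 0)),
                   class = "subvolume")
  subr <- sub
  subr$values <- rot90(vals)
  refr <- refs$A
  refr$values <- rot90(refs$A$values)
  s1 <- align_subvolume(sub, refs$A, list(type = "global_phi", step = 30))
  s2 <- align_subvolume(subr, refr, list(type = "global_phi", step = 30))
  expect_equal(s1$score, s2$score, tolerance = 1e-6)
})

test_that("averaging reproduces inputs and shrinks noise like 1/sqrt(N)", {
  hx <- helical_params()
  refs <- make_reference_pair(hx, vx, 20)
  mk <- function(values) structure(
    list(values = values, voxel_size = vx, center_nm = c(0, 0, 0),
         pose = data.frame(filament_id = 1, subunit_index = 1, x = 0, y = 0,
                           z = 0, phi = 0, theta = 0, psi = 0)),
    class = "subvolume")
  subs <- replicate(5, mk(refs$A$values), simplify = FALSE)
  avg <- average_subvolumes(subs)
  expect_equal(avg$values, refs$A$values, tolerance = 1e-12)
  # CLT: averaging 100 noise-only subvolumes shrinks the sd by ~1/10
  set.seed(44)
  nsubs <- replicate(100, mk(array(rnorm(12^3), c(12, 12, 12))),
                     simplify = FALSE)
  navg <- average_subvolumes(nsubs)
  inner <- navg$values[3:10, 3:10, 3:10]
  expect_lt(abs(sd(inner) - 1 / sqrt(100)) / (1 / sqrt(100)), 0.1)
})

test_that("averaging randomized in-plane copies yields a near-cylinder", {
  hx <- helical_params()
  refs <- make_reference_pair(hx, vx, 24)
  set.seed(45)
  subs <- lapply(1:60, function(i) structure(
    list(values = refs$A$values, voxel_size = vx, center_nm = c(0, 0, 0),
         pose = data.frame(filament_id = 1, subunit_index = i, x = 0, y = 0,
                           z = 0, phi = sample(seq(0, 330, 30), 1),
                           theta = 0, psi = 0)),
    class = "subvolume"))
  cyl <- average_subvolumes(subs)
  # azimuthal variance at the actin radius collapses relative to the
  # structured reference
  prof_var <- function(m) {
    ctr <- dim(m$values) * m$voxel_size / 2
    v <- vapply(seq(0, 350, 10), function(ph) {
      a <- ph * pi / 180
      pts <- cbind(ctr[1] + 2 * cos(a), ctr[2] + 2 * sin(a),
                   seq(ctr[3] - 4, ctr[3] + 4, length.out = 9))
      mean(sarcopack:::interp_map(m, pts))
    }, numeric(1))
    var(v)
  }
  expect_lt(prof_var(cyl), prof_var(refs$A) / 20)
})

test_that("deduplication keeps one pose per subunit and is maximal", {
  poses <- data.frame(filament_id = 1, subunit_index = 1:11,
                      x = 0, y = 0, z = (0:10) * 1.38,
                      phi = 0, theta = 0, psi = 0)
  kept <- dedupe_positions(poses, 2.76)
  expect_equal(nrow(kept), ceiling(11 / 2))
  expect_true(all(diff(kept$z) >= 2.76 - 1e-9))
  # a single pose is kept
  expect_equal(nrow(dedupe_positions(poses[1, , drop = FALSE])), 1)
  # maximality and minimum-distance invariants on random scored poses
  set.seed(46)
  rp <- data.frame(filament_id = rep(1:3, each = 30), subunit_index = 1:30,
                   x = runif(90, 0, 20), y = runif(90, 0, 20),
                   z = runif(90, 0, 20), phi = 0, theta = 0, psi = 0,
                   score = runif(90))
  kept2 <- dedupe_positions(rp, 5)
  expect_lte(nrow(kept2), nrow(rp))
  for (fid in 1:3) {
    k <- kept2[kept2$filament_id == fid, ]
    d <- as.matrix(dist(k[, c("x", "y", "z")]))
    diag(d) <- Inf
    expect_true(all(d >= 5 - 1e-9))
    dropped <- rp[rp$filament_id == fid &
                    !(rp$subunit_index %in% k$subunit_index), ]
    if (nrow(dropped)) {
      dmin <- apply(as.matrix(dropped[, c("x", "y", "z")]), 1, function(p)
        min(sqrt(colSums((t(as.matrix(k[, c("x", "y", "z")])) - p)^2))))
      expect_true(all(dmin < 5))
    }
  }
})

test_that("FSC is 1 on identical maps, ~0 on noise, and finds a planted
           cutoff", {
  hx <- helical_params()
  A <- make_reference_pair(hx, vx, 32)$A
  f <- fsc(A, A)
  expect_true(all(abs(f$fsc - 1) < 1e-9))
  expect_equal(f$resolution_nm, 2 * vx)
  # symmetry in the arguments
  set.seed(47)
  n1 <- density_map(array(rnorm(64^3), c(64, 64, 64)), vx)
  n2 <- density_map(array(rnorm(64^3), c(64, 64, 64)), vx)
  f12 <- fsc(n1, n2)
  f21 <- fsc(n2, n1)
  expect_equal(f12$fsc, f21$fsc, tolerance = 1e-12)
  expect_lt(mean(abs(f12$fsc)), 0.05)
  # band-limited signal + independent noise: crossing at the cutoff +/- one
  # shell
  sig <- lowpass_map(n1, resolution_nm = 1 / (10 / (64 * vx)))
  h1 <- density_map(sig$values + 1e-3 * array(rnorm(64^3), c(64, 64, 64)), vx)
  h2 <- density_map(sig$values + 1e-3 * array(rnorm(64^3), c(64, 64, 64)), vx)
  fb <- fsc(h1, h2)
  cross_shell <- which(fb$fsc < 0.143)[1]
  expect_lte(abs(cross_shell - 10), 1)
  expect_error(fsc(A, n1), "box")
})

test_that("polarity calls are correct on noise-free filaments of known
           polarity and symmetric under reference swap", {
  hx <- helical_params()
  box <- 32
  refs <- make_reference_pair(hx, vx, box)
  set.seed(48)
  net <- test_bundle(4, box_nm = c(66, 44, 88), reversed = c(2, 4))
  pt <- helical_poses(net, hx, phi0 = "random", seed = 49)
  tomo <- render_filament_density(pt, hx, vx, c(104, 64, 128))
  netu <- unify_directions(resample_network(net, 1.38))
  ip <- init_network_poses(netu, seed = 50)
  ip <- ip[ip$subunit_index %% 4 == 1, ]
  ex <- extract_subvolumes(tomo, ip, box)
  calls <- assign_polarity(ex$subvolumes, refs$A, refs$B,
                           angular_search = list(type = "global_phi",
                                                 step = 20))
  expect_true(all(calls$call != "unassigned"))
  expect_equal(calls$call, c("A", "B", "A", "B"))
  # swapping the references swaps calls and keeps p-values
  swapped <- assign_polarity(ex$subvolumes, refs$B, refs$A,
                             angular_search = list(type = "global_phi",
                                                   step = 20))
  expect_equal(swapped$call, c("B", "A", "B", "A"))
  expect_equal(swapped$p_value, calls$p_value, tolerance = 1e-9)
  expect_equal(swapped$mean_score_A, calls$mean_score_B, tolerance = 1e-9)
})

test_that("degenerate score samples are guarded", {
  hx <- helical_params()
  refs <- make_reference_pair(hx, vx, 16)
  # one subvolume on a filament: unassigned with p = 1 and a warning
  set.seed(51)
  solo <- list(noise_subvolume(1, 16, vx))
  expect_warning(calls <- assign_polarity(solo, refs$A, refs$B),
                 "unassigned")
  expect_equal(calls$call, "unassigned")
  expect_equal(calls$p_value, 1)
  # identical score samples (same reference on both sides) give p = 1
  set.seed(52)
  several <- replicate(4, noise_subvolume(2, 16, vx), simplify = FALSE)
  calls2 <- assign_polarity(several, refs$A, refs$A)
  expect_equal(calls2$call, "unassigned")
  expect_equal(calls2$p_value, 1)
})

test_that("iterative alignment refines to the rendering ground truth", {
  hx <- helical_params()
  box <- 32
  refs <- make_reference_pair(hx, vx, box)
  net <- test_bundle(4, box_nm = c(66, 44, 88))
  pt <- helical_poses(net, hx, phi0 = "random", seed = 52)
  tomo <- render_filament_density(pt, hx, vx, c(104, 64, 128))
  netu <- unify_directions(resample_network(net, 1.38))
  ip <- init_network_poses(netu, seed = 53)
  ip <- ip[ip$subunit_index %% 4 == 1, ]
  ex <- extract_subvolumes(tomo, ip, box)
  it <- iterate_alignment(ex$subvolumes, lowpass_map(refs$A, 2.5),
                          schedule = list(list(type = "global_phi", step = 10),
                                          list(type = "global_phi", step = 10)))
  # mean alignment score does not decrease on noise-free input
  expect_true(all(diff(it$mean_scores) > -0.02))
  expect_gt(cor(as.numeric(it$map$values), as.numeric(refs$A$values)), 0.95)
  # and the polarity stays pure: the flipped reference matches much worse
  expect_lt(cor(as.numeric(it$map$values), as.numeric(refs$B$values)),
            cor(as.numeric(it$map$values), as.numeric(refs$A$values)) - 0.1)
})
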
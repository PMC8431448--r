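# Geometric hydrogen-bond detection and occupancy.

# minimal donor and acceptor species with directly controlled coordinates
donor_spec <- molecule_spec("don", list(
  atom_spec("N1", "N", 14.007, hbond = "donor"),
  atom_spec("H1", "H", 1.008, hbond = "hydrogen", donor = "N1")
))
acceptor_spec <- molecule_spec("acc", list(
  atom_spec("O1", "O", 15.999, hbond = "acceptor", acceptor_class = "oxy")
))

# one donor/acceptor pair: N at `at`, H 1 A along +x, acceptor with
# D-H...A angle theta (deg) and H-A length L in the xy-plane
hb_pair_coords <- function(at, theta, L) {
  N <- at; H <- at + c(1, 0, 0)
  a <- (180 - theta) * pi / 180
  A <- H + L * c(cos(a), sin(a), 0)
  list(N = N, H = H, A = A)
}

hb_system <- function(pairs, box = c(100, 100, 100)) {
  n <- length(pairs)
  top <- system_topology(list(donor_spec, acceptor_spec), c(n, n), box = box)
  xyz <- matrix(0, nrow(top$atoms), 3)
  for (k in seq_len(n)) {
    xyz[2 * k - 1, ] <- pairs[[k]]$N
    xyz[2 * k, ] <- pairs[[k]]$H
    xyz[2 * n + k, ] <- pairs[[k]]$A
  }
  trajectory(top, list(xyz), box = box)
}

test_that("an ideal linear N-H...O geometry is detected", {
  tr <- hb_system(list(hb_pair_coords(c(10, 10, 10), 180, 1.9)))
  ev <- detect_hbonds(tr, 1)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$da_distance, 2.9, tolerance = 1e-9)
  expect_equal(ev$dha_angle, 180, tolerance = 1e-6)
  expect_identical(ev$acceptor_class, "oxy")
})

test_that("a 4.0 A donor-acceptor separation fails the 3.5 A criterion", {
  tr <- hb_system(list(hb_pair_coords(c(10, 10, 10), 180, 3.0)))  # DA = 4.0
  expect_identical(nrow(detect_hbonds(tr, 1)), 0L)
})

test_that("exactly the qualifying geometries are detected, matching the brute-force oracle", {
  # two qualifying, three near-miss (distance, angle, both)
  geos <- list(
    hb_pair_coords(c(10, 10, 10), 180, 1.9),   # DA 2.9, 180: qualifies
    hb_pair_coords(c(40, 10, 10), 150, 2.2),   # DA 3.11, 150: qualifies
    hb_pair_coords(c(70, 10, 10), 180, 2.8),   # DA 3.8: too far
    hb_pair_coords(c(10, 40, 10), 100, 1.9),   # angle 100: too bent
    hb_pair_coords(c(40, 40, 10), 60, 3.5)     # fails both
  )
  tr <- hb_system(geos)
  ev <- detect_hbonds(tr, 1)
  expect_identical(nrow(ev), 2L)
  a <- tr$topology$atoms
  hyd <- a[a$hbond == "hydrogen", ]
  acc <- a[a$hbond == "acceptor", ]
  don_idx <- vapply(seq_len(nrow(hyd)), function(k) {
    a$atom[a$mol == hyd$mol[k] & a$name == hyd$donor[k]]
  }, integer(1))
  orc <- oracle_hbonds(tr$coords[[1]], tr$box[1, ], don_idx, hyd$atom,
                       acc$atom, hyd$mol, acc$mol, 3.5, 120)
  expect_setequal(paste(ev$hydrogen_atom, ev$acceptor_atom),
                  paste(orc[, "hydrogen"], orc[, "acceptor"]))
})

test_that("detection matches the all-triples oracle on randomized synthetic frames", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 12, n_inhibitor = 4,
                                           n_frames = 20,
                                           hijack_fraction = 0.6,
                                           hbond_plant_rate = 0.3, seed = 81))
  tr <- g$trajectory
  a <- tr$topology$atoms
  hyd <- a[a$hbond == "hydrogen", ]
  acc <- a[a$hbond == "acceptor", ]
  don_idx <- vapply(seq_len(nrow(hyd)), function(k) {
    a$atom[a$mol == hyd$mol[k] & a$name == hyd$donor[k]]
  }, integer(1))
  for (f in seq_len(n_frames(tr))) {
    ev <- detect_hbonds(tr, f)
    orc <- oracle_hbonds(tr$coords[[f]], tr$box[f, ], don_idx, hyd$atom,
                         acc$atom, hyd$mol, acc$mol, 3.5, 120)
    got <- if (nrow(ev)) paste(ev$hydrogen_atom, ev$acceptor_atom)
           else character(0)
    want <- if (is.null(orc)) character(0)
            else paste(orc[, "hydrogen"], orc[, "acceptor"])
    expect_setequal(got, want)
  }
})

test_that("minimum image applies to hydrogen-bond geometry across the boundary", {
  p <- hb_pair_coords(c(98.5, 10, 10), 180, 1.9)  # acceptor wraps past x = 100
  p$A <- p$A - c(100, 0, 0)
  tr <- hb_system(list(p))
  ev <- detect_hbonds(tr, 1)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$da_distance, 2.9, tolerance = 1e-9)
})

test_that("occupancy counts frames with at least one event of the class", {
  near <- hb_pair_coords(c(10, 10, 10), 180, 1.9)
  far <- hb_pair_coords(c(10, 10, 10), 180, 5.0)
  top <- hb_system(list(near))$topology
  mk <- function(p) hb_system(list(p))$coords[[1]]
  tr <- trajectory(top, list(mk(near), mk(near), mk(far)))
  occ <- hbond_occupancy(tr)
  expect_equal(occ$occupancy[occ$acceptor_class == "oxy"], 2 / 3)
  # a class with no annotated acceptors reports occupancy 0
  occ2 <- hbond_occupancy(tr, acceptor_class = c("oxy", "absent"))
  expect_equal(occ2$occupancy[occ2$acceptor_class == "absent"], 0)
  expect_identical(occ2$n_frames_with_event[occ2$acceptor_class == "absent"],
                   0L)
})

test_that("systems without acceptors run with empty results, or error when required", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 6, n_frames = 2,
                                           seed = 5))
  ev <- detect_hbonds(g$trajectory, 1)
  expect_identical(nrow(ev), 0L)
  expect_error(detect_hbonds(g$trajectory, 1, require_annotations = TRUE),
               "acceptors")
  occ <- hbond_occupancy(g$trajectory)
  expect_identical(nrow(occ), 0L)
})

test_that("planted occupancies are recovered within three binomial standard errors", {
  for (p in c(0.01, 0.06, 0.25)) {
    n <- 300
    g <- generate_trajectory(traj_gen_config(
      n_monomer = 10, n_inhibitor = 2, n_frames = n, hijack_fraction = 0.2,
      hbond_plant_rate = p, seed = round(1000 * p) + 7))
    occ <- hbond_occupancy(g$trajectory)
    est <- occ$occupancy[occ$acceptor_class == "intra_ring_oxygen"]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(est - p), 3 * se + 1e-12)
    # the estimate equals the generator's recorded planted-frame count
    expect_equal(est, length(g$truth$planted_frames) / n)
  }
})

test_that("occupancy is invariant to frame and replica concatenation order", {
  mk <- function(seed) generate_trajectory(traj_gen_config(
    n_monomer = 8, n_inhibitor = 2, n_frames = 20, hijack_fraction = 0.5,
    hbond_plant_rate = 0.3, seed = seed), replica_id = paste0("r", seed))
  a <- mk(1)$trajectory; b <- mk(2)$trajectory
  occ_ab <- hbond_occupancy(build_metatrajectory(list(a, b), retain_tail = 19))
  occ_ba <- hbond_occupancy(build_metatrajectory(list(b, a), retain_tail = 19))
  expect_equal(occ_ab$occupancy[order(occ_ab$acceptor_class)],
               occ_ba$occupancy[order(occ_ba$acceptor_class)])
  set.seed(99)
  shuf <- a[sample(1:20)]
  expect_equal(hbond_occupancy(shuf)$occupancy,
               hbond_occupancy(a)$occupancy)
})
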
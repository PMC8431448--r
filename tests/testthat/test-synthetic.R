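# Generator contracts: construction guarantees, bookkeeping, determinism and
# round-trips through the file formats.

test_that("a noise-free stack is one aggregate with all pair angles zero", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 5, n_frames = 1,
                                           stack_mean_size = 5,
                                           stack_angle_sigma = 0, seed = 9))
  # force a single 5-stack by construction: all monomers in one component
  tr <- g$trajectory
  ag <- aggregates(contact_pairs(tr, 1, species = "adenine"))
  truth_sizes <- sort(lengths(g$truth$frames[[1]]$partition))
  expect_identical(sort(as.integer(ag$sizes)), as.integer(truth_sizes))
  ad <- angle_distribution(tr)
  if (ad$n > 0) expect_true(all(abs(ad$samples$angle) < 1e-6))
})

test_that("generated configurations are deterministic in the seed", {
  cfg <- traj_gen_config(n_monomer = 15, n_inhibitor = 3, n_frames = 4,
                         hijack_fraction = 0.4, hbond_plant_rate = 0.5,
                         seed = 77)
  g1 <- generate_trajectory(cfg)
  g2 <- generate_trajectory(cfg)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$truth$planted_frames, g2$truth$planted_frames)
  g3 <- generate_trajectory(traj_gen_config(n_monomer = 15, n_inhibitor = 3,
                                            n_frames = 4,
                                            hijack_fraction = 0.4,
                                            hbond_plant_rate = 0.5,
                                            seed = 78))
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(traj_gen_config(hijack_fraction = 1.2), "hijack_fraction")
  expect_error(traj_gen_config(hbond_plant_rate = 0.1, n_inhibitor = 0),
               "inhibitor")
  expect_error(traj_gen_config(box_edge = 10), "extent")
  expect_error(traj_gen_config(stack_rise = 2), "stack_rise")
  expect_error(kinetic_gen_config(doses = 1, inhibition_map = 150),
               "inhibition")
})

test_that("overcrowding is detected with a suggestion to enlarge the box", {
  expect_error(generate_trajectory(
    traj_gen_config(n_monomer = 300, box_edge = 40, n_frames = 1, seed = 1)),
    "increase box_edge")
})

test_that("analysis results survive an XYZ round trip unchanged", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 16, n_inhibitor = 3,
                                           n_frames = 3,
                                           hijack_fraction = 0.4,
                                           hbond_plant_rate = 0.4, seed = 15))
  tr <- g$trajectory
  f <- tempfile(fileext = ".xyz")
  write_trajectory(tr, f)
  back <- read_trajectory(f, tr$topology)
  ad1 <- angle_distribution(tr); ad2 <- angle_distribution(back)
  expect_equal(ad1$samples$angle, ad2$samples$angle, tolerance = 1e-4)
  occ1 <- hbond_occupancy(tr); occ2 <- hbond_occupancy(back)
  expect_equal(occ1$occupancy, occ2$occupancy)
  for (fr in 1:3) {
    c1 <- contact_pairs(tr, fr); c2 <- contact_pairs(back, fr)
    expect_identical(paste(c1$i, c1$j), paste(c2$i, c2$j))
  }
})

test_that("hijacking shifts adenine pairs away from stacked alignment", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 16, n_inhibitor = 8,
                                           n_frames = 20,
                                           hijack_fraction = 1,
                                           stack_angle_sigma = 5, seed = 16))
  ad <- angle_distribution(g$trajectory)
  # all monomer pairs are inhibitor-capped with isotropic orientations:
  # mean near 57.3 deg and only the isotropic share below 30 deg
  expect_gt(ad$mean, 45)
  expect_lt(ad$stacked_fraction, 0.3)
})

test_that("planted hydrogen-bond bookkeeping matches the recorded truth", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 10, n_inhibitor = 2,
                                           n_frames = 50,
                                           hijack_fraction = 0.2,
                                           hbond_plant_rate = 0.3, seed = 17))
  planted <- vapply(g$truth$frames, `[[`, TRUE, "planted")
  expect_identical(which(planted), g$truth$planted_frames)
  occ <- hbond_occupancy(g$trajectory)
  expect_equal(occ$occupancy[occ$acceptor_class == "intra_ring_oxygen"],
               mean(planted))
})

test_that("negative inhibition raises treated curves above the control", {
  cfg <- kinetic_gen_config(doses = 2, inhibition_map = -20, noise_sigma = 0,
                            n_replicates = 1)
  gk <- generate_kinetics(cfg)
  ctrl <- gk$curves[gk$curves$compound == "control", ]
  tr <- gk$curves[gk$curves$compound != "control", ]
  expect_equal(percent_inhibition(tr, ctrl), -20, tolerance = 1e-9)
  e_t <- tr$signal[nrow(tr)] - tr$signal[1]
  e_c <- ctrl$signal[nrow(ctrl)] - ctrl$signal[1]
  expect_equal(e_t / e_c, 1.2, tolerance = 1e-9)
})
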
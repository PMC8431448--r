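# Stacking-angle distributions and heterogeneity comparison.

test_that("perfectly aligned stacks give mean 0 and stacked fraction 1", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 10, n_frames = 5,
                                           stack_mean_size = 5,
                                           stack_angle_sigma = 0, seed = 21))
  ad <- angle_distribution(g$trajectory)
  expect_gt(ad$n, 0)
  expect_equal(ad$mean, 0, tolerance = 1e-6)
  expect_equal(ad$stacked_fraction, 1)
})

test_that("the histogram integrates to one and stats match the samples", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 20, n_frames = 10,
                                           stack_angle_sigma = 25, seed = 22))
  ad <- angle_distribution(g$trajectory)
  h <- ad$histogram
  expect_equal(sum(h$density * (h$upper - h$lower)), 1, tolerance = 1e-9)
  expect_equal(ad$mean, mean(ad$samples$angle))
  expect_equal(ad$dispersion, sd(ad$samples$angle))
  expect_equal(ad$stacked_fraction, mean(ad$samples$angle < 30))
  expect_true(all(ad$samples$angle >= 0 & ad$samples$angle <= 90))
})

test_that("measured angles equal the generator's recorded ground truth", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 30, n_frames = 8,
                                           stack_angle_sigma = 20, seed = 23))
  ad <- angle_distribution(g$trajectory)
  truth <- do.call(rbind, lapply(g$truth$frames, `[[`, "angles"))
  expect_identical(ad$n, nrow(truth))
  expect_equal(sort(ad$samples$angle), sort(truth$angle), tolerance = 1e-8)
})

test_that("isotropic random axes have mean pair angle near 57.3 degrees", {
  # E[acos|u.v|] for independent uniform axes is exactly 1 radian
  set.seed(123)
  ang <- replicate(10000, {
    u <- rnorm(3); v <- rnorm(3)
    pair_angle(u, v)
  })
  expect_equal(mean(ang), 180 / pi, tolerance = 0.02)
})

test_that("angle distributions are invariant under a global frame rotation", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 12, n_frames = 2,
                                           stack_angle_sigma = 15, seed = 31))
  tr <- g$trajectory
  ref <- angle_distribution(tr)
  set.seed(32)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
                2 * (q[2] * q[4] - q[1] * q[3]),
                2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                2 * (q[3] * q[4] + q[1] * q[2]),
                2 * (q[2] * q[4] + q[1] * q[3]),
                2 * (q[3] * q[4] - q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
              3, 3)
  cen <- c(50, 50, 50)
  rot <- tr
  for (f in 1:2) {
    moved <- sweep(sweep(tr$coords[[f]], 2, cen) %*% t(R), 2, cen, `+`)
    rot$coords[[f]] <- moved
  }
  got <- angle_distribution(rot)
  expect_equal(sort(got$samples$angle), sort(ref$samples$angle),
               tolerance = 1e-8)
})

test_that("stacked fraction decreases monotonically with angular noise", {
  fr <- vapply(c(0, 10, 25, 45), function(s) {
    g <- generate_trajectory(traj_gen_config(n_monomer = 30, n_frames = 25,
                                             stack_angle_sigma = s,
                                             seed = 41))
    angle_distribution(g$trajectory)$stacked_fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[1], 1)
})

test_that("dispersion differences between noise levels are recovered", {
  ad5 <- angle_distribution(generate_trajectory(
    traj_gen_config(n_monomer = 40, n_frames = 70, stack_angle_sigma = 5,
                    seed = 51))$trajectory)
  ad40 <- angle_distribution(generate_trajectory(
    traj_gen_config(n_monomer = 40, n_frames = 70, stack_angle_sigma = 40,
                    seed = 52))$trajectory)
  expect_gt(ad5$n, 1800)
  expect_gt(ad40$n, 1800)
  # RMS angle estimates the generative sigma of each condition
  expect_equal(ad5$rms_angle, 5, tolerance = 0.2 * 5)
  expect_equal(ad40$rms_angle, 40, tolerance = 0.2 * 40)
  diff_gen <- 40 - 5
  expect_equal(ad40$rms_angle - ad5$rms_angle, diff_gen,
               tolerance = 0.2 * diff_gen)
})

test_that("no contacts yields a flagged empty distribution, not an error", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 5, n_frames = 2,
                                           stack_mean_size = 1, seed = 61))
  ad <- angle_distribution(g$trajectory)
  expect_true(ad$empty)
  expect_identical(ad$n, 0L)
  expect_true(is.na(ad$mean))
})

test_that("unknown species in the pair request is an error", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 4, n_frames = 1,
                                           seed = 62))
  expect_error(angle_distribution(g$trajectory,
                                  species_pair = c("adenine", "nope")),
               "not in topology")
})

test_that("heterogeneity comparison is zero against itself and large for distant samples", {
  g <- generate_trajectory(traj_gen_config(n_monomer = 20, n_frames = 10,
                                           stack_angle_sigma = 15, seed = 71))
  ad <- angle_distribution(g$trajectory)
  self <- heterogeneity_compare(ad, ad)
  expect_equal(self$mean_diff, 0)
  expect_equal(self$dispersion_diff, 0)
  expect_equal(self$ks_statistic, 0)
  # a point mass at 0 vs near-uniform samples: KS approaches 1
  d0 <- smaggr:::.angle_distribution_from_samples(
    data.frame(frame = 1, i = 1, j = 2, angle = rep(0, 500)))
  du <- smaggr:::.angle_distribution_from_samples(
    data.frame(frame = 1, i = 1, j = 2, angle = seq(0.5, 89.5, length.out = 500)))
  cmp <- heterogeneity_compare(d0, du)
  expect_gt(cmp$ks_statistic, 0.95)
  expect_error(heterogeneity_compare(d0, angle_distribution(
    generate_trajectory(traj_gen_config(n_monomer = 4, n_frames = 1,
                                        stack_mean_size = 1,
                                        seed = 3))$trajectory)),
    "non-empty")
})
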
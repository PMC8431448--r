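# Sigmoid fitting, endpoint inhibition and the relative-concentration
# potency statistic.

logistic_curve <- function(times, baseline, amplitude, rate, t_half) {
  kinetic_curve(times, baseline + amplitude / (1 + exp(-rate * (times - t_half))))
}

test_that("a noiseless logistic is recovered to under 1% relative error", {
  cur <- logistic_curve(seq(0, 1500, by = 15), 0, 100, 0.02, 500)
  fit <- fit_sigmoid(cur)
  expect_identical(fit$status, "ok")
  cf <- coef(fit)
  expect_equal(cf[["amplitude"]], 100, tolerance = 0.01)
  expect_equal(cf[["rate"]], 0.02, tolerance = 0.01)
  expect_equal(cf[["t_half"]], 500, tolerance = 0.01)
  expect_lt(abs(cf[["baseline"]]), 1)
  expect_equal(fit$lag_time, 500 - 2 / 0.02, tolerance = 0.02)
  expect_lt(fit$rss, 1e-6)
})

test_that("a flat curve yields amplitude 0 and an undefined lag, flagged", {
  cur <- kinetic_curve(seq(0, 100, by = 10), rep(7, 11))
  fit <- fit_sigmoid(cur)
  expect_identical(fit$status, "flat")
  expect_equal(coef(fit)[["amplitude"]], 0)
  expect_true(is.na(fit$lag_time))
  expect_error(fit_sigmoid(kinetic_curve(1:5, 1:5)), "at least 6")
})

test_that("noisy curves are fit with under 5% median parameter error", {
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    times <- seq(0, 1500, length.out = 100)
    y <- 10 + 100 / (1 + exp(-0.02 * (times - 500))) + rnorm(100, 0, 5)
    cf <- coef(fit_sigmoid(kinetic_curve(times, y)))
    c(abs(cf[["amplitude"]] - 100) / 100, abs(cf[["rate"]] - 0.02) / 0.02,
      abs(cf[["t_half"]] - 500) / 500)
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
  expect_lt(median(errs[3, ]), 0.05)
})

test_that("sigmoid_fit behaves like a standard fitted-model object", {
  cur <- logistic_curve(seq(0, 1500, by = 25), 5, 80, 0.015, 600)
  fit <- fit_sigmoid(cur)
  expect_equal(predict(fit, c(600)), 5 + 40, tolerance = 0.05)
  expect_equal(fitted(fit) + residuals(fit), cur$signal, tolerance = 1e-8)
  s <- summary(fit)
  expect_s3_class(s, "summary.sigmoid_fit")
  expect_output(print(fit), "amplitude")
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sim), c(nrow(cur), 3L))
  # Gompertz variant fits its own generated shape
  gy <- 5 + 80 * exp(-exp(-0.015 * (cur$time - 600)))
  gfit <- fit_sigmoid(kinetic_curve(cur$time, gy), model = "gompertz")
  expect_equal(coef(gfit)[["amplitude"]], 80, tolerance = 0.01)
})

test_that("percent inhibition matches endpoint arithmetic and sign rules", {
  times <- seq(0, 1200, by = 10)
  ctrl <- logistic_curve(times, 0, 100, 0.05, 300)
  expect_equal(percent_inhibition(ctrl, ctrl), 0)
  treated <- kinetic_curve(times, ctrl$signal * 0.25)
  expect_equal(percent_inhibition(treated, ctrl, endpoint = 1000), 75,
               tolerance = 1e-6)
  accel <- kinetic_curve(times, ctrl$signal * 1.2)
  expect_equal(percent_inhibition(accel, ctrl, endpoint = 1000), -20,
               tolerance = 1e-6)
})

test_that("percent inhibition interpolates the endpoint and checks its range", {
  times <- c(0, 400, 800, 1200)
  ctrl <- kinetic_curve(times, c(0, 40, 80, 120))
  treated <- kinetic_curve(times, c(0, 20, 40, 60))
  # both read linearly interpolated values at t = 1000
  expect_equal(percent_inhibition(treated, ctrl, endpoint = 1000), 50)
  short <- kinetic_curve(c(0, 400), c(0, 40))
  expect_error(percent_inhibition(short, short, endpoint = 1000),
               "outside the sampled range")
  flat <- kinetic_curve(times, rep(5, 4))
  expect_error(percent_inhibition(treated, flat), "not positive")
})

test_that("percent inhibition is invariant to rescaling both curves", {
  times <- seq(0, 1200, by = 20)
  ctrl <- logistic_curve(times, 10, 90, 0.03, 400)
  treated <- kinetic_curve(times, 10 + 0.4 * (ctrl$signal - 10))
  ref <- percent_inhibition(treated, ctrl)
  for (s in c(0.1, 3, 42)) {
    got <- percent_inhibition(kinetic_curve(times, treated$signal * s),
                              kinetic_curve(times, ctrl$signal * s),
                              baseline = "first")
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("relative concentration follows its defining arithmetic", {
  expect_equal(as.numeric(relative_concentration(1, 100)), 0.01)
  expect_equal(as.numeric(relative_concentration(5, 25)), 0.2)
  rc <- relative_concentration(2, -20)
  expect_true(is.na(rc))
  expect_true(attr(rc, "non_inhibitor"))
  # linear in concentration; halving inhibition doubles the value
  expect_equal(as.numeric(relative_concentration(4, 25)),
               2 * as.numeric(relative_concentration(2, 25)))
  expect_equal(as.numeric(relative_concentration(2, 12.5)),
               2 * as.numeric(relative_concentration(2, 25)))
})

test_that("noiseless generated kinetics round-trip the inhibition map exactly", {
  cfg <- kinetic_gen_config(doses = c(1, 5, 20),
                            inhibition_map = c(10, 50, -20),
                            noise_sigma = 0, n_replicates = 1)
  gk <- generate_kinetics(cfg)
  ctrl <- gk$curves[gk$curves$compound == "control", ]
  for (k in 1:3) {
    d <- cfg$doses[k]
    tr <- gk$curves[gk$curves$dose == d & gk$curves$compound != "control", ]
    expect_equal(percent_inhibition(tr, ctrl), cfg$inhibition_map[k],
                 tolerance = 1e-9)
  }
})

test_that("generated kinetics are byte-identical under a fixed seed", {
  cfg <- kinetic_gen_config(doses = c(1, 5), inhibition_map = c(20, 60),
                            noise_sigma = 8, n_replicates = 3, seed = 123)
  expect_identical(generate_kinetics(cfg)$curves,
                   generate_kinetics(cfg)$curves)
})

test_that("dose-response tables rank compounds and respect the control", {
  cfg <- kinetic_gen_config(doses = c(2, 4), inhibition_map = c(40, 40),
                            noise_sigma = 0, n_replicates = 2)
  gk <- generate_kinetics(cfg)
  # a second compound with identical curves produces an identical row
  twin <- gk$curves[gk$curves$compound != "control" & gk$curves$dose == 2, ]
  twin$compound <- "twin"
  dr <- dose_response(rbind(gk$curves, twin))
  expect_s3_class(dr, "dose_response")
  expect_equal(dr$table$percent_inhibition, c(40, 40, 40), tolerance = 1e-9)
  expect_equal(dr$matrix["twin", "2"], dr$matrix["inhibitor", "2"])
  expect_error(dose_response(gk$curves, control_label = "missing"),
               "no control")
  # monotone dose -> inhibition gives monotone rescue across doses
  cfg2 <- kinetic_gen_config(doses = c(1, 5, 25),
                             inhibition_map = c(10, 35, 70),
                             noise_sigma = 0, n_replicates = 1)
  dr2 <- dose_response(generate_kinetics(cfg2)$curves)
  expect_true(all(diff(dr2$table$diff_vs_control[order(dr2$table$dose)]) > 0))
  pt <- potency_table(generate_kinetics(cfg2)$curves)
  expect_equal(pt$relative_concentration,
               cfg2$doses / cfg2$inhibition_map, tolerance = 1e-9)
})
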
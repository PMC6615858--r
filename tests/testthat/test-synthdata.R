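test_that("stimulus streams follow the paradigm timing and are seeded", {
  a <- generate_stimulus_stream(stimulus_config("A"), 6, seed = 7)
  expect_equal(nrow(a), 6)
  expect_equal(a$onset_time, c(0, 200, 400, 600, 800, 1000))
  expect_equal(a$sequence_position, 1:6)
  b <- generate_stimulus_stream(stimulus_config("B"), 8, seed = 7)
  expect_equal(diff(b$onset_time), rep(120, 7))
  expect_true(all(b$color_angle %in% ((0:7) * 45)))
  expect_true(all(a$motion_angle %in% ((0:11) * 30)))
  expect_identical(generate_stimulus_stream(stimulus_config("A"), 50, seed = 3),
                   generate_stimulus_stream(stimulus_config("A"), 50, seed = 3))
  expect_error(stimulus_config(n_classes = 10, stim_duration = 100, isi = 20,
                               sequence_length = 8),
               "8 or 12")
})

test_that("class label marginals are uniform over long streams", {
  tr <- generate_stimulus_stream(stimulus_config("B"), 12000, seed = 11)
  for (lab in list(tr$color_angle, tr$motion_angle)) {
    freq <- table(factor(lab, levels = (0:7) * 45)) / length(lab)
    se <- sqrt((1 / 8) * (7 / 8) / length(lab))
    expect_true(all(abs(freq - 1 / 8) < 3 * se))
  }
})

test_that("tuning function peaks at the preferred angle and respects periodicity", {
  expect_equal(tuning_function(30, 30, "unimodal", amplitude = 1.4,
                               baseline = 0.2), 1.6)
  # bimodal (axis) tuning repeats every 180 degrees exactly
  ang <- seq(0, 330, by = 15)
  r <- tuning_function(ang, 45, "bimodal", amplitude = 1, kappa = 3)
  r2 <- tuning_function(ang + 180, 45, "bimodal", amplitude = 1, kappa = 3)
  expect_equal(r, r2)
  # unimodal is 360-periodic
  expect_equal(tuning_function(ang, 10, "unimodal"),
               tuning_function(ang + 360, 10, "unimodal"))
  expect_equal(tuning_function(c(0, 90, 180), 0, "untuned", baseline = 0.3),
               rep(0.3, 3))
  # frozen regression value: kappa = 2, amplitude = 1, baseline = 0 at
  # delta = 180 gives exp(2 * (cos(pi) - 1)) = exp(-4)
  expect_equal(tuning_function(180, 0, "unimodal", amplitude = 1, kappa = 2),
               0.0183156388887342, tolerance = 1e-12)
})

test_that("simulated responses express the tuning and are deterministic", {
  tr <- generate_stimulus_stream(stimulus_config("B"), 32, seed = 2)
  pop <- population_config("X", n_units = 1, tuned_feature = "color",
                           tuning_shape = "untuned", noise_sd = 0)
  ep <- simulate_tuned_responses(tr, pop, seed = 5)
  # untuned + zero noise: identical traces across epochs
  expect_true(all(apply(ep$data[, 1, ], 2, function(col)
    max(col) - min(col)) < 1e-12))
  pop2 <- population_config("X", n_units = 1, tuned_feature = "color",
                            tuning_shape = "unimodal", noise_sd = 0)
  ep2 <- simulate_tuned_responses(tr, pop2, seed = 5)
  pref <- ep2$channels$pref[1]
  peak_by_epoch <- apply(ep2$data[, 1, ], 1, max)
  d <- abs(circ_diff(tr$color_angle, pref))
  expect_gt(min(peak_by_epoch[d == min(d)]),
            max(peak_by_epoch[d > min(d)]) + 1e-9)
  expect_error(simulate_tuned_responses(tr[0, ], pop2), "empty")
  ep3 <- simulate_tuned_responses(tr, pop2, seed = 5)
  expect_identical(ep2$data, ep3$data)
})

test_that("bimodal populations respond identically to opposite directions at zero noise", {
  sc <- stimulus_config("B")
  tr <- generate_stimulus_stream(sc, 64, seed = 9)
  pop <- population_config("X", n_units = 3, tuned_feature = "motion",
                           tuning_shape = "bimodal", noise_sd = 0)
  ep <- simulate_tuned_responses(tr, pop, seed = 4)
  for (ang in c(0, 45, 90, 135)) {
    i <- which(tr$motion_angle == ang)[1]
    j <- which(tr$motion_angle == ang + 180)[1]
    expect_equal(ep$data[i, , ], ep$data[j, , ], tolerance = 1e-12)
  }
})

test_that("sensor mixing is the declared linear forward model", {
  tr <- generate_stimulus_stream(stimulus_config("B"), 12, seed = 2)
  pop <- population_config("S", n_units = 3, signal_class = "SOURCE",
                           tuning_shape = "unimodal", noise_sd = 0.1)
  src <- simulate_tuned_responses(tr, pop, seed = 6)
  sens <- mix_to_sensors(src, diag(3), sensor_noise_sd = 0, seed = 1)
  expect_equal(sens$data, src$data, tolerance = 1e-12)
  expect_true(all(sens$channels$signal_class == "SENSOR"))
  # single active source: every sensor proportional to it with its gain
  gain <- matrix(0, 3, 5)
  gain[2, ] <- c(0.5, -1, 2, 0.1, 3)
  gain[c(1, 3), 1] <- 1e-9   # avoid all-zero rows; negligible leakage
  s2 <- mix_to_sensors(src, gain, sensor_noise_sd = 0, seed = 1)
  for (ch in 1:5)
    expect_equal(s2$data[4, ch, ], gain[2, ch] * src$data[4, 2, ],
                 tolerance = 1e-6)
  # noiseless sensor data has rank <= number of sources
  g3 <- matrix(rnorm(3 * 10), 3, 10)
  s3 <- mix_to_sensors(src, g3, sensor_noise_sd = 0, seed = 1)
  m <- matrix(s3$data[1, , ], 10)
  expect_lte(qr(m)$rank, 3)
  expect_error(mix_to_sensors(src, matrix(1, 4, 5)), "rows")
  expect_error(mix_to_sensors(src, rbind(rep(0, 5), matrix(1, 2, 5))),
               "all-zero")
})

test_that("eye traces encode the luminance offset in their curvature", {
  tz <- generate_eye_traces(seq(46, 64), L_eq = 55, noise_sd = 0, seed = 1)
  est <- equiluminance_from_eyetraces(tz)
  expect_equal(est$L_eq, 55, tolerance = 1e-9)
  # curvature difference flips sign across L_eq
  m <- est$measure
  expect_true(all(m$measure[m$L < 55] < 0) && all(m$measure[m$L > 55] > 0))
  # equal luminance: zero difference between conditions
  t0 <- generate_eye_traces(c(55, 55, 60), L_eq = 55, noise_sd = 0, seed = 2)
  curv <- apply(t0$traces, 1, function(y) mean(trace_curvature(y, t0$dt)))
  i55 <- t0$L == 55
  expect_equal(mean(curv[i55 & t0$condition == 1]),
               mean(curv[i55 & t0$condition == 2]), tolerance = 1e-12)
})
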
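# Shared fixtures, built in code.

# Small tuned recording: one or two population blocks, config B stream.
make_session <- function(n_events = 240, seed = 1, shape = "unimodal",
                         feature = "color", n_units = 8, onset = 80,
                         amplitude = 2, noise_sd = 0.25, area = "V4",
                         config_tag = "B") {
  tr <- generate_stimulus_stream(stimulus_config(config_tag), n_events,
                                 seed = seed)
  pop <- population_config(area, n_units = n_units, tuned_feature = feature,
                           tuning_shape = shape, onset_latency = onset,
                           amplitude = amplitude, noise_sd = noise_sd)
  simulate_tuned_responses(tr, pop, seed = seed + 1000L)
}

# Deterministic row-stochastic tensor from a seeded RNG.
random_confusion <- function(n_time = 5, K = 8, seed = 42) {
  set.seed(seed)
  probs <- array(stats::runif(n_time * K * K), c(n_time, K, K))
  for (t in seq_len(n_time))
    probs[t, , ] <- probs[t, , ] / rowSums(probs[t, , ])
  confusion_tensor(probs, seq(0, by = 10, length.out = n_time),
                   (0:(K - 1)) * (360 / K))
}

# Circulant matrix from a circular kernel f(delta) on the K-grid.
circulant_confusion <- function(f, K = 8) {
  ang <- (0:(K - 1)) * (360 / K)
  m <- outer(ang, ang, function(i, j) f(circ_diff(j, i)))
  m <- m / rowSums(m)
  attr(m, "classes") <- ang
  m
}

# Triangular information timecourse on the standard grid.
ramp_timecourse <- function(rise = c(100, 200), fall = c(200, 400),
                            chance = 0) {
  tt <- decode_time_grid()
  v <- numeric(length(tt))
  up <- tt >= rise[1] & tt <= rise[2]
  v[up] <- (tt[up] - rise[1]) / diff(rise)
  dn <- tt > fall[1] & tt <= fall[2]
  v[dn] <- 1 - (tt[dn] - fall[1]) / diff(fall)
  info_timecourse(v + chance, tt, chance)
}

# Luminance-control fixtures: epochs whose channels carry a color signal
# that is identical across luminance levels, a luminance-linked confound,
# or both. A short time axis keeps the decoding cheap; the accuracy
# window must lie inside it.
make_luminance_session <- function(n_events = 384, seed = 1,
                                   color_amp = 2, confound_amp = 0,
                                   noise_sd = 0.25) {
  tr <- generate_stimulus_stream(stimulus_config("B"), n_events,
                                 seed = seed, luminance_levels = 2)
  time <- seq(0, 200, by = 10)
  n_ch <- 8
  set.seed(seed + 7)
  prefs <- (0:(n_ch - 1)) * 45 + runif(n_ch, -10, 10)
  kern <- response_kernel(time, 40, 120)
  data <- array(0, c(n_events, n_ch, length(time)))
  for (ch in seq_len(n_ch)) {
    g_color <- color_amp *
      tuning_function(tr$color_angle, prefs[ch], "unimodal", 1, 2, 0)
    # the confound adds a level-dependent gain, emulating residual
    # luminance contrast differences between the two stimulus sets
    g_conf <- confound_amp * (tr$luminance_level - 1.5) * (ch / n_ch)
    data[, ch, ] <- outer(g_color + g_conf, kern) +
      matrix(rnorm(n_events * length(time), sd = noise_sd),
             n_events, length(time))
  }
  channels <- data.frame(name = sprintf("CH%02d", 1:n_ch), area = "OCC",
                         signal_class = "SENSOR",
                         stringsAsFactors = FALSE)
  epoched_data(data, time, tr, channels, 100)
}

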
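# Synthetic-data generators: stimulus streams, tuned population responses,
# sensor mixtures and eye traces. Everything is deterministic given a seed;
# seeds are applied through local RNG state so generators never disturb the
# caller's random stream.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Stimulus configuration
#'
#' The two rapid-stream paradigms: configuration A uses 12 uniformly
#' spaced colors and motion directions with 150 ms stimuli and 50 ms
#' inter-stimulus intervals in sequences of 6; configuration B uses 8
#' classes, 100 ms stimuli and 20 ms ISIs in sequences of 8.
#'
#' @param config_tag "A" or "B", or NULL to specify fields directly.
#' @param n_classes Number of circular classes (8 or 12).
#' @param stim_duration Stimulus duration, ms.
#' @param isi Inter-stimulus interval, ms.
#' @param sequence_length Stimuli per sequence, or "continuous".
#' @return A `stimulus_config` list with `class_angles` at
#'   k * (360 / n_classes), k = 0..n_classes - 1.
#' @export
stimulus_config <- function(config_tag = NULL, n_classes = NULL,
                            stim_duration = NULL, isi = NULL,
                            sequence_length = NULL) {
  if (!is.null(config_tag)) {
    config_tag <- match.arg(config_tag, c("A", "B"))
    defaults <- switch(config_tag,
      A = list(n_classes = 12L, stim_duration = 150, isi = 50,
               sequence_length = 6L),
      B = list(n_classes = 8L, stim_duration = 100, isi = 20,
               sequence_length = 8L))
    if (is.null(n_classes)) n_classes <- defaults$n_classes
    if (is.null(stim_duration)) stim_duration <- defaults$stim_duration
    if (is.null(isi)) isi <- defaults$isi
    if (is.null(sequence_length)) sequence_length <- defaults$sequence_length
  } else {
    config_tag <- NA_character_
  }
  if (!n_classes %in% c(8L, 12L))
    stop("n_classes must be 8 or 12")
  stopifnot(stim_duration > 0, isi >= 0)
  structure(list(
    config_tag = config_tag,
    n_classes = as.integer(n_classes),
    stim_duration = stim_duration,
    isi = isi,
    sequence_length = sequence_length,
    class_angles = (seq_len(n_classes) - 1) * (360 / n_classes)
  ), class = "stimulus_config")
}

#' Generate a random stimulus stream
#'
#' Colors and motion directions are drawn independently and uniformly
#' from the configuration's class angles; they change randomly from
#' stimulus to stimulus. Onsets follow `stim_duration + isi` spacing.
#' When `luminance_levels = 2`, each event is additionally assigned a
#' luminance level (1 = standard, 2 = 20%-reduced contrast variant),
#' balanced at random.
#'
#' @param config A `stimulus_config`.
#' @param n_events Number of stimulus events (>= 1).
#' @param seed RNG seed; identical seeds give identical tables.
#' @param session_id Session identifier recorded per row.
#' @param luminance_levels 1 or 2.
#' @return A data frame (TrialTable): `session_id`, `event_index`,
#'   `onset_time` (ms), `sequence_position`, `color_angle`,
#'   `motion_angle`, `luminance_level`, `config_tag`.
#' @export
generate_stimulus_stream <- function(config, n_events, seed = 1,
                                     session_id = "S1",
                                     luminance_levels = 1) {
  stopifnot(inherits(config, "stimulus_config"), n_events >= 1)
  with_seed(seed, {
    k <- config$n_classes
    color <- sample(config$class_angles, n_events, replace = TRUE)
    motion <- sample(config$class_angles, n_events, replace = TRUE)
    lum <- if (luminance_levels == 2)
      sample(rep_len(c(1L, 2L), n_events)) else rep(1L, n_events)
    seq_len_eff <- if (identical(config$sequence_length, "continuous"))
      n_events else config$sequence_length
    pos <- ((seq_len(n_events) - 1) %% seq_len_eff) + 1L
    data.frame(
      session_id = session_id,
      event_index = seq_len(n_events),
      onset_time = (seq_len(n_events) - 1) * (config$stim_duration + config$isi),
      sequence_position = pos,
      color_angle = color,
      motion_angle = motion,
      luminance_level = lum,
      config_tag = config$config_tag,
      stringsAsFactors = FALSE)
  })
}

#' Circular tuning function
#'
#' Unimodal tuning is a von-Mises-shaped bump
#' `baseline + amplitude * exp(kappa * (cos(delta) - 1))` where `delta`
#' is the circular distance between stimulus angle and preferred angle;
#' bimodal (axis) tuning evaluates the same bump on the doubled angle
#' `2 * delta`, making the response 180-degree periodic; untuned channels
#' return the baseline.
#'
#' @param angle Stimulus angle(s), degrees.
#' @param pref Preferred angle, degrees.
#' @param shape "unimodal", "bimodal" or "untuned".
#' @param amplitude Peak response above baseline (>= 0).
#' @param kappa Concentration (> 0); larger values give narrower tuning.
#' @param baseline Baseline response.
#' @return Response in rate units, peaking at `baseline + amplitude`.
#' @export
tuning_function <- function(angle, pref, shape = c("unimodal", "bimodal", "untuned"),
                            amplitude = 1, kappa = 2, baseline = 0) {
  shape <- match.arg(shape)
  stopifnot(amplitude >= 0, kappa > 0)
  if (shape == "untuned")
    return(rep(baseline, length(angle)))
  delta <- circ_diff(angle, pref) * pi / 180
  if (shape == "bimodal") delta <- 2 * delta
  baseline + amplitude * exp(kappa * (cos(delta) - 1))
}

#' Population configuration
#'
#' One block per simulated population (area x signal class): unit count,
#' tuned feature, tuning shape, response amplitude, tuning concentration,
#' response onset latency and temporal kernel width (ms), additive
#' Gaussian noise SD, and baseline.
#'
#' @param area_label Area name (e.g. "V1", "V4", "IT").
#' @param n_units Number of channels in the block.
#' @param signal_class "SUA", "MUA", "LFP", "SENSOR" or "SOURCE".
#' @param tuned_feature "color" or "motion".
#' @param tuning_shape "unimodal", "bimodal" or "untuned".
#' @param amplitude,kappa,baseline Tuning-curve parameters
#'   (see [tuning_function()]).
#' @param onset_latency Response onset, ms after stimulus onset.
#' @param kernel_width Width of the half-sine temporal kernel, ms.
#' @param noise_sd Additive Gaussian noise SD per sample.
#' @param position Coordinate along an occipito-frontal axis (arbitrary
#'   units) shared by the block's units.
#' @return A one-row data frame; rbind blocks to form a population table.
#' @export
population_config <- function(area_label, n_units = 8,
                              signal_class = "SUA",
                              tuned_feature = c("color", "motion"),
                              tuning_shape = c("unimodal", "bimodal", "untuned"),
                              amplitude = 2, kappa = 2,
                              onset_latency = 80, kernel_width = 60,
                              noise_sd = 0.25, baseline = 0.5,
                              position = 0) {
  tuned_feature <- match.arg(tuned_feature)
  tuning_shape <- match.arg(tuning_shape)
  signal_class <- match.arg(signal_class,
                            c("SUA", "MUA", "LFP", "SENSOR", "SOURCE"))
  stopifnot(amplitude >= 0, kappa > 0, noise_sd >= 0, onset_latency >= 0,
            kernel_width > 0, n_units >= 1)
  data.frame(area_label = area_label, n_units = as.integer(n_units),
             signal_class = signal_class, tuned_feature = tuned_feature,
             tuning_shape = tuning_shape, amplitude = amplitude,
             kappa = kappa, onset_latency = onset_latency,
             kernel_width = kernel_width, noise_sd = noise_sd,
             baseline = baseline, position = position,
             stringsAsFactors = FALSE)
}

#' Temporal response kernel
#'
#' Half-sine bump: 0 before `onset`, `sin(pi * (t - onset) / width)` on
#' `[onset, onset + width]`, 0 after. Compactly supported and smooth,
#' with its peak at `onset + width / 2` and half-maximum crossing at
#' `onset + width / 6`.
#'
#' @param t Time points, ms.
#' @param onset Onset latency, ms.
#' @param width Kernel width, ms.
#' @return Kernel values in `[0, 1]`.
#' @export
response_kernel <- function(t, onset, width) {
  k <- sin(pi * (t - onset) / width)
  k[t < onset | t > onset + width] <- 0
  pmax(k, 0)
}

#' Simulate tuned population responses
#'
#' Each epoch's channel trace is
#' `baseline + tuning(label) * kernel(t - onset_latency) + noise`.
#' Preferred angles are spread uniformly over the circle within each
#' population block (with seeded jitter) so the population as a whole
#' covers all classes.
#'
#' @param trials TrialTable from [generate_stimulus_stream()].
#' @param pop Population table (rbind of [population_config()] rows).
#' @param time Time axis in ms (default the 76-point decoding grid).
#' @param seed RNG seed.
#' @param class_angles Class angles used for tuning (defaults to the
#'   unique color angles in `trials`); prefs are jittered around them.
#' @return An [epoched_data()] object, epochs x channels x time.
#' @export
simulate_tuned_responses <- function(trials, pop,
                                     time = decode_time_grid(),
                                     seed = 1, class_angles = NULL) {
  if (nrow(trials) == 0) stop("trial table is empty")
  stopifnot(nrow(pop) >= 1)
  with_seed(seed, {
    n_epochs <- nrow(trials)
    n_time <- length(time)
    n_channels <- sum(pop$n_units)
    data <- array(0, dim = c(n_epochs, n_channels, n_time))
    ch_meta <- vector("list", nrow(pop))
    ch0 <- 0L
    for (b in seq_len(nrow(pop))) {
      blk <- pop[b, ]
      labels <- if (blk$tuned_feature == "color") trials$color_angle
                else trials$motion_angle
      prefs <- (seq_len(blk$n_units) - 1) * (360 / blk$n_units) +
        stats::runif(blk$n_units, -10, 10)
      kern <- response_kernel(time, blk$onset_latency, blk$kernel_width)
      for (u in seq_len(blk$n_units)) {
        gain <- tuning_function(labels, prefs[u], blk$tuning_shape,
                                blk$amplitude, blk$kappa, baseline = 0)
        tr <- blk$baseline + outer(gain, kern)     # epochs x time
        if (blk$noise_sd > 0)
          tr <- tr + matrix(stats::rnorm(n_epochs * n_time, sd = blk$noise_sd),
                            n_epochs, n_time)
        data[, ch0 + u, ] <- tr
      }
      ch_meta[[b]] <- data.frame(
        name = sprintf("%s_%s_%02d", blk$area_label, blk$signal_class,
                       seq_len(blk$n_units)),
        area = blk$area_label, signal_class = blk$signal_class,
        position = blk$position, pref = prefs,
        stringsAsFactors = FALSE)
      ch0 <- ch0 + blk$n_units
    }
    sr <- 1000 / stats::median(diff(time))
    epoched_data(data, time, trials, do.call(rbind, ch_meta), sr)
  })
}

#' Mix source epochs to sensor epochs
#'
#' Linear forward model: each sensor trace is the gain-weighted sum of
#' the source traces plus sensor noise. This is the forward counterpart
#' assumed by the LCMV inverse operator.
#'
#' @param sources An [epoched_data()] of source-level signals.
#' @param gain Sources x channels gain matrix; no all-zero source row.
#' @param sensor_noise_sd Additive Gaussian sensor noise SD.
#' @param seed RNG seed.
#' @return An [epoched_data()] with channels marked `SENSOR`.
#' @export
mix_to_sensors <- function(sources, gain, sensor_noise_sd = 0, seed = 1) {
  stopifnot(inherits(sources, "epoched_data"))
  gain <- as.matrix(gain)
  n_src <- dim(sources$data)[2]
  if (nrow(gain) != n_src)
    stop(sprintf("gain has %d rows but data has %d sources",
                 nrow(gain), n_src))
  if (any(rowSums(abs(gain)) == 0))
    stop("gain has an all-zero source row: every source must project somewhere")
  n_sens <- ncol(gain)
  n_epochs <- dim(sources$data)[1]
  n_time <- dim(sources$data)[3]
  with_seed(seed, {
    out <- array(0, dim = c(n_epochs, n_sens, n_time))
    for (e in seq_len(n_epochs)) {
      src <- matrix(sources$data[e, , ], n_src, n_time)
      out[e, , ] <- crossprod(gain, src)
    }
    if (sensor_noise_sd > 0)
      out <- out + array(stats::rnorm(length(out), sd = sensor_noise_sd),
                         dim = dim(out))
    channels <- data.frame(
      name = sprintf("SENS%03d", seq_len(n_sens)),
      area = "scalp", signal_class = "SENSOR", position = NA_real_,
      stringsAsFactors = FALSE)
    epoched_data(out, sources$time, sources$trials, channels,
                 sources$sampling_rate)
  })
}

#' Generate minimum-motion eye traces
#'
#' Emulates the psychophysical equiluminance readout: vertical eye
#' position whose curvature (second time-derivative) is proportional to
#' the luminance offset of the probe from the true equiluminant level,
#' with opposite sign in condition 2, plus position noise.
#'
#' @param L_values Probe luminance levels (>= 2 distinct values; the
#'   experiment used 19 values centered on the reference gray).
#' @param L_eq True equiluminant level.
#' @param n_trials_per_level Trials per level per condition.
#' @param gain Curvature units per luminance unit.
#' @param noise_sd Position noise SD.
#' @param seed RNG seed.
#' @param duration_ms Stimulus duration (default 500 ms).
#' @param sampling_rate Hz.
#' @return List with `traces` (trials x time vertical position),
#'   `time_s`, `condition` (1 or 2), `L` per trial, `dt`.
#' @export
generate_eye_traces <- function(L_values, L_eq, n_trials_per_level = 4,
                                gain = 50, noise_sd = 0.01, seed = 1,
                                duration_ms = 500, sampling_rate = 100) {
  stopifnot(length(unique(L_values)) >= 2)
  with_seed(seed, {
    dt <- 1 / sampling_rate
    t <- seq(0, duration_ms / 1000, by = dt)
    grid <- expand.grid(L = L_values, condition = c(1L, 2L),
                        rep = seq_len(n_trials_per_level))
    n <- nrow(grid)
    traces <- matrix(0, n, length(t))
    for (i in seq_len(n)) {
      sgn <- if (grid$condition[i] == 1L) 1 else -1
      curv <- sgn * gain * (grid$L[i] - L_eq)
      traces[i, ] <- 0.5 * curv * t^2 +
        if (noise_sd > 0) stats::rnorm(length(t), sd = noise_sd) else 0
    }
    list(traces = traces, time_s = t, condition = grid$condition,
         L = grid$L, dt = dt)
  })
}
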
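# Signal-conditioning chains. All filters are Butterworth designs applied
# forward-reverse (zero phase), so the effective order doubles relative to
# the stated design order. Edges are reflect-padded before filtering to
# suppress transients on short synthetic recordings.

#' Construct a continuous recording
#'
#' @param data Channels x samples numeric matrix.
#' @param sampling_rate Hz (> 0).
#' @param channels Data frame of channel metadata (`name`, `area`,
#'   `signal_class`); defaults are generated if omitted.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, sampling_rate, channels = NULL) {
  data <- as.matrix(data)
  stopifnot(sampling_rate > 0)
  if (is.null(channels))
    channels <- data.frame(name = sprintf("CH%03d", seq_len(nrow(data))),
                           area = NA_character_,
                           signal_class = NA_character_,
                           stringsAsFactors = FALSE)
  stopifnot(nrow(channels) == nrow(data))
  structure(list(data = data, sampling_rate = sampling_rate,
                 channels = channels),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$sampling_rate))
  invisible(x)
}

# Zero-phase (forward-reverse) filtering of one signal with reflect
# padding of `pad` samples at each edge. `flt` is a signal::Arma filter.
filtfilt_padded <- function(x, flt, pad) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(flt, xp)
  y <- rev(signal::filter(flt, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

# Pad length: 3 time constants of the slowest corner frequency.
pad_for <- function(fs, f_low) round(3 * fs / f_low)

# Apply a per-channel filter function to a channels x samples matrix.
apply_rows <- function(m, f) t(apply(m, 1, f))

#' Zero-phase Butterworth band-pass
#'
#' Designs a Butterworth band-pass of the given order and applies it
#' forward-reverse ("2-pass": the effective order doubles, the phase is
#' zero) with reflect padding of three time constants of the low corner.
#'
#' @param x Numeric vector, or channels x samples matrix.
#' @param low,high Corner frequencies, Hz.
#' @param fs Sampling rate, Hz.
#' @param order Design order of the single-pass filter.
#' @return Filtered data, same shape as `x`.
#' @export
butter_bandpass <- function(x, low, high, fs, order = 4) {
  if (high >= fs / 2)
    stop(sprintf("band edge %g Hz at or above Nyquist (%g Hz)", high, fs / 2))
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  pad <- pad_for(fs, low)
  if (is.matrix(x)) apply_rows(x, function(r) filtfilt_padded(r, flt, pad))
  else filtfilt_padded(x, flt, pad)
}

#' Zero-phase Butterworth low-pass
#' @inheritParams butter_bandpass
#' @param cutoff Corner frequency, Hz.
#' @export
butter_lowpass <- function(x, cutoff, fs, order = 4) {
  if (cutoff >= fs / 2)
    stop(sprintf("cutoff %g Hz at or above Nyquist (%g Hz)", cutoff, fs / 2))
  flt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- pad_for(fs, cutoff)
  if (is.matrix(x)) apply_rows(x, function(r) filtfilt_padded(r, flt, pad))
  else filtfilt_padded(x, flt, pad)
}

#' Extract analog multi-unit activity (MUA)
#'
#' Band-pass 500-6000 Hz (2nd-order zero-phase Butterworth),
#' full-wave rectification, low-pass at 250 Hz (same filter family), and
#' resampling to 1 kHz. The rectified signal is nonnegative before the
#' final low-pass, which extracts its envelope.
#'
#' @param broadband A `continuous_recording` sampled above 12 kHz.
#' @return A `continuous_recording` at 1 kHz, signal class MUA.
#' @export
extract_mua <- function(broadband) {
  stopifnot(inherits(broadband, "continuous_recording"))
  fs <- broadband$sampling_rate
  if (fs <= 12000)
    stop("sampling rate too low for the 500-6000 Hz MUA band (need > 12 kHz)")
  bp <- butter_bandpass(broadband$data, 500, 6000, fs, order = 2)
  rect <- abs(bp)
  env <- butter_lowpass(rect, 250, fs, order = 2)
  out <- resample_matrix(env, fs, 1000)
  ch <- broadband$channels
  ch$signal_class <- "MUA"
  continuous_recording(out, 1000, ch)
}

#' Extract bipolar local field potentials (LFP)
#'
#' Low-pass at 500 Hz (zero-phase Butterworth) then re-reference each
#' output channel to a local bipolar pair: output = first minus second
#' channel of the pair.
#'
#' @param broadband A `continuous_recording`.
#' @param pairing Two-column integer matrix; each row gives the channel
#'   pair (a, b) whose difference forms one bipolar output.
#' @param order Design order of the low-pass (default 2).
#' @return A `continuous_recording`, signal class LFP.
#' @export
extract_lfp <- function(broadband, pairing, order = 2) {
  stopifnot(inherits(broadband, "continuous_recording"))
  pairing <- matrix(as.integer(pairing), ncol = 2)
  n_ch <- nrow(broadband$data)
  if (any(pairing < 1 | pairing > n_ch))
    stop("pairing refers to channels outside the recording")
  if (any(pairing[, 1] == pairing[, 2]))
    stop("bipolar pairs must use two distinct channels")
  fs <- broadband$sampling_rate
  lp <- butter_lowpass(broadband$data, min(500, fs / 2 * 0.9), fs, order = order)
  out <- lp[pairing[, 1], , drop = FALSE] - lp[pairing[, 2], , drop = FALSE]
  ch <- data.frame(
    name = sprintf("%s-%s", broadband$channels$name[pairing[, 1]],
                   broadband$channels$name[pairing[, 2]]),
    area = broadband$channels$area[pairing[, 1]],
    signal_class = "LFP", stringsAsFactors = FALSE)
  continuous_recording(out, fs, ch)
}

#' Analysis band-pass (0.1-10 Hz)
#'
#' The common analysis band for all signal types: a 4th-order Butterworth
#' band-pass between 0.1 and 10 Hz applied forward-reverse. Transforms
#' spike trains into approximate instantaneous rate and makes invasive
#' signals comparable with EEG/MEG.
#'
#' @param x A `continuous_recording` or an [epoched_data()] object.
#' @param low,high Band edges, Hz.
#' @return Same type as `x`, filtered.
#' @export
analysis_bandpass <- function(x, low = 0.1, high = 10) {
  if (inherits(x, "continuous_recording")) {
    stopifnot(x$sampling_rate >= 30)
    out <- x
    out$data <- butter_bandpass(x$data, low, high, x$sampling_rate, order = 4)
    return(out)
  }
  if (inherits(x, "epoched_data")) {
    stopifnot(x$sampling_rate >= 30)
    out <- x
    for (e in seq_len(dim(x$data)[1]))
      out$data[e, , ] <- butter_bandpass(
        matrix(x$data[e, , ], dim(x$data)[2], dim(x$data)[3]),
        low, high, x$sampling_rate, order = 4)
    return(out)
  }
  stop("x must be a continuous_recording or epoched_data")
}

# Resample a channels x samples matrix to a new rate by low-pass
# anti-alias filtering at 0.8 * new Nyquist followed by linear
# interpolation onto the new sample grid.
resample_matrix <- function(m, fs, target_rate) {
  if (target_rate > fs) stop("target_rate must not exceed sampling_rate")
  if (target_rate == fs) return(m)
  if (target_rate < fs / 2 * 0.9)  # only filter when actually decimating
    m <- butter_lowpass(m, 0.8 * target_rate / 2, fs, order = 4)
  t_old <- (seq_len(ncol(m)) - 1) / fs
  t_new <- seq(0, t_old[length(t_old)], by = 1 / target_rate)
  t(apply(m, 1, function(r) stats::approx(t_old, r, xout = t_new)$y))
}

#' Resample and re-reference
#'
#' Down-samples to `target_rate` (anti-alias low-pass at the new Nyquist,
#' then interpolation onto the new grid) and optionally applies an
#' average reference, after which the instantaneous mean over channels
#' is zero.
#'
#' @param x A `continuous_recording`.
#' @param target_rate Target sampling rate, Hz (<= current rate).
#' @param reference "average" or "none".
#' @return A `continuous_recording` at `target_rate`.
#' @export
resample_rereference <- function(x, target_rate,
                                 reference = c("average", "none")) {
  stopifnot(inherits(x, "continuous_recording"))
  reference <- match.arg(reference)
  out <- resample_matrix(x$data, x$sampling_rate, target_rate)
  if (reference == "average")
    out <- sweep(out, 2, colMeans(out))
  continuous_recording(out, target_rate, x$channels)
}

#' Epoch a continuous recording around stimulus onsets
#'
#' Cuts windows (default -250..500 ms) around each event onset. The time
#' grid is the recording's own sample grid, aligned so that t = 0 falls
#' on the sample at the onset; at 100 Hz and the default window this
#' yields 76 samples per epoch. Rapid sequences produce overlapping
#' epochs that share samples.
#'
#' @param x A `continuous_recording`.
#' @param events TrialTable with `onset_time` in ms.
#' @param window Two-element window in ms relative to onset.
#' @return An [epoched_data()] object.
#' @export
epoch_recording <- function(x, events, window = c(-250, 500)) {
  stopifnot(inherits(x, "continuous_recording"))
  fs <- x$sampling_rate
  step_ms <- 1000 / fs
  rel <- seq(window[1], window[2], by = step_ms)
  n_samp <- ncol(x$data)
  if (nrow(events) == 0) {
    warning("no events: returning an empty epoch container")
    return(epoched_data(array(0, c(0, nrow(x$data), length(rel))), rel,
                        events, x$channels, fs))
  }
  onset_idx <- round(events$onset_time / step_ms) + 1
  offs <- round(rel / step_ms)
  bad <- which(onset_idx + offs[1] < 1 | onset_idx + offs[length(offs)] > n_samp)
  if (length(bad))
    stop("epoch window exceeds the recording for events: ",
         paste(events$event_index[bad], collapse = ", "))
  data <- array(0, c(nrow(events), nrow(x$data), length(rel)))
  for (e in seq_len(nrow(events)))
    data[e, , ] <- x$data[, onset_idx[e] + offs, drop = FALSE]
  epoched_data(data, rel, events, x$channels, fs)
}
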
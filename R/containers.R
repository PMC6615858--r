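#' Circular difference between angles
#'
#' Maps the difference `a - b` (degrees) onto the half-open interval
#' (-180, 180]. All circular bookkeeping in the package goes through this
#' function so that offsets such as -135 and 225 degrees are identified.
#'
#' @param a,b Angles in degrees.
#' @return Signed circular difference in degrees, in (-180, 180].
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Construct an epoched data container
#'
#' The central data object of the pipeline: a 3-d numeric array of
#' epochs x channels x time together with the time axis (ms relative to
#' stimulus onset), per-epoch trial labels and per-channel metadata.
#'
#' @param data Numeric array, epochs x channels x time.
#' @param time Numeric vector of time points in ms, strictly increasing,
#'   length `dim(data)[3]`.
#' @param trials Data frame with one row per epoch. Typically carries
#'   `color_angle`, `motion_angle`, `sequence_position`, `luminance_level`.
#' @param channels Data frame with one row per channel: `name`, `area`,
#'   `signal_class` (one of SUA, MUA, LFP, SENSOR, SOURCE) and optionally
#'   `position` (coordinate along an occipito-frontal axis).
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `epoched_data`.
#' @export
epoched_data <- function(data, time, trials, channels, sampling_rate) {
  stopifnot(length(dim(data)) == 3)
  if (length(time) != dim(data)[3])
    stop("time axis length does not match third array dimension")
  if (is.unsorted(time, strictly = TRUE))
    stop("time axis must be strictly increasing")
  if (nrow(trials) != dim(data)[1])
    stop("trials table must have one row per epoch")
  if (nrow(channels) != dim(data)[2])
    stop("channel table must have one row per channel")
  structure(
    list(data = data, time = time, trials = trials,
         channels = channels, sampling_rate = sampling_rate),
    class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_data> %d epochs x %d channels x %d time points (%g..%g ms @ %g Hz)\n",
              d[1], d[2], d[3], min(x$time), max(x$time), x$sampling_rate))
  cat("signal classes:", paste(unique(x$channels$signal_class), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an epoched data container
#'
#' @param x An `epoched_data` object.
#' @param epochs,channels Integer or logical indices (default: keep all).
#' @return An `epoched_data` restricted to the requested epochs/channels.
#' @export
subset_epochs <- function(x, epochs = NULL, channels = NULL) {
  stopifnot(inherits(x, "epoched_data"))
  if (is.null(epochs)) epochs <- seq_len(dim(x$data)[1])
  if (is.null(channels)) channels <- seq_len(dim(x$data)[2])
  epoched_data(x$data[epochs, channels, , drop = FALSE], x$time,
               x$trials[epochs, , drop = FALSE],
               x$channels[channels, , drop = FALSE],
               x$sampling_rate)
}

#' Construct a confusion tensor
#'
#' Time-resolved confusion matrices: entry `[t, i, j]` is the mean
#' predicted probability of class `j` over held-out trials whose true
#' class is `i`. Every row of every time slice is a probability vector.
#'
#' @param probs Array, time x K x K, row-stochastic at every time point.
#' @param time Time axis in ms.
#' @param classes Class angles in degrees (length K).
#' @param feature Which stimulus feature was decoded ("color" or "motion").
#' @param check Validate row-stochasticity (default TRUE).
#' @return An object of class `confusion_tensor`.
#' @export
confusion_tensor <- function(probs, time, classes, feature = NA_character_,
                             check = TRUE) {
  stopifnot(length(dim(probs)) == 3, dim(probs)[2] == dim(probs)[3])
  if (dim(probs)[1] != length(time))
    stop("time axis length does not match first dimension")
  if (dim(probs)[2] != length(classes))
    stop("class count does not match matrix dimension")
  if (check) {
    if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
      stop("confusion entries must lie in [0, 1]")
    rs <- apply(probs, c(1, 2), sum)
    if (any(abs(rs - 1) > 1e-6))
      stop("confusion rows must sum to 1 at every time point")
  }
  structure(list(probs = probs, time = time, classes = classes,
                 feature = feature),
            class = "confusion_tensor")
}

#' @export
print.confusion_tensor <- function(x, ...) {
  cat(sprintf("<confusion_tensor> %d time points, %d classes, feature = %s\n",
              length(x$time), length(x$classes), x$feature))
  invisible(x)
}

#' Construct an information timecourse
#'
#' Classifier performance (hit rate: mean of the confusion diagonal) per
#' time point, with its chance level 1/K.
#'
#' @param values Accuracy per time point, in `[0, 1]`.
#' @param time Time axis in ms.
#' @param chance Chance performance (1/K).
#' @param session_id Optional identifier.
#' @return An object of class `info_timecourse`.
#' @export
info_timecourse <- function(values, time, chance, session_id = NA) {
  stopifnot(length(values) == length(time))
  structure(list(values = values, time = time, chance = chance,
                 session_id = session_id),
            class = "info_timecourse")
}

#' @export
print.info_timecourse <- function(x, ...) {
  cat(sprintf("<info_timecourse> %d points, chance %.4g, peak %.4g at %g ms\n",
              length(x$time), x$chance, max(x$values),
              x$time[which.max(x$values)]))
  invisible(x)
}

#' The standard decoding time grid
#'
#' Analysis grid from 250 ms before to 500 ms after stimulus onset in
#' 10 ms steps: 76 time points, with t = 0 included.
#'
#' @param from,to,by Window edges and step, ms.
#' @return Numeric vector of time points in ms.
#' @export
decode_time_grid <- function(from = -250, to = 500, by = 10) {
  seq(from, to, by = by)
}

#' Coerce session timecourses to a sessions x time matrix
#' @param sessions List of `info_timecourse` objects (or a numeric matrix).
#' @return List with `values` (S x T matrix), `time`, `chance`.
#' @keywords internal
sessions_matrix <- function(sessions) {
  if (is.matrix(sessions))
    return(list(values = sessions, time = seq_len(ncol(sessions)), chance = 0))
  stopifnot(length(sessions) >= 1)
  time <- sessions[[1]]$time
  chance <- sessions[[1]]$chance
  vals <- t(vapply(sessions, function(s) {
    stopifnot(length(s$values) == length(time))
    s$values
  }, numeric(length(time))))
  list(values = vals, time = time, chance = chance)
}
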
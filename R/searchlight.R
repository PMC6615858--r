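# LCMV-style spatial filtering and searchlight decoding over synthetic
# source geometries laid out along a single occipito-frontal coordinate.

#' LCMV spatial filters with unit-gain constraint
#'
#' Linearly constrained minimum-variance beamformer: for each source with
#' leadfield column `l` (the source's row of the forward gain matrix),
#' the filter is `w = C^-1 l / (l' C^-1 l)` where `C` is the (regularized)
#' sensor covariance. The unit-gain constraint `w' l = 1` holds exactly.
#'
#' @param gain Sources x channels forward gain matrix.
#' @param sensor_cov Channels x channels sensor covariance, symmetric
#'   positive semi-definite.
#' @param lambda Regularization weight (>= 0): `C + lambda * mean(diag(C)) * I`.
#' @return Sources x channels matrix of spatial filters.
#' @export
lcmv_filters <- function(gain, sensor_cov, lambda = 0.05) {
  gain <- as.matrix(gain)
  C <- as.matrix(sensor_cov)
  stopifnot(ncol(gain) == nrow(C), nrow(C) == ncol(C), lambda >= 0)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("sensor covariance must be symmetric")
  if (lambda > 0)
    C <- C + lambda * mean(diag(C)) * diag(nrow(C))
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular regularized covariance; increase lambda"))
  W <- matrix(0, nrow(gain), ncol(gain))
  for (s in seq_len(nrow(gain))) {
    l <- gain[s, ]
    num <- Cinv %*% l
    W[s, ] <- num / drop(crossprod(l, num))
  }
  W
}

#' Reconstruct source-level epochs from sensor epochs
#'
#' Applies spatial filters (e.g. from [lcmv_filters()]) to every epoch.
#'
#' @param sensors An [epoched_data()] of sensor signals.
#' @param filters Sources x channels filter matrix.
#' @param positions Source coordinates along the occipito-frontal axis.
#' @return An [epoched_data()] with signal class `SOURCE`.
#' @export
apply_spatial_filters <- function(sensors, filters, positions = NULL) {
  stopifnot(inherits(sensors, "epoched_data"))
  filters <- as.matrix(filters)
  if (ncol(filters) != dim(sensors$data)[2])
    stop("filter columns must match sensor count")
  n_src <- nrow(filters)
  n_epochs <- dim(sensors$data)[1]; n_time <- dim(sensors$data)[3]
  out <- array(0, c(n_epochs, n_src, n_time))
  for (e in seq_len(n_epochs))
    out[e, , ] <- filters %*% matrix(sensors$data[e, , ],
                                     dim(sensors$data)[2], n_time)
  if (is.null(positions)) positions <- seq_len(n_src)
  channels <- data.frame(name = sprintf("SRC%03d", seq_len(n_src)),
                         area = "cortex", signal_class = "SOURCE",
                         position = positions, stringsAsFactors = FALSE)
  epoched_data(out, sensors$time, sensors$trials, channels,
               sensors$sampling_rate)
}

#' Searchlight decoding across source space
#'
#' Repeats the cross-validated decoding at each source, using that source
#' and its `group_size - 1` nearest neighbors along the source coordinate
#' as features, mapping information across the (synthetic) cortex.
#'
#' @param source_epochs An [epoched_data()] of source-level signals with
#'   a `position` column in the channel metadata.
#' @param feature "color" or "motion".
#' @param scheme A [cv_scheme()].
#' @param group_size Number of sources per searchlight (default 1).
#' @return List with one element per source: `timecourse`
#'   (an [info_timecourse()]), `confusion`, `position`.
#' @export
searchlight_decode <- function(source_epochs, feature = c("color", "motion"),
                               scheme = cv_scheme(n_folds = 2),
                               group_size = 1) {
  stopifnot(inherits(source_epochs, "epoched_data"))
  feature <- match.arg(feature)
  pos <- source_epochs$channels$position
  n_src <- length(pos)
  if (group_size > n_src)
    stop("group_size exceeds the number of sources")
  lapply(seq_len(n_src), function(s) {
    nb <- order(abs(pos - pos[s]), seq_len(n_src))[seq_len(group_size)]
    ct <- crossvalidated_confusion(
      subset_epochs(source_epochs, channels = sort(nb)), feature, scheme)
    list(timecourse = accuracy_timecourse(ct, session_id = s),
         confusion = ct, position = pos[s])
  })
}
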
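# Control analyses: luminance cross-classification (is color decoding
# driven by residual luminance differences?) and the minimum-motion
# equiluminance estimate from eye-trace curvature.

# Assign color classes to the two half-spaces defined by a split axis.
# The axis is a diameter of the color circle; classes are in half A when
# their circular difference from the axis angle lies in [0, 180), with
# classes exactly on the axis assigned to half A by the lower-angle rule.
half_space_assignment <- function(classes, axis_angle) {
  d <- (classes - axis_angle) %% 360
  in_a <- d < 180
  on_axis <- d == 0 | d == 180
  if (any(on_axis)) {
    ax_classes <- classes[on_axis]
    in_a[on_axis] <- ax_classes == min(ax_classes)
  }
  in_a
}

#' Luminance cross-classification control
#'
#' Decodes color with training and test sets split by luminance level:
#' `within_L1`/`within_L2` train and test on a single level (2-fold CV);
#' `cross_L1L2` trains on level 1 and tests on level 2 (and vice versa
#' for `cross_L2L1`); `half_space_G1G2` splits the color circle into two
#' halves along each possible axis, trains on level-1 stimuli from one
#' half plus level-2 stimuli from the other, tests on the complement,
#' and averages the confusion matrices over all axes before extracting
#' accuracies. A luminance confound alone drives the half-space accuracy
#' below chance; a level-invariant color signal keeps cross-mode
#' accuracy at the within-mode level.
#'
#' @param epoched An [epoched_data()] whose trials carry
#'   `luminance_level` in {1, 2}.
#' @param modes Which schemes to run (default all five).
#' @param scheme A [cv_scheme()] (used for the within modes and
#'   shrinkage/seed).
#' @param window Time window (ms) over which accuracy is averaged.
#' @param n_shuffles Label shuffles for significance (default 100).
#' @return List per mode: `accuracy` (time-averaged hit rate),
#'   `confusion` (time-averaged matrix), `timecourse`, `p_shuffle`.
#' @export
luminance_crossclassification <- function(
    epoched,
    modes = c("within_L1", "within_L2", "cross_L1L2", "cross_L2L1",
              "half_space_G1G2"),
    scheme = cv_scheme(n_folds = 2), window = c(50, 250),
    n_shuffles = 100) {
  stopifnot(inherits(epoched, "epoched_data"))
  lum <- epoched$trials$luminance_level
  labels <- epoched$trials$color_angle
  classes <- sort(unique(labels))
  miss <- which(table(factor(labels, levels = classes),
                      factor(lum, levels = 1:2)) == 0)
  if (length(miss))
    stop("every color class must occur at both luminance levels")
  run_mode <- function(mode, trials_labels) {
    ep <- epoched
    if (mode == "within_L1" || mode == "within_L2") {
      lev <- if (mode == "within_L1") 1L else 2L
      rows <- which(lum == lev)
      fold <- assign_folds(trials_labels[rows], 2, scheme$seed)
      p1 <- confusion_from_split2(ep, rows[fold == 1], rows[fold == 2],
                                  trials_labels, classes, scheme$shrinkage)
      p2 <- confusion_from_split2(ep, rows[fold == 2], rows[fold == 1],
                                  trials_labels, classes, scheme$shrinkage)
      probs <- (p1 + p2) / 2
    } else if (mode == "cross_L1L2" || mode == "cross_L2L1") {
      tr_lev <- if (mode == "cross_L1L2") 1L else 2L
      probs <- confusion_from_split2(ep, which(lum == tr_lev),
                                     which(lum != tr_lev),
                                     trials_labels, classes,
                                     scheme$shrinkage)
    } else if (mode == "half_space_G1G2") {
      axes <- classes[classes < 180]
      acc <- NULL
      for (ax in axes) {
        in_a <- half_space_assignment(classes, ax)
        cls_a <- classes[in_a]
        train <- which((lum == 1 & trials_labels %in% cls_a) |
                         (lum == 2 & !trials_labels %in% cls_a))
        test <- setdiff(seq_along(trials_labels), train)
        p <- confusion_from_split2(ep, train, test, trials_labels,
                                   classes, scheme$shrinkage)
        acc <- if (is.null(acc)) p else acc + p
      }
      probs <- acc / length(axes)
    } else stop("unknown mode: ", mode)
    probs
  }
  sel_t <- which(epoched$time >= window[1] & epoched$time <= window[2])
  out <- list()
  for (mode in modes) {
    probs <- run_mode(mode, labels)
    K <- length(classes)
    tc <- vapply(seq_along(epoched$time),
                 function(t) mean(diag(matrix(probs[t, , ], K, K))),
                 numeric(1))
    obs_acc <- mean(tc[sel_t])
    shuf_acc <- with_seed(scheme$seed + 97L, {
      vapply(seq_len(n_shuffles), function(i) {
        lab_s <- sample(labels)
        ps <- run_mode(mode, lab_s)
        mean(vapply(sel_t, function(t)
          mean(diag(matrix(ps[t, , ], K, K))), numeric(1)))
      }, numeric(1))
    })
    conf_avg <- matrix(0, K, K)
    for (t in sel_t) conf_avg <- conf_avg + matrix(probs[t, , ], K, K)
    conf_avg <- conf_avg / length(sel_t)
    attr(conf_avg, "classes") <- classes
    out[[mode]] <- list(
      accuracy = obs_acc,
      confusion = conf_avg,
      timecourse = info_timecourse(tc, epoched$time, 1 / K),
      p_shuffle = (sum(shuf_acc >= obs_acc) + 1) / (n_shuffles + 1),
      shuffle_accuracies = shuf_acc)
  }
  out
}

# Split-based confusion probabilities with externally supplied labels
# (needed so label shuffles rerun the full analysis identically).
confusion_from_split2 <- function(epoched, train_rows, test_rows,
                                  labels, classes, shrinkage) {
  K <- length(classes)
  y_tr <- factor(labels[train_rows], levels = classes)
  y_te <- factor(labels[test_rows], levels = classes)
  if (any(table(y_tr) == 0))
    stop("a class is missing from the training split")
  n_time <- length(epoched$time)
  probs <- array(0, c(n_time, K, K))
  for (t in seq_len(n_time)) {
    x_all <- epoched$data[, , t]
    if (is.null(dim(x_all))) x_all <- matrix(x_all, ncol = 1)
    model <- fit_lda(x_all[train_rows, , drop = FALSE], y_tr, shrinkage)
    pr <- predict_lda(model, x_all[test_rows, , drop = FALSE])
    for (k in seq_len(K)) {
      sel <- which(y_te == classes[k])
      if (length(sel)) probs[t, k, ] <- colMeans(pr[sel, , drop = FALSE])
    }
  }
  probs
}

#' Second time-derivative (curvature) of a trace
#'
#' Central second-difference scaled by `1/dt^2`; exact for polynomials up
#' to degree 2 (a quadratic `a*t^2` returns `2a` everywhere).
#'
#' @param y Numeric vector (position over time).
#' @param dt Sample interval in seconds.
#' @return Numeric vector of length `length(y) - 2`.
#' @export
trace_curvature <- function(y, dt) {
  n <- length(y)
  if (n < 3) stop("trace too short for a second derivative")
  (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / dt^2
}

#' Equiluminance estimate from minimum-motion eye traces
#'
#' For each probe luminance `L`, the luminance-deviation measure is the
#' difference in mean eye-trace curvature (second derivative of vertical
#' position, averaged over the stimulus period) between the two motion
#' conditions. A linear regression `measure ~ L` locates the level at
#' which the measure crosses zero: the point of perceptual
#' equiluminance.
#'
#' @param traces List from [generate_eye_traces()] (or the same layout:
#'   `traces`, `condition`, `L`, `dt`).
#' @param min_slope Minimum |slope| for a defined crossing.
#' @return List: `L_eq` (estimated equiluminant level), `slope`,
#'   `intercept`, `r_squared`, `measure` (per-L data frame), `defined`.
#' @export
equiluminance_from_eyetraces <- function(traces, min_slope = 1e-12) {
  L_vals <- sort(unique(traces$L))
  if (length(L_vals) < 3)
    stop("need at least 3 distinct probe L values")
  curv <- apply(traces$traces, 1, function(y)
    mean(trace_curvature(y, traces$dt)))
  measure <- vapply(L_vals, function(L) {
    m1 <- mean(curv[traces$L == L & traces$condition == 1])
    m2 <- mean(curv[traces$L == L & traces$condition == 2])
    m1 - m2
  }, numeric(1))
  fit <- stats::lm(measure ~ L_vals)
  a <- stats::coef(fit)[[1]]; b <- stats::coef(fit)[[2]]
  if (abs(b) < min_slope) {
    warning("no crossing: regression slope is (near) zero")
    return(list(L_eq = NA_real_, slope = b, intercept = a,
                r_squared = summary(fit)$r.squared,
                measure = data.frame(L = L_vals, measure = measure),
                defined = FALSE))
  }
  list(L_eq = -a / b, slope = b, intercept = a,
       r_squared = summary(fit)$r.squared,
       measure = data.frame(L = L_vals, measure = measure),
       defined = TRUE)
}
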
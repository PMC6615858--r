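# Population tuning properties: distance-collapsed tuning curves, the
# bimodality index, its group tests, the similarity-versus-bimodality
# regression, and single-channel tuning with preferred-stimulus alignment.

#' Collapse a confusion matrix to a circular tuning curve
#'
#' Averages confusion entries over all cell pairs at the same circular
#' distance between true and predicted class: `probs[d]` is the mean of
#' `M[i, j]` over cells with circular difference `(j - i) = d`. A peak at
#' 0 means stimuli are identified correctly; a second peak at 180 degrees
#' means stimuli are confused with their opposites (axis tuning).
#'
#' @param M K x K matrix with classes on the uniform circular grid (class
#'   angles taken from `attr(M, "classes")` or assumed uniform).
#' @return A `tuning_curve`: `distances` (signed circular offsets,
#'   (-180, 180], sorted) and `probs`.
#' @export
collapse_to_tuning <- function(M) {
  M <- as.matrix(M)
  K <- nrow(M)
  classes <- attr(M, "classes")
  if (is.null(classes)) classes <- (seq_len(K) - 1) * (360 / K)
  d <- circ_diff(matrix(classes, K, K, byrow = TRUE),
                 matrix(classes, K, K))
  offs <- sort(unique(as.vector(d)))
  probs <- vapply(offs, function(o) mean(M[d == o]), numeric(1))
  structure(list(distances = offs, probs = probs), class = "tuning_curve")
}

#' Bimodality index of a tuning curve
#'
#' `(P(180) - mean(P(135), P(-135))) / (max(P) - min(P))`: the elevation
#' of the opposite-stimulus probability over its neighbors, normalized by
#' the curve's range. Positive for a second peak at 180 degrees (axis
#' tuning), zero or negative for unimodal tuning; defined as 0 for a flat
#' curve.
#'
#' @param tc A `tuning_curve` on the 8-class (45-degree) grid, or any
#'   curve containing offsets 180 and +/-135.
#' @return A `bimodality_index` list: `value` and the components
#'   `p_opposite`, `p_next_to_opposite_mean`, `p_max`, `p_min`.
#' @export
bimodality_index <- function(tc) {
  d <- tc$distances; p <- tc$probs
  i180 <- which(d == 180)
  i135 <- which(d %in% c(135, -135))
  if (!length(i180) || length(i135) < 1)
    stop("tuning curve must contain the 180 and +/-135 degree offsets")
  p_opp <- p[i180]
  p_next <- mean(p[i135])
  rng <- max(p) - min(p)
  value <- if (rng > 0) (p_opp - p_next) / rng else 0
  structure(list(value = value, p_opposite = p_opp,
                 p_next_to_opposite_mean = p_next,
                 p_max = max(p), p_min = min(p)),
            class = "bimodality_index")
}

#' Group test for positive bimodality
#'
#' One-sided one-sample t-test of per-session (or per-subject, or
#' per-channel) bimodality indices against 0.
#'
#' @param indices Numeric vector of bimodality indices (>= 3 values).
#' @return List: `p`, `t`, `mean`, `degenerate` (TRUE when the values
#'   have zero variance; then p is 0 or 1 by the sign of the mean).
#' @export
bimodality_group_test <- function(indices) {
  indices <- indices[!is.na(indices)]
  if (length(indices) < 3) stop("need at least 3 bimodality values")
  if (stats::sd(indices) == 0) {
    return(list(p = if (mean(indices) > 0) 0 else 1, t = NA_real_,
                mean = mean(indices), degenerate = TRUE))
  }
  tt <- stats::t.test(indices, mu = 0, alternative = "greater")
  list(p = tt$p.value, t = unname(tt$statistic), mean = mean(indices),
       degenerate = FALSE)
}

#' Regression of representational similarity on bimodality differences
#'
#' For every unordered pair of entities (area x signal-class
#' combinations), regresses the pairwise similarity `r` on the absolute
#' difference of the entities' bimodality indices, quantifying how much
#' of the similarity structure bimodality differences explain.
#'
#' @param similarities Data frame with `entity1`, `entity2`, `r`
#'   (e.g. from [similarity_table()]).
#' @param bimodality Named numeric vector of per-entity bimodality
#'   indices.
#' @return List: `r_squared`, `p`, `slope`, `n_pairs`, `degenerate`.
#' @export
similarity_vs_bimodality_regression <- function(similarities, bimodality) {
  stopifnot(all(c("entity1", "entity2", "r") %in% names(similarities)))
  dbi <- abs(bimodality[similarities$entity1] -
               bimodality[similarities$entity2])
  if (anyNA(dbi)) stop("bimodality value missing for some entity")
  if (nrow(similarities) < 3) stop("need at least 3 entity pairs")
  if (stats::sd(dbi) == 0) {
    warning("all bimodality differences equal: regression degenerate")
    return(list(r_squared = 0, p = NA_real_, slope = NA_real_,
                n_pairs = nrow(similarities), degenerate = TRUE))
  }
  fit <- stats::lm(similarities$r ~ dbi)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p = stats::coef(sm)[2, 4],
       slope = stats::coef(fit)[[2]],
       n_pairs = nrow(similarities), degenerate = FALSE)
}

#' Single-channel tuning curves with preferred-stimulus alignment
#'
#' Computes per-channel mean responses per stimulus class in a response
#' window, keeps channels with one-way ANOVA p < `alpha`, aligns each
#' retained channel's tuning curve so its preferred stimulus (highest
#' response; for LFP-like signals, highest mean squared amplitude) sits
#' at offset 0, averages the aligned curves, and tests the per-channel
#' bimodality indices against 0 (one-sided).
#'
#' @param epoched An [epoched_data()] object.
#' @param feature "color" or "motion".
#' @param response_window Window in ms for the response summary
#'   (default 50-250 ms).
#' @param alpha ANOVA selection threshold (default 0.05).
#' @param power Use mean squared amplitude rather than mean amplitude
#'   (for LFP-like signals); default FALSE.
#' @return List: `curve` (mean aligned `tuning_curve`), `bimodality`
#'   (per selected channel), `group_p`, `selected` (channel indices),
#'   `anova_p` (all channels). When no channel passes selection, `curve`
#'   is NULL and `selected` empty.
#' @export
single_channel_tuning <- function(epoched, feature = c("color", "motion"),
                                  response_window = c(50, 250),
                                  alpha = 0.05, power = FALSE) {
  stopifnot(inherits(epoched, "epoched_data"))
  feature <- match.arg(feature)
  labels <- if (feature == "color") epoched$trials$color_angle
            else epoched$trials$motion_angle
  classes <- sort(unique(labels))
  K <- length(classes)
  win <- which(epoched$time >= response_window[1] &
                 epoched$time <= response_window[2])
  if (!length(win)) stop("response window contains no samples")
  n_ch <- dim(epoched$data)[2]
  resp <- matrix(0, dim(epoched$data)[1], n_ch)
  for (ch in seq_len(n_ch)) {
    seg <- epoched$data[, ch, win, drop = FALSE]
    resp[, ch] <- if (power) rowMeans(seg^2) else rowMeans(seg)
  }
  fl <- factor(labels, levels = classes)
  anova_p <- vapply(seq_len(n_ch), function(ch) {
    stats::anova(stats::lm(resp[, ch] ~ fl))[["Pr(>F)"]][1]
  }, numeric(1))
  selected <- which(anova_p < alpha)
  if (!length(selected))
    return(list(curve = NULL, bimodality = numeric(0), group_p = NA_real_,
                selected = integer(0), anova_p = anova_p))
  step <- 360 / K
  offsets <- sort(unique(circ_diff((seq_len(K) - 1) * step, 0)))
  aligned <- matrix(0, length(selected), K)
  bi <- numeric(length(selected))
  for (i in seq_along(selected)) {
    ch <- selected[i]
    means <- vapply(classes, function(cl) mean(resp[labels == cl, ch]),
                    numeric(1))
    # preferred stimulus: maximum response, ties to the lowest angle
    pref <- classes[which.max(means)]
    off <- circ_diff(classes, pref)
    ord <- match(offsets, off)
    aligned[i, ] <- means[ord]
    bi[i] <- tryCatch(
      bimodality_index(list(distances = offsets, probs = means[ord]))$value,
      error = function(e) NA_real_)
  }
  grp <- if (length(bi) >= 3 && stats::sd(bi) > 0)
    stats::t.test(bi, mu = 0, alternative = "greater")$p.value
  else NA_real_
  list(curve = structure(list(distances = offsets,
                              probs = colMeans(aligned)),
                         class = "tuning_curve"),
       bimodality = bi, group_p = grp, selected = selected,
       anova_p = anova_p)
}
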
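# Group-level inference on information timecourses: cluster-based sign
# permutation, half-maximum latency estimation with inclusion rules,
# bootstrap confidence intervals, permutation contrasts, and the
# latency-versus-position correlation.

# One-sample t statistics per column of an S x T matrix. Sign flips leave
# column sums of squares unchanged, so permuted t values can be derived
# from flipped means alone.
col_tstats <- function(vals) {
  n <- nrow(vals)
  m <- colMeans(vals)
  ss <- colSums(vals^2)
  sd <- sqrt(pmax(ss - n * m^2, 0) / (n - 1))
  se <- sd / sqrt(n)
  t <- m / se
  t[se == 0] <- ifelse(m[se == 0] > 0, Inf, ifelse(m[se == 0] < 0, -Inf, 0))
  t
}

# Contiguous supra-threshold clusters of a t-value vector; returns a list
# of (start index, end index, mass = sum of t over the cluster).
find_clusters <- function(t_vals, t_crit) {
  above <- t_vals > t_crit
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(i)
    list(start = starts[i], end = ends[i],
         mass = sum(t_vals[starts[i]:ends[i]])))
}

max_cluster_mass <- function(t_vals, t_crit) {
  cl <- find_clusters(t_vals, t_crit)
  if (!length(cl)) 0 else max(vapply(cl, `[[`, numeric(1), "mass"))
}

#' Cluster-based sign-permutation test on information timecourses
#'
#' Chance performance is subtracted from each session's timecourse, then
#' temporally contiguous clusters are formed where a one-tailed t-test
#' over sessions is significant at `cluster_alpha`. The null distribution
#' is built by multiplying each session's timecourse with +1 or -1
#' (`n_perm` draws) and recording the strongest cluster mass (sum of
#' t-values) per draw; each observed cluster gets
#' `p = (b + 1) / (n_perm + 1)` where `b` counts null maxima at least as
#' large.
#'
#' @param sessions List of [info_timecourse()] objects (>= 3), or an
#'   S x T matrix of chance-subtracted values.
#' @param cluster_alpha Cluster-forming threshold (default 0.01,
#'   one-tailed).
#' @param n_perm Number of sign-flip permutations (default 10000).
#' @param seed RNG seed.
#' @return A `cluster_test` list: data frame `clusters`
#'   (start_ms, end_ms, mass, p_value), `n_permutations`, `cluster_alpha`.
#' @export
cluster_sign_permutation <- function(sessions, cluster_alpha = 0.01,
                                     n_perm = 10000, seed = 1) {
  sm <- sessions_matrix(sessions)
  vals <- sweep(sm$values, 1, if (is.matrix(sessions)) 0 else sm$chance)
  n <- nrow(vals)
  if (n < 3) stop("need at least 3 sessions for the t-test")
  t_crit <- stats::qt(1 - cluster_alpha, df = n - 1)
  t_obs <- col_tstats(vals)
  obs <- find_clusters(t_obs, t_crit)
  ss <- colSums(vals^2)           # invariant under sign flips
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      m <- colMeans(vals * signs)
      sd <- sqrt(pmax(ss - n * m^2, 0) / (n - 1))
      tp <- m / (sd / sqrt(n))
      tp[!is.finite(tp)] <- 0
      max_cluster_mass(tp, t_crit)
    }, numeric(1))
  })
  clusters <- if (length(obs)) {
    data.frame(
      start_ms = sm$time[vapply(obs, `[[`, numeric(1), "start")],
      end_ms = sm$time[vapply(obs, `[[`, numeric(1), "end")],
      mass = vapply(obs, `[[`, numeric(1), "mass"),
      p_value = vapply(obs, function(cl)
        (sum(null_max >= cl$mass) + 1) / (n_perm + 1), numeric(1)))
  } else {
    data.frame(start_ms = numeric(0), end_ms = numeric(0),
               mass = numeric(0), p_value = numeric(0))
  }
  structure(list(clusters = clusters, n_permutations = n_perm,
                 cluster_alpha = cluster_alpha, t_obs = t_obs,
                 time = sm$time),
            class = "cluster_test")
}

#' Normalize sessions and apply the baseline inclusion rule
#'
#' Each session's timecourse is normalized as
#' `(value - chance) / (post-stimulus max - chance)` so the post-stimulus
#' peak equals 1. A session is included only when its post-stimulus peak
#' (above chance) is at least 1.5 times the largest absolute deviation
#' from chance during the pre-stimulus baseline, so latencies are not
#' dominated by noisy sessions.
#'
#' @param sessions List of [info_timecourse()] objects.
#' @param ratio Inclusion ratio (default 1.5).
#' @return List: `sessions` (normalized [info_timecourse()]s) and
#'   `included` logical mask.
#' @export
normalize_and_select <- function(sessions, ratio = 1.5) {
  stopifnot(length(sessions) >= 1)
  time <- sessions[[1]]$time
  if (!any(time < 0)) stop("time axis has no pre-stimulus baseline samples")
  pre <- time < 0; post <- time >= 0
  norm <- vector("list", length(sessions))
  included <- logical(length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    v <- s$values - s$chance
    peak <- max(v[post])
    base <- max(abs(v[pre]))
    included[i] <- peak > 0 && peak >= ratio * base
    nv <- if (peak > 0) v / peak else v * 0
    norm[[i]] <- info_timecourse(nv, s$time, 0, s$session_id)
  }
  list(sessions = norm, included = included)
}

#' Half-maximum latency of a normalized information timecourse
#'
#' The peak is the first post-stimulus local maximum reaching at least
#' `peak_frac` (75%) of the global post-stimulus maximum; the latency is
#' the first time the curve reaches half that peak, located by linear
#' interpolation between the bracketing samples of the 10 ms grid.
#'
#' @param tc A normalized [info_timecourse()] (chance at 0), or a list
#'   `list(values, time)`.
#' @param peak_frac Fraction of the global maximum a local maximum must
#'   reach to qualify as the peak (default 0.75).
#' @return A `latency_estimate` list: `latency_ms`, `peak_time_ms`,
#'   `peak_value`, `defined`.
#' @export
estimate_latency <- function(tc, peak_frac = 0.75) {
  v <- tc$values; tt <- tc$time
  post <- which(tt >= 0)
  if (!length(post)) stop("no post-stimulus samples")
  vp <- v[post]; tp <- tt[post]
  gmax <- max(vp)
  if (!is.finite(gmax) || gmax <= 0)
    return(structure(list(latency_ms = NA_real_, peak_time_ms = NA_real_,
                          peak_value = NA_real_, defined = FALSE),
                     class = "latency_estimate"))
  np <- length(vp)
  is_locmax <- vapply(seq_len(np), function(i) {
    (i == 1 || vp[i] >= vp[i - 1]) && (i == np || vp[i] >= vp[i + 1])
  }, logical(1))
  cand <- which(is_locmax & vp >= peak_frac * gmax)
  if (!length(cand))
    return(structure(list(latency_ms = NA_real_, peak_time_ms = NA_real_,
                          peak_value = NA_real_, defined = FALSE),
                     class = "latency_estimate"))
  pk <- cand[1]
  half <- vp[pk] / 2
  lat <- NA_real_
  for (i in seq_len(pk)) {
    if (vp[i] >= half) {
      if (i == 1) lat <- tp[1]
      else {
        frac <- (half - vp[i - 1]) / (vp[i] - vp[i - 1])
        lat <- tp[i - 1] + frac * (tp[i] - tp[i - 1])
      }
      break
    }
  }
  structure(list(latency_ms = lat, peak_time_ms = tp[pk],
                 peak_value = vp[pk], defined = TRUE),
            class = "latency_estimate")
}

# Group latency: latency of the session-mean normalized timecourse.
group_latency <- function(norm_sessions, peak_frac = 0.75) {
  sm <- sessions_matrix(norm_sessions)
  estimate_latency(list(values = colMeans(sm$values), time = sm$time),
                   peak_frac)$latency_ms
}

#' Bootstrap confidence interval for the group latency
#'
#' Resamples sessions with replacement, recomputes the group latency
#' (latency of the session-mean normalized timecourse), and reports the
#' 2.5 and 97.5 percentiles.
#'
#' @param norm_sessions List of normalized [info_timecourse()]s (>= 2).
#' @param n_boot Bootstrap draws (default 10000).
#' @param seed RNG seed.
#' @param level Confidence level (default 0.95).
#' @return List: `ci_low_ms`, `ci_high_ms`, `latency_ms` (point
#'   estimate), `n_defined` (draws yielding a defined latency).
#' @export
bootstrap_latency_ci <- function(norm_sessions, n_boot = 10000, seed = 1,
                                 level = 0.95) {
  stopifnot(length(norm_sessions) >= 2)
  sm <- sessions_matrix(norm_sessions)
  point <- group_latency(norm_sessions)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      rows <- sample(nrow(sm$values), replace = TRUE)
      estimate_latency(list(values = colMeans(sm$values[rows, , drop = FALSE]),
                            time = sm$time))$latency_ms
    }, numeric(1))
  })
  ok <- boots[!is.na(boots)]
  a <- (1 - level) / 2
  qs <- stats::quantile(ok, c(a, 1 - a), names = FALSE, type = 7)
  list(ci_low_ms = qs[1], ci_high_ms = qs[2], latency_ms = point,
       n_defined = length(ok))
}

#' Permutation test for a latency difference between two groups
#'
#' The observed difference of group latencies (A minus B) is compared to
#' a null distribution built by reshuffling the group labels over the
#' pooled sessions `n_perm` times and recomputing both group latencies.
#' Two-sided p with the (b+1)/(m+1) convention.
#'
#' @param groupA,groupB Lists of normalized [info_timecourse()]s.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed RNG seed.
#' @return List: `diff_ms`, `p`, `n_effective` (permutations with both
#'   latencies defined).
#' @export
latency_difference_permutation <- function(groupA, groupB, n_perm = 10000,
                                           seed = 1) {
  stopifnot(length(groupA) >= 1, length(groupB) >= 1)
  smA <- sessions_matrix(groupA); smB <- sessions_matrix(groupB)
  latA <- estimate_latency(list(values = colMeans(smA$values), time = smA$time))$latency_ms
  latB <- estimate_latency(list(values = colMeans(smB$values), time = smB$time))$latency_ms
  if (is.na(latA) && is.na(latB)) stop("latency undefined in both groups")
  d_obs <- latA - latB
  pooled <- rbind(smA$values, smB$values)
  nA <- nrow(smA$values); n <- nrow(pooled)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ix <- sample(n)
      a <- estimate_latency(list(values = colMeans(pooled[ix[seq_len(nA)], , drop = FALSE]),
                                 time = smA$time))$latency_ms
      b <- estimate_latency(list(values = colMeans(pooled[ix[-seq_len(nA)], , drop = FALSE]),
                                 time = smA$time))$latency_ms
      a - b
    }, numeric(1))
  })
  ok <- null[!is.na(null)]
  p <- (sum(abs(ok) >= abs(d_obs)) + 1) / (length(ok) + 1)
  list(diff_ms = d_obs, p = p, n_effective = length(ok))
}

#' Correlation between decoding latency and source position
#'
#' Pearson correlation between source coordinates along the
#' occipito-frontal axis and their estimated latencies, restricted to
#' sources flagged significant (e.g. cluster permutation p < 0.05).
#'
#' @param latencies Latency per source, ms (NA allowed; dropped).
#' @param positions Source coordinate per source.
#' @param mask Logical mask of significant sources.
#' @return List: `r`, `p`, `n`.
#' @export
latency_position_correlation <- function(latencies, positions,
                                         mask = rep(TRUE, length(latencies))) {
  stopifnot(length(latencies) == length(positions),
            length(mask) == length(latencies))
  keep <- mask & !is.na(latencies) & !is.na(positions)
  if (sum(keep) < 3) stop("need at least 3 significant sources")
  ct <- stats::cor.test(positions[keep], latencies[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
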
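test_that("cluster sign permutation finds no clusters in chance-level data", {
  tt <- decode_time_grid()
  flat <- lapply(1:8, function(i)
    info_timecourse(rep(0.125, length(tt)), tt, 0.125, i))
  res <- cluster_sign_permutation(flat, n_perm = 200, seed = 1)
  expect_equal(nrow(res$clusters), 0)
})

test_that("a uniform strong effect yields one whole-window cluster at the minimal p", {
  tt <- decode_time_grid()
  sess <- lapply(1:8, function(i)
    info_timecourse(rep(0.125 + 0.2, length(tt)), tt, 0.125, i))
  res <- cluster_sign_permutation(sess, n_perm = 500, seed = 2)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$start_ms, tt[1])
  expect_equal(res$clusters$end_ms, tt[length(tt)])
  # any sign flip kills the constant-effect t-statistic; only all-(+1)
  # draws can match the observed mass, so p is at the permutation floor
  # up to those draws (probability 2^-8 each)
  expect_lte(res$clusters$p_value,
             (qbinom(0.999, 500, 2^-8) + 1) / (500 + 1))
  expect_gte(res$clusters$p_value, 1 / 501)
})

test_that("cluster test controls the family-wise false-positive rate on null data", {
  tt <- decode_time_grid()
  set.seed(7)
  n_datasets <- 200
  hits <- 0
  for (d in seq_len(n_datasets)) {
    vals <- matrix(rnorm(8 * length(tt), 0, 0.02), 8)
    res <- cluster_sign_permutation(vals, n_perm = 500, seed = d)
    if (nrow(res$clusters) && any(res$clusters$p_value < 0.05))
      hits <- hits + 1
  }
  rate <- hits / n_datasets
  expect_lte(rate, 0.075)
  expect_gte(rate, 0.005)
})

test_that("permutation results are seed-deterministic and order-invariant", {
  tt <- decode_time_grid()
  set.seed(11)
  sess <- lapply(1:6, function(i)
    info_timecourse(0.125 + c(rep(0, 25), rep(0.05, 20), rep(0, 31)) +
                      rnorm(length(tt), 0, 0.02), tt, 0.125, i))
  a <- cluster_sign_permutation(sess, n_perm = 300, seed = 5)
  b <- cluster_sign_permutation(sess, n_perm = 300, seed = 5)
  expect_identical(a$clusters, b$clusters)
})

test_that("normalization and the 1.5x baseline rule select sessions as stated", {
  tt <- decode_time_grid()
  mk <- function(base_dev, post_peak) {
    v <- rep(0.125, length(tt))
    v[tt == -100] <- 0.125 + base_dev
    v[tt == 150] <- 0.125 + post_peak
    info_timecourse(v, tt, 0.125)
  }
  # baseline deviation 0.02, post peak 0.05: 0.05 >= 1.5 * 0.02 -> included
  r <- normalize_and_select(list(mk(0.02, 0.05), mk(0.04, 0.05),
                                 mk(0, 0)))
  expect_equal(r$included, c(TRUE, FALSE, FALSE))
  # normalized peak equals 1 for included sessions
  expect_equal(max(r$sessions[[1]]$values), 1)
  flat <- info_timecourse(rep(0.2, 10), seq(10, 100, 10), 0.125)
  expect_error(normalize_and_select(list(flat)), "baseline")
})

test_that("latency estimation follows the half-max and 75%-peak rules exactly", {
  # linear ramp 0 -> 1 between 100 and 200 ms: peak 200, latency 150
  tc <- ramp_timecourse(rise = c(100, 200), fall = c(10000, 10001))
  tc$values[tc$time > 200] <- 1
  est <- estimate_latency(tc)
  expect_equal(est$peak_time_ms, 200)
  expect_equal(est$latency_ms, 150)
  # early bump at 0.6 < 75% of global max 1.0 is skipped
  tt <- decode_time_grid()
  v <- numeric(length(tt))
  v[tt == 80] <- 0.6
  ramp <- tt >= 150 & tt <= 250
  v[ramp] <- (tt[ramp] - 150) / 100
  v[tt > 250] <- 1
  est2 <- estimate_latency(list(values = v, time = tt))
  expect_equal(est2$peak_time_ms, 250)
  # "first time the curve reaches half the peak": the 0 -> 0.6 flank of
  # the skipped bump crosses 0.5 first, between 70 and 80 ms
  expect_equal(est2$latency_ms, 70 + 10 * (0.5 / 0.6), tolerance = 1e-9)
  # early bump at 0.8 >= 75% of the later global max IS the peak
  v3 <- numeric(length(tt))
  v3[tt == 80] <- 0.8
  v3[ramp] <- (tt[ramp] - 150) / 100
  v3[tt > 250] <- 1
  est3 <- estimate_latency(list(values = v3, time = tt))
  expect_equal(est3$peak_time_ms, 80)
  expect_equal(est3$latency_ms, 70 + 10 * (0.4 / 0.8), tolerance = 1e-9)
  # undefined when nothing rises above zero
  est4 <- estimate_latency(list(values = numeric(length(tt)), time = tt))
  expect_false(est4$defined)
})

test_that("latency is equivariant under time shifts", {
  tc <- ramp_timecourse(rise = c(100, 200), fall = c(200, 400))
  base <- estimate_latency(tc)$latency_ms
  for (shift in c(10, 30, 50)) {
    shifted <- info_timecourse(
      c(rep(0, shift / 10), tc$values)[seq_along(tc$values)],
      tc$time, 0)
    expect_equal(estimate_latency(shifted)$latency_ms, base + shift)
  }
})

test_that("bootstrap CI collapses for identical sessions and is deterministic", {
  tc <- ramp_timecourse()
  sess <- replicate(5, tc, simplify = FALSE)
  ci <- bootstrap_latency_ci(sess, n_boot = 200, seed = 3)
  expect_equal(ci$ci_low_ms, ci$ci_high_ms)
  expect_equal(ci$ci_low_ms, estimate_latency(tc)$latency_ms)
  ci2 <- bootstrap_latency_ci(sess, n_boot = 200, seed = 3)
  expect_identical(ci, ci2)
})

test_that("bootstrap CI covers the true latency for noisy sessions", {
  tt <- decode_time_grid()
  true_lat <- 150
  cover <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    set.seed(r + 500)
    sess <- lapply(1:8, function(i) {
      v <- ramp_timecourse()$values + rnorm(length(tt), 0, 0.05)
      info_timecourse(v, tt, 0)
    })
    ci <- bootstrap_latency_ci(sess, n_boot = 100, seed = r)
    if (!is.na(ci$ci_low_ms) && ci$ci_low_ms <= true_lat &&
        ci$ci_high_ms >= true_lat)
      cover <- cover + 1
  }
  expect_gte(cover / n_rep, 0.8)
})

test_that("latency difference permutation test calibrates and detects", {
  tt <- decode_time_grid()
  mk_group <- function(onset, n, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      v <- ramp_timecourse(rise = c(onset, onset + 60),
                           fall = c(onset + 60, onset + 200))$values +
        rnorm(length(tt), 0, 0.02)
      info_timecourse(v, tt, 0)
    })
  }
  # identical groups: p near 1
  gA <- mk_group(100, 6, 1)
  res0 <- latency_difference_permutation(gA, gA, n_perm = 200, seed = 2)
  expect_equal(res0$diff_ms, 0)
  expect_gt(res0$p, 0.5)
  # 40 ms true offset at low noise: detected
  gB <- mk_group(140, 6, 3)
  res1 <- latency_difference_permutation(gA, gB, n_perm = 1000, seed = 4)
  expect_lt(res1$p, 0.01)
  expect_equal(res1$diff_ms, -40, tolerance = 0.2)
  expect_gte(res1$p, 1 / 1001)
})

test_that("latency-position correlation behaves at the extremes", {
  pos <- 1:10
  lat <- 80 + 8 * pos
  r <- latency_position_correlation(lat, pos)
  expect_equal(r$r, 1, tolerance = 1e-12)
  set.seed(9)
  noisy <- lat + rnorm(10, 0, 5)
  r2 <- latency_position_correlation(noisy, pos)
  expect_gt(r2$r, 0.5)
  expect_lt(r2$p, 0.05)
  # mask limits the test to significant sources
  expect_error(latency_position_correlation(lat, pos,
                                            mask = c(TRUE, TRUE, rep(FALSE, 8))),
               "at least 3")
  # shuffled positions: near-zero correlation on average
  rs <- replicate(50, {
    latency_position_correlation(lat, sample(pos))$r
  })
  expect_lt(abs(mean(rs)), 0.15)
})
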
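#!/usr/bin/env Rscript
# Stage 7: source-space searchlight decoding.
#
# Ten synthetic sources on an occipito-frontal coordinate: the six
# occipital-like sources carry color information with onset latencies
# rising from 80 to 130 ms; the four frontal-like sources are silent.
# Source activity is mixed to 24 sensors, reconstructed with unit-gain
# LCMV filters, and decoded in a searchlight over 6 sessions. Per-source
# significance comes from the cluster sign permutation test; the
# latency-position correlation quantifies the feed-forward-like gradient.

suppressPackageStartupMessages(library(mvdecode))
out <- "results/searchlight"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

n_sess <- 6
onsets <- c(80, 90, 100, 110, 120, 130)
pop <- do.call(rbind, c(
  lapply(1:6, function(i)
    population_config(paste0("S", i), n_units = 1, signal_class = "SOURCE",
                      tuned_feature = "color", tuning_shape = "unimodal",
                      onset_latency = onsets[i], position = i)),
  lapply(7:10, function(i)
    population_config(paste0("S", i), n_units = 1, signal_class = "SOURCE",
                      tuning_shape = "untuned", amplitude = 0, position = i))))

tc_per_source <- vector("list", 10)
for (s in 1:n_sess) {
  tr <- generate_stimulus_stream(stimulus_config("B"), 240, seed = 900 + s)
  src <- simulate_tuned_responses(tr, pop, seed = 950 + s)
  set.seed(42)
  gain <- matrix(rnorm(10 * 24), 10, 24)
  sens <- mix_to_sensors(src, gain, sensor_noise_sd = 0.2, seed = 970 + s)
  W <- lcmv_filters(gain, cov(apply(sens$data, 2, as.vector)), lambda = 0.05)
  rec <- apply_spatial_filters(sens, W, positions = pop$position)
  sl <- searchlight_decode(rec, "color", cv_scheme(n_folds = 2, seed = s),
                           group_size = 2)
  for (i in 1:10) tc_per_source[[i]][[s]] <- sl[[i]]$timecourse
}

peaks <- vapply(tc_per_source, function(tcs)
  max(colMeans(mvdecode:::sessions_matrix(tcs)$values)), numeric(1))
sig <- vapply(tc_per_source, function(tcs) {
  ct <- cluster_sign_permutation(tcs, n_perm = 1000, seed = 3)
  nrow(ct$clusters) > 0 && min(ct$clusters$p_value) < 0.05
}, logical(1))
lats <- vapply(tc_per_source, function(tcs) {
  ns <- normalize_and_select(tcs)
  if (!any(ns$included)) return(NA_real_)
  mvdecode:::group_latency(ns$sessions[ns$included])
}, numeric(1))

tab <- data.frame(source = seq_len(10), position = pop$position,
                  true_onset_ms = c(onsets, rep(NA, 4)),
                  peak_hit_rate = peaks, significant = sig,
                  latency_ms = ifelse(sig, lats, NA))
write.csv(tab, file.path(out, "per_source.csv"), row.names = FALSE)
print(tab, digits = 3)

ok <- which(sig & !is.na(lats))
res <- latency_position_correlation(lats[ok], pop$position[ok])
message(sprintf(
  "information peaks at occipital-like coordinates (max tuned %.2f vs max silent %.2f); latency-position r = %.3f, p = %.3g over %d significant sources",
  max(peaks[1:6]), max(peaks[8:10]), res$r, res$p, res$n))
jsonlite::write_json(list(r = res$r, p = res$p, n = res$n),
                     file.path(out, "latency_gradient.json"),
                     auto_unbox = TRUE, digits = 6)
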
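#!/usr/bin/env Rscript
# Stage 1: synthetic study data.
#
# Generates the two rapid-stream paradigms (configuration A: 12 classes,
# 150 ms + 50 ms ISI; configuration B: 8 classes, 100 ms + 20 ms ISI),
# simulates one session of tuned population activity per paradigm, and
# writes the trial tables plus one epochs container under results/.
# Later stages regenerate their inputs deterministically from seeds
# instead of reloading these files, so this stage doubles as a
# round-trip check of the on-disk container.

suppressPackageStartupMessages(library(mvdecode))
seed <- 1
out <- "results/simulate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (tag in c("A", "B")) {
  sc <- stimulus_config(tag)
  trials <- generate_stimulus_stream(sc, 2000, seed = seed,
                                     session_id = paste0("sim_", tag))
  write.csv(trials, file.path(out, sprintf("trials_%s.csv", tag)),
            row.names = FALSE)
  freq <- table(trials$color_angle) / nrow(trials)
  message(sprintf(
    "config %s: %d events, %d classes, onset spacing %d ms, color marginal %.4f-%.4f (uniform %.4f)",
    tag, nrow(trials), sc$n_classes, sc$stim_duration + sc$isi,
    min(freq), max(freq), 1 / sc$n_classes))
}

# one small config-B session through the container round-trip
trials <- generate_stimulus_stream(stimulus_config("B"), 200, seed = seed)
pop <- rbind(
  population_config("V4", tuned_feature = "color", tuning_shape = "unimodal"),
  population_config("MT", tuned_feature = "motion", tuning_shape = "bimodal"))
ep <- simulate_tuned_responses(trials, pop, seed = seed + 1)
write_epochs(ep, file.path(out, "epochs_B"))
back <- read_epochs(file.path(out, "epochs_B"))
stopifnot(isTRUE(all.equal(back$data, ep$data, tolerance = 1e-12)))
message(sprintf("epochs container round-trip OK: %d epochs x %d channels x %d time points",
                dim(back$data)[1], dim(back$data)[2], dim(back$data)[3]))
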
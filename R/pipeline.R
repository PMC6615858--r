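# Configuration, container I/O, orchestration and reporting. Epoched data
# is stored as a plain-text directory container: a JSON metadata file
# (dimensions, time axis, channel table, schema version) plus CSV payloads
# for the signal array and trial labels. The layout mirrors the logical
# schema /data, /time, /labels/*, /channels/*.

EPOCH_SCHEMA_VERSION <- 1L

#' Write an epoched data container
#'
#' Serializes an [epoched_data()] object to a directory: `meta.json`
#' (time axis, dimensions, channel metadata), `data.csv` (the signal
#' array flattened to (epoch x channel) rows by time columns) and
#' `labels.csv` (the trial table). The round-trip through
#' [read_epochs()] is lossless to full double precision.
#'
#' @param x An [epoched_data()] object.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoched_data"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$data)
  meta <- list(schema = "mvdecode-epochs",
               schema_version = EPOCH_SCHEMA_VERSION,
               dims = d, time = x$time, sampling_rate = x$sampling_rate,
               channels = x$channels)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  utils::write.table(format(flat, digits = 17, trim = TRUE),
                     file.path(path, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.csv(x$trials, file.path(path, "labels.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read an epoched data container
#'
#' @param path Directory written by [write_epochs()].
#' @return An [epoched_data()] object.
#' @export
read_epochs <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("schema error: missing meta.json")
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (fld in c("schema", "dims", "time", "sampling_rate", "channels"))
    if (is.null(meta[[fld]]))
      stop("schema error: meta.json is missing field '", fld, "'")
  if (!identical(meta$schema, "mvdecode-epochs"))
    stop("schema error: not an mvdecode epochs container")
  for (f in c("data.csv", "labels.csv"))
    if (!file.exists(file.path(path, f)))
      stop("schema error: missing ", f)
  d <- as.integer(meta$dims)
  flat <- as.matrix(utils::read.table(file.path(path, "data.csv"),
                                      sep = ",", header = FALSE))
  if (!all(dim(flat) == c(d[1] * d[2], d[3])))
    stop("schema error: data payload does not match declared dimensions")
  data <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  trials <- utils::read.csv(file.path(path, "labels.csv"),
                            stringsAsFactors = FALSE)
  channels <- as.data.frame(meta$channels, stringsAsFactors = FALSE)
  epoched_data(data, as.numeric(meta$time), trials, channels,
               meta$sampling_rate)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the synthetic study in one list: stimulus
#' configuration, population blocks, the cross-validation scheme,
#' analysis windows (decoding grid -250..500 ms in 10 ms steps; RSA
#' window 50-250 ms) and permutation counts (cluster 10000, RSA 10000,
#' latency 10000, luminance shuffles 100). `fast_factor` divides all
#' permutation counts (never below 100) without changing any
#' statistical definition.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param fast_factor Integer divisor for permutation counts.
#' @return A nested list, serializable to YAML.
#' @export
default_config <- function(seed = 1, fast_factor = 1) {
  perms <- function(n) max(100L, as.integer(n / fast_factor))
  list(
    seed = seed,
    stimulus = list(config_tag = "B", n_events = 2000),
    populations = list(
      list(area_label = "V4", n_units = 8, signal_class = "SUA",
           tuned_feature = "color", tuning_shape = "unimodal",
           amplitude = 2, kappa = 2, onset_latency = 80,
           kernel_width = 60, noise_sd = 0.25, baseline = 0.5,
           position = 1),
      list(area_label = "MT", n_units = 8, signal_class = "SUA",
           tuned_feature = "motion", tuning_shape = "bimodal",
           amplitude = 2, kappa = 2, onset_latency = 80,
           kernel_width = 60, noise_sd = 0.25, baseline = 0.5,
           position = 2)),
    n_sessions = 8,
    cv = list(n_folds = 10, stratify_by_sequence_position = FALSE,
              oversample = FALSE, shrinkage = 0.1),
    windows = list(decode = c(-250, 500), decode_step = 10,
                   rsa = c(50, 250)),
    permutations = list(cluster = perms(10000), rsa = perms(10000),
                        latency = perms(10000), luminance_shuffles = 100),
    output_dir = "results")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and fills unspecified fields from
#' [default_config()]. Basic schema checks are applied (required keys,
#' windows inside the epoch, explicit seed).
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  if (is.null(cfg$seed)) stop("config must declare a seed")
  w <- cfg$windows
  if (w$rsa[1] < w$decode[1] || w$rsa[2] > w$decode[2])
    stop("RSA window must lie inside the decoding window")
  cfg
}

#' Run the default synthetic pipeline
#'
#' Simulates `n_sessions` sessions of tuned population activity,
#' decodes color and motion per session and population block, and runs
#' the group statistics (cluster sign permutation), RSA (between the
#' blocks' time-averaged confusions) and tuning-bimodality analyses.
#' Every stage is seeded from the master seed; reruns with the same
#' config are identical.
#'
#' @param config Configuration list (see [default_config()]).
#' @return A `pipeline_run` list: per-feature session timecourses,
#'   cluster tests, representation matrices, similarity and bimodality
#'   tables, and a manifest (parameter echo plus seeds).
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  sc <- stimulus_config(cfg$stimulus$config_tag)
  pop <- do.call(rbind, lapply(cfg$populations,
                               function(p) do.call(population_config, p)))
  time <- decode_time_grid(cfg$windows$decode[1], cfg$windows$decode[2],
                           cfg$windows$decode_step)
  scheme <- cv_scheme(cfg$cv$n_folds, cfg$cv$stratify_by_sequence_position,
                      cfg$cv$oversample, cfg$cv$shrinkage, seed = cfg$seed)
  features <- c("color", "motion")
  sess_tc <- list(color = list(), motion = list())
  rep_mats <- list()
  bimod <- list()
  for (s in seq_len(cfg$n_sessions)) {
    sseed <- cfg$seed + 1000L * s
    trials <- generate_stimulus_stream(sc, cfg$stimulus$n_events,
                                       seed = sseed,
                                       session_id = sprintf("S%02d", s))
    ep <- simulate_tuned_responses(trials, pop, time, seed = sseed + 1L)
    for (b in seq_len(nrow(pop))) {
      blk <- pop[b, ]
      ch <- which(ep$channels$area == blk$area_label)
      feat <- blk$tuned_feature
      ct <- crossvalidated_confusion(subset_epochs(ep, channels = ch),
                                     feat, scheme)
      key <- sprintf("%s_%s", blk$area_label, blk$signal_class)
      sess_tc[[feat]][[length(sess_tc[[feat]]) + 1]] <-
        accuracy_timecourse(ct, session_id = sprintf("S%02d", s))
      ravg <- time_average_confusion(ct, cfg$windows$rsa)
      rep_mats[[key]] <- if (is.null(rep_mats[[key]])) ravg / cfg$n_sessions
                         else rep_mats[[key]] + ravg / cfg$n_sessions
      bimod[[key]] <- c(bimod[[key]],
                        bimodality_index(collapse_to_tuning(ravg))$value)
    }
  }
  cluster_tests <- lapply(features, function(f) {
    if (length(sess_tc[[f]]) >= 3)
      cluster_sign_permutation(sess_tc[[f]],
                               n_perm = cfg$permutations$cluster,
                               seed = cfg$seed + 7L)
    else NULL
  })
  names(cluster_tests) <- features
  for (k in names(rep_mats)) attr(rep_mats[[k]], "classes") <- sc$class_angles
  sim_tab <- if (length(rep_mats) >= 2)
    similarity_table(rep_mats, n_perm = cfg$permutations$rsa,
                     seed = cfg$seed + 11L)
  else NULL
  bi_tests <- lapply(bimod, function(v)
    tryCatch(bimodality_group_test(v), error = function(e) NULL))
  structure(list(
    config = cfg,
    timecourses = sess_tc,
    cluster_tests = cluster_tests,
    representations = rep_mats,
    similarity = sim_tab,
    bimodality = bimod,
    bimodality_tests = bi_tests,
    manifest = list(seed = cfg$seed,
                    n_sessions = cfg$n_sessions,
                    n_events = cfg$stimulus$n_events,
                    package_version = as.character(
                      utils::packageVersion("mvdecode")))),
    class = "pipeline_run")
}

#' Machine-readable report of a pipeline run
#'
#' Writes a JSON summary (accuracies, clusters, RSA, bimodality, the
#' full parameter echo) and CSV tables (similarity, bimodality) to a
#' directory. The JSON is schema-stable and sufficient to recreate the
#' cross-scale comparison tables on synthetic data.
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#' @param dir Output directory.
#' @return Path of the JSON report, invisibly.
#' @export
report <- function(run, dir = run$config$output_dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- list(
    parameters = run$config,
    manifest = run$manifest,
    accuracy = lapply(run$timecourses, function(tcs) {
      if (!length(tcs)) return(NULL)
      sm <- sessions_matrix(tcs)
      list(time_ms = sm$time, mean = colMeans(sm$values),
           chance = sm$chance, n_sessions = nrow(sm$values))
    }),
    clusters = lapply(run$cluster_tests, function(ct) {
      if (is.null(ct)) return(NULL)
      list(clusters = ct$clusters, n_permutations = ct$n_permutations,
           cluster_alpha = ct$cluster_alpha)
    }),
    rsa = run$similarity,
    bimodality = lapply(run$bimodality_tests, function(bt) {
      if (is.null(bt)) NULL else bt[c("p", "mean")]
    }))
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns", null = "null")
  if (!is.null(run$similarity))
    utils::write.csv(run$similarity, file.path(dir, "similarity.csv"),
                     row.names = FALSE)
  bi <- data.frame(entity = names(run$bimodality),
                   mean_index = vapply(run$bimodality, mean, numeric(1)))
  utils::write.csv(bi, file.path(dir, "bimodality.csv"), row.names = FALSE)
  invisible(json_path)
}

#' Checksum of a file (for run manifests)
#' @param path File path.
#' @return MD5 digest string.
#' @export
file_checksum <- function(path) unname(tools::md5sum(path))
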
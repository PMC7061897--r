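#' Write a run manifest
#'
#' Every pipeline stage records what ran: the full config with defaults
#' echoed, the seeds, md5 checksums of its inputs, package version, output
#' paths and a timestamp. Re-running a stage with an identical manifest
#' reproduces identical numeric outputs for deterministic stages (and
#' seed-exact outputs for stochastic ones).
#'
#' @param path manifest output path (JSON).
#' @param stage stage name.
#' @param config config list (defaults already filled in).
#' @param inputs character vector of input file paths (checksummed).
#' @param outputs character vector of output file paths.
#' @param seed the seed(s) in effect.
#' @return `path` invisibly.
#' @export
write_run_manifest <- function(path, stage, config, inputs = character(0),
                               outputs = character(0), seed = NULL) {
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("eegfactors")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed,
              config = config,
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = as.list(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

read_dataset_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dat$", full.names = TRUE))
  recs <- lapply(files, read_recording)
  labels <- read_labels(file.path(dir, "labels.tsv"))
  list(recordings = recs, labels = labels, files = files)
}

#' Pipeline stages
#'
#' Programmatic entry points behind the `eegfactors` command-line script;
#' each writes its artifact plus a run manifest next to it.
#' `pipeline_simulate` generates a synthetic labeled dataset;
#' `pipeline_decode` fits a decoder on the pooled dataset and writes the
#' model checkpoint plus all factor sequences; `pipeline_reconstruct_eval`
#' scores reconstruction per channel; `pipeline_loso` runs the full
#' leave-one-subject-out classification pipeline and writes the
#' per-subject F1 table.
#'
#' @param config named list of stage parameters (unset fields take the
#'   defaults of the underlying functions).
#' @param out_dir artifact output directory.
#' @return The stage's main artifact, invisibly (also written to disk).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config = list(), out_dir) {
  cfg <- do.call(synthetic_config, config)
  ds <- make_labeled_dataset(cfg)
  write_dataset(ds, out_dir)
  write_run_manifest(file.path(out_dir, "manifest_run.json"), "simulate",
                     unclass(cfg), outputs = list.files(out_dir),
                     seed = cfg$master_seed)
  invisible(ds)
}

#' @rdname pipeline
#' @param dataset_dir directory written by `pipeline_simulate` (or in the
#'   same layout).
#' @param decoder decoder kind (`ae`, `grbm`, `vae`, `ica`, `pca`).
#' @param m latent factor count (`m > n` is allowed for the nonlinear
#'   decoders with a warning; the run proceeds).
#' @param seed fit seed.
#' @export
pipeline_decode <- function(dataset_dir, decoder = "vae", m = 3,
                            config = list(), seed = 1, out_dir) {
  ds <- read_dataset_dir(dataset_dir)
  recs <- zscore_by_subject(ds$recordings)
  pooled <- do.call(rbind, lapply(recs, function(r) t(r$data)))
  model <- fit_decoder(decoder, pooled, m, seed, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ckpt <- file.path(out_dir, sprintf("model_%s_m%d.rds", decoder, m))
  saveRDS(list(model = model, decoder = decoder, m = m, seed = seed,
               config = config,
               data_checksum = unname(tools::md5sum(ds$files[1]))), ckpt)
  for (r in recs) {
    fs <- encode(model, r)
    write_factors(fs, file.path(out_dir, sprintf("factors_%s_%s.dat",
                                                 r$subject_id, r$trial_id)))
  }
  write_run_manifest(file.path(out_dir, "manifest_run.json"), "decode",
                     list(decoder = decoder, m = m, config = config),
                     inputs = ds$files, outputs = list.files(out_dir),
                     seed = seed)
  invisible(model)
}

#' @rdname pipeline
#' @param out_path output JSON path.
#' @export
pipeline_reconstruct_eval <- function(dataset_dir, decoder = "vae", m = 3,
                                      config = list(), seed = 1, out_path) {
  ds <- read_dataset_dir(dataset_dir)
  recs <- zscore_by_subject(ds$recordings)
  pooled <- do.call(rbind, lapply(recs, function(r) t(r$data)))
  model <- fit_decoder(decoder, pooled, m, seed, config)
  rep <- reconstruction_report(model, recs)
  out <- list(model_id = rep$model_id, m = rep$m, mean_r = rep$mean_r,
              channels = as.list(rep$channels),
              per_subject = as.list(rep$per_subject))
  jsonlite::write_json(out, out_path, auto_unbox = TRUE, digits = NA)
  write_run_manifest(paste0(out_path, ".manifest.json"), "reconstruct-eval",
                     list(decoder = decoder, m = m, config = config),
                     inputs = ds$files, outputs = out_path, seed = seed)
  invisible(rep)
}

#' @rdname pipeline
#' @param step_seconds sequence sampling step.
#' @param lstm_args list of [lstm_config()] overrides.
#' @export
pipeline_loso <- function(dataset_dir, decoder = "vae", m = 3,
                          config = list(), step_seconds = 0.25,
                          lstm_args = list(), seed = 1, out_path) {
  ds <- read_dataset_dir(dataset_dir)
  cv <- loso_cv(list(recordings = ds$recordings, labels = ds$labels),
                decoder = decoder, m = m, decoder_args = config,
                step_seconds = step_seconds,
                lstm = do.call(lstm_config, lstm_args), seed = seed)
  out <- list(decoder = decoder, m = m, per_subject = as.list(cv$per_subject),
              mean_f1 = cv$mean_f1, skipped = cv$skipped)
  jsonlite::write_json(out, out_path, auto_unbox = TRUE, digits = NA)
  write_run_manifest(paste0(out_path, ".manifest.json"), "loso",
                     list(decoder = decoder, m = m, config = config,
                          step_seconds = step_seconds, lstm = lstm_args),
                     inputs = ds$files, outputs = out_path, seed = seed)
  invisible(cv)
}

#' @rdname pipeline
#' @export
pipeline_features <- function(dataset_dir, out_path, config = list()) {
  ds <- read_dataset_dir(dataset_dir)
  reg <- if (all(c(default_pair_registry()$left, default_pair_registry()$right)
                 %in% ds$recordings[[1]]$channel_labels))
    default_pair_registry() else NULL
  rows <- lapply(ds$recordings, function(r)
    do.call(feature_vector, c(list(r), config, list(registry = reg))))
  tab <- do.call(rbind, rows)
  ids <- t(vapply(ds$recordings,
                  function(r) c(r$subject_id, r$trial_id), character(2)))
  out <- data.frame(subject_id = ids[, 1], trial_id = ids[, 2], tab,
                    check.names = FALSE)
  utils::write.table(out, out_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_run_manifest(paste0(out_path, ".manifest.json"), "features",
                     config, inputs = ds$files, outputs = out_path)
  invisible(out)
}
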
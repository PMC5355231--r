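#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the synthetic-data spec (or
#' paths to a prepared training set and library), model and training
#' configuration, prior sampling parameters, and the screening settings.
#' A single global seed fans out deterministically to per-stage seeds
#' (stage-name hashing), so stages can be re-run in isolation and two runs
#' with the same config produce byte-identical outputs.
#'
#' @param out_dir run directory (created; receives config, model
#'   checkpoint, training log, profiles, hits, unique hits, and a summary).
#' @param synthetic a [synthetic_spec()] used to simulate the training set
#'   and library, or `NULL` when `training_set_dir`/`library_path` point at
#'   prepared inputs.
#' @param training_set_dir,library_path prepared inputs (used when
#'   `synthetic` is `NULL`); screening requires a library.
#' @param n_library library size when simulating.
#' @param model_config a [aae_config()]; its seed is overridden by the
#'   fanned-out stage seed.
#' @param train_cfg a [train_config()]; seed overridden likewise.
#' @param n_samples,gi_mean,gi_sd prior sampling parameters.
#' @param lconc_threshold strict LCONC cutoff on decoded profiles.
#' @param k,chunk_size screening parameters.
#' @param seed global seed.
#' @return a `molaae_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = synthetic_spec(),
                            training_set_dir = NULL, library_path = NULL,
                            n_library = 5000L,
                            model_config = aae_config(),
                            train_cfg = train_config(),
                            n_samples = 640L, gi_mean = 5, gi_sd = 1,
                            lconc_threshold = -5.0, k = 10L,
                            chunk_size = 1000L, seed = 1L) {
  if (is.null(synthetic) && is.null(training_set_dir))
    stop("either a synthetic spec or a training_set_dir is required", call. = FALSE)
  if (is.null(synthetic) && is.null(library_path))
    stop("screening requires a library: provide library_path or a synthetic spec",
         call. = FALSE)
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 training_set_dir = training_set_dir, library_path = library_path,
                 n_library = as.integer(n_library), model_config = model_config,
                 train_cfg = train_cfg, n_samples = as.integer(n_samples),
                 gi_mean = gi_mean, gi_sd = gi_sd,
                 lconc_threshold = lconc_threshold, k = as.integer(k),
                 chunk_size = as.integer(chunk_size), seed = as.integer(seed)),
            class = "molaae_pipeline_config")
}

#' Deterministic per-stage seed from the global seed
#'
#' Hashes the stage name (a polynomial byte hash) together with the global
#' seed, modulo 2^31 - 1, so each stage gets its own reproducible stream
#' and different global seeds never share one. All intermediates stay
#' below 2^53, so the arithmetic is exact in doubles.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed in [0, 2^31 - 1).
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (byte in utf8ToInt(stage)) h <- (h * 31 + byte) %% 2147483647
  as.integer(((h * 69069) %% 2147483647 + (seed %% 2147483647)) %% 2147483647)
}

#' Run the full pipeline: simulate, train, generate, screen
#'
#' Validates the configuration up front, then runs the four stages,
#' persisting every artifact (and the effective config + seed) in
#' `out_dir`: `config.json`, `training_set/`, `library.tsv`, `model.rds`,
#' `train_log.tsv`, `profiles.tsv` (all generated), `profiles_kept.tsv`
#' (LCONC-filtered), `hits.tsv`, `unique_hits.tsv`, `summary.json`.
#' Warnings that matter scientifically (empty filter result, rejected
#' records) surface in the summary.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the trained model, training log,
#'   profiles, kept profiles, hits, unique hits, and the summary list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "molaae_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  cfg_json <- unclass(config)
  cfg_json$model_config <- unclass(config$model_config)
  cfg_json$train_cfg <- unclass(config$train_cfg)
  cfg_json$synthetic <- if (is.null(config$synthetic)) NULL else unclass(config$synthetic)
  jsonlite::write_json(cfg_json, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  # -- data stage ------------------------------------------------------
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    spec$seed <- stage_seed(config$seed, "simulate")
    say("simulating training set (", spec$n_compounds, " compounds) and library (",
        config$n_library, " compounds)")
    sim <- generate_synthetic(spec)
    ts <- sim$training_set
    lib <- synthetic_library(config$n_library, spec, sim$truth,
                             seed = stage_seed(config$seed, "library"))
    library_path <- file.path(config$out_dir, "library.tsv")
    write_fingerprint_matrix(lib, library_path)
    save_training_set(ts, file.path(config$out_dir, "training_set"))
  } else {
    ts <- load_training_set(config$training_set_dir)
    library_path <- config$library_path
    if (!file.exists(library_path))
      stop("library not found: ", library_path, call. = FALSE)
  }

  # -- training stage --------------------------------------------------
  mc <- config$model_config
  mc$seed <- stage_seed(config$seed, "init")
  tc <- config$train_cfg
  tc$seed <- stage_seed(config$seed, "train")
  say("training: ", tc$epochs, " epoch(s), batch ", tc$batch_size)
  fitres <- fit_aae(ts, mc, tc)
  save_aae(fitres$model, file.path(config$out_dir, "model.rds"))
  data.table::fwrite(fitres$log, file.path(config$out_dir, "train_log.tsv"), sep = "\t")

  # -- generation stage ------------------------------------------------
  codes <- sample_prior(prior_spec(config$n_samples, config$gi_mean, config$gi_sd,
                                   seed = stage_seed(config$seed, "generate")))
  profiles <- generate_profiles(fitres$model, codes)
  write_profiles(profiles, file.path(config$out_dir, "profiles.tsv"))
  kept <- withCallingHandlers(
    filter_by_lconc(profiles, config$lconc_threshold),
    warning = function(w) invokeRestart("muffleWarning"))
  say(length(kept$index), " of ", config$n_samples, " profiles pass LCONC < ",
      config$lconc_threshold)
  write_profiles(kept, file.path(config$out_dir, "profiles_kept.tsv"))

  # -- screening stage -------------------------------------------------
  hits <- NULL
  unique_hits <- collect_unique_hits(NULL)
  if (length(kept$index) > 0L) {
    # screen from the persisted filtered profiles so screening sees the
    # same 6-decimal precision a standalone `screen` invocation would
    kept_disk <- read_profiles(file.path(config$out_dir, "profiles_kept.tsv"))
    hits <- screen_library(kept_disk, library_path, k = config$k,
                           chunk_size = config$chunk_size)
    unique_hits <- collect_unique_hits(hits)
    say(nrow(unique_hits), " unique compounds across ",
        length(kept$index) * config$k, " hits")
  } else {
    say("screening skipped: no profile passed the LCONC filter")
  }
  hits_out <- if (is.null(hits))
    data.frame(profile_index = integer(0), rank = integer(0),
               compound_id = character(0), log_likelihood = numeric(0)) else hits
  data.table::fwrite(hits_out, file.path(config$out_dir, "hits.tsv"), sep = "\t")
  data.table::fwrite(unique_hits, file.path(config$out_dir, "unique_hits.tsv"), sep = "\t")

  summary <- list(seed = config$seed,
                  n_records = ts$counts$n_records,
                  n_compounds = ts$counts$n_compounds,
                  final_losses = if (nrow(fitres$log) > 0L)
                    as.list(fitres$log[nrow(fitres$log), -1L]) else NULL,
                  n_sampled = config$n_samples,
                  n_kept = length(kept$index),
                  lconc_threshold = config$lconc_threshold,
                  n_hits = nrow(hits_out),
                  n_unique_hits = nrow(unique_hits))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(model = fitres$model, log = fitres$log, profiles = profiles,
                 kept = kept, hits = hits_out, unique_hits = unique_hits,
                 summary = summary))
}
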
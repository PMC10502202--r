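#' Configuration for the perception-production simulation
#'
#' Defines the full simulation grid: three sensitivity regimes crossed with
#' cumulative learning trials, each learned model generating a corpus of
#' compositions that are compared with the training piece symbolically
#' (bigram distributions, Jensen-Shannon divergence) and acoustically
#' (AM band power).
#'
#' The default training input is a synthetic children's-song-like fixture
#' melody (40 notes, 8 pitches, a 4-note motif planted 5 times); any
#' monophonic MIDI file may be supplied instead via `training_midi`.
#' Tokens are (pitch, duration) pairs by default so that rhythm is part of
#' the generative alphabet and the rendered compositions carry
#' model-dependent rhythm.
#'
#' @param training_midi optional path to a MIDI file used as training data
#'   (overrides `fixture`)
#' @param fixture named list of [make_fixture_melody()] arguments
#' @param scheme tokenization scheme (see [tokenize()])
#' @param sensitivity_factors named vector of concentration scalings
#' @param max_trials number of cumulative learning repetitions
#' @param pieces_per_model compositions generated per (regime, trial) model
#' @param chunk_c chunking threshold (see [extract_chunks()])
#' @param order Markov order
#' @param base_concentration symmetric Dirichlet base concentration
#' @param sensitivity_mode `"prior"` or `"increment"` (see [dm_model()])
#' @param estimator sampling estimator for generation
#' @param generation_length length of generated pieces; `NULL` = training
#'   piece length
#' @param seed root seed; all generation substreams derive from it
#' @param audio list: `sample_rate`, `tempo_bpm`, `timbre`, `clip_seconds`
#' @param pad list: `band_rates`, `modulator_timescale`
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(training_midi = NULL,
                              fixture = list(n_notes = 40, alphabet_size = 8,
                                             motif_length = 4,
                                             motif_repeats = 5, seed = 1),
                              scheme = "pitch_duration",
                              sensitivity_factors = c(hypo = 0.25, normal = 1,
                                                      hyper = 4),
                              max_trials = 5, pieces_per_model = 100,
                              chunk_c = 5, order = 1L,
                              base_concentration = 1,
                              sensitivity_mode = "prior",
                              estimator = "posterior_mean",
                              generation_length = NULL, seed = 1,
                              audio = list(sample_rate = 16000,
                                           tempo_bpm = 120,
                                           timbre = "harmonic",
                                           clip_seconds = 10),
                              pad = list(band_rates = c(8, 4, 2, 1, 0.5),
                                         modulator_timescale = 0.1)) {
  if (any(sensitivity_factors <= 0)) stop("sensitivity factors must be positive")
  if (max_trials < 1) stop("max_trials must be >= 1")
  if (pieces_per_model < 1) stop("pieces_per_model must be >= 1")
  structure(list(training_midi = training_midi, fixture = fixture,
                 scheme = scheme, sensitivity_factors = sensitivity_factors,
                 max_trials = as.integer(max_trials),
                 pieces_per_model = as.integer(pieces_per_model),
                 chunk_c = chunk_c, order = as.integer(order),
                 base_concentration = base_concentration,
                 sensitivity_mode = sensitivity_mode, estimator = estimator,
                 generation_length = generation_length, seed = seed,
                 audio = audio, pad = pad),
            class = "experiment_config")
}

#' The (regime, trial) grid of an experiment
#' @param config an [experiment_config()]
#' @return data frame with one row per model of the grid
#' @export
model_grid <- function(config) {
  expand.grid(regime = names(config$sensitivity_factors),
              trial = seq_len(config$max_trials),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

training_sequence <- function(config) {
  if (!is.null(config$training_midi)) read_midi(config$training_midi)
  else do.call(make_fixture_melody, config$fixture)
}

#' Run the full perception-production simulation
#'
#' For each sensitivity regime the training piece is learned cumulatively,
#' trial by trial; after each trial the model is snapshotted and used to
#' (i) record the trial's total Bayesian surprise, (ii) extract chunks and
#' build the two-level hierarchy, (iii) generate a corpus of compositions,
#' (iv) compare the corpus-average bigram distribution with the training
#' piece by Jensen-Shannon divergence, and — when `audio = TRUE` — (v)
#' render the compositions and average their AM-cascade band powers.
#' Fully reproducible from the config seed.
#'
#' @param config an [experiment_config()]
#' @param audio run the audio/PAD stage (the slowest stage)
#' @param verbose print progress lines
#' @return an `hbsl_experiment`: list with `results` (one row per (regime,
#'   trial): total_surprise, n_chunks, js_distance and band-power columns),
#'   `training` (token sequence), `models` (final hierarchical model per
#'   regime), `config`.
#' @export
run_experiment <- function(config = experiment_config(), audio = TRUE,
                           verbose = FALSE) {
  train <- training_sequence(config)
  ts <- tokenize(train, config$scheme)
  K <- alphabet_size(ts)
  train_bi <- bigram_distribution(ts$tokens)
  gen_len <- if (is.null(config$generation_length)) length(ts$tokens)
             else config$generation_length
  pparams <- pad_params(modulator_timescale = config$pad$modulator_timescale)
  rows <- list()
  models <- list()
  regimes <- names(config$sensitivity_factors)
  for (ri in seq_along(regimes)) {
    regime <- regimes[ri]
    model <- dm_model(K, order = config$order,
                      sensitivity_factor = config$sensitivity_factors[[ri]],
                      base_concentration = config$base_concentration,
                      sensitivity_mode = config$sensitivity_mode)
    for (trial in seq_len(config$max_trials)) {
      step <- tryCatch({
        out <- learn_sequence(model, ts$tokens, trial_index = trial)
        model <- out$model
        chunks <- extract_chunks(model, ts$tokens, c = config$chunk_c)
        hier <- build_hierarchy(ts$tokens, chunks, model, n_passes = trial)
        sub_seed <- config$seed + 7919L * ri + 104729L * trial
        corpus <- generate_corpus(hier$hmodel, config$pieces_per_model,
                                  gen_len, seed = sub_seed,
                                  estimator = config$estimator)
        avg_bi <- average_bigram_distribution(corpus)
        row <- data.frame(regime = regime, trial = trial,
                          total_surprise = total_surprise(out$trace),
                          n_chunks = length(chunks),
                          js_distance = js_divergence(avg_bi, train_bi))
        if (audio) {
          bp <- corpus_band_power(lapply(corpus$pieces, function(p) {
            w <- render_waveform(
              detokenize(p, ts, tempo_bpm = config$audio$tempo_bpm),
              sample_rate = config$audio$sample_rate,
              tempo_bpm = config$audio$tempo_bpm,
              timbre = config$audio$timbre)
            nmax <- config$audio$clip_seconds * config$audio$sample_rate
            if (length(w$samples) > nmax)
              w <- waveform(w$samples[seq_len(nmax)], w$sample_rate)
            zscore_normalize(w)
          }), band_rates = config$pad$band_rates, params = pparams)
          row[paste0("power_", names(bp))] <- as.list(unname(bp))
        }
        list(row = row, hmodel = hier$hmodel)
      }, error = function(e) {
        stop(sprintf("experiment stage failed at (%s, trial %d): %s",
                     regime, trial, conditionMessage(e)), call. = FALSE)
      })
      rows[[length(rows) + 1L]] <- step$row
      if (trial == config$max_trials) models[[regime]] <- step$hmodel
      if (verbose)
        message(sprintf("[%s trial %d] surprise %.3f chunks %d js %.4f",
                        regime, trial, step$row$total_surprise,
                        step$row$n_chunks, step$row$js_distance))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, training = ts, models = models,
                 config = config), class = "hbsl_experiment")
}

#' @export
print.hbsl_experiment <- function(x, ...) {
  cat(sprintf("Statistical-learning simulation: %d models (%s x %d trials)\n",
              nrow(x$results),
              paste(unique(x$results$regime), collapse = "/"),
              max(x$results$trial)))
  print(x$results, digits = 4)
  invisible(x)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Export experiment results to a directory
#'
#' Writes the results table and per-quantity CSVs (surprise, chunk counts,
#' JS distances, band powers), a run-metadata JSON (config, config hash,
#' seed, package version), and optionally the final models' generated
#' corpora as MIDI and WAV.  Returns (and writes) a manifest of emitted
#' files with MD5 checksums.  Re-exporting over the same directory is
#' idempotent.
#'
#' @param experiment an `hbsl_experiment` from [run_experiment()]
#' @param out_dir output directory (created if missing)
#' @param midi,wav also write one example composition per regime as
#'   MIDI / WAV
#' @return data frame manifest (file, md5), invisibly
#' @export
export_results <- function(experiment, out_dir, midi = FALSE, wav = FALSE) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
  res <- experiment$results
  cfg <- experiment$config
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  emit(res, "results.csv")
  emit(res[, c("regime", "trial", "total_surprise")], "surprise.csv")
  emit(res[, c("regime", "trial", "n_chunks")], "chunks.csv")
  emit(res[, c("regime", "trial", "js_distance")], "distances.csv")
  pw <- grep("^power_", names(res), value = TRUE)
  if (length(pw)) emit(res[, c("regime", "trial", pw)], "band_power.csv")
  meta <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(
    list(config = unclass(cfg), config_hash = config_hash(cfg),
         seed = cfg$seed,
         package_version = as.character(utils::packageVersion("hbsl"))),
    meta, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  files <- c(files, meta)
  if (midi || wav) {
    for (regime in names(experiment$models)) {
      piece <- generate_sequence(experiment$models[[regime]],
                                 length(experiment$training$tokens),
                                 seed = cfg$seed)
      sseq <- detokenize(piece, experiment$training,
                         tempo_bpm = cfg$audio$tempo_bpm)
      if (midi) {
        p <- file.path(out_dir, sprintf("example_%s.mid", regime))
        write_midi(sseq, p)
        files <- c(files, p)
      }
      if (wav) {
        p <- file.path(out_dir, sprintf("example_%s.wav", regime))
        write_wav(render_waveform(sseq,
                                  sample_rate = cfg$audio$sample_rate,
                                  timbre = cfg$audio$timbre), p)
        files <- c(files, p)
      }
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
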
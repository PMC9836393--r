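#' Configuration for a full synthetic experiment
#'
#' Describes an end-to-end run: a synthetic corpus, a set of expectation
#' models with context lengths, per-participant simulated recordings driven
#' by note onsets and surprise, the TRF settings, and optional cluster
#' statistics on the surprise kernels. All randomness derives from
#' `seed` through per-stage substreams.
#'
#' @param n_compositions,n_notes corpus size.
#' @param melody list of overrides for [melody_gen_config()].
#' @param n_participants simulated listeners.
#' @param n_channels,srate,noise_sd recording settings.
#' @param models named list of model specs, each
#'   `list(type = "ltm"|"stm"|"both"|"temperley"|"generator", k = <int>)`;
#'   may be empty for an onset-only experiment.
#' @param include_baseline also fit the acoustic/adaptation baseline model.
#' @param trf list: `t_min`, `t_max`, `window`, `n_folds`, `method`.
#' @param cluster_stats run cluster permutation on the surprise kernel
#'   estimates across participants.
#' @param seed master seed.
#' @param out_dir optional directory for CSV outputs and the manifest.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(n_compositions = 6, n_notes = 120,
                              melody = list(), n_participants = 8,
                              n_channels = 6, srate = 50, noise_sd = 1,
                              models = list(ltm2 = list(type = "ltm", k = 2)),
                              trf = list(t_min = -0.2, t_max = 0.8,
                                         window = c(0, 0.6), n_folds = 5,
                                         method = "ols"),
                              include_baseline = TRUE,
                              cluster_stats = FALSE, seed = 1L, out_dir = NULL) {
  stopifnot(!is.null(seed))
  structure(list(n_compositions = n_compositions, n_notes = n_notes,
                 melody = melody, n_participants = n_participants,
                 n_channels = n_channels, srate = srate, noise_sd = noise_sd,
                 models = models, trf = trf, include_baseline = include_baseline,
                 cluster_stats = cluster_stats,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

build_predictor <- function(spec, ltm_cache, gen_cfg) {
  switch(spec$type,
         ltm = ltm_predictor(ltm_cache(spec$k), name = paste0("ltm", spec$k)),
         stm = stm_predictor(name = paste0("stm", spec$k)),
         both = both_predictor(ltm_cache(spec$k), name = paste0("both", spec$k)),
         temperley = temperley_predictor(name = "temperley"),
         generator = generator_predictor(gen_cfg, name = "generator"),
         abort(paste0("unknown model type: ", spec$type)))
}

#' Run a full synthetic experiment
#'
#' Generates the corpus, trains and evaluates every requested expectation
#' model, simulates one recording per participant (note-onset kernel plus a
#' surprise-driven kernel, at the configured noise level), fits the onset,
#' baseline and baseline+surprise regression models with cross-validation,
#' compares models across participants, and optionally runs cluster
#' statistics on the estimated surprise kernels. Deterministic given
#' `cfg$seed`; when `cfg$out_dir` is set, writes the surprise tables, CV
#' table, comparison table and a JSON manifest (config, seed, package
#' version) there.
#'
#' @param cfg an [experiment_config()].
#' @return a result bundle (list of class `experiment_result`): `corpus`,
#'   `evaluations`, `performance` (participant x model r), `comparison`,
#'   `cluster` (if requested) and `manifest`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  mel_args <- utils::modifyList(
    list(n_notes = cfg$n_notes, seed = derive_seed(cfg$seed, 1)), cfg$melody)
  gen_cfg <- do.call(melody_gen_config, mel_args)
  corpus <- generate_corpus(cfg$n_compositions, gen_cfg)

  ltm_models <- new.env(parent = emptyenv())
  ltm_cache <- function(k) {
    key <- as.character(k)
    if (is.null(ltm_models[[key]])) {
      train_cfg <- gen_cfg
      train_cfg$seed <- derive_seed(cfg$seed, 2)
      train <- generate_corpus(max(10, cfg$n_compositions), train_cfg)
      ltm_models[[key]] <- ngram_train(train, k)
    }
    ltm_models[[key]]
  }

  evaluations <- purrr::imap(cfg$models, function(spec, nm) {
    ev <- evaluate_model(build_predictor(spec, ltm_cache, gen_cfg), corpus, spec$k)
    ev$model_name <- nm
    ev
  })

  # neural simulation: onset response plus, when expectation models are in
  # play, a surprise-modulated response driven by the first listed model
  onsets_shifted <- shift_onsets(corpus, gap = 1)
  truth <- list(onset = default_truth_kernel(cfg$n_channels, cfg$srate, amplitude = 1))
  sim_regs <- list(onset = rep(1, nrow(onsets_shifted)))
  if (length(evaluations) > 0) {
    truth$surprise <- default_truth_kernel(cfg$n_channels, cfg$srate, amplitude = 0.6)
    s_aligned <- onsets_shifted |>
      dplyr::group_by(.data$composition_id) |>
      dplyr::mutate(note_index = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::left_join(
        evaluations[[1]]$notes[, c("composition_id", "note_index", "surprise")],
        by = c("composition_id", "note_index"))
    sim_regs$surprise <- as.vector(scale(s_aligned$surprise))
  }
  recordings <- purrr::map(seq_len(cfg$n_participants), function(i) {
    sim <- simulate_neural(
      onsets_shifted, sim_regs,
      neural_sim_config(cfg$n_channels, cfg$srate, truth,
                        noise_sd = cfg$noise_sd,
                        seed = derive_seed(cfg$seed, 100 + i)))
    sim$recording
  })

  feats_base <- build_feature_table(onsets_shifted)
  n_samples <- ncol(recordings[[1]]$data)
  designs <- list(
    onset = time_expand(to_impulse_regressors(feats_base, cfg$srate, n_samples,
                                              features = "onset_flag"),
                        cfg$trf$t_min, cfg$trf$t_max)
  )
  if (isTRUE(cfg$include_baseline)) {
    designs$baseline <- time_expand(
      to_impulse_regressors(feats_base, cfg$srate, n_samples),
      cfg$trf$t_min, cfg$trf$t_max)
  }
  for (nm in names(evaluations)) {
    feats <- build_feature_table(onsets_shifted, surprise = align_surprise(
      evaluations[[nm]], onsets_shifted))
    designs[[nm]] <- time_expand(
      to_impulse_regressors(feats, cfg$srate, n_samples,
                            features = c(BINARY_FEATURES, "surprise")),
      cfg$trf$t_min, cfg$trf$t_max)
  }

  performance <- purrr::map_dfr(seq_along(recordings), function(i) {
    purrr::imap_dfr(designs, function(design, nm) {
      cv <- cv_predictive_r(design, recordings[[i]], n_folds = cfg$trf$n_folds,
                            window = cfg$trf$window,
                            method = cfg$trf$method %||% "ols", label = nm)
      tibble::tibble(participant = i, model = nm, r = summary_r(cv))
    })
  })

  contrasts <- list("onset")
  if (isTRUE(cfg$include_baseline)) {
    contrasts <- c(contrasts, list(c("baseline", "onset")),
                   lapply(names(evaluations), function(nm) c(nm, "baseline")))
  }
  comparison <- if (cfg$n_participants >= 2) compare_models(performance, contrasts) else NULL

  cluster <- NULL
  if (isTRUE(cfg$cluster_stats) && length(evaluations) > 0) {
    kernels <- purrr::map(seq_along(recordings), function(i) {
      fit <- fit_ols(designs[[names(evaluations)[1]]], recordings[[i]])
      t(trf_kernel(fit, "surprise")) # channels x lags
    })
    arr <- array(0, c(length(kernels), dim(kernels[[1]])))
    for (i in seq_along(kernels)) arr[i, , ] <- kernels[[i]]
    lags <- designs[[names(evaluations)[1]]]$lags
    arr <- baseline_correct(arr, lags, c(cfg$trf$t_min, 0))
    cluster <- cluster_permutation(arr, ring_adjacency(cfg$n_channels),
                                   cluster_test_config(
                                     baseline = c(cfg$trf$t_min, 0),
                                     n_permutations = 500,
                                     seed = derive_seed(cfg$seed, 999)))
  }

  manifest <- list(
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    package_version = as.character(utils::packageVersion("melotrf")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    models = names(cfg$models)
  )

  out <- structure(list(corpus = corpus, evaluations = evaluations,
                        performance = performance, comparison = comparison,
                        cluster = cluster, manifest = manifest, config = cfg),
                   class = "experiment_result")
  if (!is.null(cfg$out_dir)) write_experiment(out, cfg$out_dir)
  out
}

# spread compositions along one continuous time base with a gap in between
shift_onsets <- function(corpus, gap = 1) {
  offsets <- corpus |>
    dplyr::group_by(.data$composition_id) |>
    dplyr::summarise(dur = max(.data$onset + .data$duration)) |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$dur + gap), default = 0))
  corpus |>
    dplyr::left_join(offsets[, c("composition_id", "offset")], by = "composition_id") |>
    dplyr::mutate(onset = .data$onset + .data$offset) |>
    dplyr::select(-"offset") |>
    validate_notes()
}

align_surprise <- function(ev, notes) {
  st <- ev$notes
  if (nrow(st) != nrow(notes)) abort("surprise table misaligned with notes")
  st
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$evaluations)) {
    write_surprise_table(res$evaluations[[nm]],
                         file.path(out_dir, paste0("surprise_", nm, ".csv")))
  }
  readr::write_csv(res$performance, file.path(out_dir, "performance.csv"),
                   progress = FALSE)
  readr::write_csv(res$comparison, file.path(out_dir, "comparison.csv"),
                   progress = FALSE)
  if (!is.null(res$cluster)) {
    readr::write_csv(res$cluster$clusters, file.path(out_dir, "clusters.csv"),
                     progress = FALSE)
  }
  writeLines(jsonlite::toJSON(res$manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d compositions, %d participants, models: %s\n",
              x$config$n_compositions, x$config$n_participants,
              paste(names(x$config$models), collapse = ", ")))
  print(x$comparison)
  invisible(x)
}
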
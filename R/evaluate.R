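#' Pitch predictors
#'
#' A pitch predictor is anything with a [predict_pitch()] method returning a
#' [pitch_distribution()] for a given context. Constructors:
#'
#' * `uniform_predictor()` — the chance model, uniform over 128 pitches.
#' * `temperley_predictor(params)` — the Bayesian Gestalt model.
#' * `ltm_predictor(model)` — a corpus-trained n-gram model.
#' * `stm_predictor()` — an online short-term n-gram model, re-initialised
#'   at each composition start by [evaluate_model()].
#' * `both_predictor(ltm_model, bias, mixture)` — entropy-weighted
#'   combination of stm and ltm.
#' * `generator_predictor(cfg)` — the synthetic melody generator's own
#'   transition model (the ground-truth predictor for simulated corpora).
#' * `function_predictor(fun)` — wraps `function(context) -> distribution`.
#'
#' @param params a [temperley_params()].
#' @param model a trained `"ltm"` [ngram_model()].
#' @param ltm_model a trained `"ltm"` [ngram_model()] (for `both`).
#' @param bias,mixture passed to [combine_both()].
#' @param cfg a [melody_gen_config()].
#' @param fun a `function(context)` returning a 128-probability vector.
#' @param name label used in result tables.
#' @name pitch_predictor
NULL

new_predictor <- function(type, name, ...) {
  structure(list(type = type, name = name, ...),
            class = c(paste0(type, "_predictor"), "pitch_predictor"))
}

#' @rdname pitch_predictor
#' @export
uniform_predictor <- function(name = "uniform") new_predictor("uniform", name)

#' @rdname pitch_predictor
#' @export
temperley_predictor <- function(params = temperley_params(), name = "temperley") {
  new_predictor("temperley", name, params = params)
}

#' @rdname pitch_predictor
#' @export
ltm_predictor <- function(model, name = "ltm") {
  stopifnot(inherits(model, "ngram_model"), model$mode == "ltm")
  new_predictor("ltm", name, model = model)
}

#' @rdname pitch_predictor
#' @export
stm_predictor <- function(name = "stm") new_predictor("stm", name)

#' @rdname pitch_predictor
#' @export
both_predictor <- function(ltm_model, bias = 1, mixture = "geometric", name = "both") {
  stopifnot(inherits(ltm_model, "ngram_model"), ltm_model$mode == "ltm")
  new_predictor("both", name, ltm_model = ltm_model, bias = bias, mixture = mixture)
}

#' @rdname pitch_predictor
#' @export
generator_predictor <- function(cfg, name = "generator") {
  stopifnot(inherits(cfg, "melody_gen_config"))
  new_predictor("generator", name, cfg = cfg)
}

#' @rdname pitch_predictor
#' @export
function_predictor <- function(fun, name = "custom") {
  new_predictor("custom", name, fun = fun)
}

#' Predictive distribution for the next pitch
#'
#' @param predictor a predictor from [pitch_predictor].
#' @param context integer vector of preceding pitches (already truncated to
#'   the desired context length).
#' @param ... method-specific arguments.
#' @return a [pitch_distribution()].
#' @export
predict_pitch <- function(predictor, context, ...) UseMethod("predict_pitch")

#' @export
predict_pitch.uniform_predictor <- function(predictor, context, ...) {
  uniform_pitch_distribution()
}

#' @export
predict_pitch.temperley_predictor <- function(predictor, context, ...) {
  temperley_predict(context, predictor$params)
}

#' @export
predict_pitch.ltm_predictor <- function(predictor, context, ...) {
  ngram_predict(predictor$model, context)
}

#' @export
predict_pitch.generator_predictor <- function(predictor, context, ...) {
  pitch_distribution(floor_distribution(melody_transition_probs(predictor$cfg, context)))
}

#' @export
predict_pitch.custom_predictor <- function(predictor, context, ...) {
  pitch_distribution(predictor$fun(context))
}

argmax_pitch <- function(dist) {
  # ties broken toward the lowest pitch
  PITCH_ALPHABET[which.max(dist)]
}

#' Evaluate a pitch predictor on a test corpus
#'
#' For every note the context is truncated to the most recent `k` notes of
#' the same composition; the first note of each composition is scored
#' against a uniform prior over the 128 pitches. Records note-level surprise
#' (nats), uncertainty (nats), the argmax prediction (ties toward the lowest
#' pitch) and its correctness.
#'
#' stm-type predictors are re-initialised at each composition start and
#' updated causally; `both` combines the running stm with the trained ltm
#' note by note and records the entropy weights.
#'
#' @param predictor a predictor from [pitch_predictor].
#' @param test a note table (the test corpus).
#' @param k context length (>= 1).
#' @return an object of class `surprise_eval`: a list with `notes` (the
#'   per-note tibble), `by_composition` (per-composition accuracy, median
#'   surprise/uncertainty, cross-entropy = mean surprise), `model_name`,
#'   `context_length`, and for `both` the mean stm/ltm weights.
#' @export
evaluate_model <- function(predictor, test, k) {
  stopifnot(inherits(predictor, "pitch_predictor"), k >= 1)
  test <- validate_notes(test)
  is_stm <- predictor$type %in% c("stm", "both")
  rows <- list()
  weights_acc <- c(stm = 0, ltm = 0)
  n_weighted <- 0L
  for (comp in split(test, test$composition_id)) {
    pitches <- comp$pitch
    n <- length(pitches)
    stm <- if (is_stm) ngram_model(k, "stm") else NULL
    s_vec <- u_vec <- numeric(n)
    pred_vec <- integer(n)
    for (t in seq_len(n)) {
      if (t == 1L) {
        dist <- uniform_pitch_distribution()
      } else {
        context <- pitches[max(1L, t - k):(t - 1L)]
        dist <- switch(predictor$type,
          stm = ngram_predict(stm, context),
          both = {
            cb <- combine_both(ngram_predict(stm, context),
                               ngram_predict(predictor$ltm_model, context),
                               bias = predictor$bias, mixture = predictor$mixture)
            weights_acc <- weights_acc + cb$weights
            n_weighted <- n_weighted + 1L
            cb$dist
          },
          predict_pitch(predictor, context)
        )
      }
      s_vec[t] <- surprise(dist, pitches[t])
      u_vec[t] <- uncertainty(dist)
      pred_vec[t] <- argmax_pitch(dist)
      if (is_stm) stm <- stm_step(stm, pitches[t])
    }
    rows[[comp$composition_id[1]]] <- tibble::tibble(
      composition_id = comp$composition_id,
      note_index = seq_len(n),
      pitch = pitches,
      surprise = s_vec,
      uncertainty = u_vec,
      predicted_pitch = pred_vec,
      correct = pred_vec == pitches
    )
  }
  notes <- dplyr::bind_rows(rows)
  by_comp <- notes |>
    dplyr::group_by(.data$composition_id) |>
    dplyr::summarise(
      n_notes = dplyr::n(),
      accuracy = mean(.data$correct),
      median_surprise = median(.data$surprise),
      median_uncertainty = median(.data$uncertainty),
      cross_entropy = mean(.data$surprise)
    )
  out <- list(notes = notes, by_composition = by_comp,
              model_name = predictor$name, context_length = as.integer(k))
  if (predictor$type == "both" && n_weighted > 0) {
    out$mean_weights <- weights_acc / n_weighted
  }
  structure(out, class = "surprise_eval")
}

#' @export
print.surprise_eval <- function(x, ...) {
  cat(sprintf("<surprise_eval> model=%s k=%d: %d notes, %d compositions\n",
              x$model_name, x$context_length, nrow(x$notes), nrow(x$by_composition)))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.surprise_eval <- function(x, ...) x$notes

#' Corpus-level summary of a predictor evaluation
#'
#' @param x a `surprise_eval`.
#' @param ... unused.
#' @return one-row tibble: model, context length, median accuracy / surprise
#'   / uncertainty across compositions, and overall cross-entropy.
#' @export
glance.surprise_eval <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    context_length = x$context_length,
    accuracy = median(x$by_composition$accuracy),
    median_surprise = median(x$by_composition$median_surprise),
    median_uncertainty = median(x$by_composition$median_uncertainty),
    cross_entropy = mean(x$notes$surprise)
  )
}

#' Write and read per-note surprise tables
#'
#' CSV with columns `composition_id, note_index, surprise, uncertainty,
#' predicted_pitch, correct`. Reading validates invariants (surprise >= 0,
#' uncertainty in `[0, log(128)]`) and, when a corpus is given, alignment of
#' note counts per composition.
#'
#' @param eval_or_table a `surprise_eval` or its `notes` tibble.
#' @param path file path.
#' @param corpus optional note table to validate alignment against.
#' @return [load_external_surprise()] returns a `surprise_eval`-compatible
#'   notes tibble; [write_surprise_table()] returns `path` invisibly.
#' @export
write_surprise_table <- function(eval_or_table, path) {
  tab <- if (inherits(eval_or_table, "surprise_eval")) eval_or_table$notes else eval_or_table
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_surprise_table
#' @export
load_external_surprise <- function(path, corpus = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("composition_id", "note_index", "surprise", "uncertainty")
  if (!all(req %in% names(tab))) {
    abort(paste0("surprise table must have columns: ", paste(req, collapse = ", ")))
  }
  if (any(tab$surprise < 0)) abort("surprise must be non-negative")
  if (any(tab$uncertainty < 0 | tab$uncertainty > log(N_PITCH) + 1e-9)) {
    abort("uncertainty must lie in [0, log(128)]")
  }
  if (!is.null(corpus)) {
    corpus <- validate_notes(corpus)
    got <- table(tab$composition_id)
    want <- table(corpus$composition_id)
    if (!identical(sort(names(got)), sort(names(want))) ||
        !all(got[names(want)] == want)) {
      abort("surprise table is misaligned with the corpus (note counts differ)")
    }
  }
  tibble::as_tibble(tab)
}
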
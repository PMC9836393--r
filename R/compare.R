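#' Compare regression models across simulated participants
#'
#' Takes per-participant summary correlations in long form and runs, for
#' each requested contrast, a paired t-test on the per-participant
#' difference (or a one-sample t-test against zero when `model_b` is `NA`),
#' with Bonferroni-Holm correction across all contrasts and Cohen's d
#' (mean / SD of the paired differences). A zero-SD difference is reported
#' as a degenerate contrast with `t = NA`.
#'
#' @param perf tibble with columns `participant`, `model`, `r` (one row per
#'   participant-model; models must be evaluated on identical folds).
#' @param contrasts list of character vectors: `c(model_a, model_b)` for a
#'   paired contrast, or a single model name for a one-sample test against
#'   zero. Default: every model against zero.
#' @return tibble with columns `model_a`, `model_b`, `mean_diff`, `sd_diff`,
#'   `t`, `df`, `p`, `p_holm`, `d`.
#' @export
compare_models <- function(perf, contrasts = NULL) {
  req <- c("participant", "model", "r")
  if (!all(req %in% names(perf))) abort("perf needs columns participant, model, r")
  if (dplyr::n_distinct(perf$participant) < 2) abort("need at least 2 participants")
  wide <- tidyr::pivot_wider(perf, id_cols = "participant",
                             names_from = "model", values_from = "r")
  if (anyNA(wide)) abort("mismatched fold structure: missing participant-model cells")
  models <- setdiff(names(wide), "participant")
  contrasts <- contrasts %||% as.list(models)
  rows <- purrr::map_dfr(contrasts, function(ct) {
    a <- ct[[1]]
    b <- if (length(ct) > 1) ct[[2]] else NA_character_
    diff <- if (is.na(b)) wide[[a]] else wide[[a]] - wide[[b]]
    n <- length(diff)
    m <- mean(diff)
    s <- sd(diff)
    if (s == 0) {
      tibble::tibble(model_a = a, model_b = b, mean_diff = m, sd_diff = 0,
                     t = NA_real_, df = n - 1, p = if (m == 0) 1 else NA_real_,
                     d = NA_real_)
    } else {
      tt <- m / (s / sqrt(n))
      tibble::tibble(model_a = a, model_b = b, mean_diff = m, sd_diff = s,
                     t = tt, df = n - 1,
                     p = 2 * stats::pt(abs(tt), n - 1, lower.tail = FALSE),
                     d = m / s)
    }
  })
  rows$p_holm <- p.adjust(rows$p, method = "holm")
  rows[, c("model_a", "model_b", "mean_diff", "sd_diff", "t", "df", "p", "p_holm", "d")]
}

#' Joint music/neural context-length sweep
#'
#' Re-runs the evaluation and encoding analysis over a grid of context
#' lengths: for each `k`, each predictor factory is evaluated on the corpus
#' (music accuracy) and its surprise estimates are added to the baseline
#' regressor set for every participant's recording (incremental predictive
#' correlation `delta_r` over the baseline model). This reproduces the
#' dual-axis design that dissociates how well a context length predicts the
#' music from how well it predicts the neural signal.
#'
#' @param predictor_factories named list of `function(k)` returning a
#'   [pitch_predictor] for context length `k`.
#' @param k_values integer vector of context lengths.
#' @param corpus note table used both for evaluation and as the stimulus of
#'   the recordings.
#' @param recordings list of [neural_recording()]s (one per simulated
#'   participant), all time-locked to `corpus` onsets.
#' @param base_features a [build_feature_table()] result without surprise
#'   columns.
#' @param t_min,t_max lag span; `window` scoring window; `n_folds` CV folds.
#' @return a list with `sweep` (tibble `model, k, accuracy, median_surprise,
#'   mean_delta_r`), `baseline_r` (per-participant baseline summary r) and
#'   `per_participant` (full delta-r table).
#' @export
context_sweep <- function(predictor_factories, k_values, corpus, recordings,
                          base_features, t_min = -0.2, t_max = 1,
                          window = c(0, 0.6), n_folds = 5) {
  corpus <- validate_notes(corpus)
  n_samples <- ncol(recordings[[1]]$data)
  srate <- recordings[[1]]$srate
  base_regs <- to_impulse_regressors(base_features, srate, n_samples)
  base_design <- time_expand(base_regs, t_min, t_max)
  base_r <- vapply(recordings, function(rec) {
    summary_r(cv_predictive_r(base_design, rec, n_folds = n_folds,
                              window = window, label = "baseline"))
  }, 0)
  rows <- list()
  per_part <- list()
  for (nm in names(predictor_factories)) {
    for (k in k_values) {
      ev <- evaluate_model(predictor_factories[[nm]](k), corpus, k)
      feats <- build_feature_table(corpus, surprise = ev)
      # carry over any acoustic columns present in the baseline table
      for (cn in intersect(c("rms", "flatness", "envelope_variance"),
                           names(base_features))) {
        feats[[cn]] <- base_features[[cn]]
      }
      regs <- to_impulse_regressors(
        feats, srate, n_samples,
        features = c(setdiff(base_regs$features, c("surprise", "uncertainty")),
                     "surprise"))
      design <- time_expand(regs, t_min, t_max)
      dr <- vapply(seq_along(recordings), function(i) {
        summary_r(cv_predictive_r(design, recordings[[i]], n_folds = n_folds,
                                  window = window, label = nm)) - base_r[i]
      }, 0)
      g <- glance(ev)
      rows[[paste(nm, k)]] <- tibble::tibble(
        model = nm, k = k, accuracy = g$accuracy,
        median_surprise = g$median_surprise, mean_delta_r = mean(dr))
      per_part[[paste(nm, k)]] <- tibble::tibble(
        model = nm, k = k, participant = seq_along(recordings), delta_r = dr)
    }
  }
  list(sweep = dplyr::bind_rows(rows), baseline_r = base_r,
       per_participant = dplyr::bind_rows(per_part))
}
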
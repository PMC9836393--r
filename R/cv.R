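#' Cross-validated predictive correlation of a TRF model
#'
#' Fivefold cross-validation with contiguous 20% time blocks as test sets
#' (never interleaved samples, so the lag window cannot leak across the
#' split). Training rows whose lag window straddles a fold boundary are
#' dropped. Channel data are z-scored with training-row statistics only.
#' The model is fit on the full lag span of the design; the Pearson
#' correlation between predicted and recorded signal is computed per
#' channel on the held-out rows restricted to the scoring window
#' (`window[1]`..`window[2]` seconds after a note onset).
#'
#' @param design a [time_expand()] design.
#' @param rec a [neural_recording()].
#' @param n_folds number of contiguous folds (default 5).
#' @param window scoring window in seconds relative to note onset.
#' @param method `"ols"` or `"ridge"` (nested CV for alpha inside each
#'   training fold).
#' @param alphas ridge candidates (must include 0).
#' @param label model label carried into comparison tables.
#' @param keep_fits also return the per-fold coefficient matrices (for
#'   diagnostics).
#' @return an object of class `trf_cv`: list with `folds` (tibble
#'   `channel, fold, r`), `by_channel` (median r across folds), `label`,
#'   `n_folds`, and the per-fold selected alphas for ridge.
#' @export
cv_predictive_r <- function(design, rec, n_folds = 5, window = c(0, 0.6),
                            method = c("ols", "ridge"), alphas = c(0, 10^(0:4)),
                            label = "model", keep_fits = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(design, "trf_design"), inherits(rec, "neural_recording"))
  n <- nrow(design$matrix)
  valid <- design$valid & !rec$bad_mask
  # samples inside the scoring window after any note onset
  score_ok <- rep(FALSE, n)
  w_lo <- round_half_up(window[1] * design$srate)
  w_hi <- round_half_up(window[2] * design$srate)
  for (o in design$onset_samples) {
    a <- max(1L, o + w_lo); b <- min(n, o + w_hi)
    if (a <= b) score_ok[a:b] <- TRUE
  }
  guard <- max(abs(design$lag_samples))
  fold_id <- cut(seq_len(n), n_folds, labels = FALSE)
  res <- list()
  fits <- if (keep_fits) vector("list", n_folds) else NULL
  alphas_used <- rep(NA_real_, n_folds)
  for (f in seq_len(n_folds)) {
    test <- which(fold_id == f & valid)
    if (length(test) == 0) abort(sprintf("fold %d has no valid rows", f))
    in_test_block <- fold_id == f
    near_boundary <- rep(FALSE, n)
    edges <- range(which(in_test_block))
    lo <- max(1L, edges[1] - guard); hi <- min(n, edges[2] + guard)
    near_boundary[lo:hi] <- TRUE
    train <- which(valid & !in_test_block & !near_boundary)
    if (length(train) <= ncol(design$matrix)) {
      abort(sprintf("fold %d: not enough training rows", f))
    }
    mu <- rowMeans(rec$data[, train, drop = FALSE])
    sdv <- apply(rec$data[, train, drop = FALSE], 1, sd)
    sdv[sdv == 0] <- 1
    y_train <- t((rec$data[, train, drop = FALSE] - mu) / sdv)
    M_train <- design$matrix[train, , drop = FALSE]
    if (method == "ridge") {
      alpha <- select_alpha(M_train, y_train, alphas, inner_folds = 5)
      alphas_used[f] <- alpha
      fit <- ridge_solve(M_train, y_train, alpha)
    } else {
      fit <- ridge_solve(M_train, y_train, 0)
    }
    if (keep_fits) fits[[f]] <- fit
    keep <- test[score_ok[test]]
    if (length(keep) < 3) abort(sprintf("fold %d: scoring window leaves < 3 samples", f))
    pred <- design$matrix[keep, , drop = FALSE] %*% fit$beta +
      matrix(fit$intercept, length(keep), nrow(rec$data), byrow = TRUE)
    y_test <- t((rec$data[, keep, drop = FALSE] - mu) / sdv)
    r <- vapply(seq_len(ncol(pred)), function(ch) {
      if (sd(pred[, ch]) == 0 || sd(y_test[, ch]) == 0) return(0)
      cor(pred[, ch], y_test[, ch])
    }, 0)
    res[[f]] <- tibble::tibble(channel = rec$channel_ids, fold = f, r = r)
  }
  folds <- dplyr::bind_rows(res)
  by_channel <- folds |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(r = median(.data$r)) |>
    dplyr::arrange(match(.data$channel, rec$channel_ids))
  structure(list(folds = folds, by_channel = by_channel, label = label,
                 n_folds = n_folds, method = method, alphas_used = alphas_used,
                 fits = fits),
            class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf("<trf_cv> %s (%s, %d folds): summary r = %.4f\n",
              x$label, x$method, x$n_folds, summary_r(x)))
  invisible(x)
}

#' @export
tidy.trf_cv <- function(x, ...) x$folds

#' @export
glance.trf_cv <- function(x, ...) {
  tibble::tibble(label = x$label, method = x$method, n_folds = x$n_folds,
                 summary_r = summary_r(x))
}

#' Summary predictive correlation
#'
#' Median across folds per channel, then mean across the given channels
#' (all channels when none are given).
#'
#' @param cv a `trf_cv`.
#' @param channels optional channel subset (e.g. from [select_channels()]).
#' @return a single correlation value.
#' @export
summary_r <- function(cv, channels = NULL) {
  bc <- cv$by_channel
  if (!is.null(channels)) bc <- dplyr::filter(bc, .data$channel %in% channels)
  mean(bc$r)
}

#' Select the channels most responsive to notes
#'
#' Channels whose summary r for the onset model lies strictly above the
#' given quantile (default 2/3). If the strict rule selects nothing (all
#' channels tied), all channels are kept with a warning.
#'
#' @param onset_cv a `trf_cv` for the onset-only model.
#' @param quantile selection quantile.
#' @return character vector of channel ids.
#' @export
select_channels <- function(onset_cv, quantile = 2 / 3) {
  stopifnot(inherits(onset_cv, "trf_cv"))
  bc <- onset_cv$by_channel
  if (nrow(bc) < 3) abort("channel selection needs at least 3 channels")
  thr <- stats::quantile(bc$r, quantile, type = 7)
  sel <- bc$channel[bc$r > thr]
  if (length(sel) == 0) {
    warn("no channel strictly above the selection quantile; keeping all channels")
    sel <- bc$channel
  }
  sel
}
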
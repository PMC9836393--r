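#' Per-note acoustic features from a waveform
#'
#' All three features are computed over each note's span
#' `[onset, onset + duration)` in a mono waveform:
#'
#' * [rms_per_note()] — root-mean-square amplitude (perceived loudness).
#' * [flatness_per_note()] — spectral flatness, the ratio of the geometric
#'   to the arithmetic mean of the magnitude spectrum of the note window
#'   (a standard timbre measure; 1 for a flat spectrum, near 0 for a pure
#'   tone). An all-zero window is defined as 0.
#' * [envelope_variance_per_note()] — variance of the broad-band envelope
#'   within the note span, an index of acoustic edges. The envelope is the
#'   across-band average of the magnitudes of the analytic signal after a
#'   64-band gammatone filterbank (log-spaced centre frequencies 50--8000
#'   Hz).
#'
#' @param audio numeric mono waveform.
#' @param srate audio sampling rate in Hz.
#' @param notes a validated note table; spans must lie inside the audio.
#' @return numeric vector with one value per note.
#' @name note_acoustics
NULL

note_spans <- function(audio, srate, notes) {
  a <- round_half_up(notes$onset * srate) + 1L
  b <- pmin(round_half_up((notes$onset + notes$duration) * srate), length(audio))
  if (any(a > length(audio)) || any(b < a)) abort("note span outside the audio")
  purrr::map2(a, b, ~ audio[.x:.y])
}

#' @rdname note_acoustics
#' @export
rms_per_note <- function(audio, srate, notes) {
  notes <- validate_notes(notes)
  vapply(note_spans(audio, srate, notes), function(x) sqrt(mean(x^2)), 0)
}

#' @rdname note_acoustics
#' @export
flatness_per_note <- function(audio, srate, notes) {
  notes <- validate_notes(notes)
  vapply(note_spans(audio, srate, notes), function(x) {
    mag <- Mod(fft(x))[seq_len(max(1L, length(x) %/% 2L))]
    am <- mean(mag)
    if (am == 0) return(0)
    gm <- exp(mean(log(pmax(mag, 1e-12))))
    gm / am
  }, 0)
}

# 4th-order gammatone FIR kernels, log-spaced centre frequencies
gammatone_bank <- function(srate, n_bands = 64, f_lo = 50, f_hi = 8000) {
  cf <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands))
  lapply(cf, function(f) {
    erb <- 24.7 + 0.108 * f
    b <- 1.019 * erb
    dur <- min(0.1, 12 / (2 * pi * b)) # until the envelope has decayed
    t <- seq(0, dur, by = 1 / srate)[-1]
    g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * f * t)
    g / sqrt(sum(g^2))
  })
}

analytic_magnitude <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

fft_convolve_same <- function(x, kern) {
  n <- length(x) + length(kern) - 1L
  nf <- stats::nextn(n, 2)
  y <- Re(fft(fft(c(x, numeric(nf - length(x)))) *
              fft(c(kern, numeric(nf - length(kern)))), inverse = TRUE)) / nf
  y[seq_along(x)]
}

#' Broad-band envelope of a waveform
#'
#' Gammatone filterbank (64 log-spaced bands, 50--8000 Hz), magnitude of the
#' analytic signal per band, averaged across bands.
#'
#' @param audio numeric mono waveform (sampling rate >= 16 kHz advised).
#' @param srate sampling rate in Hz.
#' @param n_bands number of filterbank bands.
#' @return numeric envelope, same length as `audio`.
#' @export
broadband_envelope <- function(audio, srate, n_bands = 64) {
  bank <- gammatone_bank(srate, n_bands)
  env <- numeric(length(audio))
  for (kern in bank) {
    env <- env + analytic_magnitude(fft_convolve_same(audio, kern))
  }
  env / length(bank)
}

#' @param envelope optional precomputed [broadband_envelope()]; computed
#'   from `audio` when missing.
#' @rdname note_acoustics
#' @export
envelope_variance_per_note <- function(audio, srate, notes, envelope = NULL) {
  notes <- validate_notes(notes)
  envelope <- envelope %||% broadband_envelope(audio, srate)
  vapply(note_spans(envelope, srate, notes), function(x) {
    if (length(x) < 2) 0 else var(x)
  }, 0)
}

#' Build the per-note feature table
#'
#' One row per note with the binary and continuous regressors of the
#' acoustic baseline set: `onset_flag` (always 1), `high_pitch` /
#' `low_pitch` (pitch strictly above the 90% / strictly below the 10%
#' pitch quantile, pooled over the whole table — ties are excluded by the
#' strict inequality), `composition_onset` (first note of each
#' composition), `repetition` (pitch equal to the immediately preceding
#' pitch), optional sound-type flags, the continuous acoustic columns, and
#' optional surprise/uncertainty columns.
#'
#' @param notes a validated note table; an optional `sound` column yields
#'   one binary flag per non-reference sound type.
#' @param audio optional list with `wave` and `srate`; when given, `rms`,
#'   `flatness` and `envelope_variance` are computed from it.
#' @param acoustics optional tibble with per-note `rms`, `flatness`,
#'   `envelope_variance` (used when no audio exists, e.g. synthetic ground
#'   truth).
#' @param surprise optional `surprise_eval` or notes tibble supplying
#'   `surprise` and `uncertainty` columns (must align note-for-note).
#' @return a tibble of class `feature_table` with the note timing columns
#'   and all regressor columns.
#' @export
build_feature_table <- function(notes, audio = NULL, acoustics = NULL,
                                surprise = NULL) {
  notes <- validate_notes(notes)
  q_hi <- quantile(notes$pitch, 0.9, type = 7)
  q_lo <- quantile(notes$pitch, 0.1, type = 7)
  tab <- notes |>
    dplyr::group_by(.data$composition_id) |>
    dplyr::mutate(
      note_index = dplyr::row_number(),
      onset_flag = 1L,
      high_pitch = as.integer(.data$pitch > q_hi),
      low_pitch = as.integer(.data$pitch < q_lo),
      composition_onset = as.integer(dplyr::row_number() == 1L),
      repetition = as.integer(!is.na(dplyr::lag(.data$pitch)) &
                                .data$pitch == dplyr::lag(.data$pitch))
    ) |>
    dplyr::ungroup()
  if ("sound" %in% names(notes)) {
    lv <- sort(unique(as.character(notes$sound)))
    for (s in lv[-1]) tab[[paste0("sound_", s)]] <- as.integer(notes$sound == s)
  }
  if (!is.null(audio)) {
    tab$rms <- rms_per_note(audio$wave, audio$srate, notes)
    tab$flatness <- flatness_per_note(audio$wave, audio$srate, notes)
    tab$envelope_variance <- envelope_variance_per_note(audio$wave, audio$srate, notes)
  } else if (!is.null(acoustics)) {
    if (nrow(acoustics) != nrow(notes)) abort("acoustics table misaligned with notes")
    for (nm in intersect(c("rms", "flatness", "envelope_variance"), names(acoustics))) {
      tab[[nm]] <- acoustics[[nm]]
    }
  }
  if (!is.null(surprise)) {
    st <- if (inherits(surprise, "surprise_eval")) surprise$notes else surprise
    if (nrow(st) != nrow(tab)) abort("surprise table misaligned with notes")
    st <- dplyr::select(st, "composition_id", "note_index", "surprise", "uncertainty")
    tab <- dplyr::left_join(tab, st, by = c("composition_id", "note_index"))
    if (any(is.na(tab$surprise))) abort("surprise table misaligned with notes")
  }
  class(tab) <- unique(c("feature_table", class(tab)))
  tab
}

BINARY_FEATURES <- c("onset_flag", "high_pitch", "low_pitch",
                     "composition_onset", "repetition")

#' Place note features as impulse regressors on a sampling grid
#'
#' Each feature value is placed at the sample `round(onset * srate)`
#' (half-up rounding). Continuous features are z-scored over the note
#' entries before placement; binary features (and any column starting with
#' `sound_`) are placed as-is. Two notes mapping to the same sample raise
#' an error.
#'
#' @param table a [build_feature_table()] result.
#' @param srate target sampling rate in Hz.
#' @param n_samples number of samples of the target grid.
#' @param features character vector of feature columns to place; default all
#'   regressor columns present.
#' @return an object of class `impulse_regressors`: list with `matrix`
#'   (samples x features), `features`, `srate`, `onset_samples`.
#' @export
to_impulse_regressors <- function(table, srate, n_samples, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  auto <- c(BINARY_FEATURES, grep("^sound_", names(table), value = TRUE),
            intersect(c("rms", "flatness", "envelope_variance",
                        "surprise", "uncertainty"), names(table)))
  features <- features %||% auto
  missing_f <- setdiff(features, names(table))
  if (length(missing_f) > 0) {
    abort(paste0("features not in table: ", paste(missing_f, collapse = ", ")))
  }
  samp <- round_half_up(table$onset * srate) + 1L
  if (any(samp > n_samples)) abort("note onset beyond the sampling grid")
  if (anyDuplicated(samp)) abort("two notes map to the same sample; raise srate")
  m <- matrix(0, n_samples, length(features), dimnames = list(NULL, features))
  for (f in features) {
    v <- as.double(table[[f]])
    is_binary <- f %in% BINARY_FEATURES || startsWith(f, "sound_")
    if (!is_binary) {
      s <- sd(v)
      v <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    }
    m[samp, f] <- v
  }
  structure(list(matrix = m, features = features, srate = srate,
                 onset_samples = samp),
            class = "impulse_regressors")
}
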
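#' Ground-truth response kernels for the neural simulator
#'
#' Builds difference-of-Gamma kernels mimicking an auditory evoked-response
#' morphology: a positive peak near 0.075 s (P1), a second positive peak near
#' 0.2 s (P2), and a sustained negative deflection over 0.3--0.6 s. Channels
#' get smoothly varying gains (including sign flips) so kernels differ across
#' the array.
#'
#' @param n_channels number of channels.
#' @param srate sampling rate in Hz.
#' @param t_min,t_max kernel lag span in seconds (within -0.2 to 1.0).
#' @param amplitude overall scale.
#' @return a list with `lags` (seconds) and `kernels`
#'   (lags x channels matrix).
#' @export
default_truth_kernel <- function(n_channels, srate, t_min = 0, t_max = 0.8,
                                 amplitude = 1) {
  stopifnot(t_min >= -0.2, t_max <= 1.0, t_min < t_max)
  lags <- seq(round_half_up(t_min * srate), round_half_up(t_max * srate)) / srate
  gam <- function(t, peak, shape) {
    rate <- shape / peak
    ifelse(t > 0, stats::dgamma(t, shape = shape, rate = rate), 0)
  }
  base <- gam(lags, 0.075, 6) / max(gam(seq(0, 1, 1e-3), 0.075, 6)) +
    0.8 * gam(lags, 0.2, 8) / max(gam(seq(0, 1, 1e-3), 0.2, 8)) -
    0.6 * gam(lags, 0.45, 10) / max(gam(seq(0, 1, 1e-3), 0.45, 10))
  gains <- amplitude * (0.6 + 0.4 * cos(2 * pi * (seq_len(n_channels) - 1) / n_channels)) *
    rep_len(c(1, 1, -1), n_channels)
  list(lags = lags, kernels = outer(base, gains))
}

#' Configuration for the neural simulator
#'
#' @param n_channels channel count.
#' @param srate sampling rate in Hz.
#' @param true_trfs named list, one entry per regressor, each a list with
#'   `lags` (seconds) and `kernels` (lags x channels); see
#'   [default_truth_kernel()].
#' @param noise_sd noise amplitude (SD) added per channel.
#' @param noise_type `"white"` or `"pink"` (1/f amplitude spectrum).
#' @param seed RNG seed.
#' @return a `neural_sim_config` list.
#' @export
neural_sim_config <- function(n_channels, srate, true_trfs, noise_sd = 1,
                              noise_type = c("white", "pink"), seed = 1L) {
  noise_type <- match.arg(noise_type)
  stopifnot(srate > 0, noise_sd >= 0)
  for (tt in true_trfs) {
    if (min(tt$lags) < -0.2 - 1e-9 || max(tt$lags) > 1.0 + 1e-9) {
      abort("truth kernel lag span must lie within [-0.2, 1.0] s")
    }
    if (nrow(as.matrix(tt$kernels)) != length(tt$lags)) {
      abort("kernel rows must match lag count")
    }
  }
  structure(list(n_channels = n_channels, srate = srate, true_trfs = true_trfs,
                 noise_sd = noise_sd, noise_type = noise_type, seed = as.integer(seed)),
            class = "neural_sim_config")
}

pink_noise <- function(n, srate) {
  # spectrally shaped white noise: 1/f amplitude above 0.1 Hz, flat below
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(0, seq_len(n - 1)) / n * srate
  f <- pmin(f, srate - f)
  shape <- 1 / sqrt(pmax(f, 0.1))
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Simulate multichannel neural recordings from note-level features
#'
#' Each channel is the sum, over regressors, of an impulse train (one value
#' per note, placed at the note-onset sample) convolved with that regressor's
#' ground-truth kernel, plus noise. The forward model is exactly linear in
#' the feature values, so the deconvolution stage can be validated against
#' the known kernels.
#'
#' @param notes a validated note table (one composition or several; onsets
#'   are interpreted on a single continuous time base).
#' @param regressors named list or data frame of per-note feature values;
#'   names must match `cfg$true_trfs`.
#' @param cfg a [neural_sim_config()].
#' @param duration recording length in seconds; default covers the last note
#'   plus the longest kernel.
#' @return a list of class `neural_sim` with elements `recording`
#'   (a [neural_recording()]), `truth` (the kernels used), `impulses`
#'   (samples x regressors matrix) and `cfg`.
#' @export
simulate_neural <- function(notes, regressors, cfg, duration = NULL) {
  stopifnot(inherits(cfg, "neural_sim_config"))
  notes <- validate_notes(notes)
  regressors <- as.list(regressors)
  if (!setequal(names(regressors), names(cfg$true_trfs))) {
    abort("regressor names must match names(cfg$true_trfs)")
  }
  if (any(lengths(regressors) != nrow(notes))) {
    abort("every regressor needs one value per note")
  }
  max_lag <- max(vapply(cfg$true_trfs, function(tt) max(tt$lags), 0))
  duration <- duration %||% (max(notes$onset) + max_lag + 0.5)
  n_samples <- ceiling(duration * cfg$srate)
  onset_samp <- round_half_up(notes$onset * cfg$srate) + 1L
  if (any(onset_samp > n_samples)) abort("recording shorter than the note span")
  signal <- matrix(0, cfg$n_channels, n_samples)
  impulses <- matrix(0, n_samples, length(regressors),
                     dimnames = list(NULL, names(regressors)))
  for (nm in names(regressors)) {
    imp <- numeric(n_samples)
    imp[onset_samp] <- imp[onset_samp] + regressors[[nm]]
    impulses[, nm] <- imp
    tt <- cfg$true_trfs[[nm]]
    kern <- as.matrix(tt$kernels)
    if (length(tt$lags) > n_samples) abort("truth kernel longer than recording")
    lag_samp <- round_half_up(tt$lags * cfg$srate)
    for (ch in seq_len(cfg$n_channels)) {
      for (j in seq_along(lag_samp)) {
        if (kern[j, ch] == 0) next
        src <- seq_len(n_samples) - lag_samp[j]
        ok <- src >= 1 & src <= n_samples
        signal[ch, ok] <- signal[ch, ok] + kern[j, ch] * imp[src[ok]]
      }
    }
  }
  if (cfg$noise_sd > 0) {
    noise <- with_seed(cfg$seed, {
      t(vapply(seq_len(cfg$n_channels), function(ch) {
        if (cfg$noise_type == "pink") pink_noise(n_samples, cfg$srate) else rnorm(n_samples)
      }, numeric(n_samples)))
    })
    signal <- signal + cfg$noise_sd * noise
  }
  structure(list(
    recording = neural_recording(signal, cfg$srate),
    truth = cfg$true_trfs,
    impulses = impulses,
    notes = notes,
    cfg = cfg
  ), class = "neural_sim")
}
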
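#' Multichannel neural recording container
#'
#' Holds a channels-by-samples data matrix with its sampling rate, a
#' per-sample bad-sample mask (`TRUE` marks samples to exclude from fitting),
#' and channel ids.
#'
#' @param data numeric matrix, channels x samples.
#' @param srate sampling rate in Hz.
#' @param bad_mask logical vector, one entry per sample; defaults to all good.
#' @param channel_ids character channel labels.
#' @return an object of class `neural_recording`.
#' @export
neural_recording <- function(data, srate, bad_mask = NULL,
                             channel_ids = NULL) {
  data <- as.matrix(data)
  stopifnot(srate > 0)
  bad_mask <- bad_mask %||% rep(FALSE, ncol(data))
  if (length(bad_mask) != ncol(data)) abort("bad_mask length must equal sample count")
  if (any(!is.finite(data[, !bad_mask, drop = FALSE]))) {
    abort("data must be finite on good samples")
  }
  channel_ids <- channel_ids %||% sprintf("ch%02d", seq_len(nrow(data)))
  structure(list(data = data, srate = srate, bad_mask = bad_mask,
                 channel_ids = channel_ids),
            class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("<neural_recording> %d channels x %d samples @ %g Hz (%d bad samples)\n",
              nrow(x$data), ncol(x$data), x$srate, sum(x$bad_mask)))
  invisible(x)
}

#' Tidy a neural recording into long format
#'
#' @param x a [neural_recording()].
#' @param ... unused.
#' @return a tibble with columns `channel`, `time`, `value`, `bad`.
#' @export
tidy.neural_recording <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channel_ids, each = ncol(x$data)),
    time = rep((seq_len(ncol(x$data)) - 1) / x$srate, nrow(x$data)),
    value = as.vector(t(x$data)),
    bad = rep(x$bad_mask, nrow(x$data))
  )
}

#' Zero-phase FIR band-pass filter
#'
#' Filters every channel with a windowed-sinc FIR band-pass applied
#' forward and backward ([signal::filtfilt()]), so the net filter has zero
#' phase. The bad-sample mask is dilated by the filter half-length on each
#' side, since filtering smears bad samples into their neighbourhood.
#'
#' @param rec a [neural_recording()].
#' @param lo,hi band edges in Hz; `lo < hi < srate / 2`.
#' @param order FIR order; default three periods of the low edge,
#'   `round(3 * srate / lo)`, rounded to even.
#' @return a filtered [neural_recording()].
#' @export
bandpass <- function(rec, lo, hi, order = NULL) {
  stopifnot(inherits(rec, "neural_recording"))
  if (!(lo < hi && hi < rec$srate / 2)) abort("need lo < hi < srate/2")
  order <- order %||% (2L * ceiling(1.5 * rec$srate / lo))
  fir <- signal::fir1(order, c(lo, hi) / (rec$srate / 2), type = "pass")
  filt <- t(apply(rec$data, 1, function(ch) signal::filtfilt(fir, ch)))
  half <- order %/% 2L
  bad <- rec$bad_mask
  if (any(bad) && half > 0) {
    idx <- which(bad)
    dil <- unique(pmax(1L, pmin(ncol(rec$data),
                                rep(idx, each = 2 * half + 1) + (-half):half)))
    bad <- rep(FALSE, ncol(rec$data))
    bad[dil] <- TRUE
  }
  neural_recording(filt, rec$srate, bad_mask = bad, channel_ids = rec$channel_ids)
}
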
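#' Time-expanded design matrix
#'
#' Expands impulse regressors into a lagged design matrix for deconvolution
#' regression: column (f, l) at row s holds regressor f at sample `s -
#' lag_l`, zero-padded at the edges. With `t_min = -0.2`, `t_max = 1` and a
#' 60 Hz grid this yields `round((t_max - t_min) * srate) + 1 = 73` lag
#' columns per regressor. Column blocks are ordered by regressor, then lag.
#'
#' @param regs an [to_impulse_regressors()] result, on the same sampling
#'   grid as the recording.
#' @param t_min,t_max lag span in seconds (`t_min < 0 < t_max` by
#'   convention: negative lags model pre-onset activity).
#' @param bad_mask optional per-sample logical; rows at bad samples are
#'   flagged invalid (e.g. from [neural_recording()]`$bad_mask`).
#' @return an object of class `trf_design`: list with `matrix` (samples x
#'   `n_regressors * n_lags`), `lags` (seconds), `lag_samples`,
#'   `regressors`, `valid` (per-row logical), `srate`, `onset_samples`.
#' @export
time_expand <- function(regs, t_min, t_max, bad_mask = NULL) {
  stopifnot(inherits(regs, "impulse_regressors"))
  if (!(t_min < t_max)) abort("need t_min < t_max")
  srate <- regs$srate
  lag_samples <- seq(round_half_up(t_min * srate), round_half_up(t_max * srate))
  n_lags <- length(lag_samples)
  X <- regs$matrix
  n <- nrow(X)
  if (n_lags > n) abort("lag span longer than the recording")
  f_names <- regs$features
  M <- matrix(0, n, length(f_names) * n_lags)
  colnames(M) <- paste0(rep(f_names, each = n_lags), "_lag",
                        rep(lag_samples, length(f_names)))
  for (fi in seq_along(f_names)) {
    for (li in seq_len(n_lags)) {
      d <- lag_samples[li]
      col <- (fi - 1L) * n_lags + li
      src <- seq_len(n) - d
      ok <- src >= 1L & src <= n
      M[ok, col] <- X[src[ok], fi]
    }
  }
  valid <- rep(TRUE, n)
  if (!is.null(bad_mask)) {
    if (length(bad_mask) != n) abort("bad_mask length must equal sample count")
    valid <- !bad_mask
  }
  structure(list(matrix = M, lags = lag_samples / srate, lag_samples = lag_samples,
                 regressors = f_names, valid = valid, srate = srate,
                 onset_samples = regs$onset_samples),
            class = "trf_design")
}

#' @export
print.trf_design <- function(x, ...) {
  cat(sprintf("<trf_design> %d samples x %d columns (%d regressors x %d lags, %.3g..%.3g s)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$regressors),
              length(x$lags), min(x$lags), max(x$lags)))
  invisible(x)
}
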
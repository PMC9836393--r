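#' Parameters of the Bayesian Gestalt pitch model
#'
#' The model combines three musicological principles, each as a probability
#' distribution over the 128-pitch alphabet: (1) central pitch tendency —
#' pitches cluster in a narrow range around a latent central pitch `c`, with
#' `c ~ N(c0, var_c0)` and `x ~ N(c, v_r)`; (2) pitch proximity — intervals
#' tend to be small, `x_t ~ N(x_{t-1}, v_x)`; (3) key membership — a
#' pitch-class profile conditioned on one of 24 keys (12 major, 12 minor),
#' with prior probability `p_maj` for major keys. The default numeric values
#' are corpus moments reported for a large monophonic corpus of Western
#' classical music.
#'
#' @param c0 mean of the central-pitch prior (default 72).
#' @param var_c0 variance of the central-pitch prior (default 34.4).
#' @param v_r range-profile variance (default 83.2).
#' @param v_x proximity variance (default 18.2).
#' @param p_maj prior probability of major keys (default 0.81).
#' @param key_profiles 24 x 12 matrix of scale-degree probabilities, rows
#'   1--12 the major keys (tonic pitch class 0--11), rows 13--24 the minor
#'   keys; each row sums to 1. Default: synthetic flat scale-membership
#'   templates (see [default_key_profiles()]).
#' @return a `temperley_params` list.
#' @export
temperley_params <- function(c0 = 72, var_c0 = 34.4, v_r = 83.2, v_x = 18.2,
                             p_maj = 0.81, key_profiles = default_key_profiles()) {
  stopifnot(var_c0 >= 0, v_r > 0, v_x > 0, p_maj >= 0, p_maj <= 1)
  key_profiles <- as.matrix(key_profiles)
  if (!all(dim(key_profiles) == c(24, 12))) abort("key_profiles must be 24 x 12")
  if (any(abs(rowSums(key_profiles) - 1) > 1e-9)) abort("key-profile rows must sum to 1")
  structure(list(c0 = c0, var_c0 = var_c0, v_r = v_r, v_x = v_x, p_maj = p_maj,
                 key_profiles = key_profiles),
            class = "temperley_params")
}

#' Synthetic flat key-profile templates
#'
#' Fallback pitch-class profiles when no corpus estimate is available:
#' uniform mass over the seven scale degrees of each key, with a small
#' residual weight on out-of-scale degrees so no pitch class has zero
#' probability. These are synthetic templates, not corpus estimates.
#'
#' @param out_weight per-degree weight of the five out-of-scale classes.
#' @return a 24 x 12 matrix (rows: 12 major then 12 minor keys).
#' @export
default_key_profiles <- function(out_weight = 0.01) {
  # rows hold scale-degree profiles relative to the tonic; the rotation to
  # absolute pitch classes happens in key_pitch_weights()
  prof <- matrix(out_weight, 24, 12)
  for (tonic in 0:11) {
    for (m in c("major", "minor")) {
      row <- tonic + 1L + if (m == "minor") 12L else 0L
      prof[row, scale_degrees(m) + 1L] <- (1 - 5 * out_weight) / 7
    }
  }
  prof / rowSums(prof)
}

# Per-key pitch weights: 24 x 128, entry (k, x) = profile value of pitch
# class (x - tonic_k) mod 12. Profiles are pitch-class profiles; the octave
# spread is absorbed by the range term.
key_pitch_weights <- function(params) {
  tonics <- rep(0:11, 2)
  t(vapply(1:24, function(k) {
    params$key_profiles[k, ((PITCH_ALPHABET - tonics[k]) %% 12) + 1L]
  }, numeric(N_PITCH)))
}

# Range x key base weights: list of 24 matrices, each 128(c) x 128(x),
# entry = N(x; c, v_r) * key weight of x. The note likelihood for a given
# previous pitch multiplies in the proximity term and normalises over x.
temperley_base_weights <- function(params) {
  range_m <- outer(PITCH_ALPHABET, PITCH_ALPHABET,
                   function(c, x) dnorm(x, c, sqrt(params$v_r)))
  key_w <- key_pitch_weights(params)
  lapply(1:24, function(k) sweep(range_m, 2, key_w[k, ], `*`))
}

temperley_note_lik <- function(base_k, params, prev = NULL) {
  w <- base_k
  if (!is.null(prev)) {
    w <- sweep(w, 2, dnorm(PITCH_ALPHABET, prev, sqrt(params$v_x)), `*`)
  }
  w / rowSums(w)
}

#' Next-pitch prediction from the Bayesian Gestalt model
#'
#' Computes the predictive distribution for the next pitch given a context,
#' marginalising exactly over the latent central pitch (discrete grid 0--127
#' with prior `N(c0, var_c0)`) and the 24 keys (prior `p_maj/12` per major
#' key, `(1-p_maj)/12` per minor key). The posterior over `(c, key)` is
#' updated from the context notes; with an empty context the proximity term
#' is omitted.
#'
#' @param context integer vector of preceding pitches (may be empty).
#' @param params a [temperley_params()].
#' @param floor_weight uniform floor mixed into the final distribution.
#' @return a [pitch_distribution()].
#' @export
temperley_predict <- function(context, params = temperley_params(),
                              floor_weight = 1e-6) {
  stopifnot(inherits(params, "temperley_params"))
  context <- as.integer(context)
  if (any(context < 0 | context > 127)) abort("context pitches must be in [0, 127]")
  base <- temperley_base_weights(params)
  if (params$var_c0 > 0) {
    prior_c <- dnorm(PITCH_ALPHABET, params$c0, sqrt(params$var_c0))
  } else {
    prior_c <- as.numeric(PITCH_ALPHABET == round_half_up(params$c0))
  }
  prior_c <- prior_c / sum(prior_c)
  prior_key <- c(rep(params$p_maj / 12, 12), rep((1 - params$p_maj) / 12, 12))

  # log posterior over (c, key), updated note by note
  log_post <- matrix(log(prior_c), N_PITCH, 24) +
    matrix(log(prior_key), N_PITCH, 24, byrow = TRUE)
  for (t in seq_along(context)) {
    prev <- if (t > 1) context[t - 1] else NULL
    for (k in 1:24) {
      lik <- temperley_note_lik(base[[k]], params, prev)
      log_post[, k] <- log_post[, k] + log(lik[, context[t] + 1L])
    }
  }
  log_post[is.infinite(log_post) & log_post < 0] <- -745 # guard exact zeros
  post <- exp(log_post - max(log_post))
  post <- post / sum(post)

  prev <- if (length(context) > 0) context[length(context)] else NULL
  pred <- numeric(N_PITCH)
  for (k in 1:24) {
    lik <- temperley_note_lik(base[[k]], params, prev)
    pred <- pred + colSums(post[, k] * lik)
  }
  pitch_distribution(floor_distribution(pred / sum(pred), floor_weight))
}

#' Fit Gestalt-model parameters as corpus moments
#'
#' Estimates all parameters of [temperley_params()] from a corpus:
#' `c0`/`var_c0` as the mean and (population) variance of the compositions'
#' mean pitches; `v_r` as the variance of each melody's first note around
#' that melody's mean; `v_x` as the variance of pitches around the previous
#' pitch, restricted to notes whose previous pitch equals the melody's
#' (rounded) central pitch; key profiles as pooled scale-degree frequencies
#' per mode (when key labels are given); `p_maj` as the proportion of
#' major-key pieces.
#'
#' @param corpus a note table covering one or more compositions.
#' @param key_labels optional tibble with columns `composition_id`,
#'   `tonic` (0--11) and `mode`; without it, the synthetic
#'   [default_key_profiles()] and the default `p_maj` are kept.
#' @return a [temperley_params()].
#' @export
fit_temperley_params <- function(corpus, key_labels = NULL) {
  corpus <- validate_notes(corpus)
  per_comp <- corpus |>
    dplyr::group_by(.data$composition_id) |>
    dplyr::summarise(mean_pitch = mean(.data$pitch),
                     first_pitch = dplyr::first(.data$pitch))
  pop_var <- function(x) mean((x - mean(x))^2)
  c0 <- mean(per_comp$mean_pitch)
  var_c0 <- pop_var(per_comp$mean_pitch)
  v_r <- mean((per_comp$first_pitch - per_comp$mean_pitch)^2)

  vx_dev <- corpus |>
    dplyr::group_by(.data$composition_id) |>
    dplyr::mutate(prev = dplyr::lag(.data$pitch),
                  central = round_half_up(mean(.data$pitch))) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev))
  at_central <- dplyr::filter(vx_dev, .data$prev == .data$central)
  if (nrow(at_central) > 0) {
    v_x <- mean((at_central$pitch - at_central$prev)^2)
  } else {
    v_x <- mean((vx_dev$pitch - vx_dev$prev)^2)
  }

  profiles <- default_key_profiles()
  p_maj <- 0.81
  if (!is.null(key_labels)) {
    lab <- dplyr::inner_join(corpus, key_labels, by = "composition_id")
    if (nrow(lab) == 0) abort("no composition with a key label")
    p_maj <- mean(key_labels$mode == "major")
    for (m in c("major", "minor")) {
      sub <- dplyr::filter(lab, .data$mode == m)
      if (nrow(sub) == 0) next
      counts <- tabulate(((sub$pitch - sub$tonic) %% 12) + 1L, nbins = 12) + 0.5
      prof <- counts / sum(counts)
      for (tonic in 0:11) {
        row <- tonic + 1L + if (m == "minor") 12L else 0L
        profiles[row, ] <- prof # same profile per mode, transposed by tonic below
      }
    }
    # rows store scale-degree (relative) profiles; key_pitch_weights rotates
    # by tonic, so all rows of one mode share the estimated profile
  }
  temperley_params(c0 = c0, var_c0 = max(var_c0, 1e-8), v_r = max(v_r, 1e-8),
                   v_x = max(v_x, 1e-8), p_maj = p_maj, key_profiles = profiles)
}
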
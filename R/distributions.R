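PITCH_ALPHABET <- 0:127
N_PITCH <- 128L

#' Pitch probability distributions
#'
#' A pitch distribution is a numeric vector of 128 probabilities indexed by
#' MIDI pitch 0--127 (names `"0"` .. `"127"`), non-negative and summing to 1.
#'
#' @param probs numeric vector of length 128.
#' @return the validated, named probability vector.
#' @export
pitch_distribution <- function(probs) {
  if (length(probs) != N_PITCH) abort("pitch distribution must have 128 entries")
  if (any(probs < 0)) abort("pitch distribution has negative entries")
  if (abs(sum(probs) - 1) > 1e-9) abort("pitch distribution must sum to 1")
  setNames(as.double(probs), as.character(PITCH_ALPHABET))
}

#' Uniform distribution over the 128-pitch alphabet
#' @return a [pitch_distribution()] with every pitch at 1/128.
#' @export
uniform_pitch_distribution <- function() pitch_distribution(rep(1 / N_PITCH, N_PITCH))

# Mix with uniform at weight `floor_weight` so no pitch has zero probability
# and surprise stays finite (cap ~ ln(128 / floor_weight)).
floor_distribution <- function(probs, floor_weight = 1e-6) {
  p <- (1 - floor_weight) * probs + floor_weight / N_PITCH
  p / sum(p)
}

#' Note-level surprise
#'
#' Surprise of an observed pitch under a predictive distribution:
#' `-log P(observed)` in nats (natural log).
#'
#' @param dist a [pitch_distribution()].
#' @param observed MIDI pitch 0--127.
#' @return surprise in nats (non-negative).
#' @examples
#' surprise(uniform_pitch_distribution(), 60) # log(128) = 4.852
#' @export
surprise <- function(dist, observed) {
  dist <- pitch_distribution(dist)
  if (length(observed) != 1 || is.na(observed) || observed < 0 || observed > 127) {
    abort("observed pitch must be a single value in [0, 127]")
  }
  -log(dist[[as.character(as.integer(observed))]])
}

#' Note-level uncertainty
#'
#' Shannon entropy of a predictive pitch distribution, in nats, with
#' `0 * log(0)` treated as 0. Maximal (`log(128)` = 4.852) for the uniform
#' distribution; 0 for a one-hot distribution.
#'
#' @param dist a [pitch_distribution()].
#' @return entropy in nats, in `[0, log(128)]`.
#' @export
uncertainty <- function(dist) {
  dist <- pitch_distribution(dist)
  p <- dist[dist > 0]
  -sum(p * log(p))
}
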
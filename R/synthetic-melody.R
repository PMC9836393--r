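#' Configuration for the synthetic melody generator
#'
#' The generator samples pitches from a key-constrained Markov process with a
#' Gaussian small-interval bias (pitch proximity), a Gaussian range constraint
#' around a central pitch, and occasional verbatim reinsertion of earlier
#' motifs. With `markov_order = 2` the proximity centre includes a melodic
#' inertia term, `x[t-1] + inertia * (x[t-1] - x[t-2])`, making the process
#' genuinely second order.
#'
#' @param n_notes number of notes (>= 2).
#' @param key list with `tonic` (pitch class 0--11) and `mode`
#'   (`"major"` or `"minor"`).
#' @param markov_order 1 or 2; order of the pitch transition kernel.
#' @param interval_scale semitone SD of the proximity bias.
#' @param motif_repeat_prob probability, at each step, of reinserting a
#'   previously generated 3--6 note motif verbatim.
#' @param tempo note rate in notes per second.
#' @param center_pitch,range_sd centre and SD of the Gaussian range constraint.
#' @param inertia weight of the previous interval in the order-2 centre.
#' @param out_of_key_weight relative weight of out-of-scale pitches.
#' @param seed RNG seed (required; generation is deterministic given the seed).
#' @return a `melody_gen_config` list.
#' @export
melody_gen_config <- function(n_notes = 200, key = list(tonic = 0L, mode = "major"),
                              markov_order = 1L, interval_scale = 2.5,
                              motif_repeat_prob = 0.1, tempo = 4,
                              center_pitch = 72, range_sd = 8,
                              inertia = 0.6, out_of_key_weight = 0.05,
                              seed = 1L) {
  stopifnot(n_notes >= 2, motif_repeat_prob >= 0, motif_repeat_prob <= 1,
            markov_order %in% c(1L, 2L), tempo > 0, interval_scale >= 0)
  structure(list(n_notes = n_notes, key = key, markov_order = as.integer(markov_order),
                 interval_scale = interval_scale, motif_repeat_prob = motif_repeat_prob,
                 tempo = tempo, center_pitch = center_pitch, range_sd = range_sd,
                 inertia = inertia, out_of_key_weight = out_of_key_weight,
                 seed = as.integer(seed)),
            class = "melody_gen_config")
}

scale_degrees <- function(mode) {
  switch(mode,
         major = c(0, 2, 4, 5, 7, 9, 11),
         minor = c(0, 2, 3, 5, 7, 8, 11),
         abort("mode must be 'major' or 'minor'"))
}

key_weight_vector <- function(key, out_of_key_weight) {
  pc <- (0:127 - key$tonic) %% 12
  w <- rep(out_of_key_weight, 128)
  w[pc %in% scale_degrees(key$mode)] <- 1
  w
}

# Exact conditional next-pitch distribution of the generator, ignoring motif
# reinsertion. `context` is the vector of preceding pitches (possibly empty).
melody_transition_probs <- function(cfg, context = integer(0)) {
  x <- 0:127
  w <- key_weight_vector(cfg$key, cfg$out_of_key_weight) *
    exp(-(x - cfg$center_pitch)^2 / (2 * cfg$range_sd^2))
  n <- length(context)
  if (n >= 1) {
    centre <- context[n]
    if (cfg$markov_order == 2L && n >= 2) {
      centre <- context[n] + cfg$inertia * (context[n] - context[n - 1])
    }
    if (cfg$interval_scale > 0) {
      w <- w * exp(-(x - centre)^2 / (2 * cfg$interval_scale^2))
    } else {
      # degenerate limit: repeat the previous pitch exactly
      w <- as.numeric(x == context[n])
    }
  }
  w / sum(w)
}

#' Generate a synthetic melody
#'
#' Samples a note sequence from the key-constrained Markov process described
#' in [melody_gen_config()]. Deterministic given the seed in the config.
#'
#' @param cfg a [melody_gen_config()].
#' @param composition_id id for the generated sequence.
#' @return a validated note table with an extra logical column `motif`
#'   marking notes copied by motif reinsertion.
#' @examples
#' m <- generate_melody(melody_gen_config(n_notes = 20, seed = 42))
#' @export
generate_melody <- function(cfg, composition_id = "synthetic") {
  stopifnot(inherits(cfg, "melody_gen_config"))
  with_seed(cfg$seed, {
    pitches <- integer(cfg$n_notes)
    motif <- logical(cfg$n_notes)
    t <- 1L
    while (t <= cfg$n_notes) {
      if (t > 8L && runif(1) < cfg$motif_repeat_prob) {
        len <- sample(3:6, 1)
        start <- sample(seq_len(t - len - 1L), 1)
        seg <- pitches[start:(start + len - 1L)]
        keep <- min(length(seg), cfg$n_notes - t + 1L)
        pitches[t:(t + keep - 1L)] <- seg[seq_len(keep)]
        motif[t:(t + keep - 1L)] <- TRUE
        t <- t + keep
      } else {
        p <- melody_transition_probs(cfg, pitches[seq_len(t - 1L)])
        pitches[t] <- sample(0:127, 1, prob = p)
        t <- t + 1L
      }
    }
    notes <- note_sequence(pitches, onset = (seq_len(cfg$n_notes) - 1) / cfg$tempo,
                           duration = 0.9 / cfg$tempo, composition_id = composition_id)
    notes$motif <- motif
    notes
  })
}

#' Generate a corpus of synthetic melodies
#'
#' @param n_compositions number of melodies.
#' @param cfg template [melody_gen_config()]; each composition gets a child
#'   seed derived from `cfg$seed`.
#' @return a note table with `n_compositions` distinct `composition_id`s.
#' @export
generate_corpus <- function(n_compositions, cfg) {
  purrr::map_dfr(seq_len(n_compositions), function(i) {
    ci <- cfg
    ci$seed <- derive_seed(cfg$seed, i)
    generate_melody(ci, composition_id = sprintf("synth%03d", i))
  })
}
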
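#' Variable-order n-gram pitch model
#'
#' Stores occurrence counts of pitch m-grams for all lengths 1..k+1, where k
#' is the order bound (the maximum context length). Two modes: `"ltm"` is
#' trained once on a corpus ([ngram_train()]); `"stm"` starts empty and
#' learns online within the current composition ([stm_step()]),
#' approximating short-term statistical learning.
#'
#' @param order_bound maximum context length k (>= 1).
#' @param mode `"ltm"` or `"stm"`.
#' @return an empty `ngram_model`.
#' @export
ngram_model <- function(order_bound, mode = c("ltm", "stm")) {
  mode <- match.arg(mode)
  stopifnot(order_bound >= 1)
  structure(list(order_bound = as.integer(order_bound), mode = mode,
                 # counts: context string -> named numeric vector of
                 # continuation counts (names are pitch values)
                 counts = new.env(parent = emptyenv()),
                 history = integer(0)),
            class = "ngram_model")
}

gram_key <- function(pitches) paste0("^", paste(pitches, collapse = " "))

cont_table <- function(model, ctx) {
  get0(gram_key(ctx), envir = model$counts, inherits = FALSE)
}

# register one (m+1)-gram: ctx (length 0..k) followed by pitch x
add_gram <- function(model, ctx, x) {
  ck <- gram_key(ctx)
  v <- get0(ck, envir = model$counts, inherits = FALSE)
  xs <- as.character(x)
  if (is.null(v)) v <- numeric(0)
  v[xs] <- (if (xs %in% names(v)) v[[xs]] else 0) + 1
  assign(ck, v, envir = model$counts)
  invisible(model)
}

#' Raw m-gram count
#'
#' @param model an `ngram_model`.
#' @param gram integer vector of pitches (length 1..k+1).
#' @return the occurrence count (0 if unseen).
#' @export
ngram_count <- function(model, gram) {
  v <- cont_table(model, gram[-length(gram)])
  xs <- as.character(gram[length(gram)])
  if (is.null(v) || !xs %in% names(v)) 0 else v[[xs]]
}

#' Train a long-term n-gram model on a corpus
#'
#' Counts all m-grams, 1 <= m <= k+1, pooled across compositions. Grams
#' never cross composition boundaries. Unigram contexts (the empty context)
#' are registered for every note.
#'
#' @param corpus a note table (one or more compositions).
#' @param order_bound maximum context length k.
#' @return a trained `ngram_model` in `"ltm"` mode.
#' @export
ngram_train <- function(corpus, order_bound) {
  corpus <- validate_notes(corpus)
  model <- ngram_model(order_bound, "ltm")
  for (pitches in split(corpus$pitch, corpus$composition_id)) {
    n <- length(pitches)
    for (t in seq_len(n)) {
      for (m in 0:min(order_bound, t - 1L)) {
        add_gram(model, if (m > 0) pitches[(t - m):(t - 1L)] else integer(0), pitches[t])
      }
    }
  }
  model
}

#' Online update of a short-term n-gram model
#'
#' Increments all m-gram counts ending at the new note (using the model's
#' own within-composition history) and appends the note to that history.
#' Predictions made before the step therefore use counts from earlier notes
#' only — the model is strictly causal. Call [stm_reset()] at each
#' composition start.
#'
#' @param model an `ngram_model` in `"stm"` mode.
#' @param new_note pitch of the incoming note.
#' @return the updated model (environments are shared; reassignment keeps
#'   the updated history).
#' @export
stm_step <- function(model, new_note) {
  if (model$mode != "stm") abort("stm_step requires an stm-mode model")
  h <- model$history
  t <- length(h) + 1L
  for (m in 0:min(model$order_bound, t - 1L)) {
    add_gram(model, if (m > 0) h[(t - m):(t - 1L)] else integer(0), new_note)
  }
  model$history <- c(h, as.integer(new_note))
  model
}

#' @rdname stm_step
#' @export
stm_reset <- function(model) {
  if (model$mode != "stm") abort("stm_reset requires an stm-mode model")
  ngram_model(model$order_bound, "stm")
}

#' Next-pitch prediction from an n-gram model
#'
#' Maximum-likelihood estimates of all orders 0..min(k, context length) are
#' blended by interpolated back-off: at each order the escape mass
#' `d / (N + d)` (d = distinct continuations, N = total continuations of the
#' context; an escape rule in the style of prediction by partial matching)
#' is given to the next-lower order, recursing to a uniform 1/128 base, and
#' the final distribution is floored by mixing with uniform at weight
#' `floor_weight`. Every pitch therefore has nonzero probability.
#'
#' @param model an `ngram_model`.
#' @param context integer vector of preceding pitches; truncated to the most
#'   recent `order_bound` notes.
#' @param floor_weight uniform floor weight.
#' @return a [pitch_distribution()].
#' @export
ngram_predict <- function(model, context, floor_weight = 1e-6) {
  context <- as.integer(context)
  m0 <- min(model$order_bound, length(context))
  p <- rep(1 / N_PITCH, N_PITCH)
  for (m in 0:m0) {
    ctx <- if (m > 0) tail(context, m) else integer(0)
    v <- cont_table(model, ctx)
    if (is.null(v) || sum(v) == 0) next
    N <- sum(v)
    d <- length(v)
    ml <- numeric(N_PITCH)
    ml[as.integer(names(v)) + 1L] <- v / N
    e <- d / (N + d)
    p <- (1 - e) * ml + e * p
  }
  pitch_distribution(floor_distribution(p, floor_weight))
}

#' Raw relative-frequency estimate for one continuation
#'
#' The unsmoothed n-gram ratio `count(context, x) / count(context)`, using
#' the raw occurrence count of the context m-gram (diagnostic; the smoothed
#' predictive distribution comes from [ngram_predict()]).
#'
#' @param model an `ngram_model`.
#' @param context integer vector of preceding pitches (length >= 1).
#' @param x candidate next pitch.
#' @return the raw ratio, or `NA` if the context was never seen.
#' @export
ngram_raw_ratio <- function(model, context, x) {
  ctx_count <- ngram_count(model, context)
  if (ctx_count == 0) return(NA_real_)
  ngram_count(model, c(context, x)) / ctx_count
}

#' Combine stm and ltm predictions with entropy-derived weights
#'
#' Each model's weight is proportional to its relative entropy
#' `(H / log(128))^(-bias)`, normalised over the two models, so the more
#' confident model dominates. The default combination is a geometric
#' (log-linear) mixture, renormalised; an arithmetic mixture is available.
#'
#' @param stm_dist,ltm_dist [pitch_distribution()]s.
#' @param bias exponent of the entropy weighting (default 1).
#' @param mixture `"geometric"` (default) or `"arithmetic"`.
#' @return a list with `dist` (the combined [pitch_distribution()]) and
#'   `weights` (named vector, `stm` and `ltm`, summing to 1).
#' @export
combine_both <- function(stm_dist, ltm_dist, bias = 1,
                         mixture = c("geometric", "arithmetic")) {
  mixture <- match.arg(mixture)
  stm_dist <- pitch_distribution(stm_dist)
  ltm_dist <- pitch_distribution(ltm_dist)
  h <- c(stm = uncertainty(stm_dist), ltm = uncertainty(ltm_dist)) / log(N_PITCH)
  eps <- 1e-12
  w <- pmax(h, eps)^(-bias)
  w <- w / sum(w)
  p <- if (mixture == "geometric") {
    exp(w[["stm"]] * log(stm_dist) + w[["ltm"]] * log(ltm_dist))
  } else {
    w[["stm"]] * stm_dist + w[["ltm"]] * ltm_dist
  }
  list(dist = pitch_distribution(p / sum(p)), weights = w)
}
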
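# Independent oracle implementations used across tests. These deliberately
# re-derive quantities from first principles (naive enumeration, direct
# recursion) and must stay independent of the package's own code paths.

# Brute-force Gestalt-model predictive distribution: direct triple loop over
# central pitch c, key and candidate pitch x, with the posterior over (c,
# key) accumulated context note by context note.
oracle_temperley <- function(context, params, floor_weight = 1e-6) {
  xs <- 0:127
  keyw <- matrix(0, 24, 128)
  tonics <- rep(0:11, 2)
  for (k in 1:24) {
    for (x in xs) keyw[k, x + 1] <- params$key_profiles[k, ((x - tonics[k]) %% 12) + 1]
  }
  if (params$var_c0 > 0) {
    pc <- stats::dnorm(xs, params$c0, sqrt(params$var_c0))
  } else {
    pc <- as.numeric(xs == floor(params$c0 + 0.5))
  }
  pc <- pc / sum(pc)
  pk <- c(rep(params$p_maj / 12, 12), rep((1 - params$p_maj) / 12, 12))
  note_lik <- function(c, k, x, prev) {
    w <- stats::dnorm(xs, c, sqrt(params$v_r)) * keyw[k, ]
    if (!is.null(prev)) w <- w * stats::dnorm(xs, prev, sqrt(params$v_x))
    w[x + 1] / sum(w)
  }
  post <- matrix(0, 128, 24)
  for (c in xs) for (k in 1:24) {
    lp <- log(pc[c + 1]) + log(pk[k])
    for (t in seq_along(context)) {
      prev <- if (t > 1) context[t - 1] else NULL
      lik <- note_lik(c, k, context[t], prev)
      lp <- lp + log(max(lik, 5e-324))
    }
    post[c + 1, k] <- lp
  }
  post <- exp(post - max(post))
  post <- post / sum(post)
  prev <- if (length(context) > 0) context[length(context)] else NULL
  pred <- numeric(128)
  for (c in xs) for (k in 1:24) {
    if (post[c + 1, k] == 0) next
    w <- stats::dnorm(xs, c, sqrt(params$v_r)) * keyw[k, ]
    if (!is.null(prev)) w <- w * stats::dnorm(xs, prev, sqrt(params$v_x))
    pred <- pred + post[c + 1, k] * w / sum(w)
  }
  pred <- pred / sum(pred)
  pred <- (1 - floor_weight) * pred + floor_weight / 128
  pred / sum(pred)
}

# Direct recursion of the interpolated back-off smoothing on explicit hand
# counts. `grams` is a list of integer vectors (every occurrence of every
# m-gram, 1 <= m <= k+1) built by brute force from the training pitches.
oracle_ngram_predict <- function(pitch_seqs, order_bound, context,
                                 floor_weight = 1e-6) {
  count_gram <- function(g) {
    total <- 0L
    for (p in pitch_seqs) {
      n <- length(p)
      m <- length(g)
      if (n < m) next
      for (s in seq_len(n - m + 1L)) {
        if (all(p[s:(s + m - 1L)] == g)) total <- total + 1L
      }
    }
    total
  }
  # continuation counts: occurrences of ctx followed by x, where ctx may be
  # empty (then every note is a continuation)
  cont_counts <- function(ctx) {
    v <- numeric(128)
    for (x in 0:127) v[x + 1] <- count_gram(c(ctx, x))
    v
  }
  m0 <- min(order_bound, length(context))
  p <- rep(1 / 128, 128)
  for (m in 0:m0) {
    ctx <- if (m > 0) context[(length(context) - m + 1L):length(context)] else integer(0)
    v <- cont_counts(ctx)
    N <- sum(v)
    if (N == 0) next
    d <- sum(v > 0)
    e <- d / (N + d)
    p <- (1 - e) * (v / N) + e * p
  }
  p <- (1 - floor_weight) * p + floor_weight / 128
  p / sum(p)
}

# Textbook step-down Holm adjustment.
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (i in seq_len(n)) {
    running <- max(running, (n - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

floor_dist_helper <- function(p, w = 1e-6) {
  q <- (1 - w) * p + w / 128
  q / sum(q)
}

# small deterministic corpus used in several tests
tiny_corpus <- function() {
  dplyr::bind_rows(
    note_sequence(c(60, 62, 64, 62, 60), 0:4 / 4, 0.2, "a"),
    note_sequence(c(67, 65, 64, 65, 67, 67), 0:5 / 4, 0.2, "b")
  )
}
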
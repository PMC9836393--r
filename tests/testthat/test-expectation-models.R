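test_that("surprise and uncertainty match their closed forms", {
  u <- uniform_pitch_distribution()
  expect_equal(surprise(u, 60), log(128), tolerance = 1e-12)
  expect_equal(uncertainty(u), log(128), tolerance = 1e-12)
  expect_equal(round(uncertainty(u), 2), 4.85)

  onehot <- pitch_distribution(as.numeric(0:127 == 72))
  expect_equal(surprise(onehot, 72), 0)
  expect_equal(uncertainty(onehot), 0)

  half <- pitch_distribution(c(0.5, 0.5, rep(0, 126)))
  expect_equal(surprise(half, 0), log(2), tolerance = 1e-12)
  expect_equal(uncertainty(half), log(2), tolerance = 1e-12)
  expect_error(surprise(u, 128), "pitch")
})

test_that("pitch distributions reject invalid vectors", {
  expect_error(pitch_distribution(rep(1, 128)), "sum")
  expect_error(pitch_distribution(c(-0.1, 1.1, rep(0, 126))), "negative")
  expect_error(pitch_distribution(rep(1 / 64, 64)), "128")
})

test_that("Gestalt predictions match the brute-force (c x key x pitch) enumeration", {
  params <- temperley_params()
  contexts <- list(integer(0), 60L, c(60L, 64L, 67L), c(72L, 71L, 69L, 67L))
  for (ctx in contexts) {
    got <- unname(temperley_predict(ctx, params))
    want <- oracle_temperley(ctx, params)
    expect_lt(max(abs(got - want)), 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("Gestalt model limits behave as the principles dictate", {
  # empty context, uniform key profiles: shape follows the marginal
  # N(c0, var_c0 + v_r); mode at the central pitch 72
  flat <- matrix(1 / 12, 24, 12)
  params <- temperley_params(key_profiles = flat)
  d <- temperley_predict(integer(0), params)
  expect_equal(unname(which.max(d)) - 1L, 72L)
  marg <- dnorm(0:127, 72, sqrt(34.4 + 83.2))
  marg <- marg / sum(marg)
  expect_gt(cor(unname(d), marg), 0.9999)

  # overwhelming proximity: tiny v_x after a long run of 60s puts the mode
  # at 60
  params2 <- temperley_params(v_x = 0.25, key_profiles = flat)
  d2 <- temperley_predict(rep(60L, 8), params2)
  expect_equal(unname(which.max(d2)) - 1L, 60L)
})

test_that("Gestalt parameters are fitted as corpus moments", {
  one <- note_sequence(rep(70L, 6), 0:5 / 4, 0.2, "const")
  p1 <- fit_temperley_params(one)
  expect_equal(p1$c0, 70)
  expect_equal(p1$var_c0, 0)

  two <- dplyr::bind_rows(
    note_sequence(c(58L, 60L, 62L), 0:2 / 4, 0.2, "lo"),
    note_sequence(c(78L, 80L, 82L), 0:2 / 4, 0.2, "hi")
  )
  p2 <- fit_temperley_params(two)
  expect_equal(p2$c0, 70)
  expect_equal(p2$var_c0, 100) # population variance of (60, 80)
})

test_that("n-gram counting matches brute-force counts and stays prefix-consistent", {
  corp <- note_sequence(c(60, 62, 60, 62, 60), 0:4 / 4, 0.2)
  ng <- ngram_train(corp, 2)
  expect_equal(ngram_count(ng, 60), 3)
  expect_equal(ngram_count(ng, c(60, 62)), 2)
  expect_equal(ngram_count(ng, c(62, 60)), 2)
  expect_equal(ngram_count(ng, c(60, 62, 60)), 2)
  expect_equal(ngram_count(ng, c(62, 61)), 0)

  # prefix consistency on random corpora: every (m+1)-gram count <= its
  # m-gram prefix count, checked against recounting from scratch
  for (seed in c(4, 18)) {
    corpus <- generate_corpus(3, melody_gen_config(n_notes = 40, seed = seed))
    k <- 3
    model <- ngram_train(corpus, k)
    seqs <- split(corpus$pitch, corpus$composition_id)
    brute_count <- function(g) {
      sum(vapply(seqs, function(p) {
        if (length(p) < length(g)) return(0L)
        sum(vapply(seq_len(length(p) - length(g) + 1L), function(s) {
          all(p[s:(s + length(g) - 1L)] == g)
        }, logical(1)))
      }, 0L))
    }
    pitches <- unique(corpus$pitch)
    set.seed(seed)
    for (i in 1:20) {
      g <- sample(pitches, sample(2:(k + 1), 1), replace = TRUE)
      cnt <- ngram_count(model, g)
      expect_equal(cnt, brute_count(g))
      expect_lte(cnt, ngram_count(model, g[-length(g)]))
    }
  }
})

test_that("n-gram prediction matches an independent back-off recursion", {
  # untrained model backs off fully to uniform
  empty <- ngram_model(2, "ltm")
  expect_equal(unname(ngram_predict(empty, c(60, 62))),
               rep(1 / 128, 128), tolerance = 1e-12)

  train <- note_sequence(c(60, 62, 60, 62), 0:3 / 4, 0.2)
  ng <- ngram_train(train, 2)
  d <- ngram_predict(ng, 60L)
  expect_equal(unname(which.max(d)) - 1L, 62L)
  want <- oracle_ngram_predict(list(c(60, 62, 60, 62)), 2, 60L)
  expect_equal(unname(d), want, tolerance = 1e-12)
  # the raw relative-frequency ratio is exposed unsmoothed
  expect_equal(ngram_raw_ratio(ng, 60L, 62L), 1.0)

  # multi-composition, longer context
  corpus <- generate_corpus(2, melody_gen_config(n_notes = 25, seed = 8))
  ng2 <- ngram_train(corpus, 3)
  ctx <- tail(corpus$pitch[corpus$composition_id == "synth001"], 3)
  want2 <- oracle_ngram_predict(split(corpus$pitch, corpus$composition_id), 3, ctx)
  expect_equal(unname(ngram_predict(ng2, ctx)), want2, tolerance = 1e-12)
})

test_that("the short-term model is causal and converges to batch counts", {
  stm <- ngram_model(2, "stm")
  expect_equal(unname(ngram_predict(stm, integer(0))), rep(1 / 128, 128))

  # on a constant sequence, surprise of successive repeats never increases
  s_prev <- Inf
  for (t in 1:8) {
    ctx <- rep(60L, min(t - 1, 2))
    s_now <- surprise(ngram_predict(stm, ctx), 60)
    expect_lte(s_now, s_prev + 1e-12)
    s_prev <- s_now
    stm <- stm_step(stm, 60L)
  }

  # counts after a full causal pass equal batch training on the same piece
  piece <- c(60L, 62L, 64L, 62L, 60L, 59L, 60L)
  stm2 <- ngram_model(2, "stm")
  for (x in piece) stm2 <- stm_step(stm2, x)
  batch <- ngram_train(note_sequence(piece, seq_along(piece) / 4, 0.2), 2)
  for (m in 1:3) {
    for (s in seq_len(length(piece) - m + 1L)) {
      g <- piece[s:(s + m - 1L)]
      expect_equal(ngram_count(stm2, g), ngram_count(batch, g))
    }
  }
})

test_that("stm predictions never depend on future notes", {
  a <- c(60L, 62L, 64L, 65L, 67L, 69L)
  b <- c(60L, 62L, 64L, 71L, 55L, 59L) # same first 3 notes
  pred_at <- function(p, t) {
    stm <- ngram_model(2, "stm")
    for (x in p[seq_len(t - 1)]) stm <- stm_step(stm, x)
    ngram_predict(stm, tail(p[seq_len(t - 1)], 2))
  }
  for (t in 1:4) expect_equal(pred_at(a, t), pred_at(b, t))
})

test_that("entropy weighting of the stm/ltm combination behaves as specified", {
  u <- uniform_pitch_distribution()
  # equal entropies: symmetric weights, normalised geometric mean
  p1 <- pitch_distribution(c(rep(0.25, 2), rep(0.5 / 126, 126)))
  p2 <- pitch_distribution(c(rep(0.5 / 126, 126), rep(0.25, 2)))
  cb <- combine_both(p1, p2)
  expect_equal(unname(cb$weights), c(0.5, 0.5))
  gm <- sqrt(p1 * p2)
  expect_equal(unname(cb$dist), unname(gm / sum(gm)), tolerance = 1e-12)

  # a near-one-hot stm dominates
  sharp <- pitch_distribution(floor_dist_helper(as.numeric(0:127 == 64)))
  cb2 <- combine_both(sharp, u)
  expect_gt(cb2$weights[["stm"]], 0.95)

  # random pair: output sums to 1 and matches the stated formula directly
  set.seed(12)
  q1 <- runif(128); q1 <- q1 / sum(q1)
  q2 <- rexp(128); q2 <- q2 / sum(q2)
  cb3 <- combine_both(pitch_distribution(q1), pitch_distribution(q2), bias = 2)
  h <- c(-sum(q1 * log(q1)), -sum(q2 * log(q2))) / log(128)
  w <- h^(-2) / sum(h^(-2))
  direct <- exp(w[1] * log(q1) + w[2] * log(q2))
  direct <- direct / sum(direct)
  expect_equal(unname(cb3$dist), direct, tolerance = 1e-12)
  expect_equal(sum(cb3$dist), 1, tolerance = 1e-9)
})

test_that("every predictor returns a valid distribution on random contexts", {
  corpus <- generate_corpus(2, melody_gen_config(n_notes = 30, seed = 3))
  ng <- ngram_train(corpus, 2)
  preds <- list(uniform_predictor(), temperley_predictor(), ltm_predictor(ng),
                generator_predictor(melody_gen_config(seed = 1)))
  set.seed(99)
  for (i in 1:5) {
    ctx <- sample(40:90, sample(0:4, 1), replace = TRUE)
    for (p in preds) {
      d <- predict_pitch(p, ctx)
      expect_true(all(d >= 0))
      expect_equal(sum(d), 1, tolerance = 1e-9)
    }
  }
})

test_that("evaluation scores the first note against the uniform prior", {
  single <- note_sequence(72, 0, 0.3, "solo")
  ev <- evaluate_model(uniform_predictor(), single, k = 2)
  expect_equal(ev$notes$surprise, log(128), tolerance = 1e-6)
  expect_equal(ev$notes$uncertainty, log(128), tolerance = 1e-6)

  # chance-level expected accuracy of the uniform predictor is 1/128
  corpus <- generate_corpus(2, melody_gen_config(n_notes = 20, seed = 6))
  ev2 <- evaluate_model(uniform_predictor(), corpus, k = 1)
  expect_equal(mean(exp(-ev2$notes$surprise)), 1 / 128, tolerance = 1e-9)
})

test_that("a matched predictor identifies its own generator against a key-shuffled one", {
  cfg <- melody_gen_config(n_notes = 50, key = list(tonic = 2L, mode = "major"),
                           motif_repeat_prob = 0, seed = 55)
  shuffled <- cfg
  shuffled$key <- list(tonic = 8L, mode = "minor")
  corpus <- generate_corpus(50, cfg)
  ev_m <- evaluate_model(generator_predictor(cfg), corpus, k = 2)
  ev_s <- evaluate_model(generator_predictor(shuffled), corpus, k = 2)
  per_piece_m <- ev_m$by_composition$cross_entropy
  per_piece_s <- ev_s$by_composition$cross_entropy
  tt <- t.test(per_piece_m, per_piece_s, paired = TRUE, alternative = "less")
  expect_lt(tt$p.value, 0.01)
  expect_gt(median(ev_m$by_composition$accuracy), 1 / 128)
})

test_that("surprise tables round-trip through CSV and validate alignment", {
  corpus <- generate_corpus(2, melody_gen_config(n_notes = 15, seed = 2))
  ev <- evaluate_model(stm_predictor(), corpus, k = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_surprise_table(ev, path)
  back <- load_external_surprise(path, corpus)
  expect_equal(back$surprise, ev$notes$surprise, tolerance = 1e-12)
  expect_equal(back$uncertainty, ev$notes$uncertainty, tolerance = 1e-12)

  short <- ev$notes[-1, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_surprise_table(short, path2)
  expect_error(load_external_surprise(path2, corpus), "misaligned")

  bad <- ev$notes
  bad$uncertainty[1] <- 5.0
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_surprise_table(bad, path3)
  expect_error(load_external_surprise(path3), "uncertainty")
})
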
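test_that("binary note flags follow their definitions", {
  s <- note_sequence(c(60, 60, 62, 70, 50), 0:4 / 2, 0.3, "a")
  ft <- build_feature_table(s)
  expect_equal(ft$repetition, c(0L, 1L, 0L, 0L, 0L))
  expect_equal(ft$composition_onset, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(ft$onset_flag, rep(1L, 5))
  # strict quantile rule: 70 is the only pitch above the 90% quantile when
  # it is extreme enough, 50 below the 10% one
  expect_equal(ft$high_pitch, as.integer(s$pitch > quantile(s$pitch, 0.9)))
  expect_equal(ft$low_pitch, as.integer(s$pitch < quantile(s$pitch, 0.1)))

  # all pitches equal: strict inequalities flag nothing
  s2 <- note_sequence(rep(64, 4), 0:3 / 2, 0.3, "b")
  ft2 <- build_feature_table(s2)
  expect_true(all(ft2$high_pitch == 0L))
  expect_true(all(ft2$low_pitch == 0L))

  # composition onset marks the first note of every composition
  both <- dplyr::bind_rows(s, s2)
  ft3 <- build_feature_table(both)
  expect_equal(sum(ft3$composition_onset), 2L)
})

test_that("per-note RMS matches closed forms", {
  srate <- 8000
  s <- note_sequence(c(60, 62, 64), c(0, 1, 2), 0.5, "x")
  n <- 3 * srate
  audio <- numeric(n)
  tvec <- seq_len(n) / srate
  audio[tvec > 0 & tvec <= 0.5] <- 0.3                 # constant amplitude
  idx2 <- tvec > 1 & tvec <= 1.5
  audio[idx2] <- 0.8 * sin(2 * pi * 40 * tvec[idx2])    # whole periods of a sine
  r <- rms_per_note(audio, srate, s)
  expect_equal(r[1], 0.3, tolerance = 1e-3)
  expect_equal(r[2], 0.8 / sqrt(2), tolerance = 1e-3)
  expect_equal(r[3], 0)                                 # silence
})

test_that("spectral flatness separates noise from tones", {
  srate <- 8000
  s <- note_sequence(c(60, 62, 64), c(0, 1, 2), 0.5, "x")
  n <- 3 * srate
  set.seed(5)
  audio <- numeric(n)
  tvec <- seq_len(n) / srate
  audio[tvec > 0 & tvec <= 0.5] <- rnorm(sum(tvec > 0 & tvec <= 0.5))
  idx2 <- tvec > 1 & tvec <= 1.5
  audio[idx2] <- sin(2 * pi * 440 * tvec[idx2])
  # third note: a single impulse has an exactly flat magnitude spectrum
  audio[which(tvec > 2)[1]] <- 1
  fl <- flatness_per_note(audio, srate, s)
  expect_gt(fl[1], 0.7)   # white noise: near 1
  expect_lt(fl[2], 0.1)   # pure tone: near 0
  expect_equal(fl[3], 1, tolerance = 1e-9)

  # an all-zero window is defined as 0
  s0 <- note_sequence(60, 0.2, 0.1, "z")
  expect_equal(flatness_per_note(numeric(srate), srate, s0), 0)
})

test_that("envelope variance indexes amplitude modulation", {
  srate <- 16000
  dur <- 0.5
  tvec <- seq(0, 2, by = 1 / srate)[-1]
  steady <- sin(2 * pi * 500 * tvec)
  am <- sqrt(2) * sin(2 * pi * 500 * tvec) * (0.5 + 0.5 * sin(2 * pi * 8 * tvec))
  audio <- numeric(length(tvec))
  audio[tvec <= dur] <- steady[tvec <= dur]
  idx <- tvec > 1 & tvec <= 1 + dur
  audio[idx] <- am[idx]
  s <- note_sequence(c(60, 62), c(0, 1), dur, "x")
  ev <- envelope_variance_per_note(audio, srate, s)
  expect_gt(ev[2], ev[1] * 2)

  s0 <- note_sequence(60, 0.2, 0.2, "z")
  expect_equal(envelope_variance_per_note(numeric(srate), srate, s0), 0)
})

test_that("acoustic features are invariant to shifting audio and onsets together", {
  srate <- 8000
  set.seed(8)
  burst <- rnorm(srate / 2)
  audio1 <- c(burst, numeric(srate))
  audio2 <- c(numeric(srate), burst, numeric(srate))
  s1 <- note_sequence(60, 0, 0.5, "a")
  s2 <- note_sequence(60, 1, 0.5, "a")
  expect_equal(rms_per_note(audio1, srate, s1), rms_per_note(audio2, srate, s2),
               tolerance = 1e-9)
  expect_equal(flatness_per_note(audio1, srate, s1),
               flatness_per_note(audio2, srate, s2), tolerance = 1e-9)
})

test_that("impulse placement, z-scoring and collision handling work", {
  s <- note_sequence(c(60, 61, 62), c(1.0, 2.0, 3.0), 0.4, "x")
  ft <- build_feature_table(s, acoustics = tibble::tibble(rms = c(0.1, 0.5, 0.9)))
  regs <- to_impulse_regressors(ft, 60, 300)
  # one note at t = 1.0 s on a 60 Hz grid lands on sample index 61 (1-based)
  expect_equal(which(regs$matrix[, "onset_flag"] != 0), c(61L, 121L, 181L))
  # continuous columns are z-scored over note entries
  v <- regs$matrix[regs$onset_samples, "rms"]
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sd(v), 1, tolerance = 1e-12)
  # binary columns placed as-is; nonzero count equals the table count
  expect_equal(sum(regs$matrix[, "onset_flag"] != 0), sum(ft$onset_flag != 0))
  expect_equal(sum(regs$matrix[, "repetition"] != 0), sum(ft$repetition != 0))

  # collision: two notes inside one sample period
  s2 <- note_sequence(c(60, 61), c(1.000, 1.004), 0.2, "y")
  ft2 <- build_feature_table(s2)
  expect_error(to_impulse_regressors(ft2, 60, 120), "same sample")
  expect_error(to_impulse_regressors(ft, 60, 100), "beyond")
})

test_that("surprise columns join by composition and note index", {
  corpus <- generate_corpus(2, melody_gen_config(n_notes = 12, seed = 4))
  ev <- evaluate_model(stm_predictor(), corpus, k = 2)
  ft <- build_feature_table(corpus, surprise = ev)
  expect_true(all(c("surprise", "uncertainty") %in% names(ft)))
  expect_equal(nrow(ft), nrow(corpus))
  expect_error(build_feature_table(corpus, surprise = ev$notes[-1, ]), "misaligned")
})
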
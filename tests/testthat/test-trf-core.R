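# shared fixture: a small noiseless simulation with two regressors
make_sim <- function(n_notes = 150, srate = 50, n_channels = 4, noise_sd = 0,
                     seed = 7, tempo = 3) {
  m <- generate_melody(melody_gen_config(n_notes = n_notes, seed = seed,
                                         tempo = tempo))
  truth <- list(onset = default_truth_kernel(n_channels, srate),
                surprise = default_truth_kernel(n_channels, srate, amplitude = 0.5))
  sv <- with(list(), {set.seed(seed + 1); as.vector(scale(rnorm(n_notes)))})
  sim <- simulate_neural(m, list(onset = rep(1, n_notes), surprise = sv),
                         neural_sim_config(n_channels, srate, truth,
                                           noise_sd = noise_sd, seed = seed))
  ft <- build_feature_table(m)
  ft$surprise <- sv
  regs <- to_impulse_regressors(ft, srate, ncol(sim$recording$data),
                                features = c("onset_flag", "surprise"))
  design <- time_expand(regs, -0.2, 1)
  list(sim = sim, design = design, truth = truth, srate = srate)
}

kernel_rows <- function(design, truth_lags, srate) {
  match(round(truth_lags * srate), round(design$lags * srate))
}

test_that("band-pass filtering has the intended frequency response", {
  srate <- 100
  n <- 30 * srate
  tvec <- seq_len(n) / srate
  gain_at <- function(f) {
    x <- if (f == 0) rep(1, n) else sin(2 * pi * f * tvec)
    rec <- neural_recording(matrix(x, 1), srate)
    y <- bandpass(rec, 0.5, 8)$data[1, ]
    mid <- seq(n / 4, 3 * n / 4)
    sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2))
  }
  expect_lt(gain_at(0), 0.05)          # DC removed
  expect_gt(gain_at(4), 0.9)           # passband
  expect_lt(gain_at(4), 1.1)
  expect_lt(gain_at(20), 0.1)          # stopband
  expect_error(bandpass(neural_recording(matrix(0, 1, 100), 30), 8, 20), "srate/2")
})

test_that("bad samples are dilated by the filter half-length", {
  srate <- 50
  rec <- neural_recording(matrix(rnorm(20 * srate), 1), srate,
                          bad_mask = replace(rep(FALSE, 20 * srate), 500, TRUE))
  out <- bandpass(rec, 0.5, 8, order = 100)
  expect_true(all(out$bad_mask[450:550]))
  expect_false(out$bad_mask[400])
})

test_that("time expansion produces the documented lag geometry", {
  imp <- structure(list(matrix = matrix(0, 600, 1), features = "f", srate = 60,
                        onset_samples = 30L), class = "impulse_regressors")
  d <- time_expand(imp, -0.2, 1)
  expect_equal(length(d$lags), 73L)
  expect_equal(ncol(d$matrix), 73L)

  imp10 <- structure(list(matrix = matrix(0, 100, 1), features = "f", srate = 10,
                          onset_samples = 10L), class = "impulse_regressors")
  d10 <- time_expand(imp10, 0, 0.5)
  expect_equal(length(d10$lags), 6L)
})

test_that("design-times-kernel reproduces convolution for impulse regressors", {
  srate <- 20
  n <- 200
  set.seed(3)
  imp_vec <- numeric(n)
  spots <- sort(sample(20:150, 6))
  imp_vec[spots] <- rnorm(6)
  imp <- structure(list(matrix = matrix(imp_vec, n, 1), features = "f",
                        srate = srate, onset_samples = spots),
                   class = "impulse_regressors")
  d <- time_expand(imp, 0, 0.5)
  kern <- rnorm(length(d$lags))
  direct <- as.vector(d$matrix %*% kern)
  conv <- numeric(n)
  for (j in seq_along(kern)) {
    lag <- d$lag_samples[j]
    src <- seq_len(n) - lag
    ok <- src >= 1 & src <= n
    conv[ok] <- conv[ok] + kern[j] * imp_vec[src[ok]]
  }
  expect_equal(direct, conv, tolerance = 1e-12)
})

test_that("OLS recovers ground-truth kernels exactly on noiseless data", {
  fx <- make_sim()
  fit <- fit_ols(fx$design, fx$sim$recording)
  idx <- kernel_rows(fx$design, fx$truth$onset$lags, fx$srate)
  expect_lt(max(abs(trf_kernel(fit, "onset_flag")[idx, ] - fx$truth$onset$kernels)),
            1e-8)
  expect_lt(max(abs(trf_kernel(fit, "surprise")[idx, ] - fx$truth$surprise$kernels)),
            1e-8)
  # lags outside the true kernel support come back (numerically) zero
  outside <- setdiff(seq_along(fx$design$lags), idx)
  expect_lt(max(abs(trf_kernel(fit, "onset_flag")[outside, ])), 1e-8)
})

test_that("a regressor predicting itself yields a delta at lag zero", {
  n <- 400
  set.seed(11)
  v <- numeric(n)
  spots <- seq(10, 390, by = 10)
  v[spots] <- rnorm(length(spots))
  imp <- structure(list(matrix = matrix(v, n, 1), features = "f", srate = 20,
                        onset_samples = spots), class = "impulse_regressors")
  d <- time_expand(imp, -0.2, 0.5)
  rec <- neural_recording(matrix(v, 1), 20)
  fit <- fit_ols(d, rec)
  k <- trf_kernel(fit, "f")[, 1]
  expect_equal(k[d$lag_samples == 0], 1, tolerance = 1e-8)
  expect_lt(max(abs(k[d$lag_samples != 0])), 1e-8)
})

test_that("rank-deficient designs are refused with the offending columns named", {
  fx <- make_sim(n_notes = 60)
  M <- fx$design
  M$matrix <- cbind(M$matrix, M$matrix[, 1, drop = FALSE])
  colnames(M$matrix)[ncol(M$matrix)] <- "dup_col"
  M$regressors <- c(M$regressors, "dup")
  expect_error(fit_ols(M, fx$sim$recording), "rank deficient")
})

test_that("ridge shrinks toward zero and equals OLS at alpha zero", {
  fx <- make_sim(n_notes = 80)
  f0 <- fit_ols(fx$design, fx$sim$recording)
  fr <- fit_ridge(fx$design, fx$sim$recording, alphas = 0)
  expect_equal(fr$coefficients, f0$coefficients, tolerance = 1e-6)

  fbig <- fit_ridge(fx$design, fx$sim$recording, alphas = 1e12)
  expect_lt(max(abs(fbig$coefficients)), 1e-3 * max(abs(f0$coefficients)))
})

test_that("nested CV keeps ridge at a negligible penalty on high-SNR data", {
  fx <- make_sim(n_notes = 200, noise_sd = 0.05, seed = 13)
  r_ols <- summary_r(cv_predictive_r(fx$design, fx$sim$recording, label = "ols"))
  cv_r <- cv_predictive_r(fx$design, fx$sim$recording, method = "ridge",
                          alphas = c(0, 1, 10, 100), label = "ridge")
  expect_lt(abs(summary_r(cv_r) - r_ols), 0.005)
})

test_that("cross-validated r behaves at the noise extremes", {
  fx <- make_sim(noise_sd = 0)
  expect_gt(summary_r(cv_predictive_r(fx$design, fx$sim$recording, label = "x")),
            0.99)

  # pure noise: mean summary r near zero across seeded runs
  rs <- vapply(1:20, function(s) {
    n <- 1500
    set.seed(s)
    rec <- neural_recording(matrix(rnorm(2 * n), 2), 25)
    m <- generate_melody(melody_gen_config(n_notes = 100, seed = s, tempo = 2))
    ft <- build_feature_table(m)
    regs <- to_impulse_regressors(ft, 25, n, features = "onset_flag")
    d <- time_expand(regs, -0.1, 0.5)
    summary_r(cv_predictive_r(d, rec, label = "null"))
  }, 0)
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("duplicated channels get identical cross-validated r", {
  fx <- make_sim(n_notes = 80, noise_sd = 0.3, seed = 5)
  rec <- fx$sim$recording
  rec2 <- neural_recording(rbind(rec$data[1, ], rec$data[1, ]), rec$srate,
                           channel_ids = c("a", "b"))
  cv <- cv_predictive_r(fx$design, rec2, label = "dup")
  wide <- tidyr::pivot_wider(cv$folds, names_from = "channel", values_from = "r")
  expect_equal(wide$a, wide$b, tolerance = 1e-12)
})

test_that("test rows never inform the fit or the scaling", {
  fx <- make_sim(n_notes = 100, noise_sd = 0.2, seed = 9)
  cv1 <- cv_predictive_r(fx$design, fx$sim$recording, label = "x",
                         keep_fits = TRUE)
  # corrupt the data inside fold 1's test block only: fold 1's own fit
  # (trained on the other blocks, with train-only scaling) must not change
  n <- ncol(fx$sim$recording$data)
  block1 <- which(cut(seq_len(n), 5, labels = FALSE) == 1)
  data2 <- fx$sim$recording$data
  data2[, block1] <- data2[, block1] * 3 + 100
  rec2 <- neural_recording(data2, fx$sim$recording$srate,
                           channel_ids = fx$sim$recording$channel_ids)
  cv2 <- cv_predictive_r(fx$design, rec2, label = "x", keep_fits = TRUE)
  expect_equal(cv2$fits[[1]]$beta, cv1$fits[[1]]$beta, tolerance = 1e-12)
  expect_equal(cv2$fits[[1]]$intercept, cv1$fits[[1]]$intercept,
               tolerance = 1e-12)
})

test_that("channel selection applies the strict quantile rule", {
  mk_cv <- function(rvals) {
    structure(list(by_channel = tibble::tibble(
      channel = sprintf("ch%02d", seq_along(rvals)), r = rvals),
      folds = NULL, label = "onset", n_folds = 5),
      class = "trf_cv")
  }
  sel <- select_channels(mk_cv(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)))
  expect_setequal(sel, c("ch05", "ch06"))
  expect_warning(sel2 <- select_channels(mk_cv(rep(0.3, 6))), "all channels")
  expect_equal(length(sel2), 6L)
  # invariant to channel ordering
  sel3 <- select_channels(mk_cv(c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1)))
  expect_setequal(sel3, c("ch01", "ch02"))
  expect_error(select_channels(mk_cv(c(0.1, 0.2))), "3 channels")
})

test_that("model comparison matches the textbook Holm step-down", {
  set.seed(2)
  perf <- tidyr::expand_grid(participant = 1:10,
                             model = c("a", "b", "c")) |>
    dplyr::mutate(r = rnorm(dplyr::n(), mean = ifelse(model == "a", 0.1, 0.08),
                            sd = 0.02))
  out <- compare_models(perf, list(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(out$p_holm, oracle_holm(out$p), tolerance = 1e-12)
  # degenerate contrast: identical models
  perf2 <- dplyr::bind_rows(perf,
                            dplyr::mutate(dplyr::filter(perf, model == "a"),
                                          model = "a2"))
  out2 <- compare_models(perf2, list(c("a", "a2")))
  expect_true(is.na(out2$t))
  expect_equal(out2$mean_diff, 0)
})

test_that("a single-k sweep equals direct evaluation", {
  cfg <- melody_gen_config(n_notes = 60, seed = 40, tempo = 3,
                           motif_repeat_prob = 0)
  corpus <- generate_corpus(2, cfg)
  shifted <- melotrf:::shift_onsets(corpus, gap = 1)
  truth <- list(onset = default_truth_kernel(3, 40))
  rec <- simulate_neural(shifted, list(onset = rep(1, nrow(shifted))),
                         neural_sim_config(3, 40, truth, noise_sd = 0.5,
                                           seed = 4))$recording
  ft <- build_feature_table(shifted)
  sw <- context_sweep(list(gen = function(k) generator_predictor(cfg)),
                      k_values = 2, corpus = shifted,
                      recordings = list(rec), base_features = ft,
                      t_min = -0.1, t_max = 0.6)
  expect_equal(nrow(sw$sweep), 1L)
  ev <- evaluate_model(generator_predictor(cfg), shifted, 2)
  expect_equal(sw$sweep$accuracy, glance(ev)$accuracy)
})
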
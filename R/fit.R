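new_trf_model <- function(coef_array, lags, regressors, channel_ids, method,
                          intercept, alpha = NA_real_) {
  structure(list(coefficients = coef_array, lags = lags, regressors = regressors,
                 channel_ids = channel_ids, method = method,
                 intercept = intercept, alpha = alpha),
            class = "trf_model")
}

coef_to_array <- function(beta, regressors, n_lags, channel_ids, lags) {
  arr <- array(beta, dim = c(n_lags, length(regressors), length(channel_ids)))
  arr <- aperm(arr, c(2, 1, 3)) # regressors x lags x channels
  dimnames(arr) <- list(regressors, NULL, channel_ids)
  arr
}

#' Ordinary-least-squares TRF estimation
#'
#' Per-channel least-squares solution of the time-expanded regression
#' `y = M beta + e` on valid rows, via QR decomposition (no explicit
#' inversion). An intercept is always included and reported separately.
#' Rank-deficient designs raise an error naming the collinear columns,
#' unless `pseudo_inverse = TRUE`, which returns the minimum-norm solution
#' and flags it in the output.
#'
#' @param design a [time_expand()] design.
#' @param rec a [neural_recording()] on the same grid.
#' @param pseudo_inverse fall back to the pseudo-inverse on rank deficiency.
#' @return a `trf_model`: coefficient array regressors x lags x channels,
#'   lag times, per-channel intercepts, fit method.
#' @export
fit_ols <- function(design, rec, pseudo_inverse = FALSE) {
  stopifnot(inherits(design, "trf_design"), inherits(rec, "neural_recording"))
  rows <- which(design$valid & !rec$bad_mask)
  M <- cbind(`(Intercept)` = 1, design$matrix[rows, , drop = FALSE])
  if (length(rows) < ncol(M)) abort("fewer valid rows than design columns")
  y <- t(rec$data[, rows, drop = FALSE])
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    if (!pseudo_inverse) {
      dropped <- colnames(M)[qrM$pivot[(qrM$rank + 1L):ncol(M)]]
      abort(paste0("design matrix is rank deficient; collinear columns: ",
                   paste(dropped, collapse = ", ")))
    }
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  } else {
    beta <- qr.coef(qrM, y)
  }
  n_lags <- length(design$lags)
  mdl <- new_trf_model(
    coef_to_array(beta[-1L, , drop = FALSE], design$regressors, n_lags,
                  rec$channel_ids, design$lags),
    design$lags, design$regressors, rec$channel_ids,
    if (qrM$rank < ncol(M)) "ols (pseudo-inverse)" else "ols",
    intercept = beta[1L, ]
  )
  mdl
}

ridge_solve <- function(M, y, alpha) {
  # intercept unpenalised: centre columns and responses, solve via SVD
  mu_x <- colMeans(M)
  mu_y <- colMeans(y)
  Xc <- sweep(M, 2, mu_x)
  Yc <- sweep(y, 2, mu_y)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[pos]
  shrink <- d / (d^2 + alpha)
  beta <- sv$v[, pos, drop = FALSE] %*% (shrink * (t(sv$u[, pos, drop = FALSE]) %*% Yc))
  intercept <- mu_y - as.vector(t(beta) %*% mu_x)
  list(beta = beta, intercept = intercept)
}

#' Ridge-regularised TRF estimation with nested cross-validated alpha
#'
#' Solves the penalised problem `(M'M + alpha I) beta = M'y` on the centred
#' design (the intercept is never penalised). The penalty `alpha` is chosen
#' from `alphas` by inner cross-validation (contiguous blocks, predictive
#' correlation); `alphas` must include 0, at which the fit coincides with
#' [fit_ols()].
#'
#' @param design a [time_expand()] design.
#' @param rec a [neural_recording()].
#' @param alphas candidate penalties; the set must include 0 so the
#'   unpenalised solution competes. A single value skips the inner CV and is
#'   used as-is.
#' @param inner_folds inner CV folds used to select alpha.
#' @return a `trf_model` with the selected `alpha` recorded.
#' @export
fit_ridge <- function(design, rec, alphas = c(0, 10^(0:4)), inner_folds = 5) {
  stopifnot(inherits(design, "trf_design"), inherits(rec, "neural_recording"))
  if (length(alphas) > 1 && !any(alphas == 0)) abort("alphas must include 0")
  rows <- which(design$valid & !rec$bad_mask)
  M <- design$matrix[rows, , drop = FALSE]
  y <- t(rec$data[, rows, drop = FALSE])
  alpha <- if (length(alphas) > 1) {
    select_alpha(M, y, alphas, inner_folds)
  } else {
    alphas
  }
  fit <- ridge_solve(M, y, alpha)
  new_trf_model(
    coef_to_array(fit$beta, design$regressors, length(design$lags),
                  rec$channel_ids, design$lags),
    design$lags, design$regressors, rec$channel_ids, "ridge",
    intercept = fit$intercept, alpha = alpha
  )
}

select_alpha <- function(M, y, alphas, inner_folds) {
  n <- nrow(M)
  fold_id <- cut(seq_len(n), inner_folds, labels = FALSE)
  score <- vapply(alphas, function(a) {
    rs <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold_id != f
      fit <- ridge_solve(M[tr, , drop = FALSE], y[tr, , drop = FALSE], a)
      pred <- M[!tr, , drop = FALSE] %*% fit$beta +
        matrix(fit$intercept, sum(!tr), ncol(y), byrow = TRUE)
      mean(diag(cor(pred, y[!tr, , drop = FALSE])), na.rm = TRUE)
    }, 0)
    mean(rs)
  }, 0)
  alphas[which.max(score)]
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %s: %d regressors x %d lags x %d channels%s\n",
              x$method, dim(x$coefficients)[1], dim(x$coefficients)[2],
              dim(x$coefficients)[3],
              if (!is.na(x$alpha)) sprintf(" (alpha = %g)", x$alpha) else ""))
  invisible(x)
}

#' Tidy a fitted TRF model
#'
#' @param x a `trf_model`.
#' @param ... unused.
#' @return tibble with columns `regressor`, `lag` (s), `channel`,
#'   `estimate`.
#' @export
tidy.trf_model <- function(x, ...) {
  d <- dim(x$coefficients)
  tibble::tibble(
    regressor = rep(x$regressors, times = d[2] * d[3]),
    lag = rep(rep(x$lags, each = d[1]), times = d[3]),
    channel = rep(x$channel_ids, each = d[1] * d[2]),
    estimate = as.vector(x$coefficients)
  )
}

#' @export
glance.trf_model <- function(x, ...) {
  tibble::tibble(method = x$method, alpha = x$alpha,
                 n_regressors = dim(x$coefficients)[1],
                 n_lags = dim(x$coefficients)[2],
                 n_channels = dim(x$coefficients)[3])
}

#' Extract one regressor's kernel from a TRF model
#'
#' @param model a `trf_model`.
#' @param regressor regressor name.
#' @return matrix lags x channels.
#' @export
trf_kernel <- function(model, regressor) {
  stopifnot(regressor %in% model$regressors)
  k <- model$coefficients[regressor, , ]
  matrix(k, length(model$lags), length(model$channel_ids),
         dimnames = list(NULL, model$channel_ids))
}
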
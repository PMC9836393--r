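#' Configuration for cluster-based TRF statistics
#'
#' @param baseline numeric length-2 window (seconds, before 0) whose mean is
#'   subtracted per participant and channel before testing.
#' @param n_permutations sign-flip permutations (>= 100; default 2000).
#' @param hat_sigma variance-regularisation factor of the hat adjustment
#'   (default 1e-3).
#' @param alpha primary cluster-forming threshold (two-sided, on the hat-t
#'   map).
#' @param tfce_e,tfce_h TFCE extent and height exponents.
#' @param tfce_steps number of TFCE integration levels (>= 50).
#' @param seed seed for the permutation draws.
#' @return a `cluster_test_config` list.
#' @export
cluster_test_config <- function(baseline = c(-0.2, 0), n_permutations = 2000,
                                hat_sigma = 1e-3, alpha = 0.05,
                                tfce_e = 0.5, tfce_h = 2, tfce_steps = 50,
                                seed = 1L) {
  stopifnot(n_permutations >= 100, baseline[1] < baseline[2], baseline[2] <= 0,
            tfce_steps >= 50)
  structure(list(baseline = baseline, n_permutations = as.integer(n_permutations),
                 hat_sigma = hat_sigma, alpha = alpha, tfce_e = tfce_e,
                 tfce_h = tfce_h, tfce_steps = as.integer(tfce_steps),
                 seed = as.integer(seed)),
            class = "cluster_test_config")
}

#' Mass-univariate one-sample t with hat variance adjustment
#'
#' `t = mean / sqrt((var + sigma * max(var)) / n)`, where the variance
#' offset scales with the maximum variance across the tested map. With
#' `sigma = 0` this is the classical one-sample t; the offset keeps t
#' finite where the sample variance is near zero.
#'
#' @param test_data array participants x channels x lags (already
#'   baseline-corrected where appropriate).
#' @param sigma variance offset factor.
#' @return matrix channels x lags of t values.
#' @export
hat_t <- function(test_data, sigma = 1e-3) {
  d <- dim(test_data)
  if (length(d) != 3 || d[1] < 2) abort("need an array participants x channels x lags with >= 2 participants")
  n <- d[1]
  flat <- matrix(test_data, n, d[2] * d[3])
  m <- colMeans(flat)
  v <- colSums(sweep(flat, 2, m)^2) / (n - 1)
  v_adj <- v + sigma * max(v)
  t_flat <- ifelse(v_adj > 0, m / sqrt(v_adj / n), 0)
  matrix(t_flat, d[2], d[3])
}

#' Subtract the baseline-window mean
#'
#' @param test_data array participants x channels x lags.
#' @param lags lag times in seconds (length = third dimension).
#' @param baseline window in seconds.
#' @return the baseline-corrected array.
#' @export
baseline_correct <- function(test_data, lags, baseline = c(-0.2, 0)) {
  idx <- which(lags >= baseline[1] & lags <= baseline[2])
  if (length(idx) == 0) abort("no lags inside the baseline window")
  bl <- apply(test_data[, , idx, drop = FALSE], c(1, 2), mean)
  sweep(test_data, c(1, 2), bl)
}

# neighbour list of the channels x lags lattice: temporal neighbours within
# a channel plus spatially adjacent channels at the same lag
lattice_neighbours <- function(n_channels, n_lags, adjacency) {
  adjacency <- as.matrix(adjacency)
  stopifnot(nrow(adjacency) == n_channels, ncol(adjacency) == n_channels)
  cell <- function(ch, l) (l - 1L) * n_channels + ch
  nb <- vector("list", n_channels * n_lags)
  for (l in seq_len(n_lags)) {
    for (ch in seq_len(n_channels)) {
      ids <- integer(0)
      if (l > 1L) ids <- c(ids, cell(ch, l - 1L))
      if (l < n_lags) ids <- c(ids, cell(ch, l + 1L))
      ids <- c(ids, cell(which(adjacency[ch, ] > 0), l))
      nb[[cell(ch, l)]] <- setdiff(ids, cell(ch, l))
    }
  }
  nb
}

# connected components of the cells where mask is TRUE; returns a list of
# integer cell-index vectors
mask_components <- function(mask, neighbours) {
  todo <- which(mask)
  seen <- logical(length(mask))
  comps <- list()
  for (start in todo) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, v)
      for (u in neighbours[[v]]) {
        if (mask[u] && !seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

cluster_masses <- function(tmap, neighbours, thr) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- as.vector(sgn * tmap > thr)
    for (members in mask_components(mask, neighbours)) {
      out[[length(out) + 1L]] <- list(members = members,
                                      mass = sum(tmap[members]), sign = sgn)
    }
  }
  out
}

#' Ring adjacency for simulated channel arrays
#'
#' @param n_channels channel count.
#' @return binary adjacency matrix where channel i neighbours i-1 and i+1
#'   (wrapping around).
#' @export
ring_adjacency <- function(n_channels) {
  a <- matrix(0L, n_channels, n_channels)
  for (i in seq_len(n_channels)) {
    a[i, (i %% n_channels) + 1L] <- 1L
    a[(i %% n_channels) + 1L, i] <- 1L
  }
  a
}

#' Cluster-based sign-flip permutation test
#'
#' Forms clusters of suprathreshold hat-t values over channel adjacency and
#' temporal contiguity (two-sided primary threshold `alpha` on the t map),
#' and compares each observed cluster's mass against the permutation null
#' of the maximum absolute cluster mass under random per-participant sign
#' flips. P-values use the `(1 + exceedances) / (1 + n_permutations)`
#' correction, so they are never zero.
#'
#' @param test_data array participants x channels x lags,
#'   baseline-corrected (see [baseline_correct()]).
#' @param adjacency channels x channels binary adjacency matrix.
#' @param cfg a [cluster_test_config()].
#' @return an object of class `cluster_result`: tibble `clusters` with
#'   columns `cluster`, `sign`, `mass`, `p`, `n_cells`, plus `members`
#'   (list of (channel, lag) index matrices), the observed `t_map` and the
#'   permutation null distribution.
#' @export
cluster_permutation <- function(test_data, adjacency, cfg = cluster_test_config()) {
  d <- dim(test_data)
  n <- d[1]
  neighbours <- lattice_neighbours(d[2], d[3], adjacency)
  thr <- qt(1 - cfg$alpha / 2, n - 1)
  tmap <- hat_t(test_data, cfg$hat_sigma)
  obs <- cluster_masses(tmap, neighbours, thr)
  flat <- matrix(test_data, n, d[2] * d[3])
  null_max <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_permutations), function(p) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      perm <- array(signs * flat, dim = d)
      pm <- hat_t(perm, cfg$hat_sigma)
      cl <- cluster_masses(pm, neighbours, thr)
      if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
    }, 0)
  })
  clusters <- purrr::imap_dfr(obs, function(cl, i) {
    tibble::tibble(cluster = i, sign = cl$sign, mass = cl$mass,
                   n_cells = length(cl$members),
                   p = (1 + sum(null_max >= abs(cl$mass))) / (1 + cfg$n_permutations))
  })
  if (nrow(clusters) == 0) {
    clusters <- tibble::tibble(cluster = integer(0), sign = numeric(0),
                               mass = numeric(0), n_cells = integer(0), p = numeric(0))
  }
  members <- lapply(obs, function(cl) {
    cbind(channel = ((cl$members - 1L) %% d[2]) + 1L,
          lag = ((cl$members - 1L) %/% d[2]) + 1L)
  })
  structure(list(clusters = clusters, members = members, t_map = tmap,
                 null_max = null_max, cfg = cfg),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations\n",
              nrow(x$clusters), x$cfg$n_permutations))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) x$clusters

tfce_transform <- function(tmap, neighbours, e_exp, h_exp, n_steps) {
  score <- matrix(0, nrow(tmap), ncol(tmap))
  for (sgn in c(1, -1)) {
    m <- sgn * tmap
    mx <- max(m)
    if (mx <= 0) next
    dh <- mx / n_steps
    for (h in seq(dh, mx, by = dh)) {
      for (members in mask_components(as.vector(m >= h), neighbours)) {
        score[members] <- score[members] +
          sgn * length(members)^e_exp * h^h_exp * dh
      }
    }
  }
  score
}

#' Threshold-free cluster enhancement test
#'
#' Integrates extent^E * height^H over `tfce_steps` threshold levels for
#' each (channel, lag) sample, for positive and negative deflections
#' separately, and compares each sample's TFCE score against the
#' permutation null of the map maximum. A sample is significant when its
#' p-value falls below `cfg$alpha`.
#'
#' @inheritParams cluster_permutation
#' @return an object of class `tfce_result`: `score` (channels x lags),
#'   `p` (same shape), `significant` (logical map), the `t_map` and the
#'   null distribution.
#' @export
tfce <- function(test_data, adjacency, cfg = cluster_test_config()) {
  d <- dim(test_data)
  n <- d[1]
  neighbours <- lattice_neighbours(d[2], d[3], adjacency)
  tmap <- hat_t(test_data, cfg$hat_sigma)
  score <- tfce_transform(tmap, neighbours, cfg$tfce_e, cfg$tfce_h, cfg$tfce_steps)
  flat <- matrix(test_data, n, d[2] * d[3])
  null_max <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_permutations), function(p) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      pm <- hat_t(array(signs * flat, dim = d), cfg$hat_sigma)
      max(abs(tfce_transform(pm, neighbours, cfg$tfce_e, cfg$tfce_h, cfg$tfce_steps)))
    }, 0)
  })
  pmat <- matrix(vapply(abs(score), function(s) {
    (1 + sum(null_max >= s)) / (1 + cfg$n_permutations)
  }, 0), d[2], d[3])
  structure(list(score = score, p = pmat, significant = pmat < cfg$alpha,
                 t_map = tmap, null_max = null_max, cfg = cfg),
            class = "tfce_result")
}
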
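#' Kernel-density rate estimate
#'
#' Classical occupancy-normalised Gaussian smoother: the ratio of the
#' blurred spike mass to the blurred visit mass (denominator floored at a
#' tiny epsilon).
#'
#' @param counts a [binned_counts()] (or list with arrays `n`, `k`).
#' @param sigma Gaussian bandwidth (standard deviation), bins.
#' @param eps denominator floor.
#' @return rate map in spikes per sample, padded grid.
#' @export
kde_rate <- function(counts, sigma, eps = 1e-9) {
  stopifnot(sigma > 0)
  ca <- as_count_arrays(counts)
  gauss_blur(ca$k, sigma) / pmax(gauss_blur(ca$n, sigma), eps)
}

#' Curvature-matched KDE bandwidths
#'
#' The scale-matched Gaussian bandwidth equates the curvature of
#' `exp(-r^2 / (2 s^2))` at zero lag with that of the radial profile
#' `J0(2 pi r / P)`, giving `s^2 = P^2 / (2 pi^2)`; the finer-scale
#' variant uses one eighth of that variance (noisier but less biased).
#'
#' @param period grid period, bins.
#' @return list with `sigma_matched_sq` and `sigma_fine_sq` (bins^2).
#' @export
matched_bandwidth <- function(period) {
  stopifnot(period > 0)
  s2 <- period^2 / (2 * pi^2)
  list(sigma_matched_sq = s2, sigma_fine_sq = s2 / 8)
}

#' Rate-map estimators for the evaluation harness
#'
#' Constructors returning functions `counts -> rate map` (spikes per
#' sample, padded grid). `estimator_kde` wraps [kde_rate()];
#' `estimator_lgcp` fits the variational posterior under a fixed prior and
#' returns the expected rate `exp(mu + v / 2)`.
#'
#' @param sigma KDE bandwidth, bins.
#' @param prior an [lgcp_prior()] (kernel parameters held fixed).
#' @param ... passed on to [fit_lgcp()].
#' @return a function of one argument (`counts`).
#' @export
estimator_kde <- function(sigma) {
  force(sigma)
  function(counts) kde_rate(counts, sigma)
}

#' @rdname estimator_kde
#' @export
estimator_lgcp <- function(prior, ...) {
  force(prior)
  args <- list(...)
  function(counts) {
    st <- do.call(fit_lgcp, c(list(counts = counts, prior = prior), args))
    exp(pmin(st$mu + st$v / 2, RATE_CEILING))
  }
}

# split a session into nb contiguous time blocks of (near-)equal length;
# returns a list of index vectors
time_blocks <- function(T, nb) {
  split(seq_len(T), cut(seq_len(T), nb, labels = FALSE))
}

subset_session <- function(sess, idx) {
  # re-space times so the subset remains uniformly sampled
  session(times = seq_along(idx) * sess$dt,
          x = sess$positions[idx, 1], y = sess$positions[idx, 2],
          spikes = sess$spikes[idx],
          heading = if (is.null(sess$heading)) NULL else sess$heading[idx],
          dt = sess$dt)
}

#' Bootstrap bias/variance/accuracy comparison of rate-map estimators
#'
#' Partitions a synthetic session into `n_blocks` contiguous blocks and,
#' for each training duration (a number of blocks), draws bootstrap
#' training sets with replacement, applies each estimator with its
#' parameters held fixed, and summarises per duration: accuracy (mean
#' Pearson correlation with the true rate), bias (root-mean-square of the
#' mean estimate minus truth) and variance (mean per-bin variance across
#' replicates). Metrics are computed in Hz on bins visited in the full
#' session.
#'
#' @param truth true log-rate map (log Hz), interior grid.
#' @param sess the synthetic [session()].
#' @param grid a [grid_spec()].
#' @param estimators named list of estimator functions (see
#'   [estimator_kde()]).
#' @param n_blocks number of contiguous blocks.
#' @param durations block counts to evaluate (defaults to
#'   `c(1, 2, 4, 8, n_blocks)`).
#' @param n_boot bootstrap replicates per duration.
#' @param seed RNG seed.
#' @return data frame with one row per (estimator, duration).
#' @export
bias_variance <- function(truth, sess, grid, estimators, n_blocks = 15,
                          durations = NULL, n_boot = 200, seed = 1L) {
  if (is.null(durations)) durations <- unique(c(1, 2, 4, 8, n_blocks))
  T <- length(sess$times)
  blocks <- time_blocks(T, n_blocks)
  # binning is additive over samples: bin each block once
  bb <- lapply(blocks, function(idx) bin_session(subset_session(sess, idx),
                                                 grid))
  full_n <- Reduce(`+`, lapply(bb, function(b) b$n))
  mask <- unpad_map(full_n, grid$pad) > 0
  truth_hz <- exp(truth)[mask]
  set.seed(seed)
  rows <- list()
  for (dur in durations) {
    draws <- matrix(sample.int(n_blocks, dur * n_boot, replace = TRUE),
                    n_boot, dur)
    ests <- lapply(estimators, function(f) {
      vapply(seq_len(n_boot), function(r) {
        sel <- tabulate(draws[r, ], n_blocks)
        n <- Reduce(`+`, Map(function(b, m) m * b$n, bb, sel))
        k <- Reduce(`+`, Map(function(b, m) m * b$k, bb, sel))
        est <- f(binned_counts(n, k, grid)) / sess$dt  # Hz
        unpad_map(est, grid$pad)[mask]
      }, numeric(sum(mask)))
    })
    for (nm in names(ests)) {
      E <- ests[[nm]]
      mean_est <- rowMeans(E)
      rows[[length(rows) + 1]] <- data.frame(
        estimator = nm, duration_blocks = dur,
        accuracy = mean(apply(E, 2, stats::cor, y = truth_hz)),
        bias = sqrt(mean((mean_est - truth_hz)^2)),
        variance = mean(apply(E, 1, stats::var)))
    }
  }
  do.call(rbind, rows)
}

#' Poisson log-likelihood of binned test data
#'
#' `sum(k * log(rate) - n * rate)` over occupied test bins (natural units;
#' the `ln y!` constant is omitted). `rate` is in spikes per sample.
#'
#' @param rate predicted rate map (spikes per sample), padded grid.
#' @param n,k test visit and spike mass.
#' @param eps rate floor.
#' @return scalar, nats.
#' @export
poisson_loglik <- function(rate, n, k, eps = 1e-12) {
  occ <- n > 0
  r <- pmax(rate[occ], eps)
  sum(k[occ] * log(r)) - sum(n[occ] * r)
}

#' Normalised explained deviance
#'
#' `(L_model - L_null) / (L_saturated - L_null)`: 0 for the mean-rate null
#' model, 1 for the saturated model; may be negative for a model worse
#' than null.
#'
#' @param l_model,l_null,l_saturated log-likelihoods, nats.
#' @return fraction.
#' @export
explained_deviance <- function(l_model, l_null, l_saturated) {
  if (l_saturated <= l_null)
    stop("degenerate deviance: saturated model no better than null")
  (l_model - l_null) / (l_saturated - l_null)
}

#' Cross-validated estimator comparison
#'
#' Contiguous-block k-fold cross-validation. Per fold: estimate a rate map
#' from the training blocks (for the LGCP: heuristic hyperparameter
#' initialisation, optionally refined by [grid_search_hyper()], with
#' held-out data excluded), rescale the prediction by a single scalar so
#' the predicted spike count matches the test fold ("adjusted"
#' log-likelihood), and score the test fold. The LGCP is scored with the
#' expected log-likelihood under its posterior (the rate
#' `exp(mu + v / 2)`); the KDE with its point-estimate likelihood. Null
#' model: the test fold's own mean rate; saturated model: the test rate
#' histogram.
#'
#' @param sess a [session()].
#' @param grid a [grid_spec()].
#' @param kernel LGCP kernel type passed to [grid_cell_prior()].
#' @param n_folds number of contiguous folds.
#' @param search `"heuristic"` (per-fold heuristic hyperparameters),
#'   `"grid"` (per-fold grid search; slow), or `"fixed"` (use `hyper`).
#' @param hyper hyperparameter list for `search = "fixed"` (fields
#'   `period`, `orientation`, `sigma0_sq`, `dc_offset`).
#' @param kde_sigma KDE bandwidth, bins; defaults to the scale-matched
#'   bandwidth at the full-session heuristic period.
#' @param keep_fraction low-rank threshold for the LGCP prior.
#' @return data frame with one row per fold and estimator: adjusted
#'   log-likelihood (nats) and explained-deviance fraction.
#' @export
crossval <- function(sess, grid, kernel = "grid", n_folds = 10,
                     search = c("heuristic", "grid", "fixed"),
                     hyper = NULL, kde_sigma = NULL, keep_fraction = 0.1) {
  search <- match.arg(search)
  T <- length(sess$times)
  folds <- time_blocks(T, n_folds)
  full <- bin_session(sess, grid)
  if (is.null(kde_sigma)) {
    P_full <- heuristic_init(full)$period0
    kde_sigma <- sqrt(matched_bandwidth(P_full)$sigma_matched_sq)
  }
  rows <- list()
  for (f in seq_len(n_folds)) {
    test_idx <- folds[[f]]
    train <- bin_session(subset_session(sess, setdiff(seq_len(T), test_idx)),
                         grid)
    test <- bin_session(subset_session(sess, test_idx), grid)
    if (sum(test$k) == 0 || sum(test$n) == 0) {
      warning("empty test fold ", f, "; skipped")
      next
    }
    # --- LGCP ---
    if (search == "grid") {
      gs <- grid_search_hyper(train, kernel = kernel,
                              keep_fraction = keep_fraction)
      st <- gs$state
      mu <- st$mu; v <- st$v
    } else {
      ini <- heuristic_init(train)
      hy <- if (search == "fixed") hyper else
        list(period = ini$period0, orientation = 0,
             sigma0_sq = ini$sigma0_sq, dc_offset = ini$dc0)
      pr <- grid_cell_prior(grid, kernel, period = hy$period,
                            orientation = hy$orientation,
                            sigma0_sq = hy$sigma0_sq,
                            dc_offset = hy$dc_offset, mu_z = ini$mu_z,
                            keep_fraction = keep_fraction)
      st <- fit_lgcp(train, pr, init_mu = ini$mu_init)
      mu <- st$mu; v <- st$v
    }
    lam_exp <- exp(pmin(mu + v / 2, RATE_CEILING))
    occ <- test$n > 0
    mean_test <- sum(test$k) / sum(test$n)
    # mean-rate adjustment: scalar alpha matching predicted to test spikes
    adjust <- function(rate) sum(test$k) / max(sum(test$n * rate), 1e-12)
    a_l <- adjust(lam_exp)
    # expected log-likelihood: sum k (mu + ln a) - sum n <lambda> a
    l_lgcp <- sum(test$k[occ] * (mu[occ] + log(a_l))) -
      sum(test$n[occ] * lam_exp[occ] * a_l)
    # --- KDE ---
    kde <- kde_rate(train, kde_sigma)
    a_k <- adjust(kde)
    l_kde <- poisson_loglik(kde * a_k, test$n, test$k)
    # --- null / saturated ---
    l_null <- poisson_loglik(array(mean_test, dim = dim(test$n)),
                             test$n, test$k)
    yhat <- test$k[occ] / test$n[occ]
    l_sat <- sum(test$k[occ][yhat > 0] * log(yhat[yhat > 0])) - sum(test$k)
    rows[[length(rows) + 1]] <- data.frame(
      fold = f,
      estimator = c("lgcp", "kde"),
      loglik = c(l_lgcp, l_kde),
      deviance_frac = c(explained_deviance(l_lgcp, l_null, l_sat),
                        explained_deviance(l_kde, l_null, l_sat)),
      l_null = l_null, l_saturated = l_sat)
  }
  do.call(rbind, rows)
}
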
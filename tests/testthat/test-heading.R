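test_that("squared-cosine weights partition opposing directions", {
  expect_equal(direction_weights(1.2, 1.2), 1)
  expect_equal(direction_weights(1.2 + pi / 2, 1.2), 0)
  expect_equal(direction_weights(1.2 + pi, 1.2), 0)
  phi <- seq(0, 2 * pi, length.out = 100)
  w1 <- direction_weights(phi, 0.4)
  expect_equal(w1, direction_weights(phi, 0.4 + 2 * pi))
  # opposing reference directions have disjoint support
  w2 <- direction_weights(phi, 0.4 + pi)
  expect_true(all(pmin(w1, w2) < 1e-12))
  expect_true(all(w1 >= 0 & w1 <= 1))
})

test_that("heading smoothing is wrap-safe and attenuates noise", {
  T <- 2500
  const <- smooth_heading(rep(1.5, T), sample_rate = 50)
  expect_equal(const$phi, rep(1.5, T), tolerance = 1e-10)
  # heading hovering at the 0 / 2 pi wrap: no 2 pi jumps after smoothing
  set.seed(41)
  raw <- (0.05 * sin(seq_len(T) / 200) + rnorm(T, 0, 0.3)) %% (2 * pi)
  sm <- smooth_heading(raw, sample_rate = 50)$phi
  jump <- abs(diff(sm))
  jump <- pmin(jump, 2 * pi - jump)  # circular step size
  expect_lt(max(jump), 0.5)
  # circular variance shrinks at least 5-fold for white angular noise
  circ_var <- function(phi) 1 - Mod(mean(exp(1i * phi)))
  noisy <- (1.1 + rnorm(T, 0, 0.5)) %% (2 * pi)
  smn <- smooth_heading(noisy, sample_rate = 50)$phi
  expect_lt(circ_var(smn) * 5, circ_var(noisy))
  # gaps are interpolated
  raw2 <- rep(2.0, 200); raw2[50:60] <- NA
  sm2 <- smooth_heading(raw2, sample_rate = 50)
  expect_true(all(is.finite(sm2$phi)))
  expect_error(smooth_heading(rep(NA_real_, 10), 50), "valid")
})

test_that("weighted binning reduces to 2D inference inputs", {
  set.seed(42)
  T <- 2000
  s <- session(times = seq_len(T) * 0.02, x = runif(T, 0, 10),
               y = runif(T, 0, 10), spikes = rpois(T, 0.5),
               heading = runif(T, 0, 2 * pi))
  g <- grid_spec(10, 10, pad = 2)
  w <- direction_weights(s$heading, 1.0)
  b <- weighted_counts(s, 1.0, g)
  expect_equal(sum(b$n), sum(w))
  expect_equal(sum(b$k), sum(w * s$spikes))
  # unit weights give exactly the unweighted binning
  b1 <- bin_session(s, g, weights = rep(1, T))
  b0 <- bin_session(s, g)
  expect_equal(b1$n, b0$n)
  expect_equal(b1$k, b0$k)
  # opposing subsets have disjoint weight support over samples
  b_op <- weighted_counts(s, 1.0 + pi, g)
  expect_equal(sum(b$n) + sum(b_op$n),
               sum(direction_weights(s$heading, 1.0) +
                     direction_weights(s$heading, 1.0 + pi)))
})

test_that("joint binning conserves mass and matches marginal binning", {
  set.seed(43)
  T <- 3000
  s <- session(times = seq_len(T) * 0.02, x = runif(T, 0, 10),
               y = runif(T, 0, 10), spikes = rpois(T, 0.5),
               heading = runif(T, 0, 2 * pi))
  g <- grid_spec(10, 10, pad = 2)
  jb <- bin_session_joint(s, g, n_dir = 8)
  expect_equal(sum(jb$n), T)
  expect_equal(sum(jb$k), sum(s$spikes))
  # marginalising over direction recovers the 2D binning
  b2 <- bin_session(s, g)
  expect_equal(apply(jb$n, c(2, 3), sum), b2$n, tolerance = 1e-10)
  expect_equal(apply(jb$k, c(2, 3), sum), b2$k, tolerance = 1e-10)
})

test_that("joint inference on direction-independent data matches the 2D fit", {
  cfg <- sim_config(grid_side = 30, period_bins = 8, duration = 300,
                    mean_rate = 3, seed = 44)
  sim <- simulate_session(cfg)
  s0 <- sim$session
  set.seed(45)
  phi <- smooth_heading(runif(length(s0$times), 0, 2 * pi), 50)$phi
  s <- session(times = s0$times, x = s0$positions[, 1],
               y = s0$positions[, 2], spikes = s0$spikes, heading = phi)
  g <- grid_spec(30, 30, pad = 10)
  counts <- bin_session(s, g)
  init <- heuristic_init(counts)
  spat <- parameterize_kernel(localize_kernel(grid_kernel(g, init$period0)),
                              init$sigma0_sq, init$dc0)
  pr2 <- lgcp_prior(build_spectral_prior(spat), init$mu_z)
  st2 <- fit_lgcp(counts, pr2, init_mu = init$mu_init)
  jb <- bin_session_joint(s, g, n_dir = 8)
  pr3 <- joint_prior(spat, n_dir = 8, mu_z = init$mu_z, rank_cap = 600)
  st3 <- fit_lgcp(jb, pr3)
  # direction-marginal joint mean matches the 2D posterior mean where
  # there is data
  occ <- counts$n > 0
  mu3 <- apply(st3$mu, c(2, 3), mean)
  expect_gt(cor(mu3[occ], st2$mu[occ]), 0.95)
  # conditional peak densities are nearly direction-independent
  cpd <- conditional_peak_density(st3, init$period0, n_samples = 40,
                                  seed = 3, pad = g$pad)
  per_dir <- apply(cpd, 1, mean)
  expect_lt(max(per_dir) - min(per_dir), 0.25 * mean(per_dir) + 0.02)
})
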
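test_that("expected rate matches the log-normal mean", {
  expect_equal(expected_rate(1, 0, 2), 2 * exp(1))
  expect_equal(expected_rate(0, 2 * log(2), 1), 2)
  set.seed(12)
  z <- rnorm(1e5, mean = -0.3, sd = sqrt(0.7))
  mc <- mean(exp(z))
  se <- sd(exp(z)) / sqrt(1e5)
  expect_lt(abs(expected_rate(-0.3, 0.7, 1) - mc), 3 * se)
  expect_warning(expected_rate(800, 0, 1), "ceiling")
  expect_error(expected_rate(0, -1, 1))
})

test_that("marginal variances agree with the dense inverse", {
  k <- random_psd_kernel(c(8, 8), ridge = 0.4, seed = 21)
  sp <- build_spectral_prior(k, keep_fraction = 0)
  S <- dense_sigma(k$values)
  # q = 0: prior marginal variance K(0) = sum(xi) / M
  mv0 <- marginal_variance(sp, matrix(0, 8, 8))
  expect_equal(as.vector(mv0$v), diag(S), tolerance = 1e-10)
  expect_equal(mv0$v[1, 1], sum(sp$xi) / 64, tolerance = 1e-10)
  set.seed(22)
  q <- matrix(rexp(64) * rbinom(64, 1, 0.6), 8, 8)
  mv <- marginal_variance(sp, q)
  vd <- diag(solve(solve(S) + diag(as.vector(q))))
  expect_equal(as.vector(mv$v), vd, tolerance = 1e-8)
  # monotonicity: increasing any single q entry shrinks every variance
  q2 <- q; q2[3, 5] <- q2[3, 5] + 2
  mv2 <- marginal_variance(sp, q2)
  expect_true(all(mv2$v <= mv$v + 1e-12))
})

test_that("MAP estimate solves the scalar optimality condition", {
  # delta-kernel prior decouples bins: each solves (z - mu_z)/s = k - n e^z
  for (case in list(list(s = 1, mu_z = 0, n = 1, k = 1),
                    list(s = 0.5, mu_z = -1, n = 3, k = 7),
                    list(s = 2, mu_z = 1, n = 0.5, k = 0))) {
    pr <- delta_prior(c(2, 2), s = case$s, mu_z = case$mu_z)
    n <- matrix(0, 2, 2); k <- matrix(0, 2, 2)
    n[1, 1] <- case$n; k[1, 1] <- case$k
    zhat <- map_estimate(list(n = n, k = k), pr, tol = 1e-12)
    root <- uniroot(function(z) (z - case$mu_z) / case$s -
                      (case$k - case$n * exp(z)),
                    c(-30, 30), tol = 1e-12)$root
    expect_equal(zhat[1, 1], root, tolerance = 1e-7)
    expect_equal(zhat[2, 2], case$mu_z, tolerance = 1e-9)  # no data: prior
  }
})

test_that("MAP matches a dense Newton oracle on a 12x12 grid", {
  d <- c(12, 12)
  k <- random_psd_kernel(d, ridge = 0.4, seed = 31)
  sp <- build_spectral_prior(k, keep_fraction = 0)
  S <- dense_sigma(k$values)
  dat <- random_poisson_data(S, mu_z = -0.5, seed = 32)
  pr <- lgcp_prior(sp, -0.5)
  zhat <- map_estimate(list(n = matrix(dat$n, d[1]), k = matrix(dat$k, d[1])),
                       pr, tol = 1e-10)
  z_oracle <- dense_map(S, rep(-0.5, prod(d)), dat$n, dat$k)
  expect_lt(max(abs(as.vector(zhat) - z_oracle)), 1e-6)
  # zero data: MAP is the prior mean
  z0 <- map_estimate(list(n = matrix(0, 12, 12), k = matrix(0, 12, 12)), pr)
  expect_equal(as.vector(z0), rep(-0.5, 144), tolerance = 1e-9)
})

test_that("scalar variational fixed point matches direct ELBO maximisation", {
  s <- 1.2; mu_z <- -0.5; n <- 4; k <- 6
  pr <- delta_prior(c(2, 2), s = s, mu_z = mu_z)
  nn <- matrix(0, 2, 2); kk <- matrix(0, 2, 2)
  nn[1, 1] <- n; kk[1, 1] <- k
  st <- fit_lgcp(list(n = nn, k = kk), pr, tol = 1e-12, max_outer = 100)
  # scalar ELBO: mu k - n exp(mu + v/2) - KL(N(mu,v) || N(mu_z,s))
  f <- function(p) {
    mu <- p[1]; v <- exp(p[2])
    mu * k - n * exp(mu + v / 2) -
      0.5 * ((mu - mu_z)^2 / s + v / s - log(v / s) - 1)
  }
  opt <- optim(c(0, 0), function(p) -f(p), method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(st$mu[1, 1], opt$par[1], tolerance = 1e-5)
  expect_equal(st$v[1, 1], exp(opt$par[2]), tolerance = 1e-4)
  # ELBO never exceeds the quadrature log-evidence, and the gap is small
  ev <- log(integrate(function(z)
    dnorm(z, mu_z, sqrt(s)) * exp(k * z - n * exp(z)),
    -20, 10, rel.tol = 1e-12)$value)
  L <- st$elbo
  expect_lte(L, ev + 1e-8)
  expect_lt(ev - L, 1e-2)
})

test_that("variational fit matches a dense diagonal-update oracle", {
  d <- c(8, 8); M <- prod(d)
  k <- random_psd_kernel(d, ridge = 0.4, seed = 41)
  sp <- build_spectral_prior(k, keep_fraction = 0)
  S <- dense_sigma(k$values)
  dat <- random_poisson_data(S, mu_z = -0.3, seed = 42)
  pr <- lgcp_prior(sp, -0.3)
  counts <- list(n = matrix(dat$n, d[1]), k = matrix(dat$k, d[1]))
  st <- fit_lgcp(counts, pr, tol = 1e-12, max_outer = 100)
  # independent oracle: BFGS ascent on the dense ELBO over (mu, log q+)
  occ <- dat$n > 0
  par0 <- c(rep(-0.3, M), rep(0, sum(occ)))
  fn <- function(p) {
    q <- numeric(M); q[occ] <- exp(p[M + seq_len(sum(occ))])
    -dense_elbo(p[1:M], q, S, rep(-0.3, M), dat$n, dat$k)
  }
  gr <- function(p) {
    q <- numeric(M); q[occ] <- exp(p[M + seq_len(sum(occ))])
    g <- dense_elbo_grad(p[1:M], q, S, rep(-0.3, M), dat$n, dat$k)
    -c(g[1:M], (g[M + seq_len(M)] * q)[occ])
  }
  opt <- optim(par0, fn, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_lt(max(abs(as.vector(st$mu) - opt$par[1:M])), 1e-4)
  expect_equal(st$elbo, -opt$value, tolerance = 1e-6)
})

test_that("posterior contracts the prior and ELBO is monotone", {
  fit <- ref_fit()
  st <- fit$state
  pv <- sum(fit$prior$spectral$xi_kept) / prod(fit$prior$spectral$dims)
  expect_true(all(st$v <= pv + 1e-8))
  expect_true(all(st$v >= 0))
  expect_true(all(diff(st$elbo_trace) >= -1e-8 * abs(st$elbo)))
  expect_true(st$converged)
  # lambda_bar vanishes off occupied bins
  counts <- ref_counts()
  expect_true(all(st$lambda_bar[counts$n == 0] == 0))
})

test_that("zero data returns the prior as posterior", {
  k <- random_psd_kernel(c(8, 8), ridge = 0.4, seed = 51)
  sp <- build_spectral_prior(k, keep_fraction = 0)
  pr <- lgcp_prior(sp, 0.7)
  st <- fit_lgcp(list(n = matrix(0, 8, 8), k = matrix(0, 8, 8)), pr)
  expect_equal(as.vector(st$mu), rep(0.7, 64), tolerance = 1e-10)
  expect_equal(as.vector(st$v), diag(dense_sigma(k$values)),
               tolerance = 1e-8)
  expect_equal(elbo(st, list(n = matrix(0, 8, 8), k = matrix(0, 8, 8)), pr),
               0, tolerance = 1e-8)
})

test_that("Laplace approximation is the frozen-variance special case", {
  d <- c(8, 8)
  k <- random_psd_kernel(d, ridge = 0.4, seed = 61)
  sp <- build_spectral_prior(k, keep_fraction = 0)
  S <- dense_sigma(k$values)
  dat <- random_poisson_data(S, mu_z = -0.2, seed = 62)
  pr <- lgcp_prior(sp, -0.2)
  counts <- list(n = matrix(dat$n, 8), k = matrix(dat$k, 8))
  zhat <- map_estimate(counts, pr, tol = 1e-10)
  lam_tilde <- expected_rate(zhat, 0 * zhat, counts$n)
  mv <- marginal_variance(sp, lam_tilde)
  v_laplace <- diag(solve(solve(S) + diag(as.vector(lam_tilde))))
  expect_equal(as.vector(mv$v), v_laplace, tolerance = 1e-8)
})

test_that("update_mean and update_variance expose the inner loop", {
  k <- random_psd_kernel(c(8, 8), ridge = 0.4, seed = 71)
  sp <- build_spectral_prior(k, keep_fraction = 0)
  S <- dense_sigma(k$values)
  dat <- random_poisson_data(S, mu_z = 0, seed = 72)
  pr <- lgcp_prior(sp, 0)
  counts <- list(n = matrix(dat$n, 8), k = matrix(dat$k, 8))
  st <- fit_lgcp(counts, pr, max_outer = 1)
  st2 <- update_variance(update_mean(st, counts, pr), counts, pr)
  expect_gte(st2$elbo, st$elbo - 1e-8 * abs(st$elbo))
  expect_true(all(st2$q[counts$n == 0] == 0))
})
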
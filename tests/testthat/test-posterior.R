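test_that("posterior samples reproduce the variational moments", {
  k <- random_psd_kernel(c(10, 10), ridge = 0.3, seed = 81)
  sp <- build_spectral_prior(k, keep_fraction = 0)
  S <- dense_sigma(k$values)
  dat <- random_poisson_data(S, mu_z = 0, seed = 82)
  pr <- lgcp_prior(sp, 0)
  st <- fit_lgcp(list(n = matrix(dat$n, 10), k = matrix(dat$k, 10)), pr)
  Sn <- 2000
  samp <- sample_posterior(st, Sn, seed = 5)
  m <- apply(samp, c(1, 2), mean)
  v <- apply(samp, c(1, 2), var)
  expect_lt(max(abs(m - st$mu)), 4 * max(sqrt(st$v / Sn)))
  expect_lt(max(abs(v - st$v) / st$v), 0.2)
  # reproducibility
  expect_identical(samp, sample_posterior(st, Sn, seed = 5))
})

test_that("prior draws reproduce the kernel autocovariance", {
  k <- random_psd_kernel(c(16, 16), ridge = 0.2, seed = 83)
  sp <- build_spectral_prior(k, keep_fraction = 0)
  pr <- lgcp_prior(sp, 0)
  # q = 0: the posterior factor is a prior factor
  st <- fit_lgcp(list(n = matrix(0, 16, 16), k = matrix(0, 16, 16)), pr)
  samp <- sample_posterior(st, 400, seed = 6)
  # empirical circular autocovariance averaged over draws
  emp <- matrix(0, 16, 16)
  for (s in 1:400) {
    x <- samp[, , s]
    emp <- emp + Re(fft(fft(x) * Conj(fft(x)), inverse = TRUE)) / 256^2
  }
  emp <- emp / 400
  expect_lt(max(abs(emp - k$values)), 0.15 * k$values[1, 1])
})

test_that("peak density marks discs around sample peaks", {
  m <- matrix(0, 21, 21)
  m[11, 11] <- 1  # single peak
  samp <- array(m, c(21, 21, 1))
  pd <- peak_density(samp, period = 10, radius_frac = 0.5)
  D <- lgcpgrid:::disp_grids(c(21, 21))
  r <- sqrt((D$dx1)^2 + (D$dx2)^2)
  # distance from bin (11,11) with circular displacement grids re-centred
  dist <- sqrt(outer((1:21 - 11)^2, (1:21 - 11)^2, `+`))
  expect_true(all(pd[dist <= 5] == 1))
  expect_true(all(pd[dist > 5.5] == 0))
  expect_true(all(pd >= 0 & pd <= 1))
})

test_that("field segmentation respects the Voronoi radius contract", {
  m <- exp(ideal_grid_log_rate(60, 12))
  seg <- segment_fields(m, period = 12)
  expect_gt(nrow(seg$peaks), 5)
  lab <- seg$labels
  for (i in seq_len(nrow(seg$peaks))) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    d <- sqrt((idx[, 1] - seg$peaks$row_f[i])^2 +
                (idx[, 2] - seg$peaks$col_f[i])^2)
    expect_true(all(d <= 0.7 * 12 + 1e-9))
  }
  # two symmetric peaks: the bisector splits labels evenly
  m2 <- matrix(0, 11, 21)
  for (cc in 1:21) m2[, cc] <- -pmin((cc - 6)^2, (cc - 16)^2) / 10
  m2 <- m2 - outer((1:11 - 6)^2, rep(1, 21)) / 10
  seg2 <- segment_fields(m2, period = 14, max_radius_frac = 0.7)
  expect_equal(nrow(seg2$peaks), 2)
  # the bisector column (equidistant ties) aside, labels split evenly
  expect_equal(sum(seg2$labels[, -11] == 1), sum(seg2$labels[, -11] == 2))
  expect_true(all(seg2$labels[, 1:10] != 2))
  expect_true(all(seg2$labels[, 12:21] != 1))
  expect_warning(segment_fields(matrix(0, 5, 5), 4), "no local maxima")
})

test_that("quadratic peak covariance matches the analytic white-noise case", {
  # state with quadratic mean -x' A x / 2 and white posterior noise c I:
  # gradient covariance at the peak is (c/2) I exactly under central
  # differences, so Sigma_dx = (c/2) A^-2
  d <- c(15, 15)
  cnoise <- 0.04
  pr <- delta_prior(d, s = 1)
  sp <- pr$spectral
  A <- matrix(c(0.5, 0.12, 0.12, 0.3), 2, 2)
  rows <- matrix(1:15 - 8, 15, 15)
  cols <- t(rows)
  mu <- -(A[1, 1] * cols^2 + 2 * A[1, 2] * cols * rows + A[2, 2] * rows^2) / 2
  st <- structure(list(mu = mu, mu_coeff = numeric(sp$rank), v = NULL,
                       q = NULL, lambda_bar = NULL, elbo = 0,
                       elbo_trace = 0, converged = TRUE,
                       factor = list(U = diag(sp$rank) / sqrt(cnoise),
                                     B = diag(sp$rank) * sqrt(cnoise),
                                     prior = sp)),
                  class = "lgcp_state")
  fp <- peak_covariance_quadratic(st, c(8, 8))
  expected <- (cnoise / 2) * solve(A) %*% solve(A)
  expect_equal(fp$peak_cov, expected, tolerance = 1e-8)
  expect_equal(fp$hessian, -A, tolerance = 1e-8)
  # PSD and symmetric by construction
  expect_equal(fp$peak_cov, t(fp$peak_cov))
  expect_gte(min(eigen(fp$peak_cov)$values), 0)
  # a saddle point is rejected
  st$mu <- outer((1:15 - 8)^2, rep(1, 15)) * 0.5 + mu
  expect_error(peak_covariance_quadratic(st, c(8, 8)), "not a peak")
})

test_that("confidence ellipses scale with the chi-square quantile", {
  e <- confidence_ellipse(diag(2) * 4, level = 0.95)
  expect_equal(e$semi_axes, rep(2 * sqrt(qchisq(0.95, 2)), 2),
               tolerance = 1e-10)
  # level -> 0 shrinks the ellipse to a point
  e0 <- confidence_ellipse(diag(2), level = 1e-12)
  expect_lt(max(e0$semi_axes), 1e-5)
  # rotation equivariance
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  C <- diag(c(4, 1))
  er <- confidence_ellipse(R %*% C %*% t(R))
  expect_equal(er$semi_axes, confidence_ellipse(C)$semi_axes,
               tolerance = 1e-10)
  ang <- (er$angle - th) %% pi
  expect_lt(min(ang, pi - ang), 1e-8)
  expect_error(confidence_ellipse(matrix(c(1, 0.5, 0.4, 1), 2)), "symmetric")
  expect_error(confidence_ellipse(matrix(c(1, 2, 2, 1), 2)), "semidefinite")
})
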
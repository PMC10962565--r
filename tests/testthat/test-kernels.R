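test_that("grid kernel matches the three-plane-wave construction", {
  g <- grid_spec(20, 20, pad = 6)
  k <- grid_kernel(g, period = 8, orientation = 0.2)
  expect_equal(k$values[1, 1], 3)
  # orientation is pi/3-periodic (wave relabelling)
  k2 <- grid_kernel(g, period = 8, orientation = 0.2 + pi / 3)
  expect_equal(k$values, k2$values, tolerance = 1e-12)
  # even symmetry on the circulant grid
  v <- k$values
  expect_equal(v, v[c(1, nrow(v):2), c(1, ncol(v):2)], tolerance = 1e-12)
  expect_error(grid_kernel(g, period = 1.5), "at least 2")
})

test_that("grid kernel spectrum concentrates on six ring components", {
  g <- grid_spec(40, 40, pad = 12)  # padded 64
  k <- grid_kernel(g, period = 8, orientation = 0.1)
  xi <- kernel_spectrum(k)
  d <- dim(k$values)
  ord <- order(abs(xi), decreasing = TRUE)
  top <- ord[1:12]  # six components + conjugate-symmetric partners
  expect_true(all(xi[top] > 0))
  # the dominant components sit on the ring at spatial frequency 1/P ...
  pos <- arrayInd(top, d) - 1L
  fr <- pmin(pos[, 1], d[1] - pos[, 1]) / d[1]
  fc <- pmin(pos[, 2], d[2] - pos[, 2]) / d[2]
  expect_true(all(abs(sqrt(fr^2 + fc^2) - 1 / 8) < 1.5 / d[1]))
  # ... one near each of the six continuum plane-wave frequencies
  a <- pi * (0:5) / 3 - 0.1
  kx <- cos(a) / 8; ky <- -sin(a) / 8
  sf1 <- ifelse(pos[, 2] > d[2] / 2, pos[, 2] - d[2], pos[, 2]) / d[2]
  sf2 <- ifelse(pos[, 1] > d[1] / 2, pos[, 1] - d[1], pos[, 1]) / d[1]
  for (l in 1:6) {
    dmin <- min(sqrt((sf1 - kx[l])^2 + (sf2 - ky[l])^2))
    expect_lt(dmin, 1.5 / d[1])
  }
})

test_that("radial kernel is the J0 profile", {
  g <- grid_spec(30, 30, pad = 10)
  k <- radial_kernel(g, period = 9)
  expect_equal(k$values[1, 1], 1)
  # first sign change at the first zero of J0
  j01 <- uniroot(function(x) besselJ(x, 0), c(2, 3), tol = 1e-12)$root
  r_zero <- j01 * 9 / (2 * pi)
  prof <- k$values[1, 1:15]  # along-axis profile, r = 0, 1, 2, ...
  first_neg <- which(prof < 0)[1] - 1
  expect_true(r_zero >= first_neg - 1 && r_zero <= first_neg + 1)
  # rotational invariance: depends on |displacement| only
  expect_equal(k$values[1, 4], k$values[4, 1])
  expect_equal(radial_kernel_3d(0, 9), 1)
  expect_equal(radial_kernel_3d(4.5, 9), sin(pi) / pi, tolerance = 1e-12)
})

test_that("kernel localisation windows, blurs and clips to PSD", {
  k3 <- lgcpgrid:::bessel_j0_zero3()
  expect_equal(k3, 8.6537, tolerance = 1e-4)
  expect_equal(k3 / (2 * pi), 1.377, tolerance = 1e-3)
  g <- grid_spec(30, 30, pad = 12)
  loc <- localize_kernel(grid_kernel(g, period = 7))
  expect_true(loc$finalized)
  expect_gte(min(kernel_spectrum(loc)), -1e-10 * max(kernel_spectrum(loc)))
  # spatial support approximately confined to window radius + blur
  # tails; the spectral clipping step spreads a small residual globally
  d <- dim(loc$values)
  D <- lgcpgrid:::disp_grids(d)
  r <- sqrt(D$dx1^2 + D$dx2^2)
  rc <- k3 * 7 / (2 * pi)
  far <- r > rc + 4 * 7 / pi
  expect_lt(mean(abs(loc$values[far])), 0.02 * loc$values[1, 1])
  expect_lt(max(abs(loc$values[far])), 0.1 * loc$values[1, 1])
  # cutoff radius must fit inside the padded grid
  expect_error(localize_kernel(grid_kernel(g, period = 22)), "increase pad")
})

test_that("scale and offset act on the spectrum as documented", {
  g <- grid_spec(16, 16, pad = 6)
  base <- localize_kernel(radial_kernel(g, period = 6))
  expect_equal(parameterize_kernel(base, 1, 0)$values, base$values)
  xi0 <- kernel_spectrum(base)
  M <- length(base$values)
  xi_c <- kernel_spectrum(parameterize_kernel(base, 1, 2.5))
  expect_equal(xi_c[1, 1], xi0[1, 1] + 2.5 * M, tolerance = 1e-8 * M)
  expect_equal(xi_c[-1], xi0[-1], tolerance = 1e-9)
  xi_2 <- kernel_spectrum(parameterize_kernel(base, 2, 0))
  expect_equal(xi_2[-1], 2 * xi0[-1], tolerance = 1e-9)
  expect_error(parameterize_kernel(base, -1, 0), "non-negative")
})

test_that("direction kernel clips a genuinely indefinite window to PSD", {
  n <- 24
  dphi <- 2 * pi * (0:(n - 1)) / n
  raw <- pmax(0, cos(dphi))^2
  raw_spec <- Re(fft(raw))
  expect_lt(min(raw_spec), -1e-6)  # the squared-cosine window is not PSD
  kd <- direction_kernel(n)
  expect_gte(min(Re(fft(kd))), -1e-12)
  expect_equal(which.max(kd), 1)
  expect_false(isTRUE(all.equal(kd, raw)))  # clipping changes the kernel
})

test_that("joint kernel is the separable product with outer-product spectrum", {
  g <- grid_spec(8, 8, pad = 2)
  spat <- localize_kernel(radial_kernel(g, period = 4))
  kd <- direction_kernel(8)
  kj <- joint_kernel(kd, spat)
  expect_equal(kj[1, 1, 1], kd[1] * spat$values[1, 1])
  sj <- Re(fft(kj))
  outer_spec <- outer(Re(fft(kd)), kernel_spectrum(spat))
  dim(outer_spec) <- dim(sj)
  expect_equal(sj, outer_spec, tolerance = 1e-8, ignore_attr = TRUE)
  expect_gte(min(sj), -1e-8 * max(sj))
})
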
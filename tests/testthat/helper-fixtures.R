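# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# reference synthetic session: the full default simulator configuration
ref_session <- function() memo("ref_session", function() {
  simulate_session(sim_config(seed = 3))
})

ref_grid <- function() grid_spec(90, 90, pad = 18)

ref_counts <- function() memo("ref_counts", function() {
  bin_session(ref_session()$session, ref_grid())
})

ref_init <- function() memo("ref_init", function() heuristic_init(ref_counts()))

# fitted grid-kernel posterior on the reference session (heuristic period,
# sigma0^2 in the ELBO-preferred range)
ref_fit <- function() memo("ref_fit", function() {
  init <- ref_init()
  pr <- grid_cell_prior(ref_grid(), "grid", period = init$period0,
                        sigma0_sq = 1.5, dc_offset = init$dc0,
                        mu_z = init$mu_z)
  list(prior = pr, state = fit_lgcp(ref_counts(), pr, init_mu = init$mu_init))
})

# small decoupled prior: delta kernel -> Sigma_z = s * I, bins independent
delta_prior <- function(d = c(2, 2), s = 1, mu_z = 0) {
  vals <- matrix(0, d[1], d[2]); vals[1, 1] <- s
  k <- structure(list(values = vals, grid = grid_spec(d[1], d[2]),
                      hyper = NULL, finalized = TRUE),
                 class = "lgcp_kernel")
  lgcp_prior(build_spectral_prior(k, keep_fraction = 0), mu_z)
}

# well-conditioned random even-symmetric PSD kernel on a small grid
random_psd_kernel <- function(d, ridge = 0.5, seed = 1) {
  set.seed(seed)
  g <- grid_spec(d[1], d[2])
  D <- lgcpgrid:::disp_grids(d)
  vals <- exp(-(D$dx1^2 + D$dx2^2) / (2 * 1.3^2)) + 0.3 * cos(2 * pi * D$dx1 / d[2])
  vals[1, 1] <- vals[1, 1] + ridge
  xi <- Re(fft(vals)); xi[xi < 0] <- 0
  vals <- Re(fft(xi, inverse = TRUE)) / length(xi)
  structure(list(values = vals, grid = g, hyper = NULL, finalized = TRUE),
            class = "lgcp_kernel")
}

# dense circulant covariance from a kernel array (oracle)
dense_sigma <- function(kv) {
  d <- dim(kv); M <- prod(d)
  idx <- arrayInd(seq_len(M), d) - 1L
  S <- matrix(0, M, M)
  for (i in seq_len(M)) {
    dr <- (idx[i, 1] - idx[, 1]) %% d[1]
    dc <- (idx[i, 2] - idx[, 2]) %% d[2]
    S[i, ] <- kv[cbind(dr + 1, dc + 1)]
  }
  S
}

# random Poisson data set on a small grid under a given dense prior
random_poisson_data <- function(S, mu_z, seed = 1, n_mean = 3) {
  set.seed(seed)
  M <- nrow(S)
  n <- rpois(M, n_mean) * 1.0
  z <- as.vector(mu_z) + as.vector(t(chol(S + 1e-10 * diag(M))) %*% rnorm(M))
  k <- rpois(M, n * exp(z)) * 1.0
  k[n == 0] <- 0
  list(n = n, k = k, z = z)
}

# safeguarded dense Newton MAP oracle
dense_map <- function(S, mu_z, n, k, tol = 1e-12) {
  Sinv <- solve(S)
  mz <- as.vector(mu_z)
  obj <- function(z) -0.5 * sum((z - mz) * (Sinv %*% (z - mz))) +
    sum(z * k) - sum(n * exp(z))
  z <- mz
  for (it in 1:200) {
    lam <- n * exp(z)
    gr <- as.vector(-Sinv %*% (z - mz)) + k - lam
    if (max(abs(gr)) < tol) break
    step <- solve(Sinv + diag(lam), gr)
    t <- 1; f0 <- obj(z)
    while (!is.finite(obj(z + t * step)) || obj(z + t * step) < f0) {
      t <- t / 2
      if (t < 1e-12) break
    }
    z <- z + t * step
  }
  z
}

# dense ELBO and analytic gradients under the diagonal-update
# parameterisation (mu, q); used as an independent variational oracle
dense_elbo <- function(mu, q, S, mu_z, n, k) {
  Sinv <- solve(S)
  Sig <- solve(Sinv + diag(q, length(q)))
  v <- diag(Sig)
  lam <- n * exp(mu + v / 2)
  ell <- sum(k * mu) - sum(lam)
  kl <- 0.5 * (sum((mu - mu_z) * (Sinv %*% (mu - mu_z))) +
                 sum(diag(Sinv %*% Sig)) -
                 determinant(Sig)$modulus + determinant(S)$modulus -
                 length(mu))
  as.numeric(ell - kl)
}

dense_elbo_grad <- function(mu, q, S, mu_z, n, k) {
  Sinv <- solve(S)
  Sig <- solve(Sinv + diag(q, length(q)))
  v <- diag(Sig)
  lam <- n * exp(mu + v / 2)
  gmu <- as.vector(-Sinv %*% (mu - mu_z)) + k - lam
  gq <- -0.5 * diag(Sig %*% diag(q - lam, length(q)) %*% Sig)
  c(gmu, gq)
}
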
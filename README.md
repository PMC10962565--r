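# lgcpgrid

Bayesian firing-rate maps for entorhinal grid cells by **variational
log-Gaussian Cox process (LGCP) regression**.

Grid cells fire as a hexagonally periodic function of an animal's 2D
position. The standard way to estimate their rate maps — an
occupancy-normalised Gaussian smoother (KDE) — is noisy with limited
data, ignores the periodic structure, and gives no uncertainty. This
package instead places a Gaussian-process prior on the *log* rate map,
with covariance kernels built for grid cells, and treats spikes as
conditionally Poisson:

- model: z ~ N(mu_z, Sigma_z), y_t | z ~ Poisson(exp(z(x_t)) dt), with
  data entering only through per-bin visit mass n and spike mass k
  (log-likelihood z'k − n'exp(z) + const);
- priors: hexagonal three-plane-wave kernels and orientation-agnostic
  radial Bessel J0(2 pi r / P) kernels, localized by a window at
  r_c = k3 P / 2 pi (k3 ≈ 8.65, third zero of J0), Gaussian blur and
  spectral clipping to positive semidefiniteness;
- inference: MAP by preconditioned Newton–Krylov iteration, and a full
  variational Gaussian posterior with the stationary parameterisation
  Sigma^-1 = Sigma_z^-1 + diag(q), optimised by alternating Newton
  steps on the mean with fixed-point sweeps q <- lambda-bar, all inside
  a low-rank real (Hartley) spectral subspace;
- model selection: hyperparameters (period, variance scale,
  orientation) chosen by hill-climbing on the evidence lower bound
  (ELBO);
- uncertainty: posterior sampling, grid-field segmentation, and
  quadratic peak-location confidence ellipses
  Sigma_dx = (H^-1 grad(R Q))(H^-1 grad(R Q))';
- extensions: head-direction-conditioned maps via squared-cosine
  weights, and joint position-plus-heading inference on a 3D circular
  grid;
- evaluation: KDE baselines with curvature-matched bandwidths
  (sigma^2 = P^2 / 2 pi^2), bootstrap bias/variance/accuracy curves,
  and 10-fold cross-validated adjusted log-likelihood and explained
  deviance;
- a synthetic grid-cell foraging simulator, so the entire pipeline is
  testable without experimental recordings.

## Worked example

```r
library(lgcpgrid)

# 1. Simulate a 30-minute foraging session from an ideal grid cell
#    (90 x 90 arena, 13-bin period, 1.2 Hz mean rate)
sim <- simulate_session(sim_config(seed = 1))
sim$session
#> <grid_session> 90000 samples, dt = 0.02 s (30.0 min), 2179 spikes

# 2. Bin onto a padded grid and initialise hyperparameters
grid   <- grid_spec(90, 90, pad = 18)
counts <- bin_session(sim$session, grid)
init   <- heuristic_init(counts)
round(c(period = init$period0, sigma0_sq = init$sigma0_sq), 2)
#>    period sigma0_sq
#>     13.11      0.25

# 3. Fit the variational posterior under a hexagonal grid-cell prior
prior <- grid_cell_prior(grid, "grid", period = init$period0,
                         sigma0_sq = init$sigma0_sq, mu_z = init$mu_z)
fit <- fit_lgcp(counts, prior, init_mu = init$mu_init)
fit
#> <lgcp_state> ELBO = -8843.7413 nats (3 outer iterations, converged)

# 4. How well does the expected rate recover the ground truth?
rate_hz <- exp(unpad_map(fit$mu + fit$v / 2, grid$pad)) / sim$session$dt
visited <- unpad_map(counts$n, grid$pad) > 0
round(cor(rate_hz[visited], exp(sim$truth)[visited]), 3)
#> [1] 0.973

# 5. Field segmentation and a peak-location confidence ellipse
seg <- segment_fields(unpad_map(fit$mu, grid$pad), init$period0)
nrow(seg$peaks)
#> [1] 32
best <- which.max(vapply(seq_len(nrow(seg$peaks)), function(i)
  sum(counts$n[seg$peaks$row[i] + grid$pad + (-3:3),
               seg$peaks$col[i] + grid$pad + (-3:3)]), 0))
fp <- peak_covariance_quadratic(
  fit, c(seg$peaks$row[best] + grid$pad, seg$peaks$col[best] + grid$pad))
round(fp$ellipse$semi_axes, 2)   # 95% CI semi-axes, bins
#> [1] 0.33 0.24
```

The heuristic recovers the simulated 13-bin period to within a tenth of
a bin; the fitted expected-rate map correlates with the ground truth at
r = 0.97 on visited bins; and the best-sampled grid field's location is
pinned down to about a third of a bin (roughly 6 mm at 2 cm bins) at
95% confidence. `grid_search_hyper()` refines the period, variance
scale and orientation further by ELBO hill-climbing, and `crossval()`
compares the fitted model against matched-bandwidth KDE baselines on
held-out data.

A thin command-line wrapper covering the same workflow (simulate / fit /
search / peaks / eval) lives at `inst/cli/lgcp.R`.

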
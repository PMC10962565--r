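---
title: "Variational LGCP regression for grid-cell rate maps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational LGCP regression for grid-cell rate maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A grid cell's spiking is modelled as a log-Gaussian Cox process (LGCP). A
behavioural session provides positions $x_t$ and spike counts $y_t$ in
uniform time bins $\Delta t$. The log firing-rate map $z(x)$ receives a
Gaussian-process prior $z \sim \mathcal N(\mu_z, \Sigma_z)$ and, given
$z$, counts are conditionally Poisson with mean $e^{z(x_t)}$ (time is
rescaled so $\Delta t = 1$; rates in Hz are recovered by dividing by
$\Delta t$). After aggregating time points that share a spatial bin, the
data enter only through the per-bin visit mass $n$ and spike mass $k$, so
the log-likelihood is $z^\top k - n^\top e^z$ up to a constant. Samples
are binned with bilinear (square-pyramidal) weights over the $2 \times 2$
surrounding bin centres, which amounts to trapezoid-rule integration of
the likelihood and conserves both masses exactly.

Because the prior covariance is stationary ($\Sigma_{z,ij} = K(x_i -
x_j)$ on a rectangular grid), $\Sigma_z$ is circulant and all products
with it are pointwise multiplications in the spatial-frequency domain. We
use the real, unitary, self-inverse Hartley transform ("cas" kernel)
rather than the complex Fourier transform so that every linear-algebra
step stays in real arithmetic; for the even-symmetric kernels used here
the Hartley and Fourier coefficients coincide. Grids are zero-padded by
at least the kernel radius so circulant wrap-around never couples
opposite arena walls.

## Kernels for grid cells

Two base kernels encode grid periodicity:

* **Hexagonal** (`grid_kernel`): the sum of three cosine plane waves with
  period $P$ rotated $\pi/3$ apart, with orientation $\theta_0$
  ($\pi/3$-periodic). On even-sized circulant grids the kernel is
  symmetrised circularly so its spectrum is exactly real.
* **Radial** (`radial_kernel`): the angular average $J_0(2\pi r/P)$,
  which is orientation-agnostic; its 3D analogue
  $\sin(2\pi r/P)/(2\pi r/P)$ is provided as a pure function.

Raw periodic kernels are global; `localize_kernel` truncates them to
nearest-neighbour interactions with a hard circular window of radius
$r_c = k_3 P / 2\pi$ ($k_3 \approx 8.65$, the third positive root of
$J_0$, computed by root-finding; the window boundary is included), blurs
with an isotropic Gaussian of standard deviation $P/\pi$, and clips any
negative Fourier coefficients to zero. The clipped spectrum is the
positive-semidefinite guarantee; its price is a small residual spatial
leakage beyond the window (on the order of 1% of $K(0)$ on average),
which the tests document rather than hide. The final prior kernel is
$K_\Theta = \sigma_0^2 K_{\text{loc}} + c$: $\sigma_0^2$ sets the
marginal variance of the spatial structure, and the constant offset $c$
adds variance only to the DC (mean log-rate) component. We fix
$c = 10^3$ so the inference is effectively free to choose the mean
log-rate.

## Low-rank spectral subspace

Most eigenvalues of a localized periodic prior are negligible. We retain
the components whose magnitude exceeds 10% of the largest *non-DC*
eigenvalue magnitude, and always retain the DC component. (The reference
point must exclude DC: with $c = 10^3$ the DC eigenvalue is $cM$, orders
of magnitude above every spatial eigenvalue, and a global threshold
would discard the entire spatial structure.) The retained rows of the
Hartley transform form a semi-orthogonal basis $\tilde R$
($\tilde R^\top \tilde R = I_D$); for the default study configuration
($90 \times 90$ arena, $P = 13$, padded to $126 \times 126$) the rank is
$D \approx 200\text{--}300$ of $M = 15876$. All inference runs on
coefficients in this subspace; the posterior mean is stored as the
deviation from $\mu_z$ in coefficients, which avoids the
ill-conditioning of mixing full-rank means with low-rank gradients.

## Inference

**MAP.** The log-posterior is concave; Newton iterations solve
$(\Sigma_z^{-1} + \mathrm{diag}\,\tilde\lambda)\,\delta = g$ with
$\tilde\lambda = n \circ e^{z}$. The solve uses a preconditioned
conjugate-gradient Krylov method whose only matrix operations are the
spectral prior product and a diagonal scaling, preconditioned by the
prior covariance applied spectrally; a backtracking line search on the
posterior objective guards each step. (The normal equations are
symmetric positive-definite, so conjugate gradients is the natural
minimum-residual-type Krylov solver here.)

**Variational posterior.** The posterior is approximated by
$\mathcal N(\mu, \Sigma)$ with the exact stationary parameterisation
$\Sigma^{-1} = \Sigma_z^{-1} + \mathrm{diag}\,q$. The evidence lower
bound (ELBO) is maximised by alternating (i) Newton optimisation of
$\mu$ (identical to MAP but with the expected rate
$\bar\lambda = n \circ e^{\mu + v/2}$) and (ii) the fixed-point sweep
$q \leftarrow \bar\lambda(v)$,
$v \leftarrow \mathrm{diag}\,(\Sigma_z^{-1} + \mathrm{diag}\,q)^{-1}$,
started from $v = 0$. Marginal variances are computed by Cholesky
factorisation of the $D \times D$ matrix $\Lambda = \mathrm{diag}\,
\tilde\xi^{-1} + X X^\top$ with $X = \tilde R^\top \sqrt q$ restricted to
occupied bins, at cost $O(D^2 N + D^3)$. The iteration keeps
$0 \preceq \Sigma \preceq \Sigma_z$; if a full fixed-point step would
ever decrease the ELBO the update is step-halved (it is a unit-step
gradient ascent on $q$), which in practice never triggers when the mean
is re-optimised before each sweep. The exponent $\mu + v/2$ is clipped
at 700 nats so degenerate hyperparameters encountered during grid search
cannot overflow.

The ELBO is reported in nats with the data constant $\ln y!$ omitted
everywhere (it does not affect any gradient and cancels in all
comparisons on fixed data), and with the Gaussian KL dimension constant
taken as the retained rank $D$ rather than $M$, so values remain
comparable across ranks.

Numerical tolerances: outer loop stops at a relative ELBO change of
$10^{-6}$ (at most 20 outer iterations); Newton stops when the projected
gradient norm falls below $10^{-6}$ relative to the spike-count norm;
conjugate gradients at relative residual $10^{-6}$ with an iteration cap
of $10 D$; a Cholesky that fails numerically is retried once with a
$10^{-10}$-scaled jitter.

## Hyperparameter selection

Initial values come from the rate histogram: the period from the first
positive secondary peak $\Delta_p$ of its radial autocorrelogram via
$P = 2\pi \Delta_p / k_{1,2}$, where $k_{1,2} \approx 7.0156$ is the
second *positive* zero of $J_1$ (the first, 3.8317, marks the trough of
$J_0$, not a peak, so 7.0156 is the constant consistent with "first
nonzero peak"; both constants are obtained by root-finding). Orientation
comes from a 6-fold sinusoid fitted on the ring at radius $\Delta_p$ of
the 2D autocorrelogram; the lattice axes sit $30^\circ$ from the wave
normals, so the fitted ring phase is shifted by $-\pi/6$ to give
$\theta_0$. Foreground and background maps are ratio-of-smoothed-counts
Gaussian estimates at widths $P/\pi$ and $5P/\pi$ (the ratio form with a
floored denominator is well defined at unvisited bins, unlike smoothing
the raw $k/n$ histogram); $\mu_z$ is the log-background, the initial
$\mu$ the log-foreground, and $\sigma_0^2$ the variance of their
difference.

The grid search then hill-climbs $(P, \sigma_0^2)$ multiplicatively with
an orientation-agnostic radial kernel, sweeps 16 orientations in
$[0, \pi/3)$ with the hexagonal kernel, and re-climbs $(P, \sigma_0^2)$
at the selected orientation, warm-starting every fit from the incumbent
state and ranking by converged ELBO. The climb starts with a step factor
of 1.3 and halves it (in log space) to about 1.02 at each local maximum;
the coarse first stage matters because the heuristic $\sigma_0^2$
routinely underestimates the ELBO-optimal value severalfold. Bounds:
$P \in [4, \text{side}/2]$ bins (also capped so $r_c$ fits in the
padding), $\sigma_0^2 \in [10^{-3}, 10^2]$; $c$ is never searched.

## Posterior summaries

Samples are drawn as $z = \mu + \tilde R\, U^{-1} \eta$ where
$\Lambda = U^\top U$. Field peaks are strict 8-neighbour local maxima
(padding excluded), refined by 2D quadratic interpolation; the arena is
segmented into Voronoi cells of the peaks out to $0.7P$. Peak-location
uncertainty uses the locally quadratic argument: with $H$ the
central-difference Hessian of $\mu$ at a peak and $G$ the
central-difference spatial gradient of the covariance factor rows,
$\Sigma_{\Delta x} = (H^{-1} G U^{-1}) (H^{-1} G U^{-1})^\top$, and the
95% ellipse scales the eigendecomposition by $\sqrt{\chi^2_2(0.95)}$. On
the synthetic study session the quadratic and sampling ellipses agree to
within a few percent in axis length on well-sampled fields; the tests
require 25%.

Head-direction analyses offer two routes. Conditioning: squared-cosine
weights $\max(0, \cos(\phi - \phi_0))^2$ turn a heading-conditioned map
into an ordinary weighted 2D problem. Joint inference: heading becomes a
third, circular, unpadded axis with the clipped squared-cosine kernel,
the joint prior is the tensor product with the spatial kernel, and the
subspace is capped at the 1000 largest components. Raw headings are
smoothed in (cos, sin) component space with a Savitzky–Golay filter
(order 3, window of one second — the combination that places the cutoff
near 2 Hz at 50 Hz sampling; both are configurable since only the cutoff
is conventionally fixed).

## The synthetic-data generator

The simulator is the package's test bed and defines the study
conditions: a $90 \times 90$ bin arena (nominally 2 cm bins), an ideal
hexagonal log-rate map with a 13-bin period, 30 minutes of foraging at
50 samples/s, and conditionally Poisson spikes calibrated so the
*trajectory-averaged* expected rate is exactly 1.2 Hz (calibrating along
the trajectory rather than over space makes the expected total spike
count independent of occupancy inhomogeneity). The trajectory is
Brownian motion, cumulative-summed from the arena centre, clipped to the
walls, then passed twice through a first-order exponential smoother with
$\tau = 190$ ms (discretised as $y_t = y_{t-1} + (1 - e^{-\Delta t/
\tau})(x_t - y_{t-1})$, initialised at the first sample). The diffusion
default is 1 bin$^2$/s, i.e. a per-sample standard deviation of
$\sqrt{0.02}$ bins: this corresponds to an instantaneous speed around
14 cm/s at 2 cm bins and lets the walk traverse the arena within a
session, which a diffusion two orders of magnitude smaller could not.
The log-rate modulation amplitude (not fixed by a mean-rate statement)
defaults to 1, giving roughly $e^{\pm 1.5}$-fold rate modulation around
the mean. One seed drives two independent sub-streams (trajectory and
spikes), so sessions are bit-reproducible.

What the generator does *not* emulate: ballistic/thigmotactic running
(plain Brownian motion covers only part of the arena in 30 minutes, so
estimator comparisons are restricted to visited bins), theta modulation,
conjunctive heading tuning (headings for the joint-inference tests are
synthesised separately), and non-Poisson dispersion. Passing tests
therefore demonstrate correctness of the estimator pipeline under the
model's own assumptions, not robustness to real-data violations of
them.

## Problem sizes used in the tests

The test suite runs dense-matrix oracles on grids up to $16 \times 16$
(where $M \times M$ algebra is exact and fast), scalar quadrature
oracles on decoupled single-bin problems, and the full study
configuration for the end-to-end checks. The estimator-comparison
harness uses 12 bootstrap replicates at two training durations, and
10-fold cross-validation with per-fold heuristic hyperparameter
estimation; the three-stage grid search is exercised on a
$45 \times 45$, 10-minute session. These sizes were chosen to keep the
whole suite under a few minutes while leaving every comparison
overwhelmingly clear of its decision boundary.

## Known limitations

* Stationary kernels only; boundary-dependent distortions of real grids
  are outside the model.
* The spectral clipping that enforces positive semidefiniteness slightly
  delocalises the kernel; the effect is documented by the tests.
* The ELBO ranks hyperparameters but is not the marginal likelihood;
  differences of a few nats between kernels should not be
  over-interpreted.
* Cross-validation uses contiguous time folds to limit trajectory
  autocorrelation leakage, but adjacent-fold boundaries still share
  short-range dependence.
* The quadratic peak-location ellipse assumes a well-separated,
  negative-definite peak; diffuse or merging fields should rely on the
  sampling route instead.
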
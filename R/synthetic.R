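#' Simulation configuration for a synthetic grid-cell session
#'
#' Bundles the parameters of the built-in foraging simulator: an ideal
#' hexagonal log-rate map on a square arena, a smoothed Brownian-motion
#' trajectory, and conditionally Poisson spike counts.
#'
#' @param grid_side arena side length in bins (square arena).
#' @param period_bins grid spatial period, in bins.
#' @param orientation grid orientation, radians.
#' @param mean_rate target trajectory-averaged firing rate, Hz.
#' @param duration session length, seconds.
#' @param sample_rate sampling rate, Hz.
#' @param diffusion Brownian diffusion constant, bins^2/s. Per-step position
#'   variance is `diffusion / sample_rate` on each axis. The default of
#'   1 bins^2/s (0.02 bins^2 per 20 ms sample) corresponds to a mean speed
#'   of roughly 14 cm/s at 2 cm bins and covers a 90-bin arena in 30 min.
#' @param smooth_tau time constant of the first-order exponential smoother
#'   applied twice to the raw walk, seconds.
#' @param log_amplitude contrast of the log-rate modulation (multiplies the
#'   three-cosine hexagonal wave, which itself spans \[-1.5, 3\]).
#' @param seed integer random seed; feeds separate sub-streams for the
#'   trajectory and the spikes.
#' @return an object of class `sim_config`.
#' @seealso [simulate_session()]
#' @export
sim_config <- function(grid_side = 90, period_bins = 13, orientation = 0,
                       mean_rate = 1.2, duration = 1800, sample_rate = 50,
                       diffusion = 1.0, smooth_tau = 0.190,
                       log_amplitude = 1.0, seed = 1L) {
  stopifnot(grid_side > 0, period_bins > 0, mean_rate >= 0, duration > 0,
            sample_rate > 0, diffusion >= 0, smooth_tau > 0,
            log_amplitude >= 0)
  if (period_bins >= grid_side)
    stop("period_bins must be smaller than grid_side")
  n_samples <- duration * sample_rate
  if (abs(n_samples - round(n_samples)) > 1e-8)
    stop("duration * sample_rate must be an integer number of samples")
  structure(list(grid_side = grid_side, period_bins = period_bins,
                 orientation = orientation, mean_rate = mean_rate,
                 duration = duration, sample_rate = sample_rate,
                 diffusion = diffusion, smooth_tau = smooth_tau,
                 log_amplitude = log_amplitude, seed = as.integer(seed)),
            class = "sim_config")
}

#' Hexagonal plane-wave sum
#'
#' Evaluates the sum of three cosine plane waves rotated pi/3 from each
#' other, the ideal grid-cell pattern with period `period` and orientation
#' `orientation`. Its value at the origin is 3 and its spatial mean over
#' whole periods is 0.
#'
#' @param x1,x2 coordinates (bins); vectors of equal length.
#' @param period spatial period, bins.
#' @param orientation grid orientation, radians.
#' @return numeric vector of the same length as `x1`.
#' @export
hex_wave <- function(x1, x2, period, orientation = 0) {
  stopifnot(period > 0)
  out <- 0
  for (l in 0:2) {
    a <- pi * l / 3 - orientation
    out <- out + cos(2 * pi / period * (x1 * cos(a) - x2 * sin(a)))
  }
  out
}

#' Ideal hexagonal log-rate map
#'
#' Evaluates `amplitude * hex_wave` at the bin centres of a square grid.
#' Bin centre (i, j) sits at coordinates (j - 0.5, i - 0.5) bins (x along
#' columns, y along rows), so the lattice origin lies at the arena corner.
#' The map is un-normalised; mean-rate calibration happens in
#' [simulate_session()].
#'
#' @param grid_side side length, bins.
#' @param period spatial period, bins (must be at least 2).
#' @param orientation radians.
#' @param amplitude log-rate contrast.
#' @return `grid_side` x `grid_side` matrix (rows = y, columns = x).
#' @export
ideal_grid_log_rate <- function(grid_side, period, orientation = 0,
                                amplitude = 1.0) {
  if (!is.numeric(period) || period < 2)
    stop("period must be at least 2 bins")
  cx <- seq_len(grid_side) - 0.5
  x1 <- matrix(cx, grid_side, grid_side, byrow = TRUE)  # x varies by column
  x2 <- matrix(cx, grid_side, grid_side)                # y varies by row
  matrix(amplitude * hex_wave(as.vector(x1), as.vector(x2), period,
                              orientation),
         grid_side, grid_side)
}

# First-order exponential smoother y_t = y_{t-1} + a (x_t - y_{t-1}),
# a = 1 - exp(-dt/tau), initialised at the first sample.
exp_smooth <- function(x, dt, tau) {
  a <- 1 - exp(-dt / tau)
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive", init = x[1]))
}

#' Simulate a foraging trajectory
#'
#' Brownian increments with per-step variance `diffusion / sample_rate` per
#' axis, cumulative-summed from the arena centre, clipped to
#' \[0, grid_side\], then passed twice through a first-order exponential
#' smoother with time constant `smooth_tau`.
#'
#' @param cfg a [sim_config()].
#' @return T x 2 matrix of positions in bins (columns x, y).
#' @export
simulate_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- round(cfg$duration * cfg$sample_rate)
  dt <- 1 / cfg$sample_rate
  sd_step <- sqrt(cfg$diffusion / cfg$sample_rate)
  set.seed(cfg$seed)
  pos <- matrix(0, n, 2)
  for (ax in 1:2) {
    raw <- cfg$grid_side / 2 + cumsum(stats::rnorm(n, 0, sd_step))
    raw <- pmin(pmax(raw, 0), cfg$grid_side)
    sm <- exp_smooth(exp_smooth(raw, dt, cfg$smooth_tau), dt, cfg$smooth_tau)
    pos[, ax] <- pmin(pmax(sm, 0), cfg$grid_side)
  }
  colnames(pos) <- c("x", "y")
  pos
}

#' Simulate a full synthetic grid-cell session
#'
#' Evaluates the ideal hexagonal log-rate along a simulated trajectory by
#' bilinear interpolation, adds a constant offset so the trajectory-averaged
#' expected rate equals `cfg$mean_rate` exactly, and draws per-sample spike
#' counts from a Poisson distribution with mean `rate * dt`.
#'
#' @param cfg a [sim_config()].
#' @return a list with components `session` (a [session()] object with
#'   positions in bins) and `truth` (the calibrated ground-truth log-rate
#'   map, log Hz, `grid_side` x `grid_side`).
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- round(cfg$duration * cfg$sample_rate)
  dt <- 1 / cfg$sample_rate
  pos <- simulate_trajectory(cfg)
  zmap <- ideal_grid_log_rate(cfg$grid_side, cfg$period_bins,
                              cfg$orientation, cfg$log_amplitude)
  ztraj <- bilinear_lookup(zmap, pos[, 1], pos[, 2])
  if (cfg$mean_rate > 0) {
    # offset so that mean(exp(z + off)) over the trajectory = mean_rate
    off <- log(cfg$mean_rate) - log(mean(exp(ztraj)))
    rate <- exp(ztraj + off)              # Hz along the trajectory
    set.seed(cfg$seed + 104729L)          # independent spike sub-stream
    spikes <- stats::rpois(n, rate * dt)
    truth <- zmap + off
  } else {
    spikes <- integer(n)
    truth <- zmap - Inf
  }
  sess <- session(times = (seq_len(n) - 1) * dt, x = pos[, 1], y = pos[, 2],
                  spikes = spikes, dt = dt)
  list(session = sess, truth = truth)
}

# Bilinear interpolation of a map (rows = y, cols = x, bin centres at
# (i - 0.5)) at continuous positions in bins. Edge samples clamp to the
# boundary bin centres.
bilinear_lookup <- function(map, x, y) {
  nr <- nrow(map); nc <- ncol(map)
  u <- pmin(pmax(x - 0.5, 0), nc - 1)  # 0-based distance from first centre
  v <- pmin(pmax(y - 0.5, 0), nr - 1)
  j0 <- pmin(floor(u), nc - 2); i0 <- pmin(floor(v), nr - 2)
  fu <- u - j0; fv <- v - i0
  idx <- function(i, j) map[cbind(i + 1, j + 1)]
  (1 - fu) * (1 - fv) * idx(i0, j0) +
    fu * (1 - fv) * idx(i0, j0 + 1) +
    (1 - fu) * fv * idx(i0 + 1, j0) +
    fu * fv * idx(i0 + 1, j0 + 1)
}
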
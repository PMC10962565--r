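#' Smooth a head-direction time series
#'
#' Converts the raw heading to cosine/sine components, fills gaps by
#' linear interpolation, low-passes each component with a Savitzky-Golay
#' filter (order 3; window of about one second, which places the cutoff
#' near 2 Hz at 50 Hz sampling), and recombines via the angle of the
#' complex sum. Component-space smoothing avoids 2-pi wrap artefacts.
#'
#' @param phi_raw heading, radians; may contain `NA`.
#' @param sample_rate sampling rate, Hz.
#' @param valid_mask optional logical vector marking usable samples
#'   (defaults to `!is.na(phi_raw)`).
#' @param order,window Savitzky-Golay polynomial order and window length
#'   (window forced odd; default about 1 s of samples).
#' @return list with `phi` (smoothed heading in \[0, 2 pi)) and
#'   `valid_mask`.
#' @export
smooth_heading <- function(phi_raw, sample_rate, valid_mask = NULL,
                           order = 3, window = NULL) {
  if (is.null(valid_mask)) valid_mask <- !is.na(phi_raw)
  if (sum(valid_mask) < 2) stop("need at least two valid heading samples")
  T <- length(phi_raw)
  if (is.null(window)) window <- round(sample_rate)
  window <- max(order + 2, window)
  if (window %% 2 == 0) window <- window + 1
  idx <- which(valid_mask)
  comp <- function(f) {
    y <- f(phi_raw[idx])
    yi <- stats::approx(idx, y, xout = seq_len(T), rule = 2)$y
    if (T > window) signal::sgolayfilt(yi, p = order, n = window) else yi
  }
  cx <- comp(cos); sx <- comp(sin)
  phi <- atan2(sx, cx) %% (2 * pi)
  list(phi = phi, valid_mask = valid_mask)
}

#' Squared-cosine head-direction weights
#'
#' `w = max(0, cos(phi - phi0))^2`: unity at the reference direction,
#' zero at +-90 degrees and for the whole opposing hemifield, so opposing
#' reference directions select disjoint data subsets.
#'
#' @param phi heading, radians.
#' @param phi0 reference direction, radians.
#' @return weights in \[0, 1\].
#' @export
direction_weights <- function(phi, phi0) {
  pmax(0, cos(phi - phi0))^2
}

#' Head-direction-weighted binned counts
#'
#' Bins a session with per-sample visit mass `w` and spike mass `w * y`,
#' where `w` are the squared-cosine weights for reference direction
#' `phi0`. Downstream inference is unchanged: a heading-conditioned rate
#' map is inferred exactly like an unconditioned one.
#'
#' @param sess a [session()] object.
#' @param heading smoothed heading, radians (length T); defaults to
#'   `sess$heading`.
#' @param phi0 reference direction, radians.
#' @param grid a [grid_spec()].
#' @return a [binned_counts()].
#' @export
weighted_counts <- function(sess, phi0, grid, heading = NULL) {
  if (is.null(heading)) heading <- sess$heading
  if (is.null(heading)) stop("session has no heading")
  bin_session(sess, grid, weights = direction_weights(heading, phi0))
}

#' Bin a session jointly over space and head direction
#'
#' Trilinear binning: bilinear in space, circular-linear over `n_dir`
#' uniformly spaced direction bins (centres at `2 pi (j - 1) / n_dir`).
#' The direction axis is circular and receives no padding.
#'
#' @param sess a [session()] object with heading (or `heading` supplied).
#' @param grid a [grid_spec()].
#' @param n_dir number of direction bins.
#' @param heading optional heading override, radians.
#' @return list with 3D arrays `n`, `k` of dimension
#'   `c(n_dir, padded rows, padded cols)`, plus `grid` and `n_dir`.
#' @export
bin_session_joint <- function(sess, grid, n_dir = 24, heading = NULL) {
  if (is.null(heading)) heading <- sess$heading
  if (is.null(heading)) stop("session has no heading")
  u <- (sess$positions[, 1] - grid$origin[1]) / grid$bin_size
  v <- (sess$positions[, 2] - grid$origin[2]) / grid$bin_size
  keep <- !is.na(u) & !is.na(v) & !is.na(heading)
  u <- u[keep]; v <- v[keep]
  spk <- sess$spikes[keep]
  phi <- heading[keep] %% (2 * pi)
  dims <- c(n_dir, padded_dim(grid))
  nr <- dims[2]; nc <- dims[3]
  # spatial bilinear weights (padded coordinates)
  uu <- pmin(pmax(u - 0.5, 0), grid$cols - 1) + grid$pad
  vv <- pmin(pmax(v - 0.5, 0), grid$rows - 1) + grid$pad
  j0 <- pmin(floor(uu), nc - 2); i0 <- pmin(floor(vv), nr - 2)
  fu <- uu - j0; fv <- vv - i0
  # circular-linear direction weights
  ud <- phi / (2 * pi) * n_dir
  d0 <- floor(ud); fd <- ud - d0
  acc_n <- numeric(prod(dims)); acc_k <- numeric(prod(dims))
  add <- function(dd, ii, jj, w) {
    lin <- (dd %% n_dir) + 1 + n_dir * (ii + nr * jj)
    s_n <- rowsum(w, lin); s_k <- rowsum(w * spk, lin)
    at <- as.integer(rownames(s_n))
    acc_n[at] <<- acc_n[at] + s_n[, 1]
    acc_k[at] <<- acc_k[at] + s_k[, 1]
  }
  for (di in 0:1) for (si in 0:1) for (sj in 0:1) {
    w <- (if (di == 0) 1 - fd else fd) *
      (if (si == 0) 1 - fv else fv) *
      (if (sj == 0) 1 - fu else fu)
    add(d0 + di, i0 + si, j0 + sj, w)
  }
  list(n = array(acc_n, dims), k = array(acc_k, dims),
       grid = grid, n_dir = n_dir)
}

#' Joint position-plus-direction prior
#'
#' Tensor product of the squared-cosine direction kernel with a finalized
#' spatial kernel, reduced to a low-rank spectral subspace capped at
#' `rank_cap` components (largest eigenvalues first).
#'
#' @param spatial a finalized `lgcp_kernel` (e.g. an optimised grid
#'   kernel passed through [parameterize_kernel()]).
#' @param n_dir number of direction bins.
#' @param mu_z prior mean log-rate: scalar, 2D map (replicated across
#'   directions) or full 3D array.
#' @param rank_cap maximum retained rank.
#' @param keep_fraction eigenvalue threshold (applied before the cap).
#' @return an [lgcp_prior()] over `c(n_dir, rows, cols)`.
#' @export
joint_prior <- function(spatial, n_dir = 24, mu_z = 0, rank_cap = 1000,
                        keep_fraction = 0) {
  kj <- joint_kernel(direction_kernel(n_dir), spatial)
  sp <- build_spectral_prior(kj, keep_fraction = keep_fraction,
                             max_rank = rank_cap)
  if (length(mu_z) > 1 && length(dim(mu_z)) == 2) {
    mu_z <- aperm(array(mu_z, dim = c(dim(mu_z), n_dir)), c(3, 1, 2))
  }
  lgcp_prior(sp, mu_z, hyper = list(n_dir = n_dir))
}

#' Head-direction-conditioned peak-density maps
#'
#' Samples the joint 2D-plus-direction posterior, slices each sample at
#' every direction bin, finds local maxima (strict 8-neighbour, interior
#' only), and accumulates a per-direction peak-density map using a disc of
#' radius `radius_frac * period`.
#'
#' @param joint_state a fitted [lgcp_state] over `c(n_dir, rows, cols)`.
#' @param period grid period, bins.
#' @param n_samples posterior draws.
#' @param seed RNG seed.
#' @param radius_frac disc radius fraction (the conventional choice for
#'   conditional maps is 1/2.5).
#' @param pad padding margin to exclude from peak detection.
#' @return array `c(n_dir, rows, cols)` of per-direction densities.
#' @export
conditional_peak_density <- function(joint_state, period, n_samples = 100,
                                     seed = 1L, radius_frac = 1 / 2.5,
                                     pad = 0) {
  sp <- joint_state$factor$prior
  stopifnot(length(sp$dims) == 3)
  n_dir <- sp$dims[1]
  d2 <- sp$dims[2:3]
  samples <- sample_posterior(joint_state, n_samples, seed = seed)
  out <- array(0, dim = sp$dims)
  for (d in seq_len(n_dir)) {
    sl <- array(samples[d, , , ], dim = c(d2, n_samples))
    out[d, , ] <- peak_density(sl, period, radius_frac = radius_frac,
                               pad = pad)
  }
  out
}
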
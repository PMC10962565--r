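#' Heuristic initialisation and ELBO-driven hyperparameter search
#'
#' The kernel hyperparameters (period P, variance scale sigma0^2, constant
#' offset c, and for oriented kernels the orientation theta0) are first
#' guessed from the radial autocorrelogram of the rate histogram, then
#' refined by a hill-climbing grid search that ranks candidates by the
#' ELBO of the fitted variational posterior.
#'
#' @name hyperparams
NULL

# circular Gaussian blur with a unit-mass kernel, via FFT
gauss_blur <- function(map, sigma) {
  d <- dim(map)
  D <- disp_grids(d)
  g <- exp(-(D$dx1^2 + D$dx2^2) / (2 * sigma^2))
  g <- g / sum(g)
  Re(stats::fft(stats::fft(map) * stats::fft(g), inverse = TRUE)) /
    length(map)
}

# second positive zero of J1 (7.0156): marks the first positive secondary
# peak of J0, hence the first nonzero peak of the radial autocorrelogram
bessel_j1_zero2 <- function() {
  stats::uniroot(function(x) besselJ(x, 1), c(6.5, 7.5), tol = 1e-12)$root
}

#' Radial autocorrelogram of a rate map
#'
#' Mean-subtracted 2D spatial autocorrelation (FFT-based, zero-padded to
#' avoid wraparound, normalised to 1 at zero lag), averaged over angles
#' into radial bins of width 1 bin. Missing values (unvisited bins) are
#' replaced by the map mean before correlating.
#'
#' @param rate_map matrix; may contain `NA` at unvisited bins.
#' @return an object of class `radial_autocorr`: list with `radius` (bin
#'   centres 0, 1, 2, ...), `correlation`, and `acmap` (the centred 2D
#'   autocorrelogram, odd dimensions, zero lag at the centre).
#' @export
radial_autocorrelogram <- function(rate_map) {
  m <- rate_map
  mu <- mean(m, na.rm = TRUE)
  if (!is.finite(mu)) stop("rate map has no finite values")
  m[!is.finite(m)] <- mu
  m <- m - mean(m)
  if (all(m == 0)) stop("constant rate map: autocorrelation undefined")
  d <- dim(m)
  dp <- 2 * d  # zero-pad for linear correlation
  mp <- matrix(0, dp[1], dp[2]); mp[seq_len(d[1]), seq_len(d[2])] <- m
  F <- stats::fft(mp)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / length(mp)
  ac <- ac / ac[1, 1]
  # centre: keep lags up to +-(d-1)
  rr <- c((dp[1] - d[1] + 2):dp[1], 1:d[1])
  cc <- c((dp[2] - d[2] + 2):dp[2], 1:d[2])
  acmap <- ac[rr, cc]  # (2 d1 - 1) x (2 d2 - 1), zero lag at centre
  ctr <- d
  dy <- (seq_len(nrow(acmap)) - ctr[1])
  dx <- (seq_len(ncol(acmap)) - ctr[2])
  r <- sqrt(outer(dy^2, dx^2, `+`))
  rmax <- floor(min(d) / 2)
  ri <- round(r)
  keep <- ri <= rmax
  prof <- as.numeric(tapply(acmap[keep], ri[keep], mean))
  structure(list(radius = as.numeric(sort(unique(ri[keep]))),
                 correlation = prof, acmap = acmap, center = ctr),
            class = "radial_autocorr")
}

# quadratic (3-point) interpolation of a local maximum
quad_peak_1d <- function(x, y) {
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom >= 0) return(x[2])
  x[2] + 0.5 * (y[1] - y[3]) / denom * (x[2] - x[1])
}

#' Estimate the grid period from a radial autocorrelogram
#'
#' Locates the first positive local maximum at nonzero lag
#' (quadratic-interpolated) and converts it to a spatial period via
#' `P = 2 pi dp / k12`, where `k12` is the second positive zero of the
#' first-order Bessel function J1 (about 7.0156) -- the lag of the first
#' positive secondary peak of the J0 profile that a period-P map induces.
#'
#' @param autocorr a [radial_autocorrelogram()] result.
#' @return estimated period, bins; the interpolated peak lag is attached
#'   as attribute `peak_lag`.
#' @export
estimate_period <- function(autocorr) {
  stopifnot(inherits(autocorr, "radial_autocorr"))
  y <- autocorr$correlation
  r <- autocorr$radius
  n <- length(y)
  found <- NA_real_
  for (i in 3:(n - 1)) {
    if (y[i] > 0 && y[i] > y[i - 1] && y[i] >= y[i + 1]) {
      found <- quad_peak_1d(r[(i - 1):(i + 1)], y[(i - 1):(i + 1)])
      break
    }
  }
  if (!is.finite(found))
    stop("no secondary peak found in radial autocorrelogram")
  P <- 2 * pi * found / bessel_j1_zero2()
  attr(P, "peak_lag") <- found
  P
}

#' Estimate grid orientation from the 2D autocorrelogram
#'
#' Samples the autocorrelogram on the ring at the first-peak lag
#' `dp = k12 P / (2 pi)` and fits a 6-fold periodic sinusoid
#' `a cos(6 (theta - theta_ring)) + b` by least squares. The hexagonal
#' lattice axes sit 30 degrees from the plane-wave normals, so the kernel
#' orientation is `theta_ring - pi/6`, reported modulo pi/3.
#'
#' @param autocorr a [radial_autocorrelogram()] result (2D map used).
#' @param period grid period, bins.
#' @return orientation in \[0, pi/3); attribute `amplitude` carries the
#'   fitted modulation amplitude relative to the ring mean (a flat ring
#'   yields amplitude about 0 and a warning).
#' @export
estimate_orientation <- function(autocorr, period) {
  stopifnot(inherits(autocorr, "radial_autocorr"))
  dp <- bessel_j1_zero2() * period / (2 * pi)
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  # acmap rows = y lags, cols = x lags, centre at $center
  xs <- autocorr$center[2] + dp * cos(theta)
  ys <- autocorr$center[1] + dp * sin(theta)
  ok <- xs >= 1 & xs <= ncol(autocorr$acmap) &
    ys >= 1 & ys <= nrow(autocorr$acmap)
  rho <- bilinear_lookup(autocorr$acmap, xs[ok] - 0.5, ys[ok] - 0.5)
  th <- theta[ok]
  c6 <- sum(rho * exp(-6i * th)) / length(th)
  amp <- 2 * abs(c6)
  theta_ring <- -Arg(c6) / 6
  if (amp < 1e-3 * max(abs(rho))) {
    warning("autocorrelogram ring is flat: orientation indeterminate")
    return(structure(0, amplitude = amp))
  }
  structure((theta_ring - pi / 6) %% (pi / 3), amplitude = amp)
}

#' Heuristic hyperparameter initialisation
#'
#' Estimates foreground and background rate maps by ratio-of-smoothed
#' counts (Gaussian widths `sigma_f = P0 / pi` and `sigma_b = 5 sigma_f`,
#' P0 from the radial autocorrelogram). The log-background becomes the
#' prior mean, the log-foreground the initial posterior mean guess, the
#' variance of their difference the kernel height sigma0^2, and the
#' constant offset is fixed at c = 1000 so the inference remains free to
#' adjust the mean log-rate.
#'
#' @param counts a [binned_counts()].
#' @return list with `period0`, `sigma0_sq`, `dc0`, `mu_z` (prior mean
#'   log-rate map, padded grid), `mu_init` (initial posterior mean map),
#'   and the autocorrelogram used.
#' @export
heuristic_init <- function(counts) {
  stopifnot(inherits(counts, "binned_counts"))
  if (sum(counts$k) <= 0) stop("no spikes: cannot initialise")
  ac <- radial_autocorrelogram(unpad_map(rate_histogram(counts),
                                         counts$grid$pad))
  P0 <- as.numeric(estimate_period(ac))
  sf <- P0 / pi
  sb <- 5 * sf
  eps <- 1e-9
  fg <- gauss_blur(counts$k, sf) / pmax(gauss_blur(counts$n, sf), eps)
  bg <- gauss_blur(counts$k, sb) / pmax(gauss_blur(counts$n, sb), eps)
  floor_rate <- eps
  lfg <- log(pmax(fg, floor_rate))
  lbg <- log(pmax(bg, floor_rate))
  occ <- counts$n > 0 & fg > 1e-8 & bg > 1e-8
  s0 <- stats::var(lfg[occ] - lbg[occ])
  if (!is.finite(s0)) s0 <- 1e-3
  list(period0 = P0, sigma0_sq = max(s0, 1e-3), dc0 = 1e3,
       mu_z = lbg, mu_init = lfg, autocorr = ac)
}

#' Build a grid-cell prior from hyperparameters
#'
#' Convenience constructor: base kernel (`grid`, `radial` or `rbf`),
#' localisation (window + blur + spectral clipping, skipped for `rbf`),
#' scale/offset parameterisation, low-rank spectral decomposition, and
#' prior mean.
#'
#' @param grid a [grid_spec()].
#' @param kernel one of `"grid"`, `"radial"`, `"rbf"`.
#' @param period period, bins (for `rbf`: converted to the curvature
#'   matched bandwidth, see [matched_bandwidth()]).
#' @param orientation radians (grid kernel only).
#' @param sigma0_sq kernel variance scale.
#' @param dc_offset constant offset c.
#' @param mu_z prior mean log-rate (array on the padded grid, or scalar).
#' @param keep_fraction eigenvalue threshold for the low-rank subspace.
#' @param max_rank optional rank cap.
#' @return an [lgcp_prior()].
#' @export
grid_cell_prior <- function(grid, kernel = c("grid", "radial", "rbf"),
                            period, orientation = 0, sigma0_sq = 1,
                            dc_offset = 1e3, mu_z = 0,
                            keep_fraction = 0.1, max_rank = Inf) {
  kernel <- match.arg(kernel)
  base <- switch(kernel,
    grid = localize_kernel(grid_kernel(grid, period, orientation)),
    radial = localize_kernel(radial_kernel(grid, period)),
    rbf = rbf_kernel(grid, sqrt(matched_bandwidth(period)$sigma_matched_sq)))
  k <- parameterize_kernel(base, sigma0_sq, dc_offset)
  sp <- build_spectral_prior(k, keep_fraction = keep_fraction,
                             max_rank = max_rank)
  lgcp_prior(sp, mu_z,
             hyper = list(kernel = kernel, period = period,
                          orientation = orientation,
                          sigma0_sq = sigma0_sq, dc_offset = dc_offset))
}

#' ELBO-driven hyperparameter grid search
#'
#' Three-stage hill climb, ranking candidates by the converged ELBO and
#' warm-starting every fit from the previous best state: (1) multiplicative
#' hill climb of (P, sigma0^2) with the orientation-agnostic radial
#' kernel, neighbourhood factors {0.9, 1, 1.1} refined toward 1.02 at each
#' local maximum; (2) a sweep of `n_angles` orientations in \[0, pi/3)
#' with the grid kernel; (3) a re-climb of (P, sigma0^2) at the selected
#' orientation. The constant offset c is never searched.
#'
#' @param counts a [binned_counts()].
#' @param init a [heuristic_init()] result (computed if missing).
#' @param kernel final kernel type, `"grid"` (default, all three stages)
#'   or `"radial"` (stage 1 only).
#' @param n_angles orientations swept in stage 2.
#' @param keep_fraction,tol,max_outer passed to the prior and fits.
#' @param verbose print progress.
#' @return list with `hyper` (selected hyperparameters), `state` (fitted
#'   [lgcp_state] at the optimum), `elbo`, and `trace` (data frame of all
#'   evaluations).
#' @export
grid_search_hyper <- function(counts, init = NULL,
                              kernel = c("grid", "radial"),
                              n_angles = 16, keep_fraction = 0.1,
                              tol = 1e-6, max_outer = 20,
                              verbose = FALSE) {
  kernel <- match.arg(kernel)
  if (is.null(init)) init <- heuristic_init(counts)
  grid <- counts$grid
  p_lim <- c(4, max(counts$grid$rows, counts$grid$cols) / 2)
  # keep the kernel cutoff radius inside the padding margin
  p_pad_max <- 2 * pi * grid$pad / bessel_j0_zero3()
  p_lim[2] <- min(p_lim[2], p_pad_max)
  s_lim <- c(1e-3, 1e2)
  trace <- list()
  cache <- new.env(parent = emptyenv())
  best_state <- NULL
  evaluate <- function(ktype, P, s0, th) {
    P <- min(max(P, p_lim[1]), p_lim[2])
    s0 <- min(max(s0, s_lim[1]), s_lim[2])
    key <- sprintf("%s|%.6g|%.6g|%.6g", ktype, P, s0, th)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pr <- grid_cell_prior(grid, ktype, period = P, orientation = th,
                          sigma0_sq = s0, dc_offset = init$dc0,
                          mu_z = init$mu_z, keep_fraction = keep_fraction)
    st <- fit_lgcp(counts, pr, tol = tol, max_outer = max_outer,
                   init_mu = if (is.null(best_state)) init$mu_init else NULL,
                   state0 = best_state)
    res <- list(P = P, s0 = s0, th = th, kernel = ktype,
                elbo = st$elbo, state = st)
    cache[[key]] <- res
    trace[[length(trace) + 1]] <<- data.frame(kernel = ktype, period = P,
                                              sigma0_sq = s0,
                                              orientation = th,
                                              elbo = st$elbo)
    if (verbose)
      message(sprintf("  %s P=%.2f s0=%.3g th=%.3f  ELBO=%.2f",
                      ktype, P, s0, th, st$elbo))
    res
  }
  climb <- function(ktype, P, s0, th, f0 = 1.3) {
    cur <- evaluate(ktype, P, s0, th)
    best_state <<- cur$state
    f <- f0
    repeat {
      cand <- list(cur)
      for (fp in c(1 / f, 1, f)) for (fs in c(1 / f, 1, f)) {
        if (fp == 1 && fs == 1) next
        cand[[length(cand) + 1]] <- evaluate(ktype, cur$P * fp,
                                             cur$s0 * fs, th)
      }
      el <- vapply(cand, function(x) x$elbo, 0)
      nxt <- cand[[which.max(el)]]
      if (nxt$elbo > cur$elbo + 1e-9) {
        cur <- nxt
        best_state <<- cur$state
      } else if (f > 1.03) {
        f <- sqrt(f)   # refine the multiplicative step toward ~1.02
      } else break
    }
    cur
  }
  s1 <- climb("radial", init$period0, init$sigma0_sq, 0)
  if (kernel == "radial") {
    out <- s1
  } else {
    angles <- seq(0, pi / 3, length.out = n_angles + 1)[seq_len(n_angles)]
    s2 <- lapply(angles, function(a) evaluate("grid", s1$P, s1$s0, a))
    el <- vapply(s2, function(x) x$elbo, 0)
    b2 <- s2[[which.max(el)]]
    best_state <- b2$state
    out <- climb("grid", b2$P, b2$s0, b2$th)
  }
  list(hyper = list(kernel = out$kernel, period = out$P,
                    orientation = out$th, sigma0_sq = out$s0,
                    dc_offset = init$dc0),
       state = out$state, elbo = out$elbo,
       trace = do.call(rbind, trace))
}
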
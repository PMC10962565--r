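#' Sample log-rate maps from the variational posterior
#'
#' Draws `z = mu + R~ B eta` with `eta ~ N(0, I_D)`, where `B` is the
#' inverse Cholesky factor of the low-rank posterior precision computed
#' during fitting.
#'
#' @param state a fitted [lgcp_state].
#' @param n_samples number of draws.
#' @param seed integer seed for reproducibility.
#' @return array of dimension `c(dims, n_samples)` (e.g. rows x cols x S).
#' @export
sample_posterior <- function(state, n_samples, seed = 1L) {
  stopifnot(inherits(state, "lgcp_state"))
  sp <- state$factor$prior
  B <- state$factor$B
  D <- ncol(B)
  set.seed(seed)
  eta <- matrix(stats::rnorm(D * n_samples), D, n_samples)
  coefs <- B %*% eta
  out <- array(0, dim = c(sp$dims, n_samples))
  M <- prod(sp$dims)
  for (s in seq_len(n_samples)) {
    out[(s - 1) * M + seq_len(M)] <- state$mu + sp_expand(sp, coefs[, s])
  }
  out
}

# strict local maxima over the 8-neighbourhood; borders excluded
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- matrix(FALSE, nr, nc)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  ctr <- m[ri, ci]
  res <- ctr > m[ri - 1, ci] & ctr > m[ri + 1, ci] &
    ctr > m[ri, ci - 1] & ctr > m[ri, ci + 1] &
    ctr > m[ri - 1, ci - 1] & ctr > m[ri - 1, ci + 1] &
    ctr > m[ri + 1, ci - 1] & ctr > m[ri + 1, ci + 1]
  ok[ri, ci] <- res
  which(ok, arr.ind = TRUE)
}

# sub-bin refinement of a local maximum by 2D quadratic interpolation;
# returns c(row, col) continuous coordinates
refine_peak <- function(m, row, col) {
  g <- c((m[row, col + 1] - m[row, col - 1]) / 2,
         (m[row + 1, col] - m[row - 1, col]) / 2)   # (d/dcol, d/drow)
  H <- peak_hessian(m, row, col)
  off <- tryCatch(-solve(H, g), error = function(e) c(0, 0))
  off <- pmin(pmax(off, -1), 1)
  c(row + off[2], col + off[1])
}

# Hessian of a map at an integer bin by central differences, in (x, y) =
# (col, row) order
peak_hessian <- function(m, row, col) {
  hxx <- m[row, col + 1] - 2 * m[row, col] + m[row, col - 1]
  hyy <- m[row + 1, col] - 2 * m[row, col] + m[row - 1, col]
  hxy <- (m[row + 1, col + 1] - m[row + 1, col - 1] -
            m[row - 1, col + 1] + m[row - 1, col - 1]) / 4
  matrix(c(hxx, hxy, hxy, hyy), 2, 2)
}

#' Peak-density map from posterior samples
#'
#' For every bin, the fraction of posterior samples containing a local
#' maximum within `radius_frac * period` of it.
#'
#' @param samples array from [sample_posterior()] (rows x cols x S).
#' @param period grid period, bins.
#' @param radius_frac disc radius as a fraction of the period.
#' @param pad padding margin to exclude when detecting peaks (peaks inside
#'   the margin are discarded); 0 if the samples are interior maps.
#' @return matrix of values in \[0, 1\], same spatial size as the samples.
#' @export
peak_density <- function(samples, period, radius_frac = 0.5, pad = 0) {
  stopifnot(length(dim(samples)) == 3)
  d <- dim(samples)[1:2]
  S <- dim(samples)[3]
  r <- radius_frac * period
  D <- disp_grids(d)
  disc <- (D$dx1^2 + D$dx2^2) <= r^2
  fdisc <- stats::fft(disc * 1)
  acc <- matrix(0, d[1], d[2])
  for (s in seq_len(S)) {
    pk <- local_maxima(samples[, , s])
    if (pad > 0) {
      keep <- pk[, 1] > pad & pk[, 1] <= d[1] - pad &
        pk[, 2] > pad & pk[, 2] <= d[2] - pad
      pk <- pk[keep, , drop = FALSE]
    }
    ind <- matrix(0, d[1], d[2])
    ind[pk] <- 1
    near <- Re(stats::fft(stats::fft(ind) * fdisc, inverse = TRUE)) /
      length(ind)
    acc <- acc + (near > 0.5)
  }
  acc / S
}

#' Segment a rate map into grid fields
#'
#' Detects the strict local maxima of the (posterior mean) map and assigns
#' every bin to the Voronoi cell of its nearest peak, out to a maximum
#' radius of `max_radius_frac * period`; more distant bins stay unlabeled
#' (0).
#'
#' @param mean_map matrix (typically the interior posterior mean log-rate).
#' @param period grid period, bins.
#' @param max_radius_frac maximum assignment radius as a fraction of the
#'   period.
#' @return list with `labels` (integer matrix, 0 = unlabeled) and `peaks`
#'   (data frame with integer `row`, `col` and refined `row_f`, `col_f`).
#' @export
segment_fields <- function(mean_map, period, max_radius_frac = 0.7) {
  pk <- local_maxima(mean_map)
  if (nrow(pk) == 0) {
    warning("no local maxima found")
    return(list(labels = matrix(0L, nrow(mean_map), ncol(mean_map)),
                peaks = data.frame(row = integer(), col = integer(),
                                   row_f = numeric(), col_f = numeric())))
  }
  ref <- t(apply(pk, 1, function(p) refine_peak(mean_map, p[1], p[2])))
  d <- dim(mean_map)
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  dist2 <- array(Inf, d)
  labels <- matrix(0L, d[1], d[2])
  for (i in seq_len(nrow(pk))) {
    d2 <- (rows - ref[i, 1])^2 + (cols - ref[i, 2])^2
    upd <- d2 < dist2
    dist2[upd] <- d2[upd]
    labels[upd] <- i
  }
  labels[dist2 > (max_radius_frac * period)^2] <- 0L
  list(labels = labels,
       peaks = data.frame(row = pk[, 1], col = pk[, 2],
                          row_f = ref[, 1], col_f = ref[, 2]))
}

#' Quadratic peak-location covariance
#'
#' Locally quadratic approximation to the posterior distribution of a
#' grid-field peak location: with `H` the Hessian of the posterior mean
#' log-rate at the peak and `G` the spatial gradient of the posterior
#' covariance factor there, the peak displacement has covariance
#' `Sigma_dx = (H^{-1} G) (H^{-1} G)^T`. Derivatives are central finite
#' differences at 1-bin spacing.
#'
#' @param state a fitted [lgcp_state].
#' @param x0 peak location, `c(row, col)` on the padded grid (integer bin
#'   of a local maximum of `state$mu`).
#' @param level confidence level for the reported ellipse.
#' @return object of class `field_peak`: list with `location` (refined,
#'   padded-grid row/col), `hessian`, `peak_cov` and `ellipse`.
#' @export
peak_covariance_quadratic <- function(state, x0, level = 0.95) {
  stopifnot(inherits(state, "lgcp_state"))
  sp <- state$factor$prior
  stopifnot(length(sp$dims) == 2)
  m <- state$mu
  row <- round(x0[1]); col <- round(x0[2])
  stopifnot(row > 1, col > 1, row < nrow(m), col < ncol(m))
  H <- peak_hessian(m, row, col)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev >= 0)) stop("Hessian not negative-definite: not a peak")
  lin <- function(r, c) r + nrow(m) * (c - 1)
  rx <- basis_rows(sp, c(lin(row, col + 1), lin(row, col - 1),
                         lin(row + 1, col), lin(row - 1, col)))
  G <- rbind((rx[1, ] - rx[2, ]) / 2,   # d/dx (col)
             (rx[3, ] - rx[4, ]) / 2)   # d/dy (row)
  Bq <- solve(H, G %*% state$factor$B)  # 2 x D
  cov <- Bq %*% t(Bq)
  structure(list(location = refine_peak(m, row, col), hessian = H,
                 peak_cov = cov,
                 ellipse = confidence_ellipse(cov, level)),
            class = "field_peak")
}

#' Confidence ellipse of a 2x2 covariance
#'
#' Eigendecomposition scaled by the chi-square quantile with 2 degrees of
#' freedom; for an isotropic covariance `sigma^2 I` at 95% the radius is
#' `sigma * sqrt(5.991)`.
#'
#' @param cov 2x2 symmetric PSD matrix.
#' @param level confidence level in \[0, 1).
#' @return list with `semi_axes` (descending, bins) and `angle` (radians,
#'   orientation of the major axis).
#' @export
confidence_ellipse <- function(cov, level = 0.95) {
  stopifnot(all(dim(cov) == c(2, 2)))
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance must be symmetric")
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-10 * max(abs(e$values)))
    stop("covariance must be positive semidefinite")
  s <- sqrt(pmax(e$values, 0) * stats::qchisq(level, df = 2))
  list(semi_axes = s, angle = atan2(e$vectors[2, 1], e$vectors[1, 1]))
}
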
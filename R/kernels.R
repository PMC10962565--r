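#' Prior covariance kernels for grid cells
#'
#' Kernels are stored in the spatial domain on the padded circulant grid,
#' origin at element `[1, 1]` with circular wraparound, so that their
#' (real) Fourier coefficients are the eigenvalues of the induced circulant
#' prior covariance. A kernel is *finalized* once its spectrum has been
#' clipped to be non-negative, making the prior positive semidefinite.
#'
#' @name kernels
NULL

# signed circular displacements for an axis of length L: 0, 1, ..., -1
signed_disp <- function(L) {
  idx <- 0:(L - 1)
  ifelse(idx > L / 2, idx - L, idx)
}

# circular even-symmetrisation K <- (K(dx) + K(-dx)) / 2: on even-sized
# grids the Nyquist displacement +-L/2 is a single stored entry, so a
# rotated (non-axis-aligned) kernel must be averaged with its reflection
# to give a symmetric circulant (real spectrum)
symmetrize_circular <- function(v) {
  d <- dim(v)
  (v + v[c(1, d[1]:2), c(1, d[2]:2)]) / 2
}

# displacement matrices (rows = y = Delta x2, cols = x = Delta x1)
disp_grids <- function(d) {
  dr <- signed_disp(d[1]); dc <- signed_disp(d[2])
  list(dx1 = matrix(dc, d[1], d[2], byrow = TRUE),
       dx2 = matrix(dr, d[1], d[2]))
}

new_kernel <- function(values, grid, hyper = NULL, finalized = FALSE) {
  structure(list(values = values, grid = grid, hyper = hyper,
                 finalized = finalized),
            class = "lgcp_kernel")
}

#' @export
print.lgcp_kernel <- function(x, ...) {
  xi <- kernel_spectrum(x)
  cat(sprintf("<lgcp_kernel> %dx%d, K(0) = %.3g, spectrum [%.3g, %.3g]%s\n",
              nrow(x$values), ncol(x$values), x$values[1, 1], min(xi),
              max(xi), if (x$finalized) ", finalized" else ""))
  invisible(x)
}

#' Eigenvalues of the circulant prior induced by a kernel
#'
#' The unnormalised discrete Fourier transform of the (even-symmetric)
#' kernel array; real for symmetric kernels.
#'
#' @param kernel an `lgcp_kernel`.
#' @return numeric array of eigenvalues, same shape as the kernel.
#' @export
kernel_spectrum <- function(kernel) {
  v <- if (inherits(kernel, "lgcp_kernel")) kernel$values else kernel
  Re(stats::fft(v))
}

#' Hexagonal grid kernel
#'
#' The sum of three cosine plane waves rotated pi/3 from each other,
#' evaluated at signed displacements on the padded circulant grid. The
#' result is an un-windowed base kernel; pass it through
#' [localize_kernel()] before use as a prior.
#'
#' @param grid a [grid_spec()].
#' @param period spatial period P, bins (at least 2).
#' @param orientation grid orientation theta0, radians. Orientations theta0
#'   and theta0 + pi/3 give identical kernels.
#' @param aniso optional per-axis scaling of the displacement (x, y) before
#'   evaluation; default isotropic.
#' @return an `lgcp_kernel` (not finalized).
#' @export
grid_kernel <- function(grid, period, orientation = 0, aniso = c(1, 1)) {
  if (period < 2) stop("period must be at least 2 bins (Nyquist)")
  d <- padded_dim(grid)
  D <- disp_grids(d)
  vals <- matrix(hex_wave(as.vector(D$dx1) * aniso[1],
                          as.vector(D$dx2) * aniso[2],
                          period, orientation), d[1], d[2])
  new_kernel(symmetrize_circular(vals), grid,
             hyper = list(period = period, orientation = orientation))
}

#' Radial Bessel kernel
#'
#' Orientation-agnostic kernel `J0(2 pi r / P)`: the angular average of the
#' hexagonal kernel, suitable for cells with a characteristic field
#' spacing but no global lattice.
#'
#' @inheritParams grid_kernel
#' @return an `lgcp_kernel` (not finalized).
#' @seealso [radial_kernel_3d()] for the volumetric analogue.
#' @export
radial_kernel <- function(grid, period, aniso = c(1, 1)) {
  if (period < 2) stop("period must be at least 2 bins (Nyquist)")
  d <- padded_dim(grid)
  D <- disp_grids(d)
  r <- sqrt((D$dx1 * aniso[1])^2 + (D$dx2 * aniso[2])^2)
  vals <- besselJ(2 * pi * r / period, 0)
  new_kernel(vals, grid, hyper = list(period = period))
}

#' 3D radial kernel profile
#'
#' The volumetric (3D) analogue of the radial Bessel kernel,
#' `sin(2 pi r / P) / (2 pi r / P)`, exposed as a pure radial function
#' (no volumetric inference is provided).
#'
#' @param r radial distance, bins.
#' @param period spatial period, bins.
#' @return numeric vector; equals 1 at r = 0.
#' @export
radial_kernel_3d <- function(r, period) {
  stopifnot(period > 0)
  u <- 2 * pi * r / period
  out <- ifelse(u == 0, 1, sin(u) / u)
  out
}

#' Gaussian RBF kernel
#'
#' Squared-exponential kernel `exp(-r^2 / (2 sigma^2))`; the prior analogue
#' of the Gaussian kernel-density smoother, used as a baseline.
#'
#' @param grid a [grid_spec()].
#' @param sigma kernel standard deviation, bins.
#' @return an `lgcp_kernel` (finalized: the RBF spectrum is non-negative).
#' @export
rbf_kernel <- function(grid, sigma) {
  stopifnot(sigma > 0)
  d <- padded_dim(grid)
  D <- disp_grids(d)
  vals <- exp(-(D$dx1^2 + D$dx2^2) / (2 * sigma^2))
  k <- new_kernel(vals, grid, hyper = list(sigma = sigma))
  finalize_kernel(k)
}

# third positive root of J0; window constant for nearest-neighbour cutoff
bessel_j0_zero3 <- function() {
  # J0's first three zeros lie near 2.405, 5.520, 8.654
  stats::uniroot(function(x) besselJ(x, 0), c(8, 9), tol = 1e-12)$root
}

#' Localize a kernel to nearest-neighbour interactions
#'
#' Multiplies the base kernel by a circular Heaviside window of radius
#' `r_c = k3 P / (2 pi)` (k3 = third positive root of J0, about 8.65; the
#' boundary r = r_c is included), blurs with an isotropic Gaussian of
#' standard deviation `sigma = P / pi` (circular convolution), and clips
#' any negative Fourier coefficients to zero. The result is a finalized,
#' positive-semidefinite kernel with good spatial locality.
#'
#' @param base an `lgcp_kernel` on the padded grid.
#' @param period spatial period P, bins; defaults to the base kernel's.
#' @return a finalized `lgcp_kernel`.
#' @export
localize_kernel <- function(base, period = NULL) {
  stopifnot(inherits(base, "lgcp_kernel"))
  if (is.null(period)) period <- base$hyper$period
  stopifnot(is.numeric(period), period > 0)
  d <- dim(base$values)
  rc <- bessel_j0_zero3() * period / (2 * pi)
  if (rc > min(d) / 2)
    stop("kernel cutoff radius ", round(rc, 1),
         " exceeds half the padded grid; increase pad")
  D <- disp_grids(d)
  r <- sqrt(D$dx1^2 + D$dx2^2)
  vals <- base$values * (r <= rc)
  # circular Gaussian blur, unit-mass kernel, via FFT
  sigma <- period / pi
  g <- exp(-r^2 / (2 * sigma^2))
  g <- g / sum(g)
  vals <- Re(stats::fft(stats::fft(vals) * stats::fft(g), inverse = TRUE)) /
    length(vals)
  k <- new_kernel(vals, base$grid, hyper = base$hyper)
  finalize_kernel(k)
}

# clip negative Fourier coefficients to zero and return to space
finalize_kernel <- function(kernel) {
  xi <- kernel_spectrum(kernel)
  xi[xi < 0] <- 0
  vals <- Re(stats::fft(xi, inverse = TRUE)) / length(xi)
  new_kernel(vals, kernel$grid, hyper = kernel$hyper, finalized = TRUE)
}

#' Scale and offset a finalized kernel
#'
#' Forms the parameterised prior kernel
#' `K = sigma0_sq * localized + dc_offset`. The constant offset adds
#' variance only to the DC (mean log-rate) component: under the
#' unnormalised-DFT eigenvalue convention used throughout, the DC
#' eigenvalue grows by `dc_offset * M` where M is the number of padded
#' bins.
#'
#' @param local a finalized `lgcp_kernel`.
#' @param sigma0_sq marginal variance scale, dimensionless (non-negative).
#' @param dc_offset constant offset c, dimensionless (non-negative).
#' @return a finalized `lgcp_kernel` with hyperparameters recorded.
#' @export
parameterize_kernel <- function(local, sigma0_sq, dc_offset = 0) {
  stopifnot(inherits(local, "lgcp_kernel"), local$finalized)
  if (sigma0_sq < 0 || dc_offset < 0)
    stop("sigma0_sq and dc_offset must be non-negative")
  hyper <- local$hyper
  hyper$sigma0_sq <- sigma0_sq
  hyper$dc_offset <- dc_offset
  new_kernel(sigma0_sq * local$values + dc_offset, local$grid,
             hyper = hyper, finalized = TRUE)
}

#' Head-direction kernel on the circle
#'
#' Evaluates the squared-cosine direction window
#' `w(dphi) = max(0, cos dphi)^2` as a displacement function on a circular
#' grid and clips its negative Fourier coefficients to zero, yielding a
#' positive-semidefinite circular kernel. (The raw squared-cosine window is
#' not PSD: some of its circular Fourier coefficients are negative.)
#'
#' @param n_bins number of direction bins (at least 4).
#' @return numeric vector of length `n_bins` (finalized circular kernel).
#' @export
direction_kernel <- function(n_bins) {
  stopifnot(n_bins >= 4)
  dphi <- 2 * pi * (0:(n_bins - 1)) / n_bins
  w <- pmax(0, cos(dphi))^2
  xi <- Re(stats::fft(w))
  xi[xi < 0] <- 0
  Re(stats::fft(xi, inverse = TRUE)) / n_bins
}

#' Joint direction-by-space kernel
#'
#' Separable (outer) product of a circular direction kernel and a spatial
#' kernel: `K(dphi, dx) = K_phi(dphi) * K_x(dx)`. Its spectrum is the
#' outer product of the marginal spectra, hence PSD when both factors are.
#' The direction axis is circular and receives no padding.
#'
#' @param direction numeric vector from [direction_kernel()].
#' @param spatial a finalized `lgcp_kernel`.
#' @return 3D array of dimension `c(n_dir, rows, cols)` (padded spatial
#'   dims), with attribute `grid` carrying the spatial [grid_spec()].
#' @export
joint_kernel <- function(direction, spatial) {
  stopifnot(inherits(spatial, "lgcp_kernel"), spatial$finalized)
  arr <- outer(direction, spatial$values)
  dim(arr) <- c(length(direction), dim(spatial$values))
  attr(arr, "grid") <- spatial$grid
  arr
}
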
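#' Discrete Hartley transform
#'
#' Real-valued unitary relative of the Fourier transform: the sum of the
#' real part and the negated imaginary part of the unitary DFT (the "cas"
#' kernel cos + sin). It is its own inverse and preserves the Euclidean
#' norm. For an even-symmetric array (such as a covariance kernel) the
#' Hartley coefficients coincide with the (real) Fourier coefficients.
#' Works on vectors, matrices and arrays of any dimension.
#'
#' @param x real numeric vector, matrix or array.
#' @return transformed array of the same shape.
#' @export
hartley <- function(x) {
  F <- stats::fft(x)
  (Re(F) - Im(F)) / sqrt(length(x))
}

#' @rdname hartley
#' @export
inverse_hartley <- function(x) hartley(x)

#' Low-rank spectral representation of a circulant prior
#'
#' Computes the eigenvalues `xi` of the circulant prior covariance induced
#' by a stationary kernel (the unnormalised DFT of the kernel array) and
#' retains the components whose magnitude exceeds `keep_fraction` times the
#' largest eigenvalue magnitude. The retained components define a
#' semi-orthogonal Hartley basis mapping a rank-D coefficient space to the
#' full map space. The DC component is always retained so the mean log-rate
#' stays adjustable even when the kernel's constant offset is small.
#'
#' @param kernel a finalized `lgcp_kernel`, or a plain numeric array
#'   holding a (finalized) kernel on a circulant grid of any dimension
#'   (e.g. the 3D array from [joint_kernel()]).
#' @param keep_fraction eigenvalue-magnitude threshold relative to the
#'   maximum; components with `|xi| > keep_fraction * |xi_max|` are kept.
#'   Use 0 to keep every strictly positive component.
#' @param max_rank optional cap on the retained rank; the largest-magnitude
#'   components are kept.
#' @return an object of class `spectral_prior` with fields `xi` (full
#'   eigenvalue array), `keep_idx` (linear indices of retained
#'   components), `xi_kept`, `rank`, `dims`, `freq` (per-axis integer
#'   frequencies of retained components) and `grid` (the spatial
#'   [grid_spec()] when known).
#' @export
build_spectral_prior <- function(kernel, keep_fraction = 0.1,
                                 max_rank = Inf) {
  grid <- NULL
  if (inherits(kernel, "lgcp_kernel")) {
    if (!kernel$finalized)
      stop("kernel must be finalized (see localize_kernel)")
    grid <- kernel$grid
    vals <- kernel$values
  } else {
    vals <- kernel
    grid <- attr(kernel, "grid")
  }
  xi <- Re(stats::fft(vals))
  xi[xi < 0 & xi > -1e-10 * max(abs(xi))] <- 0  # numerical noise only
  if (all(xi == 0)) stop("all-zero kernel")
  # threshold on the non-DC spectrum: the DC eigenvalue carries the
  # (typically enormous) mean-log-rate variance c * M and is always
  # retained, so it must not set the scale for the spatial components
  ref <- if (length(xi) > 1) max(abs(xi[-1])) else abs(xi[1])
  keep <- abs(xi) > keep_fraction * ref
  keep[1] <- TRUE  # DC always retained
  keep_idx <- which(keep)
  if (length(keep_idx) > max_rank) {
    ord <- order(abs(xi[keep_idx]), decreasing = TRUE)
    keep_idx <- sort(unique(c(1L, keep_idx[ord[seq_len(max_rank)]])))
  }
  dims <- dim(vals)
  if (is.null(dims)) dims <- length(vals)
  # per-axis 0-based frequency index of each retained component
  freq <- arrayInd(keep_idx, dims) - 1L
  structure(list(xi = xi, keep_idx = keep_idx,
                 xi_kept = as.numeric(xi[keep_idx]),
                 rank = length(keep_idx), dims = dims, freq = freq,
                 grid = grid),
            class = "spectral_prior")
}

#' @export
print.spectral_prior <- function(x, ...) {
  cat(sprintf("<spectral_prior> rank D = %d of M = %d (%.1f%%), xi in [%.3g, %.3g]\n",
              x$rank, prod(x$dims), 100 * x$rank / prod(x$dims),
              min(x$xi_kept), max(x$xi_kept)))
  invisible(x)
}

#' Apply the prior covariance (or its subspace inverse) to a map
#'
#' Computes `Sigma_z v` by pointwise multiplication of Hartley coefficients
#' by the eigenvalues `xi`, or, with `inverse = TRUE`, `Sigma_z^{-1} v`
#' restricted to the retained subspace (coefficients outside the subspace
#' are zeroed).
#'
#' @param prior a [build_spectral_prior()] object.
#' @param v numeric array on the (padded) grid.
#' @param inverse apply the subspace inverse instead.
#' @return array of the same shape as `v`.
#' @export
circulant_apply <- function(prior, v, inverse = FALSE) {
  stopifnot(inherits(prior, "spectral_prior"))
  h <- hartley(v)
  if (inverse) {
    if (any(prior$xi_kept <= 0))
      stop("singular prior: retained eigenvalue is zero")
    out <- array(0, dim = prior$dims)
    out[prior$keep_idx] <- h[prior$keep_idx] / prior$xi_kept
    h <- out
  } else {
    h <- h * prior$xi
  }
  inverse_hartley(h)
}

#' Project a map into the retained coefficient space
#'
#' `sp_project` computes the length-D coefficient vector `t(R~) v`;
#' `sp_expand` maps coefficients back to a full map, `R~ c`. Their
#' composition `sp_expand(sp_project(v))` is the orthogonal projector onto
#' the retained subspace.
#'
#' @param prior a [build_spectral_prior()] object.
#' @param v array on the grid (`sp_project`).
#' @param coef length-D coefficient vector (`sp_expand`).
#' @return coefficient vector, or array on the grid.
#' @export
sp_project <- function(prior, v) {
  hartley(v)[prior$keep_idx]
}

#' @rdname sp_project
#' @export
sp_expand <- function(prior, coef) {
  h <- array(0, dim = prior$dims)
  h[prior$keep_idx] <- coef
  inverse_hartley(h)
}

#' Materialise rows of the low-rank Hartley basis
#'
#' Returns the N x D matrix of basis entries `R~[j, d]` for the bins with
#' linear indices `bin_idx`. Used to form products like
#' `t(R~) diag(w) R~` restricted to occupied bins without touching empty
#' ones.
#'
#' @param prior a [build_spectral_prior()] object.
#' @param bin_idx integer linear indices of bins (column-major).
#' @return N x D numeric matrix.
#' @export
basis_rows <- function(prior, bin_idx) {
  pos <- arrayInd(bin_idx, prior$dims) - 1L     # N x ndim, 0-based
  L <- prior$dims
  # phase = 2 pi sum_a m_a j_a / L_a; outer over (bins, components)
  phase <- (pos %*% (t(prior$freq) / L)) * (2 * pi)
  (cos(phase) + sin(phase)) / sqrt(prod(L))
}

# prior marginal variance (stationary): K(0) restricted to the subspace
prior_marginal_variance <- function(prior) {
  sum(prior$xi_kept) / prod(prior$dims)
}

# Preconditioned conjugate-gradient solve of A x = b for SPD operator A,
# given as a function; preconditioner precond(r) approximates A^{-1} r.
krylov_solve <- function(Aop, b, precond = identity, tol = 1e-6,
                         max_iter = NULL) {
  if (is.null(max_iter)) max_iter <- max(10L * length(b), 50L)
  x <- numeric(length(b))
  r <- b
  z <- precond(r)
  p <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b * b))
  if (b_norm == 0) return(x)
  for (it in seq_len(max_iter)) {
    Ap <- Aop(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * b_norm) break
    z <- precond(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}
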
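#' Spatial grid specification
#'
#' Describes the rectangular binning grid: interior size, bin size, arena
#' origin, and the zero-padded margin required by circulant (FFT-based)
#' priors. Positions map to fractional bin coordinates
#' `u = (pos - origin) / bin_size`, with bin centres at `(i - 0.5)` and
#' array index `[row, col]` corresponding to `(y, x)`.
#'
#' @param rows,cols interior grid size, bins.
#' @param bin_size metres (or arena units) per bin.
#' @param origin length-2 arena lower-left corner, same units as positions.
#' @param pad padding margin on every side, bins; must be at least the
#'   kernel cutoff radius of any prior used with this grid.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(rows, cols, bin_size = 1, origin = c(0, 0), pad = 0) {
  stopifnot(rows >= 2, cols >= 2, bin_size > 0, pad >= 0,
            length(origin) == 2)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 bin_size = bin_size, origin = as.numeric(origin),
                 pad = as.integer(pad)),
            class = "grid_spec")
}

padded_dim <- function(grid) c(grid$rows + 2L * grid$pad,
                               grid$cols + 2L * grid$pad)

#' Zero-pad a map
#'
#' Adds `pad` bins of zeros on all sides. `unpad_map` is its inverse.
#'
#' @param x matrix.
#' @param pad margin width, bins.
#' @return padded (or cropped) matrix.
#' @export
pad_map <- function(x, pad) {
  stopifnot(pad >= 0)
  if (pad == 0) return(x)
  out <- matrix(0, nrow(x) + 2 * pad, ncol(x) + 2 * pad)
  out[pad + seq_len(nrow(x)), pad + seq_len(ncol(x))] <- x
  out
}

#' @rdname pad_map
#' @export
unpad_map <- function(x, pad) {
  stopifnot(pad >= 0)
  if (pad == 0) return(x)
  if (2 * pad >= nrow(x) || 2 * pad >= ncol(x))
    stop("pad exceeds array size")
  x[pad + seq_len(nrow(x) - 2 * pad), pad + seq_len(ncol(x) - 2 * pad),
    drop = FALSE]
}

# Distribute unit mass at fractional centre-coordinates (u, v) over the
# 2 x 2 neighbourhood of bin centres; returns accumulation into a matrix of
# dim d = c(rows, cols). Weights at the arena edge clamp to the boundary
# bin so mass is conserved exactly.
accumulate_bilinear <- function(d, v_row, u_col, mass) {
  nr <- d[1]; nc <- d[2]
  u <- pmin(pmax(u_col - 0.5, 0), nc - 1)
  v <- pmin(pmax(v_row - 0.5, 0), nr - 1)
  j0 <- pmin(floor(u), nc - 2); i0 <- pmin(floor(v), nr - 2)
  fu <- u - j0; fv <- v - i0
  acc <- numeric(nr * nc)
  add <- function(i, j, w) {
    lin <- i + 1 + nr * j
    s <- rowsum(w, lin)
    acc[as.integer(rownames(s))] <<- acc[as.integer(rownames(s))] + s[, 1]
  }
  add(i0,     j0,     mass * (1 - fu) * (1 - fv))
  add(i0,     j0 + 1, mass * fu * (1 - fv))
  add(i0 + 1, j0,     mass * (1 - fu) * fv)
  add(i0 + 1, j0 + 1, mass * fu * fv)
  matrix(acc, nr, nc)
}

#' Bin a session onto a padded grid
#'
#' Each sample's visit mass and spike count are distributed over the 2 x 2
#' neighbourhood of surrounding bin centres by bilinear weights
#' (square-pyramidal basis functions). The padded margin receives zero
#' mass. Total visit mass equals the number of (weighted) samples and total
#' spike mass equals the (weighted) spike count, exactly.
#'
#' @param sess a [session()] object.
#' @param grid a [grid_spec()].
#' @param weights optional per-sample visit weights in \[0, 1\] (defaults
#'   to 1); used for head-direction-conditioned maps.
#' @return an object of class `binned_counts` with fields `n`, `k` (padded
#'   matrices) and `grid`.
#' @export
bin_session <- function(sess, grid, weights = NULL) {
  stopifnot(inherits(sess, "grid_session"), inherits(grid, "grid_spec"))
  u <- (sess$positions[, 1] - grid$origin[1]) / grid$bin_size
  v <- (sess$positions[, 2] - grid$origin[2]) / grid$bin_size
  w <- if (is.null(weights)) rep(1, length(u)) else weights
  stopifnot(length(w) == length(u))
  keep <- !is.na(u) & !is.na(v)
  if (!all(keep)) {
    message(sum(!keep), " samples with missing position dropped")
    u <- u[keep]; v <- v[keep]; w <- w[keep]
  }
  bad <- which(u < -1e-9 | u > grid$cols + 1e-9 |
               v < -1e-9 | v > grid$rows + 1e-9)
  if (length(bad))
    stop("position outside arena extent at sample ", bad[1])
  spk <- sess$spikes[keep]
  d <- c(grid$rows, grid$cols)
  n <- accumulate_bilinear(d, v, u, w)
  k <- accumulate_bilinear(d, v, u, w * spk)
  binned_counts(pad_map(n, grid$pad), pad_map(k, grid$pad), grid)
}

#' Binned visit and spike masses
#'
#' Low-level constructor; most users call [bin_session()].
#'
#' @param n,k padded matrices of visit and spike mass.
#' @param grid the [grid_spec()].
#' @return an object of class `binned_counts`.
#' @export
binned_counts <- function(n, k, grid) {
  stopifnot(all(dim(n) == padded_dim(grid)), all(dim(k) == dim(n)),
            all(n >= 0), all(k >= 0))
  structure(list(n = n, k = k, grid = grid), class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf(
    "<binned_counts> %dx%d interior (+%d pad), visit mass %.1f, spikes %.1f\n",
    x$grid$rows, x$grid$cols, x$grid$pad, sum(x$n), sum(x$k)))
  invisible(x)
}

#' Raw firing-rate histogram
#'
#' The ratio of spike to visit mass, `k / n`, on the padded grid;
#' `NA` where the visit mass is zero.
#'
#' @param counts a [binned_counts()].
#' @return matrix, spikes per sample per bin.
#' @export
rate_histogram <- function(counts) {
  y <- counts$k / counts$n
  y[counts$n == 0] <- NA_real_
  y
}
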
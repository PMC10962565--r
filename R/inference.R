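#' Prior specification for LGCP inference
#'
#' Couples a low-rank spectral prior covariance with a prior mean log-rate
#' map.
#'
#' @param spectral a [build_spectral_prior()] object.
#' @param mu_z prior mean log-rate, an array matching the prior's grid
#'   dimensions, or a scalar (constant mean).
#' @param hyper optional list of kernel hyperparameters, recorded for
#'   provenance.
#' @return an object of class `lgcp_prior`.
#' @export
lgcp_prior <- function(spectral, mu_z = 0, hyper = NULL) {
  stopifnot(inherits(spectral, "spectral_prior"))
  if (length(mu_z) == 1) mu_z <- array(mu_z, dim = spectral$dims)
  stopifnot(all(dim(mu_z) == spectral$dims) ||
              length(mu_z) == prod(spectral$dims))
  if (!all(is.finite(mu_z))) stop("prior mean must be finite")
  structure(list(spectral = spectral, mu_z = mu_z, hyper = hyper),
            class = "lgcp_prior")
}

# log-rate ceiling guarding exp() overflow on degenerate hyperparameters
RATE_CEILING <- 700

#' Expected visit-weighted firing rate
#'
#' Under the log-normal posterior marginals, the expected rate at a bin is
#' `exp(mu + v / 2)`; weighting by the visit mass `n` gives the
#' visit-weighted expected rate used throughout inference. The exponent is
#' clipped at 700 nats (with a warning) to avoid overflow on degenerate
#' fits.
#'
#' @param mu posterior mean log-rate (array or vector).
#' @param v posterior marginal variance, same shape, non-negative.
#' @param n visit mass, same shape.
#' @return `n * exp(mu + v / 2)` elementwise.
#' @export
expected_rate <- function(mu, v, n) {
  stopifnot(all(v >= 0))
  ex <- mu + v / 2
  if (any(ex > RATE_CEILING)) {
    warning("log-rate exceeded ceiling; clipping (degenerate fit?)")
    ex <- pmin(ex, RATE_CEILING)
  }
  n * exp(ex)
}

# ---------------------------------------------------------------------------
# Inference engine: precomputes the occupied-bin basis and exposes the
# mean/variance updates as closures over a mutable state list.
# state: mu_coeff (D), v_occ (N), q_occ (N), U (chol of Lambda), B (U^-1)
# ---------------------------------------------------------------------------

as_count_arrays <- function(counts) {
  if (inherits(counts, "binned_counts")) list(n = counts$n, k = counts$k)
  else {
    stopifnot(is.list(counts), !is.null(counts$n), !is.null(counts$k))
    counts
  }
}

lgcp_engine <- function(counts, prior) {
  ca <- as_count_arrays(counts)
  sp <- prior$spectral
  stopifnot(length(ca$n) == prod(sp$dims))
  occ <- which(ca$n > 0)
  if (any(ca$k[ca$n == 0] > 0)) stop("spike mass found in unvisited bins")
  e <- new.env(parent = emptyenv())
  e$sp <- sp
  e$mu_z <- prior$mu_z
  e$occ <- occ
  e$n_occ <- as.numeric(ca$n[occ])
  e$k_occ <- as.numeric(ca$k[occ])
  e$mu_z_occ <- as.numeric(prior$mu_z[occ])
  e$Rocc <- basis_rows(sp, occ)
  e$xi <- sp$xi_kept
  e$D <- sp$rank
  e
}

engine_lambda <- function(e, mu_coeff, v_occ) {
  mu_occ <- e$mu_z_occ + as.numeric(e$Rocc %*% mu_coeff)
  ex <- pmin(mu_occ + v_occ / 2, RATE_CEILING)
  list(mu_occ = mu_occ, lam = e$n_occ * exp(ex))
}

# Cholesky of Lambda = diag(1/xi) + t(R) diag(q) R over occupied bins;
# jitters and retries once if numerically indefinite.
engine_factor <- function(e, q_occ) {
  A <- diag(1 / e$xi, e$D)
  pos <- q_occ > 0
  if (any(pos)) {
    X <- e$Rocc[pos, , drop = FALSE] * sqrt(q_occ[pos])
    A <- A + crossprod(X)
  }
  U <- tryCatch(chol(A), error = function(err) {
    chol(A + diag(1e-10 * max(diag(A)), e$D))
  })
  U
}

# ELBO (constants ln y! omitted; low-rank -D correction applied)
engine_elbo <- function(e, mu_coeff, v_occ, U) {
  B <- backsolve(U, diag(e$D))
  quad <- sum(mu_coeff^2 / e$xi)
  tr <- sum(rowSums(B^2) / e$xi)
  logdet_post <- -2 * sum(log(diag(U)))
  logdet_prior <- sum(log(e$xi))
  lamd <- engine_lambda(e, mu_coeff, v_occ)
  ell <- sum(e$k_occ * lamd$mu_occ) - sum(lamd$lam)
  kl <- 0.5 * (quad + tr + logdet_prior - logdet_post - e$D)
  ell - kl
}

# Newton ascent on mu_coeff for fixed v; rate = expected if v given, point
# estimate if v = 0. Returns updated mu_coeff.
engine_newton_mean <- function(e, mu_coeff, v_occ, tol = 1e-6,
                               max_iter = 50, cg_tol = 1e-6) {
  obj <- function(mc) {
    lamd <- engine_lambda(e, mc, v_occ)
    -0.5 * sum(mc^2 / e$xi) + sum(e$k_occ * lamd$mu_occ) - sum(lamd$lam)
  }
  f <- obj(mu_coeff)
  scale <- 1 + sqrt(sum(e$k_occ^2))
  for (it in seq_len(max_iter)) {
    lamd <- engine_lambda(e, mu_coeff, v_occ)
    g <- -mu_coeff / e$xi +
      as.numeric(crossprod(e$Rocc, e$k_occ - lamd$lam))
    if (sqrt(sum(g^2)) < tol * scale) break
    lam <- lamd$lam
    Aop <- function(u) u / e$xi +
      as.numeric(crossprod(e$Rocc, lam * as.numeric(e$Rocc %*% u)))
    step <- krylov_solve(Aop, g, precond = function(r) r * e$xi,
                         tol = cg_tol, max_iter = 10L * e$D)
    # backtracking line search on the mean objective
    t <- 1
    repeat {
      cand <- mu_coeff + t * step
      fc <- obj(cand)
      if (is.finite(fc) && fc >= f - 1e-12 * abs(f)) break
      t <- t / 2
      if (t < 1e-8) { cand <- mu_coeff; fc <- f; break }
    }
    if (abs(fc - f) <= 1e-12 * (1 + abs(f)) && t < 1) {
      mu_coeff <- cand
      break
    }
    mu_coeff <- cand
    f <- fc
  }
  mu_coeff
}

# diag of posterior covariance: full grid (D inverse transforms) or at
# occupied bins only (dense product with the cached basis rows)
engine_v_occ <- function(e, B) {
  RB <- e$Rocc %*% B
  rowSums(RB^2)
}

full_variance_map <- function(sp, B) {
  v <- array(0, dim = sp$dims)
  for (d in seq_len(ncol(B))) {
    h <- array(0, dim = sp$dims)
    h[sp$keep_idx] <- B[, d]
    v <- v + inverse_hartley(h)^2
  }
  v
}

# ---------------------------------------------------------------------------
# Public operations
# ---------------------------------------------------------------------------

#' Posterior marginal variances under a diagonal precision update
#'
#' Computes `v = diag((Sigma_z^{-1} + diag(q))^{-1})` in the retained
#' low-rank subspace: forms `Lambda = diag(1/xi) + t(X) X` with
#' `X = sqrt(q) R~` over the bins carrying positive `q`, Cholesky-factors
#' it, and accumulates the squared rows of `R~ U^{-1}`. The returned factor
#' also enables posterior sampling.
#'
#' @param prior an [lgcp_prior()] or [build_spectral_prior()] object.
#' @param q per-bin precision update (array on the grid, non-negative;
#'   zero off occupied bins).
#' @return list with `v` (array of marginal variances) and `factor` (list
#'   with the Cholesky factor `U`, its inverse `B`, and the spectral
#'   prior), such that posterior samples are `mu + R~ B eta`.
#' @export
marginal_variance <- function(prior, q) {
  sp <- if (inherits(prior, "lgcp_prior")) prior$spectral else prior
  stopifnot(inherits(sp, "spectral_prior"))
  stopifnot(all(q >= 0))
  D <- sp$rank
  A <- diag(1 / sp$xi_kept, D)
  occ <- which(q > 0)
  if (length(occ)) {
    X <- basis_rows(sp, occ) * sqrt(as.numeric(q[occ]))
    A <- A + crossprod(X)
  }
  U <- tryCatch(chol(A), error = function(err) {
    chol(A + diag(1e-10 * max(diag(A)), D))
  })
  B <- backsolve(U, diag(D))
  v <- full_variance_map(sp, B)
  list(v = v, factor = list(U = U, B = B, prior = sp))
}

#' Maximum a posteriori log-rate map
#'
#' Maximises the log-posterior of the LGCP model by inexact Newton
#' iteration in the retained coefficient subspace. Each Newton step solves
#' `(Sigma_z^{-1} + diag(lambda~)) step = grad` with a preconditioned
#' conjugate-gradient Krylov solver whose matrix-vector products use only
#' the spectral prior and the diagonal likelihood curvature; the
#' preconditioner is the prior covariance applied spectrally.
#'
#' @param counts a [binned_counts()] (or list with arrays `n`, `k`).
#' @param prior an [lgcp_prior()].
#' @param tol gradient-norm tolerance (relative to the spike-count norm).
#' @param max_iter maximum Newton iterations.
#' @return the MAP log-rate map (array on the padded grid).
#' @export
map_estimate <- function(counts, prior, tol = 1e-6, max_iter = 50) {
  e <- lgcp_engine(counts, prior)
  mc <- engine_newton_mean(e, numeric(e$D), rep(0, length(e$occ)),
                           tol = tol, max_iter = max_iter)
  prior$mu_z + sp_expand(e$sp, mc)
}

#' Variational posterior state
#'
#' Container returned by [fit_lgcp()]: posterior mean log-rate map `mu`
#' (and its low-rank coefficients `mu_coeff`, stored as the deviation from
#' the prior mean), marginal variances `v`, precision update `q`,
#' visit-weighted expected rate `lambda_bar`, the ELBO value and
#' per-iteration trace, and the covariance factor used for sampling.
#'
#' @name lgcp_state
NULL

new_state <- function(prior, mu_coeff, v, q, lambda_bar, elbo, trace,
                      factor, converged) {
  structure(list(mu = prior$mu_z + sp_expand(prior$spectral, mu_coeff),
                 mu_coeff = mu_coeff, v = v, q = q,
                 lambda_bar = lambda_bar, elbo = elbo, elbo_trace = trace,
                 factor = factor, converged = converged),
            class = "lgcp_state")
}

#' @export
print.lgcp_state <- function(x, ...) {
  cat(sprintf("<lgcp_state> ELBO = %.4f nats (%d outer iterations%s)\n",
              x$elbo, length(x$elbo_trace),
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Variational LGCP regression
#'
#' Fits the variational Gaussian posterior over the log-rate map by
#' alternating Newton optimisation of the posterior mean (in the low-rank
#' coefficient space) with fixed-point sweeps of the marginal variances
#' `v <- diag((Sigma_z^{-1} + diag(lambda_bar(v)))^{-1})`, starting from
#' `v = 0`. Iterations stop when the relative ELBO change falls below
#' `tol`. The variance sweep is safeguarded by step-halving on the rare
#' occasions a full fixed-point step would decrease the ELBO.
#'
#' @param counts a [binned_counts()] (or list with arrays `n`, `k`).
#' @param prior an [lgcp_prior()].
#' @param tol relative ELBO tolerance for the outer loop.
#' @param max_outer maximum outer iterations.
#' @param init_mu optional initial posterior mean log-rate map (defaults to
#'   the prior mean).
#' @param state0 optional previous [lgcp_state] for warm-starting (e.g.
#'   during hyperparameter search); overrides `init_mu`.
#' @param verbose print the per-iteration ELBO.
#' @return an object of class `lgcp_state`.
#' @export
fit_lgcp <- function(counts, prior, tol = 1e-6, max_outer = 20,
                     init_mu = NULL, state0 = NULL, verbose = FALSE) {
  e <- lgcp_engine(counts, prior)
  N <- length(e$occ)
  mc <- numeric(e$D)
  v_occ <- rep(0, N)
  q_occ <- rep(0, N)
  if (!is.null(state0)) {
    stopifnot(inherits(state0, "lgcp_state"))
    if (length(state0$mu) == prod(e$sp$dims)) {
      mc <- sp_project(e$sp, state0$mu - prior$mu_z)
      v_occ <- pmin(as.numeric(state0$v[e$occ]),
                    prior_marginal_variance(e$sp))
    }
  } else if (!is.null(init_mu)) {
    mc <- sp_project(e$sp, init_mu - prior$mu_z)
  }
  U <- engine_factor(e, q_occ)
  L_prev <- engine_elbo(e, mc, v_occ, U)
  trace <- numeric(0)
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    mc <- engine_newton_mean(e, mc, v_occ)
    # fixed-point variance sweep with ELBO step-halving safeguard
    lam <- engine_lambda(e, mc, v_occ)$lam
    q_new <- lam
    for (try in 1:6) {
      U_new <- engine_factor(e, q_new)
      B_new <- backsolve(U_new, diag(e$D))
      v_new <- engine_v_occ(e, B_new)
      L_new <- engine_elbo(e, mc, v_new, U_new)
      if (is.finite(L_new) && L_new >= L_prev - 1e-8 * (1 + abs(L_prev)))
        break
      q_new <- (q_new + q_occ) / 2
    }
    q_occ <- q_new; U <- U_new; v_occ <- v_new
    trace <- c(trace, L_new)
    if (verbose)
      message(sprintf("  outer %2d: ELBO = %.6f", outer, L_new))
    if (abs(L_new - L_prev) < tol * (1 + abs(L_new))) {
      L_prev <- L_new
      converged <- TRUE
      break
    }
    L_prev <- L_new
  }
  B <- backsolve(U, diag(e$D))
  v_full <- full_variance_map(e$sp, B)
  q_full <- array(0, dim = e$sp$dims); q_full[e$occ] <- q_occ
  lam_full <- array(0, dim = e$sp$dims)
  lam_full[e$occ] <- engine_lambda(e, mc, v_occ)$lam
  new_state(prior, mc, v_full, q_full, lam_full, L_prev, trace,
            factor = list(U = U, B = B, prior = e$sp), converged = converged)
}

#' One Newton pass on the posterior mean
#'
#' Re-optimises the posterior mean log-rate of `state` at its current
#' marginal variances. Exposed mainly for inspection; [fit_lgcp()] calls
#' the same update internally.
#'
#' @inheritParams fit_lgcp
#' @param state an [lgcp_state] object.
#' @return updated `lgcp_state`.
#' @export
update_mean <- function(state, counts, prior, tol = 1e-6) {
  e <- lgcp_engine(counts, prior)
  v_occ <- as.numeric(state$v[e$occ])
  mc <- engine_newton_mean(e, state$mu_coeff, v_occ, tol = tol)
  U <- engine_factor(e, as.numeric(state$q[e$occ]))
  L <- engine_elbo(e, mc, v_occ, U)
  new_state(prior, mc, state$v, state$q, state$lambda_bar, L,
            c(state$elbo_trace, L), state$factor, state$converged)
}

#' One fixed-point sweep on the posterior variances
#'
#' Sets `q <- lambda_bar(v)` and recomputes
#' `v = diag((Sigma_z^{-1} + diag(q))^{-1})`.
#'
#' @inheritParams update_mean
#' @return updated `lgcp_state`.
#' @export
update_variance <- function(state, counts, prior) {
  e <- lgcp_engine(counts, prior)
  v_occ <- as.numeric(state$v[e$occ])
  lam <- engine_lambda(e, state$mu_coeff, v_occ)$lam
  q_full <- array(0, dim = e$sp$dims)
  q_full[e$occ] <- lam
  mv <- marginal_variance(prior, q_full)
  lam_full <- array(0, dim = e$sp$dims)
  lam_full[e$occ] <- engine_lambda(e, state$mu_coeff,
                                   as.numeric(mv$v[e$occ]))$lam
  L <- engine_elbo(e, state$mu_coeff, as.numeric(mv$v[e$occ]),
                   mv$factor$U)
  new_state(prior, state$mu_coeff, mv$v, q_full, lam_full, L,
            c(state$elbo_trace, L), mv$factor, state$converged)
}

#' Evidence lower bound of a variational state
#'
#' Evaluates the ELBO (nats) in the rank-D subspace: expected Poisson
#' log-likelihood minus the Gaussian KL divergence from the prior, with
#' the dimension constant taken as D (not the full grid size) so values
#' are comparable across ranks, and the data-dependent `ln y!` constant
#' omitted throughout.
#'
#' @inheritParams update_mean
#' @return scalar ELBO, nats.
#' @export
elbo <- function(state, counts, prior) {
  e <- lgcp_engine(counts, prior)
  U <- engine_factor(e, as.numeric(state$q[e$occ]))
  engine_elbo(e, state$mu_coeff, as.numeric(state$v[e$occ]), U)
}
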
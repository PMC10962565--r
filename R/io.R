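RESULTS_VERSION <- 1L

#' Save and load fitted results
#'
#' Serialises a fitted [lgcp_state] together with its [lgcp_prior()] and
#' any hyperparameter record to a versioned RDS container; `load_results`
#' refuses files written under a different container version or truncated
#' files.
#'
#' @param state an [lgcp_state].
#' @param prior the [lgcp_prior()] it was fitted under.
#' @param path file path.
#' @param extra optional named list stored alongside (seeds, config).
#' @return `save_results` the path, invisibly; `load_results` a list with
#'   `state`, `prior`, `extra`.
#' @export
save_results <- function(state, prior, path, extra = list()) {
  stopifnot(inherits(state, "lgcp_state"), inherits(prior, "lgcp_prior"))
  saveRDS(list(version = RESULTS_VERSION, state = state, prior = prior,
               extra = extra), path)
  invisible(path)
}

#' @rdname save_results
#' @export
load_results <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read results file (truncated or corrupt): ",
         conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$version))
    stop("not a results container")
  if (obj$version != RESULTS_VERSION)
    stop("results container version ", obj$version,
         " not supported (expected ", RESULTS_VERSION, ")")
  obj[c("state", "prior", "extra")]
}

#' Plot a fitted rate map
#'
#' Image panels of the posterior mean rate `exp(mu + v/2)` and the
#' posterior marginal standard deviation, interior region only.
#'
#' @param x an [lgcp_state].
#' @param pad padding margin to strip (taken from the prior's grid when
#'   supplied there).
#' @param dt sample interval, seconds, to display rates in Hz (1 = rates
#'   per sample).
#' @param ... ignored.
#' @export
plot.lgcp_state <- function(x, pad = 0, dt = 1, ...) {
  stopifnot(length(dim(x$mu)) == 2)
  rate <- exp(pmin(x$mu + x$v / 2, RATE_CEILING)) / dt
  sdm <- sqrt(x$v)
  if (pad > 0) {
    rate <- unpad_map(rate, pad)
    sdm <- unpad_map(sdm, pad)
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(rate)[, rev(seq_len(nrow(rate)))], axes = FALSE,
                  main = "expected rate", useRaster = TRUE)
  graphics::image(t(sdm)[, rev(seq_len(nrow(sdm)))], axes = FALSE,
                  main = "posterior SD (log-rate)", useRaster = TRUE)
  invisible(x)
}
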
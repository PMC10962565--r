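#' Behavioural session container
#'
#' A session is a uniformly sampled time series of positions, spike counts
#' and (optionally) head direction. Positions are in arena units (bins for
#' simulated data, metres for experimental data; the grid specification
#' maps them to bins either way).
#'
#' @param times sample times, seconds; strictly increasing, uniform spacing.
#' @param x,y positions, length T.
#' @param spikes non-negative integer spike counts, length T.
#' @param heading optional head direction, radians in \[0, 2 pi); `NULL` or
#'   a length-T vector (may contain `NA` for dropped tracking samples).
#' @param dt sample interval, seconds. Defaults to the median time step.
#' @return an object of class `grid_session`.
#' @export
session <- function(times, x, y, spikes, heading = NULL, dt = NULL) {
  T <- length(times)
  stopifnot(length(x) == T, length(y) == T, length(spikes) == T)
  if (T < 2) stop("a session needs at least two samples")
  steps <- diff(times)
  if (any(steps <= 0)) stop("times must be strictly increasing")
  if (is.null(dt)) dt <- stats::median(steps)
  if (max(abs(steps - dt)) > 1e-6 * dt)
    stop("times must be uniformly spaced")
  if (any(spikes < 0) || any(spikes != round(spikes), na.rm = TRUE))
    stop("spikes must be non-negative integers")
  if (!is.null(heading)) {
    stopifnot(length(heading) == T)
    heading <- heading %% (2 * pi)
  }
  if (any(!is.finite(x) & !is.na(x)) || any(!is.finite(y) & !is.na(y)))
    stop("positions must be finite or NA")
  structure(list(times = as.numeric(times),
                 positions = cbind(x = as.numeric(x), y = as.numeric(y)),
                 spikes = as.numeric(spikes),
                 heading = heading, dt = dt),
            class = "grid_session")
}

#' @export
print.grid_session <- function(x, ...) {
  cat(sprintf("<grid_session> %d samples, dt = %g s (%.1f min), %d spikes%s\n",
              length(x$times), x$dt, diff(range(x$times)) / 60,
              sum(x$spikes), if (is.null(x$heading)) "" else ", with heading"))
  invisible(x)
}

#' Write a session to CSV
#'
#' Columns `t,x,y,heading,spikes`; the heading column is omitted when the
#' session carries none.
#'
#' @param sess a [session()] object.
#' @param path output file path.
#' @export
write_session <- function(sess, path) {
  stopifnot(inherits(sess, "grid_session"))
  df <- data.frame(t = sess$times, x = sess$positions[, 1],
                   y = sess$positions[, 2])
  if (!is.null(sess$heading)) df$heading <- sess$heading
  df$spikes <- sess$spikes
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a session from CSV
#'
#' Parses the `t,x,y,heading,spikes` format written by [write_session()]
#' (heading optional). Rows with missing time are a parse error; samples
#' with missing position are kept as `NA` and dropped (with a message) at
#' binning time.
#'
#' @param path file path.
#' @return a [session()] object.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "spikes")
  if (!all(need %in% names(df)))
    stop("session file must have columns t,x,y,spikes (heading optional)")
  if (anyNA(df$t)) stop("missing values in time column at row(s) ",
                        paste(utils::head(which(is.na(df$t)), 3),
                              collapse = ", "))
  session(times = df$t, x = df$x, y = df$y, spikes = df$spikes,
          heading = if ("heading" %in% names(df)) df$heading else NULL)
}
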
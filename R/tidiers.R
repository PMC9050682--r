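#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Bayes factor timecourse
#'
#' @param x A `bf_timecourse`.
#' @param ... Ignored.
#' @return A plain tibble of the per-timepoint results.
#' @export
tidy.bf_timecourse <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a Bayes factor timecourse
#'
#' @param x A `bf_timecourse`.
#' @param threshold Onset evidence threshold (default 10).
#' @param ... Ignored.
#' @return A tibble with the contrast, number of participants, prior
#'   settings, detected onset latency and peak evidence.
#' @export
glance.bf_timecourse <- function(x, threshold = 10, ...) {
  prior <- attr(x, "prior")
  tibble(
    contrast = x$contrast[1],
    n = x$n[1],
    prior_scale = prior$scale,
    prior_interval = prior$interval,
    prior_direction = prior$direction,
    onset_ms = onset_time(x, threshold = threshold),
    max_bf10 = max(x$bf10),
    time_max_bf10 = x$time_ms[which.max(x$bf10)]
  )
}

#' Tidy a decoding timecourse
#'
#' @param x A `decoding_timecourse`.
#' @param ... Ignored.
#' @return A plain tibble.
#' @export
tidy.decoding_timecourse <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Per-trial metadata of an epoch set
#'
#' @param x An `epoch_set`.
#' @param ... Ignored.
#' @return The metadata tibble (one row per epoch).
#' @export
tidy.epoch_set <- function(x, ...) {
  x$metadata
}

#' One-row summary of an epoch set
#'
#' @param x An `epoch_set`.
#' @param ... Ignored.
#' @return A tibble with trial/channel/timepoint counts and the time window.
#' @export
glance.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    n_trials = d[1], n_channels = d[2], n_times = d[3],
    srate_hz = x$srate,
    tmin_ms = min(x$times_ms), tmax_ms = max(x$times_ms),
    n_analysable = sum(x$metadata$analysable == 1)
  )
}
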
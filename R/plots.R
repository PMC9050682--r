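#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_point
#'   geom_ribbon facet_wrap labs scale_y_log10 theme_minimal
NULL

#' Plot a decoding accuracy timecourse
#'
#' Accuracy against time relative to stimulus onset, one line per role,
#' facetted by ISI filter, with the 50% chance level marked.
#'
#' @param object A `decoding_timecourse` (or several row-bound together).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.decoding_timecourse <- function(object, ...) {
  ggplot(object, aes(x = .data$time_ms, y = .data$accuracy,
                     colour = .data$role,
                     group = interaction(.data$role, .data$analysis_group,
                                         .data$participant_id))) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    geom_line() +
    facet_wrap(~isi_filter) +
    labs(x = "Time relative to stimulus onset (ms)",
         y = "Decoding accuracy", colour = "Orientation") +
    theme_minimal()
}

#' Plot a Bayes factor timecourse
#'
#' Group mean (with bootstrap CI ribbon when present) on top of a log-scale
#' BF10 raster, with the evidence thresholds 1/10, 1/3, 3 and 10 marked.
#'
#' @param object A `bf_timecourse`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.bf_timecourse <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$time_ms, y = .data$bf10)) +
    geom_hline(yintercept = c(1 / 10, 1 / 3, 3, 10),
               linetype = "dotted", colour = "grey60") +
    geom_hline(yintercept = 1, colour = "grey30") +
    geom_point(aes(colour = .data$evidence), size = 0.8) +
    geom_line(alpha = 0.4) +
    scale_y_log10() +
    facet_wrap(~contrast) +
    labs(x = "Time relative to stimulus onset (ms)", y = "BF10",
         colour = "Evidence") +
    theme_minimal()
  p
}

#' @export
print.forward_model <- function(x, ...) {
  cat("<forward_model>\n")
  cat(sprintf("  channels: %d, amplitude: %.3g uV, noise sd: %.3g uV (AR phi %.2f)\n",
              x$n_channels, x$amplitude, x$noise_sd, x$ar_phi))
  cat(sprintf("  kernel: [%g, %g) ms, peak %g ms; gain divergence at %g ms (%.2g vs %.2g)\n",
              x$t_on, x$t_off, x$t_peak, x$tau, x$g_att, x$g_unatt))
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d timepoints (%g Hz), %g to %g ms\n",
              d[1], d[2], d[3], x$srate, min(x$times_ms), max(x$times_ms)))
  invisible(x)
}
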
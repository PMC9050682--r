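#' Specify an interval-null Cauchy prior on standardised effect size
#'
#' The alternative hypothesis places a Cauchy prior with scale `scale` on the
#' standardised effect size d, truncated to exclude the interval of
#' irrelevantly small effects: d in (0, `interval`) for directional
#' (positive-only) tests, or (-`interval`, `interval`) for two-sided tests.
#'
#' @param scale Cauchy scale r (default 0.707).
#' @param interval Excluded small-effect half-width (default 0.5).
#' @param direction `"positive_only"` (half-Cauchy) or `"two_sided"`.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(scale = 0.707, interval = 0.5,
                       direction = c("positive_only", "two_sided")) {
  direction <- match.arg(direction)
  stopifnot(scale > 0, interval >= 0)
  structure(list(scale = scale, interval = interval, direction = direction),
            class = "prior_spec")
}

#' Bayes factor for a one-sample t-test with an interval-null Cauchy prior
#'
#' Computes `t = mean(values - null_value) / (sd / sqrt(n))` and the Bayes
#' factor BF10 comparing the interval-null Cauchy alternative against the
#' point null:
#' `BF10 = integral f_nct(t; nu, delta * sqrt(n)) pi(delta) d delta / f_t(t; nu)`
#' where `pi` is the Cauchy(0, r) density truncated to `delta >= interval`
#' (directional) or `|delta| >= interval` (two-sided) and renormalised.
#' The half-line is mapped to (0, 1) by `delta = interval + u / (1 - u)` and
#' integrated adaptively to a relative tolerance of 1e-8.
#'
#' @param values Numeric vector of per-participant statistics.
#' @param null_value Value under the null (0.5 for raw accuracies, 0 for
#'   paired differences).
#' @param prior A [prior_spec()].
#' @return BF10 (positive scalar).
#' @seealso [bf10_t()] to work directly from a t statistic.
#' @export
bf10 <- function(values, null_value = 0, prior = prior_spec()) {
  n <- length(values)
  if (n < 2) abort("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) abort("zero variance: t statistic undefined")
  t <- (mean(values) - null_value) / (s / sqrt(n))
  if (!is.finite(t)) abort("non-finite t statistic")
  bf10_t(t, n, prior)
}

#' Bayes factor from a t statistic
#'
#' @param t One-sample t statistic.
#' @param n Number of participants (degrees of freedom `n - 1`).
#' @param prior A [prior_spec()].
#' @return BF10 (positive scalar).
#' @export
bf10_t <- function(t, n, prior = prior_spec()) {
  stopifnot(n >= 2, is.finite(t))
  nu <- n - 1
  a <- prior$interval
  tail_mass <- 1 - stats::pcauchy(a, 0, prior$scale)
  half_integral <- function(sign) {
    # delta = sign * (a + u / (1 - u)), u in (0, 1)
    f <- function(u, robust = FALSE) {
      delta <- sign * (a + u / (1 - u))
      dens <- if (robust) {
        vapply(delta * sqrt(n), dnct_tail, numeric(1), t = t, nu = nu)
      } else {
        suppressWarnings(stats::dt(t, nu, ncp = delta * sqrt(n)))
      }
      dens * stats::dcauchy(delta, 0, prior$scale) / (1 - u)^2
    }
    quad <- function(...) {
      stats::integrate(f, 0, 1, ..., rel.tol = 1e-8, abs.tol = 0,
                       subdivisions = 500L, stop.on.error = FALSE)$value
    }
    val <- quad()
    # stats::dt(..., ncp) carries an absolute error floor (~1e-12); when the
    # whole integral is small that floor dominates, so recompute the density
    # from the chi scale-mixture representation, which is relatively
    # accurate at any magnitude
    if (val < 1e-4) val <- quad(robust = TRUE)
    val
  }
  num <- if (prior$direction == "positive_only") {
    half_integral(1) / tail_mass
  } else {
    (half_integral(1) + half_integral(-1)) / (2 * tail_mass)
  }
  num / stats::dt(t, nu)
}

# Internal: noncentral t density from the scale-mixture representation
#   T = (Z + ncp) / X,  X = sqrt(V / nu),  V ~ chi^2_nu,
#   f_T(t) = int_0^inf x phi(t x - ncp) f_X(x) dx,
# evaluated with log-space factors. Relatively accurate at any magnitude,
# unlike stats::dt(..., ncp) whose ~1e-12 absolute error floor destroys the
# far tail; used when an integral falls below that regime.
dnct_tail <- function(t, nu, ncp) {
  log_fx <- function(x) {
    log(2) + (nu / 2) * log(nu / 2) - lgamma(nu / 2) +
      (nu - 1) * log(x) - nu * x^2 / 2
  }
  g <- function(x) x * exp(stats::dnorm(t * x - ncp, log = TRUE) + log_fx(x))
  stats::integrate(g, 0, Inf, rel.tol = 1e-10, abs.tol = 0,
                   subdivisions = 500L, stop.on.error = FALSE)$value
}

# Evidence categories used for plotting (thresholds 1/10, 1/3, 3, 10).
bf_evidence <- function(bf) {
  cut(bf, breaks = c(0, 1 / 10, 1 / 3, 3, 10, Inf),
      labels = c("strong_null", "substantial_null", "inconclusive",
                 "substantial_alt", "strong_alt"))
}

# Internal: per-participant values for a contrast at every timepoint, from
# the long run_all_conditions() table stacked over participants.
contrast_values <- function(curves, contrast) {
  pick <- function(measure, role = NULL, isi = NULL) {
    out <- curves[curves$measure == measure, ]
    if (!is.null(role)) out <- out[!is.na(out$role) & out$role == role, ]
    if (!is.null(isi)) out <- out[!is.na(out$isi_filter) & out$isi_filter == isi, ]
    out
  }
  switch(contrast,
    cued_vs_chance = list(data = pick("accuracy", role = "cued", isi = "all"),
                          null = 0.5, direction = "positive_only"),
    uncued_vs_chance = list(data = pick("accuracy", role = "uncued", isi = "all"),
                            null = 0.5, direction = "positive_only"),
    attention_effect = list(data = pick("attention_effect", isi = "all"),
                            null = 0, direction = "positive_only"),
    attention_effect_constant = list(data = pick("attention_effect", isi = "constant"),
                                     null = 0, direction = "positive_only"),
    attention_effect_varied = list(data = pick("attention_effect", isi = "varied"),
                                   null = 0, direction = "positive_only"),
    expectation_effect = list(data = pick("expectation_effect"),
                              null = 0, direction = "positive_only"),
    interaction = {
      wide <- pick("attention_effect") %>%
        filter(.data$isi_filter %in% c("constant", "varied")) %>%
        tidyr::pivot_wider(id_cols = c("participant_id", "time_ms"),
                           names_from = "isi_filter", values_from = "value") %>%
        mutate(measure = "interaction", value = .data$varied - .data$constant)
      list(data = wide, null = 0, direction = "two_sided")
    },
    abort(paste0("unknown contrast: '", contrast, "'"))
  )
}

#' Group-level Bayes factor timecourse for a contrast
#'
#' Builds the per-participant group sample at every timepoint (raw accuracies
#' against chance, or paired differences against zero) and applies [bf10()].
#' The prior is directional (half-Cauchy) for every contrast except the
#' attention x expectation `interaction`, which uses the two-sided prior.
#'
#' @param curves Output of [run_all_conditions()] row-bound over
#'   participants.
#' @param contrast One of `"cued_vs_chance"`, `"uncued_vs_chance"`,
#'   `"attention_effect"`, `"attention_effect_constant"`,
#'   `"attention_effect_varied"`, `"expectation_effect"`, `"interaction"`.
#' @param prior Optional [prior_spec()] override; by default the direction
#'   is chosen by the contrast with scale 0.707 and excluded interval 0.5.
#' @param ci If `TRUE`, add percentile bootstrap confidence intervals of the
#'   group mean per timepoint.
#' @param n_boot,ci_seed Bootstrap samples and seed (see [bootstrap_ci()]).
#' @return A `bf_timecourse` tibble: `contrast`, `time_ms`, `estimate`
#'   (group mean), `bf10`, `evidence`, `n`, plus `ci_low`/`ci_high` when
#'   requested. The prior is attached as attribute `prior`.
#' @export
bf_timecourse <- function(curves, contrast, prior = NULL, ci = FALSE,
                          n_boot = 10000, ci_seed = NULL) {
  cv <- contrast_values(curves, contrast)
  if (is.null(prior)) prior <- prior_spec(direction = cv$direction)
  d <- cv$data
  n_participants <- length(unique(d$participant_id))
  if (n_participants < 2) abort("need at least 2 participants")
  if (anyNA(d$value)) abort("missing values in contrast data")
  split_vals <- split(d$value, d$time_ms)
  lens <- lengths(split_vals)
  if (any(lens != n_participants)) {
    abort("participants do not share a common time axis")
  }
  times <- as.numeric(names(split_vals))
  ord <- order(times)
  out <- tibble(
    contrast = contrast,
    time_ms = times[ord],
    estimate = vapply(split_vals[ord], mean, numeric(1)),
    bf10 = vapply(split_vals[ord], bf10, numeric(1),
                  null_value = cv$null, prior = prior),
    n = n_participants
  )
  out$evidence <- bf_evidence(out$bf10)
  if (ci) {
    cis <- purrr::map(split_vals[ord], bootstrap_ci, n_boot = n_boot, seed = ci_seed)
    out$ci_low <- vapply(cis, `[[`, numeric(1), 1)
    out$ci_high <- vapply(cis, `[[`, numeric(1), 2)
  }
  attr(out, "prior") <- prior
  class(out) <- c("bf_timecourse", class(out))
  out
}

#' Onset latency from a Bayes factor timecourse
#'
#' Scans post-stimulus timepoints in temporal order and returns the time of
#' the second point of the first pair of consecutive points whose BF10 both
#' exceed the threshold; isolated suprathreshold points yield no onset.
#'
#' @param bf A `bf_timecourse` (or any tibble with `time_ms` and `bf10`).
#' @param threshold Evidence threshold (default 10, i.e. strong evidence).
#' @param t_min Restrict the scan to `time_ms >= t_min` (default 0, stimulus
#'   onset).
#' @return Onset time in ms, or `NA` if no qualifying pair exists.
#' @export
onset_time <- function(bf, threshold = 10, t_min = 0) {
  d <- bf[order(bf$time_ms), ]
  d <- d[d$time_ms >= t_min, ]
  above <- d$bf10 > threshold
  pair <- which(above[-1] & above[-length(above)])
  if (length(pair) == 0) return(NA_real_)
  d$time_ms[pair[1] + 1]
}

#' Percentile bootstrap confidence interval of a group mean
#'
#' Resamples participants with replacement and recomputes the mean.
#'
#' @param values Per-participant values (n >= 2).
#' @param n_boot Number of bootstrap samples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed; with a seed the interval is reproducible.
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 10000, level = 0.95, seed = NULL) {
  n <- length(values)
  stopifnot(n >= 2)
  draw <- function() {
    m <- matrix(sample(values, n * n_boot, replace = TRUE), nrow = n)
    stats::quantile(colMeans(m), c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
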
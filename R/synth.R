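#' Construct a forward model for synthetic EEG generation
#'
#' The forward model maps each stimulus presentation to a multichannel evoked
#' response: every orientation has a fixed spatial pattern across channels
#' (seeded random vectors, orthogonalised and unit-normalised), modulated in
#' time by a response kernel (a raised-cosine bump supported on
#' `[t_on, t_off)` ms post-onset, peaking at `t_peak`). Attention acts as a
#' gain on the kernel: before the divergence latency `tau` the cued and
#' uncued orientations of a presentation carry identical gain 1; from `tau`
#' onwards the cued orientation carries `g_att` and the uncued `g_unatt`.
#' With the defaults the two streams are coded equally early and diverge at
#' 230 ms, the ground truth the downstream inference must recover.
#'
#' Noise is spatially correlated (rank-`n_noise_factors` factor covariance
#' plus a diagonal, normalised to unit average channel variance) and
#' temporally correlated (AR(1) with coefficient `ar_phi`); `noise_sd` is the
#' stationary per-channel standard deviation in microvolts.
#'
#' @param n_channels Number of EEG channels (>= 4; default 64).
#' @param seed Optional integer seed for the pattern and covariance draws.
#' @param amplitude Evoked amplitude A in microvolts (kernel peak, unit-norm
#'   pattern).
#' @param tau Attention gain divergence latency in ms post stimulus onset.
#' @param g_att,g_unatt Gains applied to the cued / uncued orientation from
#'   `tau` onwards.
#' @param t_on,t_peak,t_off Response-kernel onset, peak and end (ms).
#' @param noise_sd Stationary noise SD per channel (microvolts).
#' @param ar_phi AR(1) coefficient of the temporal noise process.
#' @param n_noise_factors Rank of the shared spatial noise component.
#' @return A `forward_model` object.
#' @export
make_forward_model <- function(n_channels = 64L, seed = NULL,
                               amplitude = 1, tau = 230,
                               g_att = 1, g_unatt = 0.4,
                               t_on = 80, t_peak = 170, t_off = 400,
                               noise_sd = 3, ar_phi = 0.95,
                               n_noise_factors = 8L) {
  if (n_channels < 4L) {
    abort("n_channels must be at least 4 (four orientation patterns are orthogonalised)")
  }
  stopifnot(t_on < t_peak, t_peak < t_off, ar_phi >= 0, ar_phi < 1, noise_sd >= 0)
  build <- function() {
    orth_patterns <- function(k) {
      m <- matrix(stats::rnorm(n_channels * k), n_channels, k)
      q <- qr.Q(qr(m))[, seq_len(k), drop = FALSE]
      q
    }
    patterns <- orth_patterns(4L)
    colnames(patterns) <- as.character(ORIENTATIONS)
    event_patterns <- orth_patterns(4L)
    colnames(event_patterns) <- as.character(EVENT_ORIENTATIONS)
    L <- matrix(stats::rnorm(n_channels * n_noise_factors, sd = sqrt(0.5)),
                n_channels, n_noise_factors)
    sigma <- tcrossprod(L) + diag(n_channels)
    d <- sqrt(diag(sigma))
    sigma <- sigma / tcrossprod(d)     # unit channel variances
    list(patterns = patterns, event_patterns = event_patterns,
         noise_chol = chol(sigma), sigma = sigma)
  }
  parts <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  structure(
    list(
      n_channels = as.integer(n_channels),
      patterns = parts$patterns,
      event_patterns = parts$event_patterns,
      amplitude = amplitude,
      tau = tau, g_att = g_att, g_unatt = g_unatt,
      t_on = t_on, t_peak = t_peak, t_off = t_off,
      noise_sd = noise_sd, ar_phi = ar_phi,
      noise_sigma = parts$sigma, noise_chol = parts$noise_chol,
      channel_names = sprintf("ch%02d", seq_len(n_channels)),
      seed = seed
    ),
    class = "forward_model"
  )
}

#' Evoked response kernel of a forward model
#'
#' Raised-cosine bump: rises from `t_on` to 1 at `t_peak`, falls back to 0 at
#' `t_off`; identically 0 outside `[t_on, t_off)`.
#'
#' @param fm A `forward_model`.
#' @param lag_ms Numeric vector of lags (ms after stimulus onset).
#' @return Kernel amplitude at each lag (dimensionless, peak 1).
#' @export
response_kernel <- function(fm, lag_ms) {
  k <- numeric(length(lag_ms))
  rise <- lag_ms >= fm$t_on & lag_ms < fm$t_peak
  fall <- lag_ms >= fm$t_peak & lag_ms < fm$t_off
  k[rise] <- 0.5 - 0.5 * cos(pi * (lag_ms[rise] - fm$t_on) / (fm$t_peak - fm$t_on))
  k[fall] <- 0.5 + 0.5 * cos(pi * (lag_ms[fall] - fm$t_peak) / (fm$t_off - fm$t_peak))
  k
}

#' Attention gain profiles of a forward model
#'
#' Both gains are 1 before the divergence latency `tau`; from `tau` onwards
#' the attended orientation carries `g_att` and the unattended `g_unatt`.
#' The modulation applies only while the stimulus is the most recent one:
#' once the next stimulus appears (`soa_next_ms`), processing is captured by
#' the new input and the residual response reverts to the common gain. This
#' keeps every analysis window free of attention information from
#' neighbouring presentations, so the pre-`tau` ground truth of equal coding
#' holds exactly in each epoch.
#'
#' @param fm A `forward_model`.
#' @param lag_ms Numeric vector of lags (ms after stimulus onset).
#' @param soa_next_ms Onset asynchrony to the next stimulus (default `Inf`,
#'   i.e. no interruption).
#' @return List with numeric vectors `attended` and `unattended`.
#' @export
attention_gains <- function(fm, lag_ms, soa_next_ms = Inf) {
  mod <- lag_ms >= fm$tau & lag_ms < soa_next_ms
  list(
    attended = ifelse(mod, fm$g_att, 1),
    unattended = ifelse(mod, fm$g_unatt, 1)
  )
}

# Internal: spatial pattern for one orientation, split by stimulus class.
pattern_for <- function(fm, orientation) {
  key <- as.character(orientation)
  if (key %in% colnames(fm$patterns)) {
    fm$patterns[, key]
  } else if (key %in% colnames(fm$event_patterns)) {
    fm$event_patterns[, key]
  } else {
    abort(paste0("no spatial pattern for orientation ", orientation))
  }
}

#' Simulate a continuous EEG recording for one sequence
#'
#' Every presentation adds
#' `A * kernel(lag) * [g_att(lag) * pattern(cued) + g_unatt(lag) * pattern(uncued)]`
#' to the recording at its onset; responses of temporally overlapping
#' presentations sum linearly (the attention modulation of a presentation is
#' interrupted by the next onset; see [attention_gains()]).
#' Spatio-temporally correlated noise is added on
#' top (AR(1) in time, factor covariance across channels). Sampling rate is
#' 1000 Hz. A silent lead-in and tail are added so that epoching windows
#' around every presentation fall inside the recording.
#'
#' @param sequence One sequence of a `session_design` (rows of one
#'   `sequence_id`).
#' @param fm A `forward_model`.
#' @param noise If `FALSE`, return the noiseless superposition (used by the
#'   linearity and superposition tests).
#' @param lead_in_ms,tail_ms Silence before the first / after the last onset
#'   (defaults comfortably cover the -100 to 800 ms epoch window).
#' @return An `eeg_recording`: list with `data` (channels x samples matrix,
#'   microvolts), `srate` (1000), `channel_names`, and `events` (the sequence
#'   table with an added `onset_sample`, 1-based).
#' @export
simulate_recording <- function(sequence, fm, noise = TRUE,
                               lead_in_ms = 200, tail_ms = 950) {
  stopifnot(inherits(fm, "forward_model"))
  onsets_ms <- sequence$onset_ms + lead_in_ms
  onset_sample <- as.integer(round(onsets_ms)) + 1L
  n <- max(onset_sample) + as.integer(tail_ms)
  p <- fm$n_channels

  # Accumulate one amplitude envelope per (orientation pattern), then map to
  # channels with a single matrix product.
  all_keys <- c(colnames(fm$patterns), colnames(fm$event_patterns))
  env <- matrix(0, length(all_keys), n, dimnames = list(all_keys, NULL))
  lags <- seq(ceiling(fm$t_on), ceiling(fm$t_off) - 1L)  # 1 ms resolution
  k <- response_kernel(fm, lags)
  base <- fm$amplitude * k
  soa_next <- c(diff(onsets_ms), Inf)
  for (i in seq_along(onset_sample)) {
    idx <- onset_sample[i] + lags
    keep <- idx <= n
    g <- attention_gains(fm, lags, soa_next[i])
    ck <- as.character(sequence$cued_orientation[i])
    uk <- as.character(sequence$uncued_orientation[i])
    env[ck, idx[keep]] <- env[ck, idx[keep]] + (base * g$attended)[keep]
    env[uk, idx[keep]] <- env[uk, idx[keep]] + (base * g$unattended)[keep]
  }
  P <- cbind(fm$patterns, fm$event_patterns)
  data <- P %*% env

  if (noise && fm$noise_sd > 0) {
    data <- data + .sim_noise(p, n, fm$noise_chol, fm$ar_phi, fm$noise_sd)
  }

  structure(
    list(
      data = data,
      srate = 1000,
      channel_names = fm$channel_names,
      events = mutate(sequence, onset_sample = onset_sample)
    ),
    class = "eeg_recording"
  )
}

#' Simulate a group of participants
#'
#' Each participant gets an independent design, independent forward-model
#' patterns (derived seed), and an evoked amplitude drawn from
#' `Normal(amplitude, between_subject_sd)` truncated at zero. Everything is
#' reproducible from `base_seed`.
#'
#' Recordings for a full 64-sequence session are large (~150 MB per
#' participant at 64 channels); for group-level analyses prefer the streaming
#' [run_pipeline()], which discards each participant's raw data after
#' decoding.
#'
#' @param n_participants Number of participants (>= 2).
#' @param base_seed Master seed.
#' @param n_sequences Sequences per participant.
#' @param n_channels Channels per recording.
#' @param between_subject_sd SD of the per-participant amplitude.
#' @param ... Forward-model overrides passed to [make_forward_model()]
#'   (e.g. `amplitude`, `g_unatt`, `noise_sd`).
#' @return A list with one element per participant: `participant_id`,
#'   `design`, `fm`, and `recordings` (one `eeg_recording` per sequence).
#' @export
simulate_participants <- function(n_participants, base_seed, n_sequences = 64L,
                                  n_channels = 64L, between_subject_sd = 0.25,
                                  ...) {
  stopifnot(n_participants >= 2)
  purrr::map(seq_len(n_participants), function(i) {
    pid <- sprintf("sim%02d", i)
    design <- generate_session(pid, derive_seed(base_seed, "design", i), n_sequences)
    fm <- participant_forward_model(base_seed, i, n_channels, between_subject_sd, ...)
    recs <- withr::with_seed(derive_seed(base_seed, "noise", i), {
      lapply(split(design, design$sequence_id), simulate_recording, fm = fm)
    })
    list(participant_id = pid, design = design, fm = fm, recordings = recs)
  })
}

# Internal: forward model for participant i, with amplitude drawn from a
# truncated normal around the group mean.
participant_forward_model <- function(base_seed, i, n_channels,
                                      between_subject_sd, ...) {
  overrides <- list(...)
  fm <- do.call(make_forward_model,
                c(list(n_channels = n_channels,
                       seed = derive_seed(base_seed, "forward_model", i)),
                  overrides))
  if (between_subject_sd > 0) {
    fm$amplitude <- withr::with_seed(derive_seed(base_seed, "amplitude", i), {
      a <- -1
      while (a < 0) a <- stats::rnorm(1, fm$amplitude, between_subject_sd)
      a
    })
  }
  fm
}
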
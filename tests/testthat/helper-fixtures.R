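# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# A miniature two-sequence design (1 constant + 1 varied ISI).
tiny_design <- function() {
  fixture("tiny_design", function() generate_session("t01", seed = 101, n_sequences = 2))
}

# A small forward model used across synth/preprocess tests.
tiny_fm <- function() {
  fixture("tiny_fm", function() make_forward_model(8L, seed = 202, noise_sd = 2))
}

# Epochs of a 4-sequence, 16-channel session with the default attention
# effect; exercises design -> synth -> preprocess.
tiny_epochs <- function() {
  fixture("tiny_epochs", function() {
    des <- generate_session("t02", seed = 303, n_sequences = 4)
    fm <- make_forward_model(16L, seed = 304)
    withr::with_seed(305, {
      preprocess_session(lapply(split(des, des$sequence_id),
                                simulate_recording, fm = fm))
    })
  })
}

# Hand-built epoch set with planted class patterns: analysable trials in
# both analysis groups, labels encoded in the channel means during a known
# time window. `snr = Inf` gives a noiseless, perfectly separable problem.
planted_epochs <- function(n_seq = 4, trials_per_class = 6, n_ch = 6,
                           n_time = 20, signal_window = 8:14, snr = 10,
                           seed = 99) {
  withr::with_seed(seed, {
    stimset <- make_stimulus_set()
    rows <- list(); data_rows <- list()
    sd_noise <- if (is.infinite(snr)) 0 else 1 / snr
    for (s in seq_len(n_seq)) {
      for (id in rep(seq_len(8), length.out = 8 * ceiling(trials_per_class / 2))) {
        cued <- stimset$blue_orientation[id]   # cued colour blue throughout
        uncued <- stimset$orange_orientation[id]
        x <- matrix(stats::rnorm(n_ch * n_time, sd = sd_noise), n_ch, n_time)
        pat_c <- as.numeric(cued == c(22.5, 67.5, 112.5, 157.5))
        pat_u <- as.numeric(uncued == c(22.5, 67.5, 112.5, 157.5))
        x[seq_len(4), signal_window] <- x[seq_len(4), signal_window] +
          pat_c + 0.5 * pat_u
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = "planted", sequence_id = s,
          cued_orientation = cued, uncued_orientation = uncued,
          analysable = 1L,
          analysis_group = if (cued %in% c(22.5, 112.5)) 1L else 2L,
          isi_condition = if (s %% 2 == 0) "constant" else "varied",
          role = "non_target"
        )
        data_rows[[length(data_rows) + 1]] <- x
      }
    }
    data <- array(0, dim = c(length(data_rows), n_ch, n_time))
    for (i in seq_along(data_rows)) data[i, , ] <- data_rows[[i]]
    structure(
      list(data = data, times_ms = seq(0, by = 4, length.out = n_time),
           srate = 250, channel_names = sprintf("ch%d", seq_len(n_ch)),
           metadata = dplyr::bind_rows(rows)),
      class = "epoch_set"
    )
  })
}
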
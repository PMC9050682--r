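test_that("forward model patterns are orthonormal and parameters validated", {
  fm <- make_forward_model(16L, seed = 5)
  for (P in list(fm$patterns, fm$event_patterns)) {
    G <- crossprod(P)
    expect_equal(G, diag(4), tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(make_forward_model(3L), "at least 4")

  # overrides are applied
  fm2 <- make_forward_model(8L, seed = 5, amplitude = 0, g_att = 1, g_unatt = 1)
  expect_equal(fm2$amplitude, 0)
  g <- attention_gains(fm2, c(100, 300, 399))
  expect_equal(g$attended, g$unattended)
})

test_that("response kernel is a unit-peak bump supported on [t_on, t_off)", {
  fm <- tiny_fm()
  lags <- seq(-50, 500, by = 1)
  k <- response_kernel(fm, lags)
  expect_true(all(k[lags < fm$t_on | lags >= fm$t_off] == 0))
  expect_equal(max(k), 1)
  expect_equal(lags[which.max(k)], fm$t_peak)
  expect_true(all(k >= 0 & k <= 1))
})

test_that("attention gains are equal before tau and after the next onset", {
  fm <- tiny_fm()
  lags <- c(0, 100, 229, 230, 300, 399)
  g <- attention_gains(fm, lags, soa_next_ms = Inf)
  expect_equal(g$attended[lags < fm$tau], g$unattended[lags < fm$tau])
  expect_equal(g$attended[lags >= fm$tau], rep(fm$g_att, 3))
  expect_equal(g$unattended[lags >= fm$tau], rep(fm$g_unatt, 3))
  # modulation interrupted by the next stimulus onset
  g2 <- attention_gains(fm, lags, soa_next_ms = 300)
  expect_equal(g2$attended[lags >= 300], g2$unattended[lags >= 300])
  expect_equal(g2$unattended[lags >= fm$tau & lags < 300], fm$g_unatt)
})

test_that("noiseless recordings equal the brute-force superposition of shifted kernels", {
  des <- tiny_design()
  s1 <- des[des$sequence_id == 1, ][1:10, ]
  fm <- tiny_fm()
  rec <- simulate_recording(s1, fm, noise = FALSE, lead_in_ms = 200)

  # independent brute-force reconstruction at probe samples
  probes <- sort(sample.int(ncol(rec$data), 200))
  expected <- matrix(0, fm$n_channels, length(probes))
  for (j in seq_along(probes)) {
    t_ms <- probes[j] - 1  # sample i holds time (i-1) ms
    for (i in seq_len(nrow(s1))) {
      # onsets are discretised to the 1 ms sample grid
      lag_int <- t_ms - round(s1$onset_ms[i] + 200)
      if (lag_int < ceiling(fm$t_on) || lag_int >= ceiling(fm$t_off)) next
      soa <- if (i < nrow(s1)) s1$onset_ms[i + 1] - s1$onset_ms[i] else Inf
      k <- response_kernel(fm, lag_int)
      mod <- lag_int >= fm$tau && lag_int < soa
      ga <- if (mod) fm$g_att else 1
      gu <- if (mod) fm$g_unatt else 1
      pc <- fm$patterns[, as.character(s1$cued_orientation[i])]
      pu <- fm$patterns[, as.character(s1$uncued_orientation[i])]
      expected[, j] <- expected[, j] + fm$amplitude * k * (ga * pc + gu * pu)
    }
  }
  expect_equal(rec$data[, probes], expected, tolerance = 1e-10)
})

test_that("recording responses superpose linearly over events", {
  des <- tiny_design()
  s1 <- des[des$sequence_id == 1, ][1:12, ]
  fm <- tiny_fm()
  # split the events into two halves; onsets (and hence the gain handoffs)
  # are evaluated per subset, so use subsets with preserved spacing
  a <- s1[seq(1, 12, by = 2), ]
  b <- s1[seq(2, 12, by = 2), ]
  # with tau = Inf the gain handoff never engages, so the response is a pure
  # linear superposition of per-event contributions
  fm_unint <- make_forward_model(8L, seed = 202, noise_sd = 2, tau = Inf)
  full <- simulate_recording(s1, fm_unint, noise = FALSE, tail_ms = 2000)
  ra <- simulate_recording(a, fm_unint, noise = FALSE, tail_ms = 2000)
  rb <- simulate_recording(b, fm_unint, noise = FALSE, tail_ms = 2000)
  n <- min(ncol(ra$data), ncol(rb$data), ncol(full$data))
  expect_equal(full$data[, 1:n], ra$data[, 1:n] + rb$data[, 1:n],
               tolerance = 1e-10)
})

test_that("with equal gains the cued and uncued envelopes are identical", {
  fm <- make_forward_model(8L, seed = 9, g_att = 1, g_unatt = 1)
  des <- tiny_design()
  s1 <- des[des$sequence_id == 1, ][5, ]  # single event
  rec <- simulate_recording(s1, fm, noise = FALSE)
  # project onto cued and uncued patterns: envelopes must match
  env_c <- as.numeric(fm$patterns[, as.character(s1$cued_orientation)] %*% rec$data)
  env_u <- as.numeric(fm$patterns[, as.character(s1$uncued_orientation)] %*% rec$data)
  expect_equal(env_c, env_u, tolerance = 1e-12)
})

test_that("noise-only recordings have the stationary AR(1) covariance", {
  fm <- make_forward_model(6L, seed = 13, amplitude = 0, noise_sd = 2,
                           ar_phi = 0.9)
  des <- tiny_design()
  s1 <- des[des$sequence_id == 1, ]
  rec <- withr::with_seed(14, simulate_recording(s1, fm, tail_ms = 30000))
  emp <- tcrossprod(rec$data) / ncol(rec$data)
  theo <- fm$noise_sigma * fm$noise_sd^2
  # relative Frobenius error small at ~70k samples (correlated -> slow MC rate)
  expect_lt(norm(emp - theo, "F") / norm(theo, "F"), 0.15)
  # lag-1 autocorrelation recovers phi
  ac <- mean(sapply(1:6, function(ch) {
    stats::cor(rec$data[ch, -1], rec$data[ch, -ncol(rec$data)])
  }))
  expect_equal(ac, fm$ar_phi, tolerance = 0.02)
})

test_that("amplitude zero yields pure noise and seed contract holds", {
  des <- tiny_design()
  s1 <- des[des$sequence_id == 1, ][1:5, ]
  fm0 <- make_forward_model(8L, seed = 3, amplitude = 0)
  r1 <- withr::with_seed(77, simulate_recording(s1, fm0))
  r2 <- withr::with_seed(77, simulate_recording(s1, fm0))
  expect_identical(r1$data, r2$data)
  noiseless <- simulate_recording(s1, fm0, noise = FALSE)
  expect_true(all(noiseless$data == 0))
})

test_that("simulate_participants reproduces under the base seed and shares amplitude at sd 0", {
  g1 <- simulate_participants(2, base_seed = 55, n_sequences = 2, n_channels = 6)
  g2 <- simulate_participants(2, base_seed = 55, n_sequences = 2, n_channels = 6)
  expect_identical(g1[[1]]$recordings[[1]]$data, g2[[1]]$recordings[[1]]$data)
  expect_identical(g1[[2]]$design, g2[[2]]$design)
  expect_length(g1, 2)
  expect_length(g1[[1]]$recordings, 2)
  # independent patterns across participants
  expect_false(identical(g1[[1]]$fm$patterns, g1[[2]]$fm$patterns))
  # between-subject amplitude
  expect_false(g1[[1]]$fm$amplitude == g1[[2]]$fm$amplitude)
  g3 <- simulate_participants(2, base_seed = 55, n_sequences = 2, n_channels = 6,
                              between_subject_sd = 0)
  expect_equal(g3[[1]]$fm$amplitude, g3[[2]]$fm$amplitude)
})
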
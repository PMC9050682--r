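test_that("stimulus set matches brute-force enumeration of the 45-degree constraint", {
  ss <- make_stimulus_set()

  # independent brute-force enumeration over all 4 x 4 orientation pairs
  oris <- c(22.5, 67.5, 112.5, 157.5)
  brute <- 0L
  for (b in oris) for (o in oris) {
    d <- abs(b - o) %% 180
    if (min(d, 180 - d) == 45) brute <- brute + 1L
  }
  expect_equal(nrow(ss), brute)
  expect_equal(nrow(ss), 8L)

  # every pair is rotated exactly 45 degrees
  d <- abs(ss$blue_orientation - ss$orange_orientation) %% 180
  expect_true(all(pmin(d, 180 - d) == 45))

  # each cued orientation co-occurs with both possible uncued orientations
  expect_true(all(c(67.5, 157.5) %in% ss$orange_orientation[ss$blue_orientation == 22.5]))
  expect_equal(as.integer(table(ss$blue_orientation)), rep(2L, 4))

  # deterministic ordering by (blue, orange)
  expect_equal(order(ss$blue_orientation, ss$orange_orientation), 1:8)
})

test_that("ISI grids follow the 60 Hz frame raster", {
  expect_equal(isi_grid("constant"), 200)
  g <- isi_grid("varied")
  expect_length(g, 13)
  expect_equal(g[1], 100)
  expect_equal(g[13], 300)
  expect_equal(unique(round(diff(g), 10)), round(1000 / 60, 10))
  expect_equal(mean(g), 200)
  expect_error(isi_grid("jittered"), "unknown ISI condition")
})

test_that("non-target streams are exactly balanced and seed-reproducible", {
  s1 <- withr::with_seed(7, generate_nontarget_stream("varied"))
  expect_equal(nrow(s1), 104L)
  # each (ISI, type) cell exactly once
  expect_true(all(table(s1$isi_frames, s1$stimulus_id) == 1L))
  expect_equal(as.integer(table(s1$stimulus_id)), rep(13L, 8))

  s2 <- withr::with_seed(7, generate_nontarget_stream("varied"))
  expect_identical(s1, s2)
  s3 <- withr::with_seed(8, generate_nontarget_stream("varied"))
  expect_false(identical(s1$stimulus_id, s3$stimulus_id))

  sc <- withr::with_seed(7, generate_nontarget_stream("constant"))
  expect_true(all(sc$isi_frames == 12L))
  expect_equal(as.integer(table(sc$stimulus_id)), rep(13L, 8))
})

test_that("event and padding insertion yields the published sequence arithmetic", {
  for (cfg in list(c(1, 1, 128), c(2, 2, 144), c(1, 2, 136), c(2, 1, 136))) {
    seq_des <- withr::with_seed(11 + cfg[1] * 10 + cfg[2], {
      stream <- generate_nontarget_stream("varied")
      insert_events_and_padding(stream, cfg[1], cfg[2], "blue", 90, "varied")
    })
    expect_equal(nrow(seq_des), cfg[3])
    expect_equal(sum(seq_des$analysable), 104L)
    expect_equal(sum(seq_des$role == "target"), cfg[1])
    expect_equal(sum(seq_des$role == "foil"), cfg[2])

    # 4 padding at both sequence boundaries
    expect_true(all(seq_des$role[1:4] == "padding"))
    expect_true(all(seq_des$role[(nrow(seq_des) - 3):nrow(seq_des)] == "padding"))

    # each event is wrapped by 3 padding before and 4 after
    for (i in which(seq_des$role %in% c("target", "foil"))) {
      expect_true(all(seq_des$role[(i - 3):(i - 1)] == "padding"))
      expect_true(all(seq_des$role[(i + 1):(i + 4)] == "padding"))
    }

    # events never flagged analysable; non-targets always are
    expect_true(all(seq_des$analysable[seq_des$role != "non_target"] == 0L))

    # event stimuli: target orientation in the cued colour for targets,
    # uncued colour for foils, paired with 45 or 135
    tg <- seq_des[seq_des$role == "target", ]
    expect_true(all(tg$cued_orientation == 90 & tg$uncued_orientation %in% c(45, 135)))
    fl <- seq_des[seq_des$role == "foil", ]
    expect_true(all(fl$uncued_orientation == 90 & fl$cued_orientation %in% c(45, 135)))

    # onsets strictly increasing on the frame grid, duration fixed at 100 ms
    expect_true(all(diff(seq_des$onset_ms) > 0))
    expect_true(all(seq_des$duration_ms == 100))
  }
})

test_that("padding blocks draw stimulus types without replacement", {
  seq_des <- withr::with_seed(21, {
    insert_events_and_padding(generate_nontarget_stream("constant"),
                              2, 2, "orange", 0, "constant")
  })
  r <- rle(seq_des$role == "padding")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (b in which(r$values)) {
    ids <- seq_des$stimulus_id[starts[b]:ends[b]]
    expect_false(anyDuplicated(ids) > 0)
  }
})

test_that("sessions counterbalance the 32 design cells exactly and reproduce under seed", {
  des <- generate_session("p01", seed = 31, n_sequences = 64)
  seq_level <- dplyr::distinct(des, sequence_id, cued_colour, target_orientation,
                               isi_condition, n_targets, n_foils)
  expect_equal(nrow(seq_level), 64L)
  cell_counts <- dplyr::count(seq_level, cued_colour, target_orientation,
                              isi_condition, n_targets, n_foils)
  expect_equal(nrow(cell_counts), 32L)
  expect_true(all(cell_counts$n == 2L))
  expect_equal(sum(des$analysable), 64L * 104L)

  expect_identical(des, generate_session("p01", seed = 31, n_sequences = 64))
  des2 <- generate_session("p01", seed = 32, n_sequences = 64)
  expect_false(identical(des$onset_ms, des2$onset_ms))
})

test_that("uncued orientations are balanced within every cued orientation", {
  des <- tiny_design()
  nt <- des[des$analysable == 1L, ]
  for (s in unique(nt$sequence_id)) {
    tab <- table(nt$cued_orientation[nt$sequence_id == s],
                 nt$uncued_orientation[nt$sequence_id == s])
    # each cued orientation pairs with exactly 2 uncued orientations, 13 each
    expect_true(all(tab[tab > 0] == 13L))
    expect_equal(unname(rowSums(tab > 0)), rep(2L, 4))
  }
})

test_that("events files round-trip losslessly", {
  des <- tiny_design()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(des, path)
  back <- read_events_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(des)[, names(back)],
               tolerance = 1e-12)
})
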
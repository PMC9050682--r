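#' The stimulus set: eight overlaid blue/orange orientation pairs
#'
#' Each stimulus overlays a blue and an orange set of lines at fixation. Both
#' orientations come from \{22.5, 67.5, 112.5, 157.5\} degrees and the two
#' colours are always rotated 45 degrees from each other, which yields exactly
#' eight combinations. The 45-degree offset is what makes the cued and uncued
#' orientations orthogonal across the two analysis groups: for every cued
#' orientation, both possible uncued orientations occur equally often.
#'
#' @return A tibble with columns `id`, `blue_orientation`, `orange_orientation`,
#'   ordered by (blue, orange).
#' @examples
#' make_stimulus_set()
#' @export
make_stimulus_set <- function() {
  grid <- expand.grid(
    blue_orientation = ORIENTATIONS,
    orange_orientation = ORIENTATIONS
  )
  keep <- orientation_diff(grid$blue_orientation, grid$orange_orientation) == 45
  out <- grid[keep, ]
  out <- out[order(out$blue_orientation, out$orange_orientation), ]
  tibble(
    id = seq_len(nrow(out)),
    blue_orientation = out$blue_orientation,
    orange_orientation = out$orange_orientation
  )
}

#' Inter-stimulus interval grid for a timing condition
#'
#' The constant condition always uses a 200 ms ISI. The varied condition uses
#' 13 ISIs equally spaced between 100 and 300 ms on the 60 Hz display frame
#' grid (steps of 1000/60 ms, i.e. frames 6 through 18).
#'
#' @param condition `"constant"` or `"varied"`.
#' @return Numeric vector of ISIs in ms.
#' @export
isi_grid <- function(condition) {
  frames <- isi_grid_frames(condition)
  frames * FRAME_MS
}

# Internal frame-count representation (exact integers; avoids FP drift).
isi_grid_frames <- function(condition) {
  switch(condition,
    constant = 12L,
    varied = 6:18,
    abort(paste0("unknown ISI condition: '", condition, "'"))
  )
}

#' Generate the balanced non-target stream of one sequence
#'
#' Produces the 104 non-target presentations of a sequence. In the varied
#' condition every (ISI, stimulus type) cell of the 13 x 8 design occurs
#' exactly once; in the constant condition every type occurs 13 times at a
#' 200 ms ISI. The order is a random permutation drawn from the current RNG
#' state (seed it with [set.seed()] or [withr::with_seed()]).
#'
#' @param isi_condition `"constant"` or `"varied"`.
#' @return A tibble with columns `stimulus_id`, `isi_frames`, 104 rows.
#' @export
generate_nontarget_stream <- function(isi_condition) {
  frames <- isi_grid_frames(isi_condition)
  cells <- expand.grid(stimulus_id = 1:8, isi_frames = frames)
  if (isi_condition == "constant") {
    cells <- cells[rep(seq_len(nrow(cells)), each = 13L), ]
  }
  cells <- cells[sample.int(nrow(cells)), ]
  as_tibble(cells)
}

# Internal: draw a padding block of `n` stimulus types without replacement.
draw_padding_block <- function(n) {
  sample.int(8L, n, replace = FALSE)
}

# Internal: orientations of a target or foil event. The target orientation
# (0 or 90 deg) appears in the cued colour for targets and in the uncued
# colour for foils; the other colour carries 45 or 135 deg, drawn uniformly.
draw_event_stimulus <- function(role, target_orientation) {
  other <- sample(c(45, 135), 1L)
  if (role == "target") {
    list(cued = target_orientation, uncued = other)
  } else {
    list(cued = other, uncued = target_orientation)
  }
}

#' Insert target/foil events and padding into a non-target stream
#'
#' Wraps the 104-presentation non-target stream with 4 padding presentations
#' at the start and end of the sequence, and inserts `n_targets` target and
#' `n_foils` foil events, each flanked by 3 padding presentations before and
#' 4 after. Event blocks are placed uniformly at random in distinct gaps
#' between non-targets, so they never overlap each other nor touch the
#' boundary padding. Padding stimuli are drawn without replacement from the
#' 8 stimulus types within each padding block. Only the non-targets are
#' flagged analysable.
#'
#' @param stream Tibble from [generate_nontarget_stream()].
#' @param n_targets,n_foils Integers in \{1, 2\}.
#' @param cued_colour `"blue"` or `"orange"`.
#' @param target_orientation 0 or 90 (degrees).
#' @param isi_condition `"constant"` or `"varied"`.
#' @param sequence_id Integer identifier stored on every row.
#' @return A tibble with one row per presentation (ordered in time), columns
#'   described in [generate_session()].
#' @export
insert_events_and_padding <- function(stream, n_targets, n_foils, cued_colour,
                                      target_orientation, isi_condition,
                                      sequence_id = 1L) {
  stopifnot(n_targets %in% 1:2, n_foils %in% 1:2,
            cued_colour %in% c("blue", "orange"),
            target_orientation %in% c(0, 90),
            nrow(stream) == 104L)
  stimset <- make_stimulus_set()
  frames <- isi_grid_frames(isi_condition)
  draw_isi <- function(n) {
    if (length(frames) == 1L) rep(frames, n) else sample(frames, n, replace = TRUE)
  }

  pad_row <- function(n) {
    ids <- draw_padding_block(n)
    tibble(
      role = "padding",
      stimulus_id = ids,
      blue_orientation = stimset$blue_orientation[ids],
      orange_orientation = stimset$orange_orientation[ids],
      isi_frames = draw_isi(n)
    )
  }
  nt_rows <- tibble(
    role = "non_target",
    stimulus_id = stream$stimulus_id,
    blue_orientation = stimset$blue_orientation[stream$stimulus_id],
    orange_orientation = stimset$orange_orientation[stream$stimulus_id],
    isi_frames = stream$isi_frames
  )

  n_events <- n_targets + n_foils
  roles <- sample(c(rep("target", n_targets), rep("foil", n_foils)))
  # Distinct gaps strictly inside the non-target stream (after positions
  # 1..103); at these sizes a valid placement always exists.
  gaps <- sort(sample(seq_len(103L), n_events))

  event_block <- function(role) {
    ev <- draw_event_stimulus(role, target_orientation)
    ori <- if (cued_colour == "blue") {
      list(blue = ev$cued, orange = ev$uncued)
    } else {
      list(blue = ev$uncued, orange = ev$cued)
    }
    bind_rows(
      pad_row(3L),
      tibble(role = role, stimulus_id = NA_integer_,
             blue_orientation = ori$blue, orange_orientation = ori$orange,
             isi_frames = draw_isi(1L)),
      pad_row(4L)
    )
  }

  pieces <- list(pad_row(4L))
  prev <- 0L
  for (k in seq_len(n_events)) {
    pieces <- c(pieces, list(nt_rows[(prev + 1L):gaps[k], ], event_block(roles[k])))
    prev <- gaps[k]
  }
  pieces <- c(pieces, list(nt_rows[(prev + 1L):104L, ], pad_row(4L)))
  events <- bind_rows(pieces)

  # onset_i = sum of all preceding (isi + duration) + own isi, on the frame grid
  dur_frames <- 6L  # 100 ms at 60 Hz
  onset_frames <- cumsum(events$isi_frames) + dur_frames * (seq_len(nrow(events)) - 1L)

  cued_is_blue <- cued_colour == "blue"
  events %>%
    mutate(
      sequence_id = sequence_id,
      index_in_sequence = seq_len(nrow(events)),
      onset_ms = onset_frames * FRAME_MS,
      duration_ms = 100,
      isi_before_ms = round(.data$isi_frames * FRAME_MS, 2),
      cued_colour = cued_colour,
      cued_orientation = if (cued_is_blue) .data$blue_orientation else .data$orange_orientation,
      uncued_orientation = if (cued_is_blue) .data$orange_orientation else .data$blue_orientation,
      analysable = as.integer(.data$role == "non_target"),
      analysis_group = if_else(
        .data$analysable == 1L,
        if_else(.data$cued_orientation %in% c(22.5, 112.5), 1L, 2L),
        NA_integer_
      ),
      isi_condition = isi_condition,
      target_orientation = target_orientation,
      n_targets = n_targets,
      n_foils = n_foils,
      trial_type = if_else(
        .data$role %in% c("target", "foil"), .data$role,
        sprintf("b%05.1f_o%05.1f", .data$blue_orientation, .data$orange_orientation)
      )
    ) %>%
    select("sequence_id", "index_in_sequence", "onset_ms", "duration_ms",
           "isi_frames", "isi_before_ms", "trial_type", "role", "stimulus_id",
           "blue_orientation", "orange_orientation", "cued_colour",
           "cued_orientation", "uncued_orientation", "analysable",
           "analysis_group", "isi_condition", "target_orientation",
           "n_targets", "n_foils")
}

#' Generate a full counterbalanced session design
#'
#' A session comprises `n_sequences` sequences crossing cued colour (2) x
#' target orientation (2) x ISI condition (2) x number of target/foil events
#' (2 x 2), each cell occurring equally often; with the default 64 sequences
#' every one of the 32 cells appears exactly twice. Sequence order is a
#' seeded random permutation.
#'
#' @param participant_id Identifier stored on every row.
#' @param seed Integer seed making the whole design reproducible.
#' @param n_sequences Number of sequences (default 64; exact counterbalance
#'   requires a multiple of 32, smaller values give a balanced prefix of the
#'   design and are meant for miniature test fixtures).
#' @return A `session_design` tibble, one row per stimulus presentation.
#' @examples
#' des <- generate_session("p01", seed = 1, n_sequences = 32)
#' dplyr::count(des, analysable)
#' @export
generate_session <- function(participant_id, seed, n_sequences = 64L) {
  stopifnot(n_sequences >= 2L)
  withr::with_seed(seed, {
    cells <- expand.grid(
      isi_condition = c("constant", "varied"),
      cued_colour = c("blue", "orange"),
      target_orientation = c(0, 90),
      n_targets = 1:2,
      n_foils = 1:2,
      stringsAsFactors = FALSE
    )
    # Any prefix of this ordering is near-balanced, so sessions smaller than
    # one full 32-cell replicate (used for miniature fixtures) still split
    # evenly over ISI condition and cued colour.
    cells <- cells[rep(seq_len(32L), times = ceiling(n_sequences / 32L)), ]
    cells <- cells[seq_len(n_sequences), ]
    cells <- cells[sample.int(nrow(cells)), ]
    seqs <- purrr::pmap(
      list(cells$cued_colour, cells$target_orientation, cells$isi_condition,
           cells$n_targets, cells$n_foils, seq_len(n_sequences)),
      function(cc, to, ic, nt, nf, sid) {
        stream <- generate_nontarget_stream(ic)
        insert_events_and_padding(stream, nt, nf, cc, to, ic, sequence_id = sid)
      }
    )
    out <- bind_rows(seqs) %>% mutate(participant_id = participant_id, .before = 1L)
    attr(out, "seed") <- seed
    class(out) <- c("session_design", class(out))
    out
  })
}

#' Write a design to a BIDS-style events file
#'
#' One tab-separated file per session, with `onset` and `duration` in
#' seconds and one row per stimulus presentation.
#'
#' @param design A `session_design` tibble (or any sequence subset of one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  out <- design %>%
    mutate(onset = .data$onset_ms / 1000, duration = .data$duration_ms / 1000) %>%
    select("onset", "duration", "trial_type", "role", "blue_orientation",
           "orange_orientation", "cued_colour", "cued_orientation",
           "uncued_orientation", "isi_before_ms", "isi_condition",
           "sequence_id", "analysable", "participant_id",
           "index_in_sequence", "target_orientation", "n_targets", "n_foils")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a BIDS-style events file back into a session design
#'
#' Timing is reconstructed exactly from the frame grid: ISIs are snapped back
#' to integer 60 Hz frames and onsets recomputed, so a write/read round trip
#' is lossless.
#'
#' @param path Events file written by [write_events_tsv()].
#' @return A `session_design` tibble.
#' @export
read_events_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  out <- raw %>%
    mutate(
      isi_frames = as.integer(round(.data$isi_before_ms / FRAME_MS)),
      duration_ms = .data$duration * 1000,
      stimulus_id = NA_integer_
    ) %>%
    group_by(.data$sequence_id) %>%
    mutate(onset_ms = (cumsum(.data$isi_frames) + 6L * (row_number() - 1L)) * FRAME_MS) %>%
    ungroup() %>%
    mutate(
      across(c("sequence_id", "index_in_sequence", "n_targets", "n_foils"),
             as.integer),
      analysable = as.integer(.data$analysable),
      analysis_group = if_else(
        .data$analysable == 1L,
        if_else(.data$cued_orientation %in% c(22.5, 112.5), 1L, 2L),
        NA_integer_
      )
    )
  stimset <- make_stimulus_set()
  key <- paste(stimset$blue_orientation, stimset$orange_orientation)
  idx <- match(paste(out$blue_orientation, out$orange_orientation), key)
  out$stimulus_id <- if_else(out$role %in% c("target", "foil"), NA_integer_,
                             as.integer(idx))
  out <- out %>%
    select("participant_id", "sequence_id", "index_in_sequence", "onset_ms",
           "duration_ms", "isi_frames", "isi_before_ms", "trial_type", "role",
           "stimulus_id", "blue_orientation", "orange_orientation",
           "cued_colour", "cued_orientation", "uncued_orientation",
           "analysable", "analysis_group", "isi_condition",
           "target_orientation", "n_targets", "n_foils")
  class(out) <- c("session_design", class(out))
  out
}
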
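#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom Rcpp evalCpp
#' @useDynLib attnmvpa, .registration = TRUE
NULL

# Monitor refresh interval (ms) that all stimulus timing is locked to.
FRAME_MS <- 1000 / 60

# The four non-target line orientations (degrees).
ORIENTATIONS <- c(22.5, 67.5, 112.5, 157.5)

# Orientations reserved for target/foil event stimuli (degrees).
EVENT_ORIENTATIONS <- c(0, 45, 90, 135)

#' Derive a stage-specific RNG seed from a master seed
#'
#' Decouples the random streams of pipeline stages (design, noise, forward
#' model, ...) so that changing one stage's consumption of random numbers
#' does not perturb the others. Purely arithmetic, deterministic, and keeps
#' the result within the 32-bit integer range `set.seed()` accepts.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @param id Integer sub-identifier (e.g. participant number).
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage, id = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (abs(master) %% 2^20) * 1009 + (h %% 99991) * 7919 + (abs(id) %% 2^16) * 104729
  as.integer(s %% (2^31 - 1))
}

# Internal: angular difference between two orientations, folded into [0, 90].
orientation_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
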
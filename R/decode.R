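#' Regularised linear discriminant analysis (two classes)
#'
#' Closed-form LDA with shrinkage of the pooled within-class covariance:
#' `S_r = S + lambda * mean(diag(S)) * I`, discriminant
#' `w = S_r^-1 (mu1 - mu0)`, decision threshold at the midpoint of the
#' projected class means (equal priors). Deterministic. This is the pure-R
#' reference implementation; [decode_task()] runs the same computation in
#' compiled code and the two are held in exact agreement by the tests.
#'
#' @param train_x Numeric matrix, trials x channels.
#' @param train_y Vector of two class labels (any type), one per trial.
#' @param test_x Numeric matrix of test trials.
#' @param lambda Shrinkage parameter (default 0.01).
#' @return Predicted labels for `test_x`, with attributes `weights` and
#'   `threshold` (predictions are `weights %*% x > threshold` for the second
#'   class level).
#' @export
fit_predict_lda <- function(train_x, train_y, test_x, lambda = 0.01) {
  classes <- sort(unique(train_y))
  if (length(classes) != 2) abort("training data must contain exactly 2 classes")
  x0 <- train_x[train_y == classes[1], , drop = FALSE]
  x1 <- train_x[train_y == classes[2], , drop = FALSE]
  if (nrow(x0) < 2 || nrow(x1) < 2) abort("need at least 2 trials per class")
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  sc0 <- crossprod(sweep(x0, 2, mu0))
  sc1 <- crossprod(sweep(x1, 2, mu1))
  S <- (sc0 + sc1) / (nrow(x0) + nrow(x1) - 2)
  ridge <- lambda * mean(diag(S))
  if (ridge <= 0) ridge <- 1e-12  # degenerate (noise-free) covariance
  Sr <- S + ridge * diag(ncol(S))
  w <- solve(Sr, mu1 - mu0)
  thr <- sum(w * (mu0 + mu1)) / 2
  pred <- ifelse(as.numeric(test_x %*% w) > thr, classes[2], classes[1])
  attr(pred, "weights") <- as.numeric(w)
  attr(pred, "threshold") <- thr
  pred
}

# Internal: class labels decoded for a (role, analysis group) task.
task_class_labels <- function(role, analysis_group) {
  g1_cued <- c(22.5, 112.5); g2_cued <- c(67.5, 157.5)
  if (analysis_group == 1L) {
    if (role == "cued") g1_cued else g2_cued
  } else {
    if (role == "cued") g2_cued else g1_cued
  }
}

# Internal: select the analysable trials of one decoding task and return
# indices, labels and fold ids.
task_trials <- function(epochs, role, analysis_group, isi_filter) {
  meta <- epochs$metadata
  sel <- meta$analysable == 1L & !is.na(meta$analysis_group) &
    meta$analysis_group == analysis_group
  if (isi_filter != "all") sel <- sel & meta$isi_condition == isi_filter
  labels <- if (role == "cued") meta$cued_orientation else meta$uncued_orientation
  cls <- task_class_labels(role, analysis_group)
  sel <- sel & labels %in% cls
  idx <- which(sel)
  for (cl in cls) {
    if (!any(labels[idx] == cl)) {
      abort(sprintf("no trials for class %g of task (%s, group %d, isi %s)",
                    cl, role, analysis_group, isi_filter))
    }
  }
  list(idx = idx, y = as.integer(labels[idx] == cls[2]),
       seq_id = meta$sequence_id[idx], classes = cls)
}

#' Decode one orientation task per timepoint
#'
#' Restricts the epochs to the analysable trials of one decoding task (cued
#' or uncued orientation, within one analysis group, optionally within one
#' ISI condition), then runs leave-one-sequence-out cross-validated
#' regularised LDA per timepoint, using all channels at that timepoint as
#' features. Accuracy is pooled over folds (total correct / total tested).
#'
#' @param epochs An `epoch_set`.
#' @param role `"cued"` or `"uncued"`: which orientation's label is decoded.
#' @param analysis_group 1 or 2 (the two orthogonal orientation pairings).
#' @param isi_filter `"all"`, `"constant"` or `"varied"`.
#' @param lambda LDA shrinkage parameter.
#' @return A `decoding_timecourse` tibble: `participant_id`, `role`,
#'   `analysis_group`, `isi_filter`, `time_ms`, `accuracy`, `n_test`.
#' @export
decode_task <- function(epochs, role = c("cued", "uncued"), analysis_group = 1L,
                        isi_filter = "all", lambda = 0.01) {
  role <- match.arg(role)
  stopifnot(analysis_group %in% 1:2, isi_filter %in% c("all", "constant", "varied"))
  tr <- task_trials(epochs, role, analysis_group, isi_filter)
  seqs <- unique(tr$seq_id)
  if (length(seqs) < 2) abort("decoding requires at least 2 sequences")
  fold <- match(tr$seq_id, seqs)
  # sort trials by (fold, class) so each CV cell is a contiguous block, and
  # hand the compiled core channels-major data for contiguous access
  ord <- order(fold, tr$y)
  cube <- aperm(epochs$data[tr$idx[ord], , , drop = FALSE], c(2, 1, 3))
  res <- .decode_core(cube, as.integer(tr$y[ord]),
                      as.integer(fold[ord]), lambda)
  pid <- if ("participant_id" %in% names(epochs$metadata)) {
    epochs$metadata$participant_id[1]
  } else NA_character_
  out <- tibble(
    participant_id = pid,
    role = role,
    analysis_group = as.character(analysis_group),
    isi_filter = isi_filter,
    time_ms = epochs$times_ms,
    accuracy = as.numeric(res$accuracy),
    n_test = as.numeric(res$n_test)
  )
  class(out) <- c("decoding_timecourse", class(out))
  out
}

#' Average the two analysis groups of a decoding task
#'
#' Pointwise mean of the two accuracy curves; with the balanced design this
#' yields a 50% chance level.
#'
#' @param tc_group1,tc_group2 `decoding_timecourse`s for analysis groups 1
#'   and 2 of the same participant, role and ISI filter.
#' @return A `decoding_timecourse` with `analysis_group = "avg"`.
#' @export
average_analysis_groups <- function(tc_group1, tc_group2) {
  same <- identical(tc_group1$time_ms, tc_group2$time_ms) &&
    identical(tc_group1$role, tc_group2$role) &&
    identical(tc_group1$isi_filter, tc_group2$isi_filter)
  if (!same) abort("timecourses differ in time axis, role or ISI filter")
  out <- tc_group1
  out$accuracy <- (tc_group1$accuracy + tc_group2$accuracy) / 2
  out$n_test <- tc_group1$n_test + tc_group2$n_test
  out$analysis_group <- "avg"
  out
}

#' Run all decoding conditions and contrasts for one participant
#'
#' Produces the pair-averaged accuracy timecourses for
#' \{cued, uncued\} x \{all, constant, varied\} ISI filters, plus the derived
#' contrasts: the attention effect (cued - uncued) per ISI filter and the
#' temporal-expectation effect (constant - varied, averaged over the cued
#' and uncued conditions).
#'
#' @param epochs An `epoch_set` for one participant.
#' @param isi_filters Which ISI filters to compute (restrict to `"all"` to
#'   skip the per-condition splits).
#' @param lambda LDA shrinkage parameter.
#' @return A tibble with columns `participant_id`, `measure` (`"accuracy"`,
#'   `"attention_effect"` or `"expectation_effect"`), `role`, `isi_filter`,
#'   `time_ms`, `value`, `n_test`.
#' @export
run_all_conditions <- function(epochs, isi_filters = c("all", "constant", "varied"),
                               lambda = 0.01) {
  grid <- tidyr::expand_grid(role = c("cued", "uncued"), isi = isi_filters)
  curves <- purrr::pmap(grid, function(role, isi) {
    avg <- average_analysis_groups(
      decode_task(epochs, role, 1L, isi, lambda),
      decode_task(epochs, role, 2L, isi, lambda)
    )
    tibble(participant_id = avg$participant_id, measure = "accuracy",
           role = role, isi_filter = isi, time_ms = avg$time_ms,
           value = avg$accuracy, n_test = avg$n_test)
  }) %>% bind_rows()

  wide <- curves %>%
    select("participant_id", "role", "isi_filter", "time_ms", "value") %>%
    tidyr::pivot_wider(names_from = "role", values_from = "value")
  attn <- wide %>%
    mutate(measure = "attention_effect", role = NA_character_,
           value = .data$cued - .data$uncued, n_test = NA_real_) %>%
    select("participant_id", "measure", "role", "isi_filter", "time_ms",
           "value", "n_test")

  out <- bind_rows(curves, attn)
  if (all(c("constant", "varied") %in% isi_filters)) {
    byisi <- curves %>%
      filter(.data$isi_filter %in% c("constant", "varied")) %>%
      group_by(.data$participant_id, .data$isi_filter, .data$time_ms) %>%
      summarise(value = mean(.data$value), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "isi_filter", values_from = "value")
    expect <- byisi %>%
      mutate(measure = "expectation_effect", role = NA_character_,
             isi_filter = NA_character_, value = .data$constant - .data$varied,
             n_test = NA_real_) %>%
      select("participant_id", "measure", "role", "isi_filter", "time_ms",
             "value", "n_test")
    out <- bind_rows(out, expect)
  }
  out
}

#' Audit the orthogonality of the non-decoded orientation
#'
#' For every training fold of a task, counts the non-decoded colour's
#' orientations within each decoded class. In the balanced design these
#' counts are identical across the two classes, which is what guarantees
#' the other feature carries no information usable by the classifier.
#'
#' @inheritParams decode_task
#' @return A tibble with one row per (held-out sequence, other-orientation):
#'   counts `n_class1`, `n_class2` in the training data and a logical
#'   `balanced`.
#' @export
audit_fold_orthogonality <- function(epochs, role = "cued", analysis_group = 1L,
                                     isi_filter = "all") {
  tr <- task_trials(epochs, role, analysis_group, isi_filter)
  meta <- epochs$metadata[tr$idx, ]
  other <- if (role == "cued") meta$uncued_orientation else meta$cued_orientation
  seqs <- unique(tr$seq_id)
  purrr::map(seqs, function(s) {
    train <- tr$seq_id != s
    tab <- table(other[train], tr$y[train])
    tibble(
      held_out_sequence = s,
      other_orientation = as.numeric(rownames(tab)),
      n_class1 = as.integer(tab[, "0"]),
      n_class2 = as.integer(tab[, "1"])
    )
  }) %>%
    bind_rows() %>%
    mutate(balanced = .data$n_class1 == .data$n_class2)
}
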
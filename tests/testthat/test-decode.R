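test_that("LDA separates well-separated clouds and is at chance on null labels", {
  withr::with_seed(1, {
    n <- 40
    x0 <- matrix(rnorm(n * 4), n, 4)
    x1 <- matrix(rnorm(n * 4), n, 4) + 6  # d' >> 1
    train_x <- rbind(x0, x1)
    train_y <- rep(c("a", "b"), each = n)
    test_x <- rbind(matrix(rnorm(20 * 4), 20, 4),
                    matrix(rnorm(20 * 4), 20, 4) + 6)
    pred <- fit_predict_lda(train_x, train_y, test_x)
    expect_equal(as.character(pred), rep(c("a", "b"), each = 20))

    # labels independent of the data -> expected accuracy 0.5
    accs <- replicate(200, {
      xs <- matrix(rnorm(24 * 3), 24, 3)
      ys <- rep(c(0, 1), each = 12)
      mean(fit_predict_lda(xs, ys, matrix(rnorm(40 * 3), 40, 3)) ==
             rep(c(0, 1), each = 20))
    })
    expect_lt(abs(mean(accs) - 0.5), 2 * sd(accs) / sqrt(length(accs)))
  })
  expect_error(fit_predict_lda(matrix(1:8, 4), rep("a", 4), matrix(1:2, 1)),
               "exactly 2 classes")
})

test_that("LDA matches the closed-form equations on a hand-specified instance", {
  # 2 channels, 8 trials; small enough to solve by hand with the stated
  # formulae: S_r = S_pooled + 0.01 * mean(diag(S_pooled)) * I,
  # w = S_r^-1 (mu1 - mu0), threshold = w'(mu0 + mu1)/2
  x <- matrix(c(0.0,  0.1,
                0.2, -0.1,
                0.1,  0.3,
               -0.1,  0.1,
                1.0,  0.9,
                1.2,  1.1,
                0.9,  1.2,
                1.1,  0.8), ncol = 2, byrow = TRUE)
  y <- rep(c(0, 1), each = 4)
  test_x <- matrix(c(0.5, 0.5, 0.0, 0.0, 1.0, 1.0), ncol = 2, byrow = TRUE)

  # independent brute-force computation
  mu0 <- colMeans(x[1:4, ]); mu1 <- colMeans(x[5:8, ])
  c0 <- sweep(x[1:4, ], 2, mu0); c1 <- sweep(x[5:8, ], 2, mu1)
  S <- (t(c0) %*% c0 + t(c1) %*% c1) / 6
  Sr <- S + 0.01 * mean(diag(S)) * diag(2)
  w <- c(solve(Sr) %*% (mu1 - mu0))
  thr <- sum(w * (mu0 + mu1)) / 2
  expected <- as.numeric((test_x %*% w) > thr)

  pred <- fit_predict_lda(x, y, test_x)
  expect_equal(as.numeric(pred), expected)
  expect_equal(attr(pred, "weights"), w, tolerance = 1e-12)
  expect_equal(attr(pred, "threshold"), thr, tolerance = 1e-12)
})

test_that("decode_task agrees exactly with a fold-by-fold R reference", {
  ep <- planted_epochs(snr = 2, seed = 12)
  tc <- decode_task(ep, "cued", 1L)

  # independent R-level cross-validation using fit_predict_lda
  meta <- ep$metadata
  sel <- which(meta$analysis_group == 1L)
  y <- meta$cued_orientation[sel]
  folds <- meta$sequence_id[sel]
  ref <- sapply(seq_along(ep$times_ms), function(t) {
    correct <- 0; total <- 0
    for (s in unique(folds)) {
      tr <- folds != s
      pred <- fit_predict_lda(ep$data[sel[tr], , t], y[tr],
                              ep$data[sel[!tr], , t])
      correct <- correct + sum(pred == y[!tr]); total <- total + sum(!tr)
    }
    correct / total
  })
  expect_equal(tc$accuracy, ref, tolerance = 1e-12)
  expect_equal(tc$n_test[1], length(sel))

  # determinism
  expect_identical(tc, decode_task(ep, "cued", 1L))
})

test_that("decoding recovers planted signal inside its window and chance outside", {
  ep <- planted_epochs(snr = Inf, seed = 21)
  for (role in c("cued", "uncued")) {
    for (g in 1:2) {
      tc <- decode_task(ep, role, g)
      expect_true(all(tc$accuracy[8:14] == 1))
    }
  }
  # pure noise: mean accuracy near chance across timepoints
  ep0 <- planted_epochs(snr = 1e-6, seed = 22)
  tc0 <- decode_task(ep0, "cued", 1L)
  expect_lt(abs(mean(tc0$accuracy) - 0.5), 0.04)
  expect_true(all(tc0$accuracy >= 0 & tc0$accuracy <= 1))
})

test_that("analysis-group averaging is the pointwise mean with matched axes", {
  ep <- planted_epochs(snr = 2, seed = 31)
  t1 <- decode_task(ep, "cued", 1L)
  t2 <- decode_task(ep, "cued", 2L)
  avg <- average_analysis_groups(t1, t2)
  expect_equal(avg$accuracy, (t1$accuracy + t2$accuracy) / 2)
  expect_equal(avg$analysis_group[1], "avg")
  t2bad <- decode_task(ep, "uncued", 2L)
  expect_error(average_analysis_groups(t1, t2bad), "differ")
})

test_that("training folds keep the non-decoded orientation exactly balanced", {
  ep <- tiny_epochs()
  for (role in c("cued", "uncued")) {
    for (g in 1:2) {
      audit <- audit_fold_orthogonality(ep, role, g)
      expect_true(all(audit$balanced))
      expect_equal(sort(unique(audit$other_orientation)),
                   if ((role == "cued") == (g == 1)) c(67.5, 157.5) else c(22.5, 112.5))
    }
  }
})

test_that("fold partitions never mix train and test trials", {
  ep <- planted_epochs(n_seq = 3, snr = 2, seed = 41)
  tr <- attnmvpa:::task_trials(ep, "cued", 1L, "all")
  seqs <- unique(tr$seq_id)
  # test folds partition the task trials
  expect_equal(sort(unlist(lapply(seqs, function(s) which(tr$seq_id == s)))),
               seq_along(tr$idx))
  for (s in seqs) {
    expect_length(intersect(which(tr$seq_id == s), which(tr$seq_id != s)), 0)
  }
})

test_that("run_all_conditions returns the full bookkeeping of curves and contrasts", {
  ep <- tiny_epochs()
  out <- run_all_conditions(ep)
  counts <- dplyr::count(out, measure, role, isi_filter)
  expect_equal(sum(counts$n[counts$measure == "accuracy"]), 6 * 226)
  expect_equal(sum(counts$n[counts$measure == "attention_effect"]), 3 * 226)
  expect_equal(sum(counts$n[counts$measure == "expectation_effect"]), 226)
  # attention effect is the cued - uncued difference
  acc <- out[out$measure == "accuracy" & out$isi_filter == "all", ]
  att <- out[out$measure == "attention_effect" & out$isi_filter == "all", ]
  cued <- acc$value[acc$role == "cued"]
  uncued <- acc$value[acc$role == "uncued"]
  expect_equal(att$value, cued - uncued)
})

test_that("label permutation drives accuracy to chance", {
  ep <- planted_epochs(snr = Inf, seed = 51)
  # permute the class labels independently of the data
  withr::with_seed(52, {
    ep$metadata$cued_orientation <- sample(ep$metadata$cued_orientation)
    ep$metadata$analysis_group <- dplyr::if_else(
      ep$metadata$cued_orientation %in% c(22.5, 112.5), 1L, 2L)
  })
  tc <- decode_task(ep, "cued", 1L)
  expect_lt(abs(mean(tc$accuracy) - 0.5), 0.05)
})
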
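test_that("certainty is a stabilized softmax", {
  expect_equal(certainty(c(0, 0, 0, 0, 0)), rep(0.2, 5))
  expect_equal(certainty(c(5, 0, 0, 0, 0))[1], 0.9737555, tolerance = 1e-6)
  z <- rnorm(5)
  expect_equal(certainty(z), certainty(z + 7.3), tolerance = 1e-12)
  expect_equal(sum(certainty(c(1000, 999, 998, 0, 0))), 1)  # no overflow
  expect_error(certainty(numeric(0)), "empty")
  expect_error(certainty(c(1, Inf)), "finite")
})

test_that("confusion counts and accuracy match a brute-force tally", {
  ca <- confusion_and_accuracy(c(1, 0), c(0, 1))
  expect_equal(ca$accuracy, 0)
  expect_equal(ca$confusion["IC", "LR"], 1L, ignore_attr = TRUE)
  expect_equal(ca$confusion["LR", "IC"], 1L, ignore_attr = TRUE)
  perfect <- confusion_and_accuracy(0:4, 0:4)
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(diag(perfect$confusion)), rep(1L, 5))
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    true <- sample(0:4, n, replace = TRUE)
    pred <- sample(0:4, n, replace = TRUE)
    ca <- confusion_and_accuracy(pred, true)
    oc <- oracle_confusion(true, pred)
    expect_equal(unclass(ca$confusion), oc, ignore_attr = TRUE)
    expect_equal(ca$accuracy, mean(true == pred))
    expect_equal(sum(ca$confusion), n)
  }
  expect_error(confusion_and_accuracy(integer(0), integer(0)), "empty")
  expect_error(confusion_and_accuracy(0:3, 0:4), "differ")
})

test_that("misprediction offsets are distances to the predicted class", {
  expect_length(misprediction_offsets(0:4, 0:4)$offsets_ms, 0)
  # (A,A,A,B,B,B) vs (A,A,A,A,B,B): one 1-frame miss = 8.33 ms at 120 Hz
  off <- misprediction_offsets(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 0, 1, 1), 120)
  expect_equal(off$offsets_ms, 1000 / 120, tolerance = 1e-9)
  # a predicted class absent from the stream is reported, not dropped
  off2 <- misprediction_offsets(c(0, 0, 1), c(0, 2, 1))
  expect_length(off2$offsets_ms, 0)
  expect_equal(off2$unmatched$frame, 1)        # 0-based
  expect_equal(off2$unmatched$pred, 2)
})

test_that("boundary shifts produce constant offsets of the shift size", {
  # shift every transition of a synthetic label stream by k frames
  s <- simulate_subject(noiseless_synth(duration_s = 8, seed = 10), 1)
  true <- phase_codes(s$labels$labels)
  for (k in c(1, 3)) {
    pred <- c(true[-seq_len(k)], rep(4L, k))   # predictions run k frames early
    off <- misprediction_offsets(true, pred, 120)
    expect_gt(length(off$offsets_frames), 0)
    expect_true(all(off$offsets_frames <= k))
    expect_true(all(off$offsets_frames >= 1))
    expect_equal(max(off$offsets_frames), k)
    expect_equal(off$offsets_ms, off$offsets_frames * 1000 / 120)
  }
})

test_that("tolerance accuracy equals brute force and is monotone", {
  t6 <- c(0, 0, 0, 1, 1, 1); p6 <- c(0, 0, 0, 0, 1, 1)
  expect_equal(tolerance_accuracy(t6, p6, 0), 5 / 6)
  expect_equal(tolerance_accuracy(t6, p6, 1), 1)
  expect_equal(tolerance_accuracy(0:4, 0:4, 0), 1)
  set.seed(123)
  for (rep in 1:25) {
    n <- sample(10:300, 1)
    true <- sample(0:4, n, replace = TRUE)
    pred <- sample(0:4, n, replace = TRUE)
    prev <- -1
    for (tol in 0:4) {
      v <- tolerance_accuracy(true, pred, tol)
      expect_equal(v, oracle_tolerance_accuracy(true, pred, tol))
      expect_gte(v, prev)
      prev <- v
    }
    expect_equal(tolerance_accuracy(true, pred, 0), mean(true == pred))
  }
})

test_that("rejection bookkeeping conserves counts", {
  probs <- rbind(c(0.95, 0.02, 0.01, 0.01, 0.01),
                 c(0.85, 0.05, 0.05, 0.03, 0.02),
                 c(0.40, 0.30, 0.10, 0.10, 0.10),
                 c(0.70, 0.10, 0.10, 0.05, 0.05),
                 c(0.99, 0.005, 0.002, 0.002, 0.001))
  ps <- structure(list(probs = probs, pred = c(0L, 0L, 0L, 0L, 0L),
                       true = c(0L, 1L, 0L, 0L, 1L),
                       subject_ids = rep("s", 5), sequence_ids = rep("q", 5)),
                  class = "prediction_set")
  r <- reject_by_certainty(ps, 0.8)
  expect_equal(r$n_unknown, 2)                  # certainties 0.40 and 0.70
  expect_equal(r$n_correct_to_unknown, 2)
  expect_equal(r$n_wrong_to_unknown, 0)
  expect_equal(r$n_unknown, r$n_correct_to_unknown + r$n_wrong_to_unknown)
  expect_equal(r$accuracy_retained, 1 / 3)      # retained: rows 1, 2, 5
  expect_equal(r$frac_unknown, 2 / 5)
  expect_equal(r$frac_correct_to_unknown, 2 / 3)
  expect_equal(r$frac_wrong_to_unknown, 0)
  # threshold 0: nothing rejected; threshold 1: everything
  r0 <- reject_by_certainty(ps, 0)
  expect_equal(r0$n_unknown, 0)
  expect_equal(r0$accuracy_retained, mean(ps$pred == ps$true))
  r1 <- reject_by_certainty(ps, 1)
  expect_equal(r1$n_unknown, 5)
  expect_true(is.na(r1$accuracy_retained))
  expect_true(r1$all_rejected)
  set.seed(5)
  for (rep in 1:15) {
    n <- sample(5:80, 1)
    pr <- matrix(rexp(n * 5), n)
    pr <- pr / rowSums(pr)
    ps2 <- structure(list(probs = pr,
                          pred = max.col(pr, ties.method = "first") - 1L,
                          true = sample(0:4, n, replace = TRUE),
                          subject_ids = rep("s", n), sequence_ids = rep("q", n)),
                     class = "prediction_set")
    th <- runif(1)
    r <- reject_by_certainty(ps2, th)
    cert <- apply(pr, 1, max)
    expect_equal(r$n_unknown, sum(cert <= th))
    expect_equal(r$n_unknown, r$n_correct_to_unknown + r$n_wrong_to_unknown)
    expect_equal(r$n, n)
  }
})

test_that("loocv summary reproduces hand statistics and loocv runs at toy scale", {
  x <- c(0.9, 0.8, 0.7)
  sm <- loocv_summary(x)
  expect_equal(sm$mean, 0.8)
  expect_equal(sm$median, 0.8)
  expect_equal(sm$sd, sqrt(mean((x - 0.8)^2)))      # population convention
  expect_equal(sm$sd_sample, sd(x))
  # 2 subjects -> 2 models, 2 accuracies above chance
  cfg <- tiny_synth(n_subjects = 2, duration_s = 8, seed = 19)
  seqs <- unlist(lapply(simulate_dataset(cfg), subject_sequences,
                        sequence_len = 40L), recursive = FALSE)
  res <- loocv(seqs, tiny_model_cfg(seed = 3),
               train_config(epochs = 3, batch_sequences = 3, seed = 3),
               input_shape = c(50, 70), train_fraction = 0.6,
               val_fraction_of_train = 0.2)
  expect_equal(nrow(res$per_subject), 2)
  chance <- max(table(unlist(lapply(seqs, `[[`, "frame_labels")))) /
    length(unlist(lapply(seqs, `[[`, "frame_labels")))
  expect_true(all(res$per_subject$accuracy > 0.3))
  expect_equal(res$summary$n, 2)
})

test_that("evaluate_predictions ties the pieces together consistently", {
  s <- simulate_subject(tiny_synth(n_subjects = 1, duration_s = 8, seed = 23), 1)
  seqs <- subject_sequences(s, sequence_len = 40L)
  fit <- train_model(build_model(tiny_model_cfg(seed = 5), c(50, 70)),
                     seqs[1:3], seqs[4], train_config(epochs = 4, seed = 5))
  ps <- predict_phases(fit$net, seqs[5:6])
  rep <- evaluate_predictions(ps, rate_hz = 120, tolerances = 0:3)
  expect_equal(sum(rep$confusion), length(ps$pred))
  expect_equal(rep$tolerance_accuracy[["tol_0"]], rep$accuracy)
  expect_true(all(diff(rep$tolerance_accuracy) >= 0))
  # tolerance-2 accuracy = plain + mass of errors within 2 frames (identity
  # linking the offset analysis to the tolerance curve)
  close_errors <- sum(rep$offsets_ms <= 2 * 1000 / 120 + 1e-9)
  expect_equal(rep$tolerance_accuracy[["tol_2"]],
               rep$accuracy + close_errors / rep$n, tolerance = 1e-9)
})
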
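test_that("channel reordering is the stated bijection", {
  m <- matrix(seq_len(20 * 70), 20, 70)
  colnames(m) <- gaitphase:::imu_column_names()
  by_meas <- arrange_channels(m, "by_measurement", n_sensors = 10, n_channels = 7)
  # gz of sensor 0: by_device column 5 (0-based) -> R column 6;
  # by_measurement column 5*10 + 0 = 50 -> R column 51
  expect_equal(unname(by_meas[, 51]), unname(m[, 6]))
  expect_equal(colnames(by_meas)[51], "l_foot_gz")
  # bijectivity: the inverse permutation restores the original
  inv <- match(colnames(m), colnames(by_meas))
  expect_identical(by_meas[, inv], m)
  expect_true(setequal(colnames(by_meas), colnames(m)))
  # N = 1: both orders identical
  m1 <- matrix(rnorm(40), 10, 4)
  expect_equal(arrange_channels(m1, "by_measurement", n_sensors = 1,
                                n_channels = 4), m1)
  expect_error(arrange_channels(m, "sideways"), "arg")
})

test_that("sequence chunking follows the windows-per-sequence arithmetic", {
  T <- 2 * (480 + 49)
  m <- matrix(rnorm(T * 3), T, 3)
  lab <- rep(0:4, length.out = T)
  sq <- make_sequences(m, lab, sequence_len = 480, window_len = 50)
  expect_length(sq, 2)
  expect_equal(nrow(sq[[1]]$frames), 529)
  ws <- make_windows(sq[[1]], window_spec(window_len = 50, shift = 1))
  expect_equal(length(ws$labels), 480)          # 529 frames -> 480 windows
  # chunks are disjoint, ordered and verbatim
  expect_identical(sq[[2]]$frames, m[530:1058, ])
  # frames mode retained behind a flag: 480 raw frames -> 431 windows
  sqf <- make_sequences(m, lab, sequence_len = 480, window_len = 50,
                        mode = "frames")
  expect_equal(nrow(sqf[[1]]$frames), 480)
  expect_equal(length(make_windows(sqf[[1]], window_spec())$labels), 431)
  # too-short input -> empty list
  expect_length(make_sequences(m[1:100, ], lab[1:100], sequence_len = 480), 0)
})

test_that("windows are verbatim slices with the last-frame label", {
  m <- matrix(rnorm(200 * 4), 200, 4)
  lab <- rep(0:4, each = 40)
  ws <- make_windows(m, window_spec(window_len = 50, shift = 1),
                     frame_labels = lab)
  expect_equal(dim(ws$windows), c(50, 4, 151))
  expect_identical(ws$windows[, , 1], m[1:50, ])
  expect_identical(ws$windows[, , 137], m[137:186, ])
  expect_equal(ws$labels[1], lab[50])
  expect_equal(ws$labels[151], lab[200])
  # center labeling and wider shifts
  ws2 <- make_windows(m, window_spec(window_len = 50, shift = 10,
                                     label_frame = "center"),
                      frame_labels = lab)
  expect_equal(length(ws2$labels), (200 - 50) %/% 10 + 1)
  expect_equal(ws2$labels[1], lab[25])
  # the 50 x 70 input window of the full sensor set
  s <- simulate_subject(tiny_synth(duration_s = 5), 1)
  wsf <- make_windows(s$imu$samples[1:60, ], window_spec(),
                      frame_labels = phase_codes(s$labels$labels[1:60]))
  expect_equal(dim(wsf$windows)[1:2], c(50, 70))
})

test_that("split isolates the unseen subject and partitions the rest", {
  cfg <- tiny_synth(n_subjects = 4, duration_s = 15, seed = 31)
  seqs <- unlist(lapply(simulate_dataset(cfg), subject_sequences),
                 recursive = FALSE)
  plan <- split_plan("subject_02", seed = 5)
  parts <- split_and_shuffle(seqs, plan)
  ids <- function(part) vapply(part, `[[`, character(1), "sequence_id")
  all_ids <- ids(seqs)
  got <- c(ids(parts$train), ids(parts$val), ids(parts$test), ids(parts$unseen))
  expect_true(setequal(got, all_ids))
  expect_equal(anyDuplicated(got), 0L)
  subj <- function(part) unique(vapply(part, `[[`, character(1), "subject_id"))
  expect_equal(subj(parts$unseen), "subject_02")
  expect_false("subject_02" %in% c(subj(parts$train), subj(parts$val),
                                   subj(parts$test)))
  # deterministic under the seed
  parts2 <- split_and_shuffle(seqs, plan)
  expect_identical(ids(parts$train), ids(parts2$train))
  # fractions: 3 subjects remain -> train+val = floor(0.66 * n)
  n_rest <- sum(all_ids != "" ) - length(parts$unseen)
  expect_equal(length(parts$train) + length(parts$val),
               floor(0.66 * n_rest))
  expect_error(split_and_shuffle(seqs, split_plan("nobody")), "not present")
})

test_that("no window of train/val shares frames with the unseen subject", {
  # subject-level leakage check: sequences carry their subject id and the
  # split keeps them whole, so it suffices that no train/val sequence
  # belongs to the unseen subject and sequences never straddle subjects
  cfg <- tiny_synth(n_subjects = 3, duration_s = 12, seed = 8)
  ds <- simulate_dataset(cfg)
  seqs <- unlist(lapply(ds, subject_sequences), recursive = FALSE)
  parts <- split_and_shuffle(seqs, split_plan("subject_01", seed = 1))
  for (part in c("train", "val")) {
    for (s in parts[[part]]) expect_false(s$subject_id == "subject_01")
  }
  # and a sequence's frames are a verbatim block of its own subject only
  s1 <- parts$unseen[[1]]
  src <- ds[[1]]$imu$samples
  expect_true(any(apply(src, 1, function(r) all(r == s1$frames[1, ]))))
})
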
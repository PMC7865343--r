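# Shared fixtures: small, fast configurations used across test files.

tiny_synth <- function(..., n_subjects = 2L, duration_s = 10, seed = 3L) {
  synthetic_config(n_subjects = n_subjects, duration_s = duration_s,
                   seed = seed, ...)
}

noiseless_synth <- function(..., seed = 3L) {
  tiny_synth(noise_sd_imu = 0, noise_sd_force = 0, seed = seed, ...)
}

# A desk-scale model configuration (topology unchanged, widths reduced).
tiny_model_cfg <- function(..., seed = 7L) {
  model_config(conv_filters = c(2L, 2L, 3L, 3L, 3L, 3L), lstm_units = 8L,
               dense_units = c(12L, 8L), dropout = 0, seed = seed, ...)
}

# Sequences for one simulated subject, ready for training/prediction.
subject_sequences <- function(subject, sequence_len = 60L, window_len = 50L) {
  make_sequences(subject$imu$samples, subject$labels$labels,
                 sequence_len = sequence_len, window_len = window_len,
                 subject_id = subject$imu$subject_id)
}

# Brute-force oracles (deliberately naive; used to cross-check the
# vectorized implementations).
oracle_tolerance_accuracy <- function(true, pred, tol) {
  n <- length(true)
  ok <- logical(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - tol); hi <- min(n, t + tol)
    ok[t] <- any(true[lo:hi] == pred[t])
  }
  mean(ok)
}

oracle_offsets_frames <- function(true, pred) {
  out <- numeric(0)
  for (t in seq_along(true)) {
    if (pred[t] == true[t]) next
    where <- which(true == pred[t])
    if (length(where) == 0L) next
    out <- c(out, min(abs(where - t)))
  }
  out
}

oracle_confusion <- function(true, pred) {
  cm <- matrix(0L, 5, 5, dimnames = list(gait_phases(), gait_phases()))
  for (t in seq_along(true)) {
    cm[true[t] + 1L, pred[t] + 1L] <- cm[true[t] + 1L, pred[t] + 1L] + 1L
  }
  cm
}
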
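# Input representation for the classifier: channel ordering, sequence
# chunking and shuffling, sliding windows, and subject-level splits.

#' Sliding-window specification
#'
#' @param window_len frames per window (default 50).
#' @param shift window shift in frames (default 1, overlapping windows).
#' @param channel_order `"by_device"` (all channels of an IMU adjacent) or
#'   `"by_measurement"` (channels grouped by measurement: all ax, all ay, ...).
#' @param label_frame which frame's phase the window carries: `"last"`
#'   (causal, the current phase — default) or `"center"`.
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_len = 50L, shift = 1L,
                        channel_order = c("by_device", "by_measurement"),
                        label_frame = c("last", "center")) {
  channel_order <- match.arg(channel_order)
  label_frame <- match.arg(label_frame)
  if (window_len < 1L) stop_config("window_len", "must be >= 1")
  if (shift < 1L) stop_config("shift", "must be >= 1")
  structure(list(window_len = as.integer(window_len), shift = as.integer(shift),
                 channel_order = channel_order, label_frame = label_frame),
            class = "window_spec")
}

#' Reorder IMU channels for the 2D input window
#'
#' With N sensor units and C channels per unit, `by_device` places channel c
#' of sensor n at column `n*C + c` (0-based) and `by_measurement` at
#' `c*N + n`. The reordering is a bijection; values are untouched. The input
#' recording is assumed to be in `by_device` order (the on-disk layout).
#'
#' @param recording an `imu_recording`, or a plain matrix (then `n_sensors`
#'   and `n_channels` must be given).
#' @param order target order token.
#' @param n_sensors,n_channels layout when `recording` is a bare matrix.
#' @return Matrix `[T x N*C]` with permuted, renamed columns.
#' @export
arrange_channels <- function(recording,
                             order = c("by_device", "by_measurement"),
                             n_sensors = NULL, n_channels = NULL) {
  order <- match.arg(order)
  if (inherits(recording, "imu_recording")) {
    m <- recording$samples
    n_sensors <- length(recording$sensor_locations)
    n_channels <- length(recording$channels)
  } else {
    m <- recording
    if (is.null(n_sensors) || is.null(n_channels))
      stop("n_sensors and n_channels are required for a bare matrix")
  }
  if (ncol(m) != n_sensors * n_channels)
    stop("recording has ", ncol(m), " columns; expected N*C = ",
         n_sensors * n_channels)
  if (order == "by_device") return(m)
  # new column (c, n) at c*N + n  <-  old column n*C + c   (0-based)
  n0 <- rep(seq_len(n_sensors) - 1L, times = n_channels)
  c0 <- rep(seq_len(n_channels) - 1L, each = n_sensors)
  m[, n0 * n_channels + c0 + 1L, drop = FALSE]
}

#' Cut a recording into shuffleable sequences
#'
#' Consecutive, disjoint chunks in time order; the trailing remainder is
#' dropped. By default (`mode = "windows"`) a sequence is defined by the
#' number of windows it yields: each chunk spans
#' `seq_len + window_len - 1` raw frames so that a shift-1 sliding window
#' produces exactly `seq_len` windows. `mode = "frames"` instead makes each
#' chunk exactly `seq_len` raw frames long (yielding
#' `seq_len - window_len + 1` windows).
#'
#' @param samples numeric matrix `[T x D]` of (already channel-ordered)
#'   sensor values.
#' @param labels per-frame phase labels (`phase_labels`, factor, or integer
#'   codes) of length `T`.
#' @param sequence_len sequence length (windows, or frames under
#'   `mode = "frames"`); default 480 (4 s of windows at 120 Hz).
#' @param window_len frames per window, used to size the chunks.
#' @param mode `"windows"` (default) or `"frames"`.
#' @param subject_id identifier stamped on each sequence.
#' @return List of sequences: `list(frames, frame_labels, subject_id,
#'   sequence_id)`.
#' @export
make_sequences <- function(samples, labels, sequence_len = 480L, window_len = 50L,
                           mode = c("windows", "frames"),
                           subject_id = "subject") {
  mode <- match.arg(mode)
  if (inherits(labels, "phase_labels")) labels <- labels$labels
  labels <- phase_codes(labels)
  if (length(labels) != nrow(samples))
    stop("labels length (", length(labels), ") must match frame count (",
         nrow(samples), ")")
  chunk <- if (mode == "windows") as.integer(sequence_len) + window_len - 1L else as.integer(sequence_len)
  n_chunks <- nrow(samples) %/% chunk
  if (n_chunks < 1L) return(list())
  lapply(seq_len(n_chunks), function(k) {
    idx <- ((k - 1L) * chunk + 1L):(k * chunk)
    list(frames = samples[idx, , drop = FALSE],
         frame_labels = labels[idx],
         subject_id = subject_id,
         sequence_id = paste0(subject_id, "_seq", k))
  })
}

#' Materialize the sliding windows of one sequence
#'
#' Window w (0-based) covers frames `[w*shift, w*shift + window_len)` of the
#' sequence; every window is a verbatim slice of the source matrix (no
#' filtering). Its label is the phase at the window's last frame (or center,
#' per the spec).
#'
#' @param sequence a sequence from [make_sequences()], or a plain frame
#'   matrix (then `frame_labels` must be supplied).
#' @param spec a [window_spec()].
#' @param frame_labels per-frame integer codes when `sequence` is a matrix.
#' @return A `window_set`: array `windows [window_len x D x W]`, integer
#'   `labels [W]` (codes 0..4), `sequence_ids`, `subject_ids`.
#' @export
make_windows <- function(sequence, spec = window_spec(), frame_labels = NULL) {
  if (is.list(sequence) && !is.null(sequence$frames)) {
    frames <- sequence$frames
    frame_labels <- sequence$frame_labels
    sid <- sequence$subject_id %||% "subject"
    qid <- sequence$sequence_id %||% "seq"
  } else {
    frames <- sequence
    if (is.null(frame_labels)) stop("frame_labels required for a bare matrix")
    sid <- "subject"; qid <- "seq"
  }
  L <- nrow(frames); wl <- spec$window_len; sh <- spec$shift
  if (L < wl) stop("sequence length (", L, ") shorter than window_len (", wl, ")")
  W <- (L - wl) %/% sh + 1L
  starts <- (seq_len(W) - 1L) * sh               # 0-based window starts
  lab_off <- if (spec$label_frame == "last") wl - 1L else (wl - 1L) %/% 2L
  windows <- array(0, dim = c(wl, ncol(frames), W))
  for (w in seq_len(W)) windows[, , w] <- frames[(starts[w] + 1L):(starts[w] + wl), ]
  structure(list(windows = windows,
                 labels = as.integer(frame_labels[starts + lab_off + 1L]),
                 label_frames = starts + lab_off,
                 sequence_ids = rep(qid, W), subject_ids = rep(sid, W),
                 spec = spec),
            class = "window_set")
}

#' Leave-one-subject-out split plan
#'
#' @param unseen_subject id of the subject withheld entirely.
#' @param train_fraction fraction of the remaining sequences used for
#'   training (default 0.66; the rest is the test set).
#' @param val_fraction_of_train fraction of the training sequences held out
#'   for validation during training (default 0.10).
#' @param seed shuffle seed.
#' @return A `split_plan` list.
#' @export
split_plan <- function(unseen_subject, train_fraction = 0.66,
                       val_fraction_of_train = 0.10, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction", "must lie in (0, 1)")
  if (val_fraction_of_train <= 0 || val_fraction_of_train >= 1)
    stop_config("val_fraction_of_train", "must lie in (0, 1)")
  structure(list(unseen_subject = unseen_subject,
                 train_fraction = train_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Shuffle sequences and split them into train/val/test/unseen
#'
#' The unseen subject's sequences are isolated untouched; the remaining
#' subjects' sequences are shuffled as whole units (frames within a sequence
#' are never permuted) and partitioned into train/test, with a slice of the
#' training sequences set aside for validation.
#'
#' @param sequences flat list of sequences from [make_sequences()] (all
#'   subjects pooled).
#' @param plan a [split_plan()].
#' @return `list(train, val, test, unseen)` of sequence lists.
#' @export
split_and_shuffle <- function(sequences, plan) {
  sids <- vapply(sequences, function(s) s$subject_id, character(1))
  if (!plan$unseen_subject %in% sids)
    stop("unseen_subject '", plan$unseen_subject, "' not present in the data")
  if (length(unique(sids)) < 2L) stop("need at least 2 subjects to split")
  unseen <- sequences[sids == plan$unseen_subject]
  rest <- sequences[sids != plan$unseen_subject]
  perm <- with_seed(plan$seed, sample.int(length(rest)))
  rest <- rest[perm]
  n_train_all <- floor(plan$train_fraction * length(rest))
  if (n_train_all < 2L) stop("too few sequences to form a train/val split")
  trainval <- rest[seq_len(n_train_all)]
  test <- rest[setdiff(seq_along(rest), seq_len(n_train_all))]
  n_val <- max(1L, floor(plan$val_fraction_of_train * n_train_all))
  val <- trainval[seq_len(n_val)]
  train <- trainval[setdiff(seq_along(trainval), seq_len(n_val))]
  list(train = train, val = val, test = test, unseen = unseen)
}
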
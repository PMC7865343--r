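# Evaluation suite: confusion matrices and plain accuracy, transition-offset
# analysis, tolerance accuracy, softmax-certainty rejection, LOOCV and
# activation heatmaps.

#' Softmax certainty of a logit vector
#'
#' `certainty(z)_i = exp(z_i) / sum_j exp(z_j)`, computed with max-logit
#' stabilization. The maximum entry of the result is the rejection score
#' attached to a prediction; it is a confidence score, not a calibrated
#' probability (no temperature scaling is applied).
#'
#' @param z numeric vector of logits.
#' @return Probability vector summing to 1.
#' @export
certainty <- function(z) {
  if (length(z) == 0L) stop("empty logit vector")
  if (any(!is.finite(z))) stop("logits must be finite")
  e <- exp(z - max(z))
  e / sum(e)
}

#' Confusion matrix and plain accuracy
#'
#' @param pred a `prediction_set`, or an integer/character vector of
#'   predicted phases (then `true` must be given).
#' @param true true phases when `pred` is a bare vector.
#' @return List with `confusion` (5x5 count matrix, rows = true,
#'   cols = predicted) and `accuracy` (diagonal sum over total).
#' @export
confusion_and_accuracy <- function(pred, true = NULL) {
  if (inherits(pred, "prediction_set")) {
    true <- pred$true; pred <- pred$pred
  }
  if (length(pred) == 0L) stop("empty prediction set")
  if (length(pred) != length(true))
    stop("pred and true lengths differ (", length(pred), " vs ", length(true), ")")
  cm <- table(true = phase_factor(true), predicted = phase_factor(pred))
  cm <- unclass(cm)
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
}

#' Time offsets of mispredictions from the nearest occurrence of the
#' predicted class
#'
#' For every frame t with `pred[t] != true[t]`, the offset is the distance
#' (in frames, converted to ms) to the nearest frame t' where
#' `true[t'] == pred[t]` — i.e. how far the prediction missed the actual
#' occurrence of what it claimed. Predictions of a class that never occurs
#' in the stream cannot be assigned an offset and are reported separately.
#'
#' @param true,pred per-frame aligned phase streams (codes or labels).
#' @param rate_hz sampling rate for the ms conversion.
#' @return List: `offsets_ms` (one entry per matched misprediction),
#'   `offsets_frames`, and `unmatched` (data.frame of frame/predicted class
#'   for mispredictions whose class is absent from the true stream).
#' @export
misprediction_offsets <- function(true, pred, rate_hz = 120) {
  true <- phase_codes(true); pred <- phase_codes(pred)
  if (length(true) != length(pred)) stop("aligned streams required")
  wrong <- which(pred != true)
  if (length(wrong) == 0L)
    return(list(offsets_ms = numeric(0), offsets_frames = numeric(0),
                unmatched = data.frame(frame = integer(0), pred = integer(0))))
  occ <- lapply(0:4, function(k) which(true == k))   # 1-based frames per class
  d <- vapply(wrong, function(t) {
    nearest_frame_distance(t, occ[[pred[t] + 1L]])
  }, numeric(1))
  matched <- is.finite(d)
  list(offsets_ms = d[matched] * ms_per_frame(rate_hz),
       offsets_frames = d[matched],
       unmatched = data.frame(frame = wrong[!matched] - 1L,
                              pred = pred[wrong[!matched]]))
}

#' Accuracy under a transition tolerance
#'
#' A prediction at frame t counts as correct iff the true stream holds the
#' predicted class anywhere within `tol_frames` frames of t (symmetric, so
#' a prediction missing a class boundary by up to the tolerance is
#' accepted). At `tol_frames = 0` this is plain accuracy.
#'
#' @inheritParams misprediction_offsets
#' @param tol_frames non-negative tolerance, in frames (8 ms per frame at
#'   120 Hz).
#' @return Fraction of accepted predictions.
#' @export
tolerance_accuracy <- function(true, pred, tol_frames) {
  if (tol_frames < 0) stop("tol_frames must be >= 0")
  true <- phase_codes(true); pred <- phase_codes(pred)
  if (length(true) != length(pred)) stop("aligned streams required")
  if (length(true) == 0L) stop("empty streams")
  occ <- lapply(0:4, function(k) which(true == k))
  ok <- vapply(seq_along(pred), function(t) {
    nearest_frame_distance(t, occ[[pred[t] + 1L]]) <= tol_frames
  }, logical(1))
  mean(ok)
}

#' Summarize an evaluation: confusion, accuracies, offsets
#'
#' Applies [confusion_and_accuracy()], [tolerance_accuracy()] at the
#' requested tolerances and [misprediction_offsets()] per sequence (streams
#' never straddle a sequence boundary) and pools the results.
#'
#' @param pred_set a `prediction_set`.
#' @param rate_hz sampling rate.
#' @param tolerances integer vector of tolerances (frames).
#' @return An `eval_report` list: `confusion`, `accuracy`,
#'   `tolerance_accuracy` (named by tolerance), `offsets_ms`,
#'   `certainty_correct`/`certainty_wrong` (boxplot-style five-number
#'   summaries plus outlier counts).
#' @export
evaluate_predictions <- function(pred_set, rate_hz = 120,
                                 tolerances = 0:3) {
  stopifnot(inherits(pred_set, "prediction_set"))
  ca <- confusion_and_accuracy(pred_set)
  ids <- unique(pred_set$sequence_ids)
  tol_acc <- stats::setNames(numeric(length(tolerances)),
                             paste0("tol_", tolerances))
  offsets <- numeric(0)
  n_tot <- length(pred_set$pred)
  for (k in seq_along(tolerances)) {
    acc_num <- 0
    for (id in ids) {
      i <- pred_set$sequence_ids == id
      acc_num <- acc_num +
        tolerance_accuracy(pred_set$true[i], pred_set$pred[i],
                           tolerances[k]) * sum(i)
    }
    tol_acc[k] <- acc_num / n_tot
  }
  for (id in ids) {
    i <- pred_set$sequence_ids == id
    offsets <- c(offsets,
                 misprediction_offsets(pred_set$true[i], pred_set$pred[i],
                                       rate_hz)$offsets_ms)
  }
  cert <- apply(pred_set$probs, 1L, max)
  correct <- pred_set$pred == pred_set$true
  box_stats <- function(x) {
    if (length(x) == 0L)
      return(list(q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                  whisker_lo = NA_real_, whisker_hi = NA_real_,
                  n_outliers = 0L, mean = NA_real_))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    list(q1 = q[1], median = q[2], q3 = q[3],
         whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr,
         n_outliers = sum(x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr),
         mean = mean(x))
  }
  structure(list(confusion = ca$confusion, accuracy = ca$accuracy,
                 tolerance_accuracy = tol_acc, offsets_ms = offsets,
                 certainty_correct = box_stats(cert[correct]),
                 certainty_wrong = box_stats(cert[!correct]),
                 rate_hz = rate_hz, n = n_tot),
            class = "eval_report")
}

#' Rejection bookkeeping at a certainty threshold
#'
#' Predictions whose maximum softmax certainty is `<= threshold` are
#' reassigned to an "unknown" class; accuracy is recomputed on the retained
#' set. All counts and fractions of the rejection table are returned.
#'
#' @param pred_set a `prediction_set`.
#' @param threshold certainty cutoff in `[0, 1]`.
#' @return A `rejection_report`: `threshold`, `accuracy_retained` (`NA` with
#'   `all_rejected = TRUE` when nothing is retained), `n_unknown`,
#'   `n_correct_to_unknown`, `n_wrong_to_unknown`, and the fractions
#'   `frac_unknown`, `frac_correct_to_unknown`, `frac_wrong_to_unknown`
#'   (of all / of correct / of wrong samples).
#' @export
reject_by_certainty <- function(pred_set, threshold) {
  stopifnot(inherits(pred_set, "prediction_set"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  cert <- apply(pred_set$probs, 1L, max)
  correct <- pred_set$pred == pred_set$true
  unknown <- cert <= threshold
  n <- length(cert)
  n_unknown <- sum(unknown)
  retained <- !unknown
  structure(list(
    threshold = threshold,
    accuracy_retained = if (any(retained)) mean(correct[retained]) else NA_real_,
    all_rejected = !any(retained),
    n = n, n_unknown = n_unknown,
    n_correct_to_unknown = sum(unknown & correct),
    n_wrong_to_unknown = sum(unknown & !correct),
    frac_unknown = n_unknown / n,
    frac_correct_to_unknown = if (any(correct)) sum(unknown & correct) / sum(correct) else NA_real_,
    frac_wrong_to_unknown = if (any(!correct)) sum(unknown & !correct) / sum(!correct) else NA_real_),
    class = "rejection_report")
}

#' Summary statistics of leave-one-subject-out accuracies
#'
#' The standard deviation reported as `sd` uses the population (1/n)
#' convention of numpy's default, which is how such tables are usually
#' summarized; the sample (1/(n-1)) value is also returned.
#'
#' @param accuracies numeric vector of per-subject accuracies.
#' @return List with `mean`, `sd` (population), `sd_sample`, `median`, `n`.
#' @export
loocv_summary <- function(accuracies) {
  n <- length(accuracies)
  if (n == 0L) stop("no accuracies supplied")
  list(mean = mean(accuracies),
       sd = stats::sd(accuracies) * sqrt((n - 1) / n),
       sd_sample = stats::sd(accuracies),
       median = stats::median(accuracies), n = n)
}

#' Leave-one-subject-out cross-validation
#'
#' Trains one model per held-out subject (that subject's sequences appear in
#' no training or validation set) and evaluates it on the held-out data.
#'
#' @param sequences flat list of sequences from [make_sequences()], pooling
#'   all subjects.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param input_shape window shape `c(window_len, n_columns)`.
#' @param train_fraction,val_fraction_of_train split fractions within the
#'   remaining subjects.
#' @param verbose print progress.
#' @return List: `per_subject` data.frame (subject, accuracy) and `summary`
#'   from [loocv_summary()].
#' @export
loocv <- function(sequences, model_cfg, train_cfg,
                  input_shape = c(50L, 70L), train_fraction = 0.66,
                  val_fraction_of_train = 0.10, verbose = FALSE) {
  subjects <- unique(vapply(sequences, function(s) s$subject_id, character(1)))
  if (length(subjects) < 2L) stop("LOOCV needs at least 2 subjects")
  acc <- numeric(0)
  for (sub in subjects) {
    parts <- split_and_shuffle(sequences,
                               split_plan(sub, train_fraction,
                                          val_fraction_of_train,
                                          seed = train_cfg$seed))
    net <- build_model(model_cfg, input_shape)
    fit <- tryCatch(
      train_model(net, c(parts$train, parts$test), parts$val, train_cfg),
      error = function(e) stop("LOOCV training failed for held-out subject '",
                               sub, "': ", conditionMessage(e)))
    ps <- predict_phases(fit$net, parts$unseen)
    a <- confusion_and_accuracy(ps)$accuracy
    if (verbose) message(sub, ": unseen accuracy ", round(a, 4))
    acc <- c(acc, a)
  }
  list(per_subject = data.frame(subject = subjects, accuracy = acc),
       summary = loocv_summary(acc))
}

#' Mean absolute activation map of the last convolutional layer
#'
#' Forwards the given sequences through the conv stack, averages the
#' absolute activations of the last conv layer over all windows and
#' filters, min–max normalizes to `[0, 1]` (a constant map maps to all
#' zeros) and bilinearly upsamples the grid to `target_dim`. Columns of the
#' upsampled map correspond to input channels, so high-mass column bands
#' identify informative sensors under the active channel order.
#'
#' @param net a trained `convlstm_net`.
#' @param seqs list of sequences.
#' @param target_dim output resolution, default the input window shape.
#' @param channel_labels optional input-column names for the annotation.
#' @param shift window shift.
#' @return An `activation_heatmap`: `map` (target_dim matrix in `[0, 1]`),
#'   `grid` (raw last-conv spatial grid), `channel_labels`.
#' @export
activation_heatmap <- function(net, seqs, target_dim = NULL,
                               channel_labels = NULL, shift = 1L) {
  if (!isTRUE(net$trained)) stop("activation heatmap requires a trained network")
  if (length(seqs) == 0L) stop("no sequences supplied")
  if (is.null(target_dim)) target_dim <- net$input_shape
  p <- net$params
  pool_after <- net$geom$pool_after
  acc <- NULL; n_windows <- 0L
  for (s in seqs) {
    b <- sequences_to_batch(list(s), net$input_shape[1], shift)
    a <- b$x
    for (l in 1:6) {
      a <- relu(.conv2d_forward(a, p[[paste0("conv", l, "_w")]],
                                p[[paste0("conv", l, "_b")]]))
      if (l < 6L && l %in% pool_after) {
        kp <- net$cfg$pool_kernels[[match(l, pool_after)]]
        a <- .maxpool_forward(a, kp[1], kp[2])$y
      }
    }
    # a: last conv layer output (pre final pool) [h, w, F, B]
    m <- apply(abs(a), c(1L, 2L), sum)
    acc <- if (is.null(acc)) m else acc + m
    n_windows <- n_windows + dim(a)[4]
  }
  grid <- acc / (n_windows * net$cfg$conv_filters[6])
  rng <- range(grid)
  norm <- if (rng[2] > rng[1]) (grid - rng[1]) / (rng[2] - rng[1])
          else grid * 0
  map <- bilinear_resize(norm, target_dim)
  structure(list(map = map, grid = norm,
                 channel_labels = channel_labels %||% imu_column_names()),
            class = "activation_heatmap")
}
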
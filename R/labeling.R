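# Label generation: align the pressure trace with the IMU stream, detect the
# step events from the force curve's local extrema, and expand the events
# into per-frame five-phase labels.
#
# Frame coordinates are 0-based throughout this module and phase intervals
# are half-open, matching the CSV interfaces (`frame` column starts at 0).

#' Align an IMU recording and a pressure trace on their trigger frames
#'
#' Both streams are cropped so their trigger frames coincide at index 0 and
#' truncated to the shorter length. If the sampling rates differ and
#' `interpolate = TRUE`, the pressure trace is linearly resampled to the IMU
#' rate first.
#'
#' @param imu an `imu_recording`.
#' @param pressure a `pressure_trace`.
#' @param interpolate allow linear-interpolation resampling on rate mismatch.
#' @param max_sync_error_ms declared synchronization uncertainty bound,
#'   echoed into the returned alignment info (trigger uncertainty of about
#'   one frame plus one frame of sampling jitter at 120 Hz gives 16 ms).
#' @return `list(imu, pressure, alignment)`; `alignment` holds the original
#'   trigger frames and `max_sync_error_ms`.
#' @export
align_streams <- function(imu, pressure, interpolate = FALSE,
                          max_sync_error_ms = 16) {
  if (is.null(imu$trigger_frame) || is.na(imu$trigger_frame))
    stop("alignment error: IMU stream carries no trigger frame")
  if (is.null(pressure$trigger_frame) || is.na(pressure$trigger_frame))
    stop("alignment error: pressure stream carries no trigger frame")
  if (max_sync_error_ms < 0) stop("max_sync_error_ms must be >= 0")

  info <- list(imu_trigger_frame = imu$trigger_frame,
               pressure_trigger_frame = pressure$trigger_frame,
               max_sync_error_ms = max_sync_error_ms)

  force <- pressure$force
  p_trig <- pressure$trigger_frame
  if (pressure$rate_hz != imu$rate_hz) {
    if (!interpolate)
      stop("alignment error: sampling rates differ (",
           pressure$rate_hz, " vs ", imu$rate_hz,
           " Hz) and interpolation is disabled")
    # Crop at the trigger, then resample onto the IMU-rate grid.
    force <- force[(p_trig + 1L):length(force)]
    t_src <- (seq_along(force) - 1L) / pressure$rate_hz
    n_out <- floor(t_src[length(t_src)] * imu$rate_hz) + 1L
    t_out <- (seq_len(n_out) - 1L) / imu$rate_hz
    force <- stats::approx(t_src, force, xout = t_out)$y
    p_trig <- 0L
  }

  force <- force[(p_trig + 1L):length(force)]
  samples <- imu$samples[(imu$trigger_frame + 1L):nrow(imu$samples), ,
                         drop = FALSE]
  n <- min(length(force), nrow(samples))
  imu$samples <- samples[seq_len(n), , drop = FALSE]
  imu$trigger_frame <- 0L
  pressure$force <- force[seq_len(n)]
  pressure$rate_hz <- imu$rate_hz
  pressure$trigger_frame <- 0L
  list(imu = imu, pressure = pressure, alignment = info)
}

#' Detect per-step gait events from a total-force trace
#'
#' Stance intervals are the contiguous runs where the raw force exceeds
#' `contact_threshold`. Within each stance the two force maxima and the
#' interior minimum are located on a moving-average-smoothed copy (measured
#' force curves are not perfectly smooth) and then refined by one frame
#' against the raw trace, so noiseless curves are recovered exactly. Stances
#' shorter than `2 * smooth_window` frames are discarded as artifacts; a
#' stance without two separable maxima is flagged unlabelable (with a
#' warning) rather than silently mislabeled.
#'
#' @param pressure a `pressure_trace`, or a bare numeric force vector.
#' @param contact_threshold force level separating contact from swing;
#'   default 2% of the trace maximum.
#' @param smooth_window moving-average width (frames) for extremum search.
#' @return List of steps; each holds 0-based `contact`, `peak1`, `valley`,
#'   `toe_off` frames and an `unlabelable` flag (in which case the extremum
#'   fields are `NA`).
#' @export
detect_step_events <- function(pressure, contact_threshold = NULL,
                               smooth_window = 5L) {
  force <- if (inherits(pressure, "pressure_trace")) pressure$force else pressure
  if (any(force < 0)) stop("force trace must be non-negative")
  if (length(force) == 0L || all(force == 0)) return(list())
  if (is.null(contact_threshold)) contact_threshold <- 0.02 * max(force)
  smooth_window <- max(1L, as.integer(smooth_window))

  above <- force > contact_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L * smooth_window
  smoothed <- moving_average(force, smooth_window)

  steps <- list()
  for (k in which(keep)) {
    a <- starts[k]; b <- ends[k]                 # 1-based stance bounds
    seg <- smoothed[a:b]
    n <- length(seg)
    # interior local maxima of the smoothed segment; ties (plateaus) resolve
    # to the first index, matching which.max()
    d <- diff(seg)
    up <- c(TRUE, d > 0)
    down <- c(d <= 0, TRUE)
    locmax <- which(up & down)
    locmax <- locmax[locmax > 1L & locmax < n]
    step <- list(contact = a - 1L, peak1 = NA_integer_, valley = NA_integer_,
                 toe_off = b, unlabelable = FALSE)   # toe_off 0-based = b+1-1
    # the two bumps: greedily take the largest maximum, then the largest one
    # at least 2*smooth_window frames away (noise wiggles near a peak must
    # not masquerade as the second bump)
    second <- NA_integer_
    if (length(locmax) >= 2L) {
      ord <- order(seg[locmax], decreasing = TRUE)
      first <- locmax[ord[1]]
      rest <- locmax[ord[-1]]
      rest <- rest[abs(rest - first) >= 2L * smooth_window]
      if (length(rest) >= 1L) second <- rest[1]
    }
    if (length(locmax) < 2L || is.na(second)) {
      step$unlabelable <- TRUE
      warning("stance starting at frame ", a - 1L,
              " has no two separable force maxima; flagged unlabelable")
      steps[[length(steps) + 1L]] <- step
      next
    }
    two <- sort(c(first, second))
    i1 <- two[1]; i2 <- two[2]
    iv <- i1 + which.min(seg[(i1 + 1L):(i2 - 1L)])
    refine <- function(idx, fun) {
      lo <- max(1L, idx - 1L); hi <- min(n, idx + 1L)
      lo - 1L + fun(force[(a + lo - 1L):(a + hi - 1L)])
    }
    i1 <- refine(i1, which.max)
    i2 <- refine(i2, which.max)
    iv <- refine(iv, which.min)
    step$peak1 <- a - 1L + i1 - 1L
    step$valley <- a - 1L + iv - 1L
    step$peak2 <- a - 1L + i2 - 1L
    steps[[length(steps) + 1L]] <- step
  }
  steps
}

#' Expand step events into per-frame five-phase labels
#'
#' Per step the classes tile the timeline in the fixed order
#' IC -> LR -> MS -> TS -> SW with half-open, 0-based intervals:
#' IC `[contact, contact + ic_stretch)`, LR `[.., peak1)`, MS
#' `[peak1, valley)`, TS `[valley, toe_off)`, SW `[toe_off, next contact)`.
#' Frames before the first contact and after the last toe-off are swing.
#' Initial contact is a single instant; stretching it over `ic_stretch`
#' frames keeps the five classes roughly balanced, and the first frame of
#' each IC run remains the actual contact event.
#'
#' @param event_frames list of steps as from [detect_step_events()];
#'   unlabelable steps are skipped.
#' @param T total number of frames to label.
#' @param ic_stretch frames the IC class spans (default 10, ~83 ms at
#'   120 Hz); must stay below each step's `peak1 - contact` or an error is
#'   raised (IC would swallow LR).
#' @return A `phase_labels` object: factor `labels` of length `T`,
#'   `event_frames` (the labelable steps) and `ic_stretch`.
#' @export
events_to_labels <- function(event_frames, T, ic_stretch = 10L) {
  ic_stretch <- as.integer(ic_stretch)
  if (ic_stretch < 1L) stop("ic_stretch must be >= 1")
  codes <- rep.int(4L, T)                        # default SW
  usable <- Filter(function(s) !isTRUE(s$unlabelable), event_frames)
  for (s in usable) {
    if (is.null(s$contact) || is.null(s$peak1) ||
        is.null(s$valley) || is.null(s$toe_off))
      stop("step event list must carry contact, peak1, valley, toe_off")
    if (!(s$contact < s$peak1 && s$peak1 < s$valley && s$valley < s$toe_off))
      stop("step events out of order: contact < peak1 < valley < toe_off ",
           "required (contact frame ", s$contact, ")")
    if (ic_stretch >= s$peak1 - s$contact)
      stop("ic_stretch (", ic_stretch, ") must be smaller than peak1 - ",
           "contact (", s$peak1 - s$contact, "); IC would swallow LR")
    fill <- function(from, to, code) {          # 0-based half-open [from, to)
      if (to > from) codes[(from + 1L):min(to, T)] <<- code
    }
    fill(s$contact, s$contact + ic_stretch, 0L)
    fill(s$contact + ic_stretch, s$peak1, 1L)
    fill(s$peak1, s$valley, 2L)
    fill(s$valley, s$toe_off, 3L)
    # [toe_off, next contact) keeps the default SW code
  }
  structure(list(labels = phase_factor(codes), event_frames = usable,
                 ic_stretch = ic_stretch),
            class = "phase_labels")
}

#' Run label generation on an aligned subject
#'
#' Convenience wrapper: [align_streams()], [detect_step_events()],
#' [events_to_labels()] in one call.
#'
#' @inheritParams align_streams
#' @inheritParams detect_step_events
#' @inheritParams events_to_labels
#' @return `list(imu, pressure, labels, alignment)` with labels on the
#'   aligned timeline.
#' @export
label_subject <- function(imu, pressure, contact_threshold = NULL,
                          smooth_window = 5L, ic_stretch = 10L,
                          interpolate = FALSE) {
  al <- align_streams(imu, pressure, interpolate = interpolate)
  steps <- detect_step_events(al$pressure, contact_threshold, smooth_window)
  labels <- events_to_labels(steps, nrow(al$imu$samples),
                             ic_stretch = ic_stretch)
  list(imu = al$imu, pressure = al$pressure, labels = labels,
       alignment = al$alignment)
}
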
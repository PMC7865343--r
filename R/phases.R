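#' Gait phase codes
#'
#' The five frame-level classes used throughout the package, in their
#' within-step order: initial contact (IC), loading response (LR), mid
#' stance (MS), terminal stance (TS) and swing (SW). Integer codes run
#' 0..4 in this order.
#'
#' @return Character vector of the five phase codes.
#' @export
gait_phases <- function() c("IC", "LR", "MS", "TS", "SW")

#' Convert phase labels between string and integer coding
#'
#' @param x a character/factor vector of phase codes, or an integer vector
#'   with values in 0..4.
#' @return `phase_codes()` returns integers 0..4; `phase_factor()` returns a
#'   factor with levels `gait_phases()`.
#' @export
phase_codes <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  m <- match(as.character(x), gait_phases())
  if (anyNA(m)) stop("unknown phase label(s): ",
                     paste(unique(setdiff(as.character(x), gait_phases())), collapse = ", "))
  m - 1L
}

#' @rdname phase_codes
#' @export
phase_factor <- function(x) {
  if (is.numeric(x)) {
    if (any(x < 0 | x > 4)) stop("integer phase codes must lie in 0..4")
    factor(gait_phases()[as.integer(x) + 1L], levels = gait_phases())
  } else {
    factor(as.character(x), levels = gait_phases())
  }
}

# Sensor layout used by the generator: 10 units (master excluded), 7 channels.
imu_locations <- function() {
  c("l_foot", "r_foot", "l_tibia", "r_tibia", "l_thigh",
    "r_thigh", "l_hip", "r_hip", "l_arm", "r_arm")
}

imu_channels <- function() c("ax", "ay", "az", "gx", "gy", "gz", "p1")

imu_column_names <- function(locations = imu_locations(),
                             channels = imu_channels()) {
  as.vector(t(outer(locations, channels, paste, sep = "_")))
}

#' Milliseconds spanned by one sample frame
#'
#' @param rate_hz sampling rate in Hz.
#' @param rounded if `TRUE`, round to the whole-ms figure commonly used for
#'   axis labels (8 ms at 120 Hz); otherwise the exact value (8.33 ms).
#' @return Frame duration in milliseconds.
#' @export
ms_per_frame <- function(rate_hz, rounded = FALSE) {
  if (rate_hz <= 0) stop("rate_hz must be positive")
  ms <- 1000 / rate_hz
  if (rounded) round(ms) else ms
}
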
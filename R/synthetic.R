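# Synthetic walking-data generator: coupled IMU + pressure-plate streams with
# exact ground-truth phase boundaries, so the whole pipeline is testable
# without access to laboratory recordings.

#' Configuration for the synthetic gait generator
#'
#' The generator emulates treadmill walking recorded by 10 body-worn IMUs
#' (7 channels each: 3-axis acceleration, 3-axis gyroscope, barometric
#' pressure) at 120 Hz, synchronized with a pressure plate that measures the
#' total vertical force. Each gait cycle lasts about one second; the stance
#' interval carries a two-peaked force curve and the swing interval has
#' exactly zero force.
#'
#' @param n_subjects number of subjects to simulate.
#' @param duration_s recording length per subject, seconds.
#' @param rate_hz sampling rate of both streams (Hz).
#' @param cycle_s_mean,cycle_s_sd gait-cycle duration distribution across
#'   subjects (seconds); each subject draws one cycle length.
#' @param stance_fraction fraction of the cycle with nonzero plate force.
#' @param peak1_frac,valley_frac,peak2_frac positions of the two force maxima
#'   and the inter-peak minimum, as fractions of the stance interval; must
#'   satisfy `0 < peak1 < valley < peak2 < 1`.
#' @param noise_sd_imu additive Gaussian noise on every IMU channel
#'   (arbitrary units; waveform amplitudes are order 1).
#' @param noise_sd_force additive Gaussian noise on the force during stance
#'   (units of the unit-height force curve). Swing force stays exactly zero.
#' @param subject_gain_sd standard deviation of the per-subject,
#'   per-channel log-normal amplitude gain.
#' @param trigger_offset_frames frames of pre-trigger padding prepended to the
#'   pressure stream (its trigger lands at this index); exercises stream
#'   alignment. The IMU trigger is always frame 0.
#' @param ic_stretch frames the initial-contact class spans in the
#'   ground-truth labels (see [events_to_labels()]).
#' @param seed RNG seed; identical configs reproduce every array exactly.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 11L,
                             duration_s = 60,
                             rate_hz = 120,
                             cycle_s_mean = 1.0,
                             cycle_s_sd = 0.05,
                             stance_fraction = 0.6,
                             peak1_frac = 0.25,
                             valley_frac = 0.50,
                             peak2_frac = 0.75,
                             noise_sd_imu = 0.05,
                             noise_sd_force = 0.005,
                             subject_gain_sd = 0.10,
                             trigger_offset_frames = 0L,
                             ic_stretch = 10L,
                             seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), duration_s = duration_s,
              rate_hz = rate_hz, cycle_s_mean = cycle_s_mean,
              cycle_s_sd = cycle_s_sd, stance_fraction = stance_fraction,
              peak1_frac = peak1_frac, valley_frac = valley_frac,
              peak2_frac = peak2_frac, noise_sd_imu = noise_sd_imu,
              noise_sd_force = noise_sd_force,
              subject_gain_sd = subject_gain_sd,
              trigger_offset_frames = as.integer(trigger_offset_frames),
              ic_stretch = as.integer(ic_stretch), seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop_config("n_subjects", "must be >= 1")
  if (cfg$duration_s <= 0) stop_config("duration_s", "must be > 0")
  if (cfg$rate_hz <= 0) stop_config("rate_hz", "must be > 0")
  if (cfg$cycle_s_mean <= 0) stop_config("cycle_s_mean", "must be > 0")
  if (cfg$cycle_s_sd < 0) stop_config("cycle_s_sd", "must be >= 0")
  if (cfg$stance_fraction <= 0 || cfg$stance_fraction >= 1)
    stop_config("stance_fraction", "must lie in (0, 1)")
  p <- c(cfg$peak1_frac, cfg$valley_frac, cfg$peak2_frac)
  if (!(0 < p[1] && p[1] < p[2] && p[2] < p[3] && p[3] < 1))
    stop_config("peak1_frac/valley_frac/peak2_frac",
                "must satisfy 0 < peak1 < valley < peak2 < 1")
  if (cfg$noise_sd_imu < 0) stop_config("noise_sd_imu", "must be >= 0")
  if (cfg$noise_sd_force < 0) stop_config("noise_sd_force", "must be >= 0")
  if (cfg$subject_gain_sd < 0) stop_config("subject_gain_sd", "must be >= 0")
  if (cfg$trigger_offset_frames < 0)
    stop_config("trigger_offset_frames", "must be >= 0")
  if (cfg$ic_stretch < 1L) stop_config("ic_stretch", "must be >= 1")
  invisible(cfg)
}

# Raised-cosine bump of unit height centered at `center` with half-width
# `halfwidth`, evaluated at stance positions s in [0, 1]; zero outside.
raised_cosine <- function(s, center, halfwidth) {
  u <- (s - center) / halfwidth
  out <- numeric(length(s))
  inside <- abs(u) <= 1
  out[inside] <- 0.5 * (1 + cos(pi * u[inside]))
  out
}

# Deterministic (noise-free) force curve over one stance interval, sampled at
# mid-frame positions. Two raised cosines of heights 1.0 and 0.95. The
# half-width is chosen so the curve is strictly positive across the whole
# stance yet the two peaks stay separated by an interior minimum.
stance_force_curve <- function(n_stance, cfg) {
  s <- (seq_len(n_stance) - 0.5) / n_stance
  hw <- min(cfg$peak2_frac - cfg$peak1_frac - 0.01,
            max(cfg$peak1_frac, 1 - cfg$peak2_frac) + 0.10)
  if (hw <= 0) stop_config("peak1_frac/peak2_frac",
                           "peaks too close for a two-bump force curve")
  1.0 * raised_cosine(s, cfg$peak1_frac, hw) +
    0.95 * raised_cosine(s, cfg$peak2_frac, hw)
}

# Ground-truth step events for one stance interval: indices (0-based, within
# the stance) of the two maxima and the interior minimum on the noise-free
# curve.
stance_truth_extrema <- function(fbase, cfg) {
  n <- length(fbase)
  vb <- max(2L, min(n - 1L, round(cfg$valley_frac * n)))
  i1 <- which.max(fbase[1:vb])
  i2 <- vb + which.max(fbase[(vb + 1L):n])
  iv <- i1 + which.min(fbase[(i1 + 1L):(i2 - 1L)])
  c(peak1 = i1 - 1L, valley = iv - 1L, peak2 = i2 - 1L)
}

#' Simulate one subject's coupled IMU and pressure recordings
#'
#' Produces a phase-locked, per-subject-scaled IMU matrix, a two-bump stance
#' force trace with exactly-zero swing force, and the generator's exact
#' ground-truth phase labels. The 60 motion channels are two-harmonic
#' sinusoids of the cycle phase with waveform parameters fixed per
#' sensor-channel by the config seed (so the phase is decodable from any
#' window); right-side sensors run half a cycle out of phase. Barometric
#' channels drift slowly and carry no phase information. Gait cycles that do
#' not complete their stance before the recording ends are emitted as quiet
#' standing (zero force, swing label).
#'
#' @param config a [synthetic_config()].
#' @param subject_index 1-based subject number, `<= n_subjects`.
#' @return A list with elements `imu` (class `imu_recording`), `pressure`
#'   (class `pressure_trace`) and `labels` (class `phase_labels`, the ground
#'   truth on the IMU timeline).
#' @export
simulate_subject <- function(config, subject_index) {
  validate_synthetic_config(config)
  if (subject_index < 1L || subject_index > config$n_subjects)
    stop("subject_index must lie in 1..n_subjects")

  n_loc <- length(imu_locations()); n_ch <- length(imu_channels())
  n_col <- n_loc * n_ch
  Tn <- round(config$duration_s * config$rate_hz)

  # Waveform family: fixed per sensor-channel from the config seed, shared
  # across subjects (what differs between subjects is gain and cadence).
  wf <- with_seed(config$seed, {
    list(a1 = runif(n_col, 0.5, 1.5), a2 = runif(n_col, 0.2, 0.8),
         ph1 = runif(n_col, 0, 2 * pi), ph2 = runif(n_col, 0, 2 * pi),
         baro_phase = runif(n_loc, 0, 2 * pi))
  })

  sub_seed <- (config$seed %% 100000L) * 20011L + subject_index
  out <- with_seed(sub_seed, {
    cycle_s <- max(0.4, stats::rnorm(1, config$cycle_s_mean, config$cycle_s_sd))
    gains <- exp(stats::rnorm(n_col, 0, config$subject_gain_sd))
    L <- max(4L, as.integer(round(cycle_s * config$rate_hz)))
    n_st <- max(3L, as.integer(round(config$stance_fraction * L)))

    fbase_cycle <- stance_force_curve(n_st, config)
    extrema <- stance_truth_extrema(fbase_cycle, config)

    starts <- seq(0L, Tn - 1L, by = L)            # 0-based cycle starts
    complete <- starts + n_st <= Tn               # stance fits the recording
    force <- numeric(Tn)
    events <- list()
    walking <- logical(Tn)                        # frames with gait waveform
    for (k in seq_along(starts)) {
      s0 <- starts[k]
      if (!complete[k]) next
      idx <- s0 + seq_len(n_st)                   # 1-based frame indices
      fnoisy <- fbase_cycle
      if (config$noise_sd_force > 0)
        fnoisy <- pmax(fnoisy + stats::rnorm(n_st, 0, config$noise_sd_force),
                       1e-8)
      force[idx] <- fnoisy
      cyc_end <- min(s0 + L, Tn)
      walking[(s0 + 1L):cyc_end] <- TRUE
      events[[length(events) + 1L]] <- list(
        contact = s0,
        peak1 = s0 + unname(extrema["peak1"]),
        valley = s0 + unname(extrema["valley"]),
        toe_off = s0 + n_st)
    }

    # Cycle phase for every frame; incomplete trailing cycles stand still.
    frame0 <- seq_len(Tn) - 1L
    phi <- (frame0 %% L) / L
    half_shift <- rep(rep(c(0, 0.5), each = n_ch), length.out = n_col)
    motion <- matrix(0, Tn, n_col)
    for (j in seq_len(n_col)) {
      ph <- phi + half_shift[j]
      motion[, j] <- wf$a1[j] * sin(2 * pi * ph + wf$ph1[j]) +
        wf$a2[j] * sin(4 * pi * ph + wf$ph2[j])
    }
    motion[!walking, ] <- 0
    baro_cols <- seq(n_ch, n_col, by = n_ch)      # every unit's p1 channel
    tsec <- frame0 / config$rate_hz
    for (i in seq_along(baro_cols)) {
      motion[, baro_cols[i]] <-
        1 + 0.05 * sin(2 * pi * 0.02 * tsec + wf$baro_phase[i])
    }
    samples <- sweep(motion, 2L, gains, `*`)
    if (config$noise_sd_imu > 0)
      samples <- samples +
        matrix(stats::rnorm(length(samples), 0, config$noise_sd_imu),
               nrow(samples), ncol(samples))
    list(force = force, events = events, samples = samples, cycle_s = cycle_s)
  })

  colnames(out$samples) <- imu_column_names()
  imu <- structure(list(
    subject_id = sprintf("subject_%02d", subject_index),
    samples = out$samples, rate_hz = config$rate_hz, trigger_frame = 0L,
    sensor_locations = imu_locations(), channels = imu_channels()),
    class = "imu_recording")

  off <- config$trigger_offset_frames
  pressure <- structure(list(
    force = c(numeric(off), out$force), rate_hz = config$rate_hz,
    trigger_frame = off), class = "pressure_trace")

  labels <- events_to_labels(out$events, Tn, ic_stretch = config$ic_stretch)
  list(imu = imu, pressure = pressure, labels = labels)
}

#' Simulate a full multi-subject dataset
#'
#' @param config a [synthetic_config()].
#' @return List of length `n_subjects`; each element as in
#'   [simulate_subject()].
#' @export
simulate_dataset <- function(config) {
  validate_synthetic_config(config)
  lapply(seq_len(config$n_subjects), function(i) simulate_subject(config, i))
}

#' Write one simulated subject to plain-text files
#'
#' Creates `<dir>/imu.csv` (named channel columns), `<dir>/force.csv`
#' (`frame,force`, 0-based frames), `<dir>/labels.csv` (`frame,phase`),
#' `<dir>/events.json` and `<dir>/meta.json` (config echo, seed, triggers).
#'
#' @param subject a list as returned by [simulate_subject()].
#' @param dir output directory (created if missing).
#' @param config the generating [synthetic_config()], echoed into the sidecar.
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(subject$imu$samples),
                   file.path(dir, "imu.csv"), row.names = FALSE)
  utils::write.csv(data.frame(frame = seq_along(subject$pressure$force) - 1L,
                              force = subject$pressure$force),
                   file.path(dir, "force.csv"), row.names = FALSE)
  if (!is.null(subject$labels)) {
    utils::write.csv(data.frame(
      frame = seq_along(subject$labels$labels) - 1L,
      phase = as.character(subject$labels$labels)),
      file.path(dir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(subject$labels$event_frames,
                         file.path(dir, "events.json"), auto_unbox = TRUE)
  }
  meta <- list(subject_id = subject$imu$subject_id,
               rate_hz = subject$imu$rate_hz,
               imu_trigger_frame = subject$imu$trigger_frame,
               pressure_trigger_frame = subject$pressure$trigger_frame,
               sensor_locations = subject$imu$sensor_locations,
               channels = subject$imu$channels,
               config = if (!is.null(config)) unclass(config) else NULL)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a subject written by [write_subject()]
#'
#' @param dir the subject directory.
#' @param require_labels error if `labels.csv` is missing.
#' @return A list with `imu`, `pressure` and (if present) `labels`.
#' @export
read_subject <- function(dir, require_labels = FALSE) {
  imu_path <- file.path(dir, "imu.csv")
  force_path <- file.path(dir, "force.csv")
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(imu_path)) stop_data("missing IMU CSV: ", imu_path)
  if (!file.exists(force_path)) stop_data("missing force CSV: ", force_path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  samples <- as.matrix(utils::read.csv(imu_path, check.names = FALSE))
  fdf <- utils::read.csv(force_path)
  if (!all(c("frame", "force") %in% names(fdf)))
    stop_data("force CSV must have columns frame,force: ", force_path)
  rate <- as.numeric(meta$rate_hz %||% 120)
  imu <- structure(list(
    subject_id = meta$subject_id %||% basename(dir), samples = samples,
    rate_hz = rate, trigger_frame = as.integer(meta$imu_trigger_frame %||% 0L),
    sensor_locations = unlist(meta$sensor_locations %||% imu_locations()),
    channels = unlist(meta$channels %||% imu_channels())),
    class = "imu_recording")
  pressure <- structure(list(
    force = fdf$force, rate_hz = rate,
    trigger_frame = as.integer(meta$pressure_trigger_frame %||% 0L)),
    class = "pressure_trace")
  out <- list(imu = imu, pressure = pressure)
  lab_path <- file.path(dir, "labels.csv")
  if (file.exists(lab_path)) {
    ldf <- utils::read.csv(lab_path)
    out$labels <- structure(list(labels = phase_factor(ldf$phase),
                                 event_frames = NULL, ic_stretch = NA_integer_),
                            class = "phase_labels")
  } else if (require_labels) {
    stop_data("missing labels CSV: ", lab_path)
  }
  out
}
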
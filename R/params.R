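#' Light protocol describing the epoch schedule of an assay
#'
#' The standard assay exposes an arena of flies to a 2-min low-intensity
#' epoch (0.4 klx, comparable to room light), a 2-min high-intensity epoch
#' (18 klx), and a 2-min low-intensity recovery epoch. Behaviour is scored
#' in 10-s bins, so each epoch duration must be a multiple of the bin width.
#'
#' @param label character vector of epoch labels.
#' @param duration_s epoch durations in seconds.
#' @param intensity_klx illuminance of each epoch in kilolux.
#' @param bin_s scoring bin width in seconds (used only to validate that the
#'   bin grid divides each epoch evenly).
#' @return a tibble with one row per epoch and columns `epoch`, `label`,
#'   `duration_s`, `intensity_klx`, `t_start`, `t_end`.
#' @examples
#' light_protocol()
#' @export
light_protocol <- function(label = c("low", "high", "low"),
                           duration_s = c(120, 120, 120),
                           intensity_klx = c(0.4, 18, 0.4),
                           bin_s = 10) {
  if (length(label) != length(duration_s) || length(label) != length(intensity_klx))
    stopf("flycourt_input", "label, duration_s and intensity_klx must have equal length")
  if (any(duration_s <= 0)) stopf("flycourt_input", "epoch durations must be positive")
  if (any(duration_s %% bin_s != 0))
    stopf("flycourt_input", "each epoch duration must be a multiple of the %g-s bin", bin_s)
  t_end <- cumsum(duration_s)
  tibble(
    epoch = seq_along(label),
    label = as.character(label),
    duration_s = as.numeric(duration_s),
    intensity_klx = as.numeric(intensity_klx),
    t_start = t_end - duration_s,
    t_end = t_end
  )
}

#' Default light dose-response curve for chase initiation
#'
#' Logistic in log10-intensity with its steepest relative rise between
#' 2 and 6 klx, mapping illuminance to the per-second probability that an
#' unengaged male initiates a chase. A small floor keeps spontaneous
#' courtship possible under room light.
#'
#' @param intensity_klx illuminance in kilolux (vectorised).
#' @param rate_max saturating per-second initiation probability.
#' @param rate_min floor rate at negligible light.
#' @param mid_klx intensity of the logistic midpoint.
#' @param slope_decades logistic scale in decades of intensity.
#' @return per-second chase initiation probability, same length as input.
#' @export
chase_rate_logistic <- function(intensity_klx, rate_max = 0.06, rate_min = 0.0015,
                                mid_klx = 4.2, slope_decades = 0.1) {
  x <- log10(pmax(intensity_klx, 1e-6))
  rate_min + (rate_max - rate_min) / (1 + exp(-(x - log10(mid_klx)) / slope_decades))
}

#' Parameters of the agent-based arena simulator
#'
#' @param n_flies number of flies in the arena.
#' @param arena_radius_mm arena radius (default 13 mm, i.e. a 26-mm disc).
#' @param frame_rate frames per second of the simulated record.
#' @param protocol light protocol, see [light_protocol()].
#' @param chase_rate function mapping intensity (klx) to the per-second
#'   probability that a fly initiates a chase; must be non-decreasing in
#'   intensity.
#' @param chain_rate per-second probability that an ongoing chase recruits a
#'   further fly into a follow-line.
#' @param base_speed_mm_s walking speed of undisturbed flies.
#' @param chase_speed_mm_s pursuit speed cap during chases.
#' @param turn_noise heading diffusion of walkers, radians per sqrt(second).
#' @param avoid_radius_mm walkers steer away from flies closer than this
#'   (flies not engaged in courtship keep their distance).
#' @param pause_rate per-second probability a walking fly pauses.
#' @param pause_mean_s mean pause duration.
#' @param chase_min_s,chase_mean_s minimum and mean chase duration; the
#'   duration is `chase_min_s` plus an exponential tail.
#' @param recruit_radius_mm maximum distance at which a free fly can be
#'   targeted or recruited.
#' @param follow_gap_mm preferred spacing between consecutive members of a
#'   follow-line.
#' @param seed integer seed; identical parameters (including seed) give
#'   bit-identical simulations.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_flies = 8,
                       arena_radius_mm = 13,
                       frame_rate = 15,
                       protocol = light_protocol(),
                       chase_rate = chase_rate_logistic,
                       chain_rate = 0.5,
                       base_speed_mm_s = 8,
                       chase_speed_mm_s = 18,
                       turn_noise = 2,
                       avoid_radius_mm = 4,
                       pause_rate = 0.2,
                       pause_mean_s = 1,
                       chase_min_s = 2.0,
                       chase_mean_s = 3.0,
                       recruit_radius_mm = 6,
                       follow_gap_mm = 3,
                       seed = 1L) {
  if (n_flies < 1) stopf("flycourt_input", "n_flies must be >= 1")
  if (arena_radius_mm <= 0) stopf("flycourt_input", "arena_radius_mm must be positive")
  if (frame_rate <= 0) stopf("flycourt_input", "frame_rate must be positive")
  if (any(protocol$duration_s <= 0)) stopf("flycourt_input", "epoch durations must be positive")
  if (is.numeric(chase_rate)) {
    cr <- chase_rate
    chase_rate <- function(intensity_klx) rep(cr, length(intensity_klx))
  }
  if (!is.function(chase_rate)) stopf("flycourt_input", "chase_rate must be a function or a constant")
  grid <- sort(unique(c(protocol$intensity_klx, 0.1, 1, 10, 100)))
  if (is.unsorted(chase_rate(grid))) stopf("flycourt_input", "chase_rate must be non-decreasing in intensity")
  structure(list(
    n_flies = as.integer(n_flies), arena_radius_mm = arena_radius_mm,
    frame_rate = frame_rate, protocol = protocol, chase_rate = chase_rate,
    chain_rate = chain_rate, base_speed_mm_s = base_speed_mm_s,
    chase_speed_mm_s = chase_speed_mm_s, turn_noise = turn_noise,
    avoid_radius_mm = avoid_radius_mm,
    pause_rate = pause_rate, pause_mean_s = pause_mean_s,
    chase_min_s = chase_min_s, chase_mean_s = chase_mean_s,
    recruit_radius_mm = recruit_radius_mm, follow_gap_mm = follow_gap_mm,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Arena geometry and imaging scale
#'
#' @param mm_per_px image scale in millimetres per pixel.
#' @param roi_centres_px matrix (n x 2) of ROI centre pixel coordinates
#'   (column, row); a single arena by default.
#' @param roi_diameter_mm physical ROI diameter (26 mm in the standard plate).
#' @param frame_rate frames per second of the video.
#' @param margin_px blank margin around the ROI when rendering.
#' @return a list of class `arena_config` with derived `roi_radius_px` and
#'   rendered image dimensions `dim_px` (rows, cols).
#' @export
arena_config <- function(mm_per_px = 0.1,
                         roi_centres_px = NULL,
                         roi_diameter_mm = 26,
                         frame_rate = 15,
                         margin_px = 10) {
  if (mm_per_px <= 0) stopf("flycourt_input", "mm_per_px must be positive")
  roi_radius_px <- (roi_diameter_mm / 2) / mm_per_px
  if (is.null(roi_centres_px)) {
    half <- ceiling(roi_radius_px) + margin_px
    roi_centres_px <- matrix(c(half, half), 1, 2)
    dim_px <- c(2 * half, 2 * half)
  } else {
    roi_centres_px <- matrix(as.numeric(roi_centres_px), ncol = 2)
    dim_px <- c(max(roi_centres_px[, 2]) + ceiling(roi_radius_px) + margin_px,
                max(roi_centres_px[, 1]) + ceiling(roi_radius_px) + margin_px)
  }
  structure(list(mm_per_px = mm_per_px, roi_centres_px = roi_centres_px,
                 roi_radius_px = roi_radius_px, roi_diameter_mm = roi_diameter_mm,
                 frame_rate = frame_rate, dim_px = as.integer(dim_px)),
            class = "arena_config")
}

#' Thresholds for proximity, chase and chain detection
#'
#' The proximity criterion of 3.75 mm between centroids was chosen as
#' optimal for capturing chasing events; an interaction is registered when
#' the mutual distance is strictly less than this value. Chaining requires a
#' mobile single-file line of at least 4 flies.
#'
#' @param proximity_mm centroid distance below which two flies interact.
#' @param min_chase_duration_s minimum sustained duration of a chase.
#' @param heading_alignment_deg maximum angle between the chaser's heading
#'   and its bearing to the target.
#' @param chain_min_size minimum number of flies in a chain.
#' @param chain_min_speed_mm_s mobility criterion for chases and chains.
#' @param chain_min_duration_s minimum chain duration.
#' @return a validated list of class `interaction_params`.
#' @export
interaction_params <- function(proximity_mm = 3.75,
                               min_chase_duration_s = 1.0,
                               heading_alignment_deg = 60,
                               chain_min_size = 4,
                               chain_min_speed_mm_s = 2.0,
                               chain_min_duration_s = 1.0) {
  if (proximity_mm <= 0) stopf("flycourt_input", "proximity_mm must be positive")
  if (chain_min_size < 2) stopf("flycourt_input", "chain_min_size must be >= 2")
  if (min_chase_duration_s <= 0 || chain_min_duration_s <= 0)
    stopf("flycourt_input", "durations must be positive")
  structure(list(proximity_mm = proximity_mm,
                 min_chase_duration_s = min_chase_duration_s,
                 heading_alignment_deg = heading_alignment_deg,
                 chain_min_size = as.integer(chain_min_size),
                 chain_min_speed_mm_s = chain_min_speed_mm_s,
                 chain_min_duration_s = chain_min_duration_s),
            class = "interaction_params")
}

#' Parameters for courtship-song segmentation
#'
#' Band edges and thresholds follow common practice for Drosophila song
#' analysis; all are tunable.
#'
#' @param pulse_band_hz band-pass edges for pulse detection (Hz).
#' @param sine_band_hz band in which a sustained spectral peak counts as
#'   sine song (Hz).
#' @param peak_thresh_mad pulse envelope threshold in multiples of the
#'   envelope MAD above its median (noise-relative, hence amplitude
#'   invariant).
#' @param refractory_s minimum spacing between detected pulses.
#' @param bout_gap_s maximum inter-pulse interval within one bout.
#' @param min_pulses_per_bout minimum pulses for a run to count as a bout.
#' @param min_sine_s minimum sine-segment duration.
#' @return a validated list of class `song_params`.
#' @export
song_params <- function(pulse_band_hz = c(100, 500),
                        sine_band_hz = c(100, 200),
                        peak_thresh_mad = 6,
                        refractory_s = 0.005,
                        bout_gap_s = 0.1,
                        min_pulses_per_bout = 3,
                        min_sine_s = 0.2) {
  for (b in list(pulse_band_hz, sine_band_hz))
    if (length(b) != 2 || any(b <= 0) || b[1] >= b[2])
      stopf("flycourt_input", "frequency bands must be positive and ordered (lo, hi)")
  if (peak_thresh_mad <= 0) stopf("flycourt_input", "peak_thresh_mad must be positive")
  structure(list(pulse_band_hz = pulse_band_hz, sine_band_hz = sine_band_hz,
                 peak_thresh_mad = peak_thresh_mad, refractory_s = refractory_s,
                 bout_gap_s = bout_gap_s,
                 min_pulses_per_bout = as.integer(min_pulses_per_bout),
                 min_sine_s = min_sine_s),
            class = "song_params")
}
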
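#' Song element specifications
#'
#' Helpers building the element table consumed by [synthesize_song()].
#' Drosophila courtship song alternates trains of brief sound pulses
#' (pulse song) with sustained near-sinusoidal humming (sine song).
#'
#' @param start_s element onset in seconds.
#' @param n_pulses number of pulses in the bout.
#' @param ipi_s inter-pulse interval in seconds.
#' @param ipi_jitter_s standard deviation of the per-interval IPI jitter
#'   (0 for perfectly regular trains); jittered intervals are truncated at
#'   half the nominal IPI.
#' @param carrier_hz pulse/sine carrier frequency in Hz.
#' @param decay_s exponential decay constant of each pulse.
#' @param duration_s sine segment duration in seconds.
#' @param amp peak amplitude.
#' @return a one-row tibble element specification.
#' @export
pulse_bout <- function(start_s, n_pulses, ipi_s, ipi_jitter_s = 0,
                       carrier_hz = 220, decay_s = 0.005, amp = 1) {
  if (n_pulses < 1 || ipi_s <= 0) stopf("flycourt_input", "need n_pulses >= 1 and ipi_s > 0")
  tibble(type = "pulse_bout", start_s = start_s,
         end_s = start_s + (n_pulses - 1) * (ipi_s + 3 * ipi_jitter_s) +
           5 * decay_s,
         n_pulses = as.integer(n_pulses), ipi_s = ipi_s,
         ipi_jitter_s = ipi_jitter_s,
         freq_hz = carrier_hz, decay_s = decay_s, amp = amp)
}

#' @rdname pulse_bout
#' @export
sine_song <- function(start_s, duration_s, carrier_hz = 150, amp = 0.5) {
  if (duration_s <= 0) stopf("flycourt_input", "duration_s must be positive")
  tibble(type = "sine", start_s = start_s, end_s = start_s + duration_s,
         n_pulses = NA_integer_, ipi_s = NA_real_, ipi_jitter_s = NA_real_,
         freq_hz = carrier_hz, decay_s = NA_real_, amp = amp)
}

#' Synthesize courtship-song audio with known ground truth
#'
#' Builds a waveform containing exponentially damped-sinusoid pulses at
#' specified inter-pulse intervals and pure-tone sine segments, optionally
#' embedded in white noise at a stated signal-to-noise ratio. The returned
#' ground truth records every element parameter, so segmentation output can
#' be scored against it.
#'
#' @param elements a tibble of element specs from [pulse_bout()] /
#'   [sine_song()] rows bound together (or an empty tibble / NULL for
#'   silence).
#' @param sample_rate audio sampling rate in Hz.
#' @param duration_s total clip duration; all elements must fit inside it.
#' @param noise_snr_db if non-NULL, add white Gaussian noise at this SNR
#'   (dB, relative to the RMS of the clean signal; relative to unit
#'   amplitude if the clip is silent).
#' @param seed optional seed for the noise.
#' @return a list of class `song_audio`: `wave` (numeric vector),
#'   `sample_rate`, and `truth` (the element table).
#' @examples
#' au <- synthesize_song(pulse_bout(0.1, 10, 0.035), 10000, 1)
#' @export
synthesize_song <- function(elements = NULL, sample_rate = 10000, duration_s = 1,
                            noise_snr_db = NULL, seed = NULL) {
  if (sample_rate <= 0 || duration_s <= 0)
    stopf("flycourt_input", "sample_rate and duration_s must be positive")
  if (is.null(elements) || nrow(elements) == 0) {
    elements <- pulse_bout(0, 1, 1)[0, ]
  }
  elements <- arrange(elements, .data$start_s)
  if (any(elements$start_s < 0) || any(elements$end_s > duration_s))
    stopf("flycourt_range", "song elements must lie within [0, duration_s]")
  if (nrow(elements) > 1 &&
      any(elements$start_s[-1] < elements$end_s[-nrow(elements)]))
    stopf("flycourt_overlap", "song elements overlap in time")

  n <- round(sample_rate * duration_s)
  t <- (seq_len(n) - 1) / sample_rate
  wave <- numeric(n)
  jit <- function(e) {
    j <- if ("ipi_jitter_s" %in% names(e)) e$ipi_jitter_s else 0
    if (is.null(j) || is.na(j) || j == 0 || e$n_pulses < 2)
      return(rep(0, max(e$n_pulses - 1, 0)))
    pmax(rnorm(e$n_pulses - 1, 0, j), -e$ipi_s / 2)
  }
  build <- function() {
    wave <- numeric(n)
    for (k in seq_len(nrow(elements))) {
      e <- elements[k, ]
      if (e$type == "pulse_bout") {
        p_times <- e$start_s +
          cumsum(c(0, rep(e$ipi_s, e$n_pulses - 1) + jit(e)))
        span_s <- 5 * e$decay_s
        for (t0 in p_times) {
          i0 <- round(t0 * sample_rate) + 1L
          i1 <- min(n, i0 + round(span_s * sample_rate))
          tt <- t[i0:i1] - t[i0]
          wave[i0:i1] <- wave[i0:i1] +
            e$amp * exp(-tt / e$decay_s) * sin(2 * pi * e$freq_hz * tt + pi / 2)
        }
      } else if (e$type == "sine") {
        i0 <- round(e$start_s * sample_rate) + 1L
        i1 <- min(n, round(e$end_s * sample_rate))
        tt <- t[i0:i1] - t[i0]
        ramp_n <- min(round(0.01 * sample_rate), floor((i1 - i0 + 1) / 2))
        env <- rep(1, i1 - i0 + 1L)
        if (ramp_n > 0) {
          ramp <- seq(0, 1, length.out = ramp_n)
          env[seq_len(ramp_n)] <- ramp
          env[(length(env) - ramp_n + 1L):length(env)] <- rev(ramp)
        }
        wave[i0:i1] <- wave[i0:i1] + e$amp * env * sin(2 * pi * e$freq_hz * tt)
      } else {
        stopf("flycourt_input", "unknown song element type '%s'", e$type)
      }
    }
    if (!is.null(noise_snr_db)) {
      sig_rms <- sqrt(mean(wave^2))
      ref <- if (sig_rms > 0) sig_rms else 1
      wave <- wave + rnorm(n, 0, ref / 10^(noise_snr_db / 20))
    }
    wave
  }
  wave <- if (is.null(seed)) build() else withr::with_seed(seed, build())

  structure(list(wave = wave, sample_rate = sample_rate, truth = elements),
            class = "song_audio")
}
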
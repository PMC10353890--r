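butter_filt <- function(x, cutoff_hz, fs, type, order = 3) {
  wn <- cutoff_hz / (fs / 2)
  bf <- signal::butter(order, wn, type = type)
  as.numeric(signal::filtfilt(bf, x))
}

# rectify + low-pass envelope (simpler contract than a Hilbert transform,
# equivalent at these bands)
envelope <- function(x, fs, cutoff_hz = 50) {
  e <- butter_filt(abs(x), cutoff_hz, fs, "low")
  pmax(e, 0)
}

#' Segment courtship song into pulses, bouts and sine segments
#'
#' Band-passes the waveform in the pulse band and detects pulses as local
#' maxima of the rectified-and-smoothed envelope exceeding a noise-relative
#' threshold (median plus `peak_thresh_mad` MADs of the envelope), with a
#' refractory spacing and a local-contrast test that rejects maxima on
#' sustained (sine) plateaus. Pulses separated by gaps of at most
#' `bout_gap_s` are grouped into bouts; bouts with at least
#' `min_pulses_per_bout` pulses are reported with their inter-pulse
#' intervals (IPIs). Sine song is detected as maximal runs of sustained
#' sine-band envelope of at least `min_sine_s` whose segment periodogram
#' peaks inside the sine band; the dominant frequency is the periodogram
#' peak. Because the threshold is noise-relative, scaling the waveform by
#' any positive constant leaves the segmentation unchanged.
#'
#' @param audio a `song_audio` object from [synthesize_song()], or a
#'   numeric waveform (then `sample_rate` is required).
#' @param params a [song_params()].
#' @param sample_rate sampling rate in Hz when `audio` is a bare vector.
#' @return a list of class `song_segmentation`: `pulses` (tibble
#'   `time_s`), `bouts` (`start_s`, `end_s`, `n_pulses`, `mean_ipi_s`,
#'   list-column `ipi_s`), `sines` (`start_s`, `end_s`, `duration_s`,
#'   `freq_hz`), `sample_rate`.
#' @export
segment_song <- function(audio, params = song_params(), sample_rate = NULL) {
  if (inherits(audio, "song_audio")) {
    wave <- audio$wave; fs <- audio$sample_rate
  } else {
    wave <- as.numeric(audio); fs <- sample_rate
    if (is.null(fs)) stopf("flycourt_input", "sample_rate is required for a bare waveform")
  }
  hi <- max(params$pulse_band_hz, params$sine_band_hz)
  if (fs < 2 * hi)
    stopf("flycourt_rate", "sample rate %g Hz is below twice the upper band edge (%g Hz)", fs, hi)

  empty <- structure(list(
    pulses = tibble(time_s = numeric()),
    bouts = tibble(start_s = numeric(), end_s = numeric(),
                   n_pulses = integer(), mean_ipi_s = numeric(),
                   ipi_s = list()),
    sines = tibble(start_s = numeric(), end_s = numeric(),
                   duration_s = numeric(), freq_hz = numeric()),
    sample_rate = fs), class = "song_segmentation")
  if (length(wave) < 10 || max(abs(wave)) == 0) return(empty)

  # ---- pulses
  bp <- butter_filt(wave, params$pulse_band_hz, fs, "pass")
  # envelope cutoff high enough to resolve pulses at the shortest IPIs
  env <- envelope(bp, fs, cutoff_hz = 150)
  # noise level estimated as the MAD of the band-passed waveform: robust to
  # sparse song content, and scales with the waveform so the threshold is
  # amplitude invariant
  noise_mad <- stats::mad(bp)
  thr <- params$peak_thresh_mad * noise_mad
  pulse_idx <- integer(0)
  if (noise_mad > 0 && any(env > thr)) {
    refr <- max(1L, round(params$refractory_s * fs))
    pk <- pracma::findpeaks(env, minpeakheight = thr,
                            minpeakdistance = refr)
    if (!is.null(pk)) {
      cand <- sort(pk[, 2])
      # local-contrast: a pulse stands well above the envelope's local
      # median; maxima riding a sustained plateau (sine song) do not
      half_w <- round(0.06 * fs)
      keep <- vapply(cand, function(i) {
        lo <- max(1L, i - half_w); hi2 <- min(length(env), i + half_w)
        env[i] > 3 * stats::median(env[lo:hi2])
      }, logical(1))
      pulse_idx <- cand[keep]
    }
  }
  pulse_t <- (pulse_idx - 1) / fs

  bouts <- empty$bouts
  if (length(pulse_t) >= params$min_pulses_per_bout) {
    grp <- cumsum(c(1, diff(pulse_t) > params$bout_gap_s))
    bouts <- tibble(time_s = pulse_t, grp = grp) |>
      group_by(.data$grp) |>
      summarise(start_s = min(.data$time_s), end_s = max(.data$time_s),
                n_pulses = dplyr::n(),
                ipi_s = list(diff(.data$time_s)), .groups = "drop") |>
      filter(.data$n_pulses >= params$min_pulses_per_bout) |>
      mutate(mean_ipi_s = purrr::map_dbl(.data$ipi_s, mean)) |>
      select("start_s", "end_s", "n_pulses", "mean_ipi_s", "ipi_s")
  }

  # ---- sine segments
  sn <- butter_filt(wave, params$sine_band_hz, fs, "pass")
  env_s <- envelope(sn, fs, cutoff_hz = 20)
  med_s <- stats::median(env_s); mad_s <- stats::mad(env_s)
  sines <- empty$sines
  if (mad_s > 0) {
    thr_s <- med_s + params$peak_thresh_mad * mad_s
    runs <- true_runs(env_s > thr_s)
    min_n <- round(params$min_sine_s * fs)
    runs <- runs[runs$end - runs$start + 1L >= min_n, , drop = FALSE]
    if (nrow(runs)) {
      sines <- purrr::pmap_dfr(runs, function(start, end) {
        seg <- wave[start:end]
        pg <- stats::spec.pgram(seg, taper = 0, detrend = TRUE, plot = FALSE)
        f <- pg$freq * fs
        fdom <- f[which.max(pg$spec)]
        if (fdom < params$sine_band_hz[1] || fdom > params$sine_band_hz[2])
          return(tibble())
        tibble(start_s = (start - 1) / fs, end_s = (end - 1) / fs,
               duration_s = (end - start) / fs, freq_hz = fdom)
      })
      if (nrow(sines) == 0) sines <- empty$sines
    }
  }

  structure(list(pulses = tibble(time_s = pulse_t), bouts = bouts,
                 sines = sines, sample_rate = fs),
            class = "song_segmentation")
}

#' @export
print.song_segmentation <- function(x, ...) {
  cat(sprintf("<song_segmentation> %d pulses in %d bout(s), %d sine segment(s)\n",
              nrow(x$pulses), nrow(x$bouts), nrow(x$sines)))
  invisible(x)
}

#' Compare song parameter distributions between two segmentations
#'
#' For each song parameter (pooled inter-pulse intervals, pulses per bout,
#' sine dominant frequency, sine duration) reports summary statistics, the
#' fraction of the two ranges that overlaps (intersection over union of the
#' observed ranges) and a two-sided Wilcoxon rank-sum p-value. Parameters
#' empty in either segmentation are flagged not comparable.
#'
#' @param a,b `song_segmentation` objects.
#' @return tibble with one row per parameter: `parameter`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `overlap_fraction`, `p_value`, `comparable`.
#' @export
compare_song_stats <- function(a, b) {
  get_par <- function(s) list(
    ipi_s = unlist(s$bouts$ipi_s) %||% numeric(0),
    pulses_per_bout = as.numeric(s$bouts$n_pulses),
    sine_freq_hz = s$sines$freq_hz,
    sine_duration_s = s$sines$duration_s)
  pa <- get_par(a); pb <- get_par(b)
  purrr::map_dfr(names(pa), function(nm) {
    xa <- pa[[nm]]; xb <- pb[[nm]]
    if (length(xa) == 0 || length(xb) == 0)
      return(tibble(parameter = nm, n_a = length(xa), n_b = length(xb),
                    mean_a = NA_real_, mean_b = NA_real_,
                    overlap_fraction = NA_real_, p_value = NA_real_,
                    comparable = FALSE))
    ra <- range(xa); rb <- range(xb)
    inter <- max(0, min(ra[2], rb[2]) - max(ra[1], rb[1]))
    uni <- max(ra[2], rb[2]) - min(ra[1], rb[1])
    ov <- if (uni > 0) inter / uni else as.numeric(inter >= 0)
    pv <- suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    tibble(parameter = nm, n_a = length(xa), n_b = length(xb),
           mean_a = mean(xa), mean_b = mean(xb),
           overlap_fraction = ov, p_value = pv, comparable = TRUE)
  })
}
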
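#' Read and write trajectory tables
#'
#' Fixed CSV dialect: comma separated, header row, UTF-8, '.' decimal;
#' columns `frame`, `time_s`, `fly_id`, `x_mm`, `y_mm`, `valid`. The round
#' trip is lossless for positions (within double representation), ids,
#' validity masks and the time axis.
#'
#' @param traj trajectory tibble.
#' @param path file path.
#' @return `read_trajectories()` returns the trajectory tibble;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(traj, path) {
  traj <- check_traj(traj)
  readr::write_csv(traj[, c("frame", "time_s", "fly_id", "x_mm", "y_mm", "valid")],
                   path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "time_s", "fly_id", "x_mm", "y_mm", "valid")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stopf("flycourt_parse", "trajectory file is missing column(s): %s",
          paste(miss, collapse = ", "))
  tr <- tr |> mutate(frame = as.integer(.data$frame),
                     fly_id = as.integer(.data$fly_id),
                     valid = as.logical(.data$valid))
  attr(tr, "frame_rate") <- traj_frame_rate(tr)
  tr
}

#' Read and write behavioural event tables
#'
#' CSV with columns `type` (or `behaviour`), `members`
#' (semicolon-separated ids, optional), `start_s`, `end_s`.
#'
#' @param events event tibble (list-column `members` is flattened).
#' @param path file path.
#' @export
write_events <- function(events, path) {
  ev <- as_tibble(events)
  if ("members" %in% names(ev) && is.list(ev$members))
    ev$members <- vapply(ev$members, paste, "", collapse = ";")
  readr::write_csv(ev, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("start_s", "end_s") %in% names(ev)))
    stopf("flycourt_parse", "event file is missing column(s): %s",
          paste(setdiff(c("start_s", "end_s"), names(ev)), collapse = ", "))
  if ("members" %in% names(ev) && is.character(ev$members))
    ev$members <- lapply(strsplit(ev$members, ";"), as.integer)
  ev
}

#' Minimal mono 16-bit PCM WAV input/output
#'
#' Reads and writes canonical RIFF/WAVE files with a single 16-bit PCM
#' channel — sufficient for arena microphone recordings and synthesized
#' song. Samples are scaled to [-1, 1].
#'
#' @param wave numeric vector in [-1, 1] (clipped if outside).
#' @param sample_rate sampling rate in Hz.
#' @param path file path.
#' @return `read_wav()` returns a list `wave`, `sample_rate`;
#'   `write_wav()` returns `path` invisibly.
#' @export
write_wav <- function(wave, sample_rate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wavefmt <- readChar(con, 8)
  if (riff != "RIFF" || wavefmt != "WAVEfmt ")
    stopf("flycourt_parse", "not a canonical RIFF/WAVE file")
  fmt_len <- readBin(con, "integer", 1, 4, endian = "little")
  fmt <- readBin(con, "integer", 1, 2, endian = "little")
  n_chan <- readBin(con, "integer", 1, 2, endian = "little")
  fs <- readBin(con, "integer", 1, 4, endian = "little")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  invisible(readBin(con, "integer", 1, 2, endian = "little"))
  bits <- readBin(con, "integer", 1, 2, endian = "little")
  if (fmt_len > 16) invisible(readBin(con, "raw", fmt_len - 16))
  if (fmt != 1L || n_chan != 1L || bits != 16L)
    stopf("flycourt_parse", "only mono 16-bit PCM WAV is supported")
  tag <- readChar(con, 4)
  dlen <- readBin(con, "integer", 1, 4, endian = "little")
  while (tag != "data") {
    invisible(readBin(con, "raw", dlen))
    tag <- readChar(con, 4)
    dlen <- readBin(con, "integer", 1, 4, endian = "little")
  }
  pcm <- readBin(con, "integer", dlen / 2, 2, signed = TRUE, endian = "little")
  list(wave = pcm / 32767, sample_rate = fs)
}

#' Write a grayscale frame sequence as PNG files
#'
#' @param frames list of matrices in [0, 1].
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @return invisibly, the written paths.
#' @export
write_frames_png <- function(frames, dir, prefix = "frame") {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("flycourt_input", "the 'png' package is required to write PNG frames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- names(frames) %||% as.character(seq_along(frames) - 1L)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix, as.integer(nm)))
  purrr::walk2(frames, paths, function(fm, p) png::writePNG(fm, p))
  invisible(paths)
}

#' Write a provenance manifest for a pipeline run
#'
#' Records the configuration (echoed verbatim), a content hash of the
#' configuration, the seed, and package/R versions. Timestamps are kept
#' out of the hashed content so reproducibility checks can be byte-exact.
#'
#' @param path output JSON path.
#' @param config named list of configuration values.
#' @param seed integer seed of the run.
#' @return invisibly, the manifest list.
#' @export
write_manifest <- function(path, config, seed) {
  hashable <- list(config = config, seed = seed)
  manifest <- list(
    config = config, seed = seed,
    config_hash = rlang::hash(hashable),
    package_version = as.character(utils::packageVersion("flycourt")),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
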
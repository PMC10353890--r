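#' Temporal background model
#'
#' Per-pixel high quantile (default 0.9) over an initial block of frames;
#' flies are darker than the background, so a high quantile recovers the
#' background level even under pixels where a fly dwells for most of the
#' block (a plain temporal median is corrupted once a fly sits still for
#' more than half of it). The per-pixel MAD around that level feeds the
#' detection threshold.
#'
#' @param frames list of grayscale matrices (as from [render_frames()]).
#' @param n_frames number of leading frames to use (default up to 100).
#' @param prob background quantile.
#' @return list with matrices `med` and `mad`.
#' @export
build_background <- function(frames, n_frames = 100, prob = 0.9) {
  use <- frames[seq_len(min(n_frames, length(frames)))]
  arr <- array(unlist(use), dim = c(dim(use[[1]]), length(use)))
  med <- apply(arr, c(1, 2), stats::quantile, probs = prob, names = FALSE)
  madm <- apply(arr, c(1, 2), stats::mad)
  # cap at a multiple of the typical noise level: under pixels where a fly
  # dwelt, the raw MAD reflects the fly, not the sensor noise
  madm <- pmin(madm, 3 * stats::median(madm))
  list(med = med, mad = madm)
}

roi_mask <- function(arena, roi = 1) {
  dims <- arena$dim_px
  cx <- arena$roi_centres_px[roi, 1]; cy <- arena$roi_centres_px[roi, 2]
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  sqrt((cc - cx)^2 + (rr - cy)^2) <= arena$roi_radius_px + 1
}

#' Detect fly blobs in one frame
#'
#' Thresholds pixels darker than the background model (median minus three
#' MADs, with a minimum contrast floor), labels connected components inside
#' the ROI, filters them by area, and reports blob centroids. When fewer
#' blobs than `expected_n` are found, the largest blobs are treated as
#' merged-fly candidates and split by 2-means on their pixel coordinates
#' until the expected count is reached (or no blob is large enough to
#' split); split centroids are flagged `merged`.
#'
#' @param frame grayscale matrix.
#' @param arena an [arena_config()].
#' @param expected_n expected number of flies in the ROI.
#' @param background background model from [build_background()]; if NULL a
#'   flat background at the frame's upper quartile is assumed.
#' @param roi which ROI to process.
#' @param min_area_mm2 smallest blob area kept, in mm^2.
#' @param min_contrast minimum threshold offset below the background.
#' @return tibble with columns `x_px`, `y_px` (centroid, col/row pixel
#'   coordinates), `area_px`, `merged`.
#' @export
detect_flies <- function(frame, arena, expected_n = 8, background = NULL,
                         roi = 1, min_area_mm2 = 0.3, min_contrast = 0.15) {
  dims <- arena$dim_px
  if (nrow(frame) < dims[1] || ncol(frame) < dims[2])
    stopf("flycourt_geometry", "frame (%d x %d) smaller than arena extent (%d x %d)",
          nrow(frame), ncol(frame), dims[1], dims[2])
  if (is.null(background)) {
    bg <- matrix(stats::quantile(frame, 0.75), nrow(frame), ncol(frame))
    bgmad <- matrix(0, nrow(frame), ncol(frame))
  } else {
    bg <- background$med; bgmad <- background$mad
  }
  thr <- bg - pmax(3 * bgmad, min_contrast)
  bw <- (frame < thr) & roi_mask(arena, roi)
  lab <- EBImage::bwlabel(bw)
  n_lab <- max(lab)
  if (n_lab == 0)
    return(tibble(x_px = numeric(), y_px = numeric(),
                  area_px = numeric(), merged = logical()))
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  area <- tabulate(labs, n_lab)
  cx <- tapply(cols, labs, mean)
  cy <- tapply(rows, labs, mean)
  min_area_px <- min_area_mm2 / arena$mm_per_px^2
  keep <- which(area >= min_area_px)
  dets <- tibble(x_px = as.numeric(cx[as.character(keep)]),
                 y_px = as.numeric(cy[as.character(keep)]),
                 area_px = as.numeric(area[keep]), merged = FALSE)
  # split merged blobs until the expected count is reached
  pix <- lapply(keep, function(l) cbind(cols[labs == l], rows[labs == l]))
  med_area <- stats::median(dets$area_px)
  while (nrow(dets) < expected_n && nrow(dets) > 0) {
    big <- which.max(dets$area_px)
    # candidate must be large in absolute terms and not clearly a single fly
    if (dets$area_px[big] < 0.7 * med_area || dets$area_px[big] < 2 * min_area_px) break
    sp <- split_blob(pix[[big]])
    if (is.null(sp)) break
    halves <- tibble(x_px = c(sp$centers[1, 1], sp$centers[2, 1]),
                     y_px = c(sp$centers[1, 2], sp$centers[2, 2]),
                     area_px = as.numeric(sp$sizes), merged = TRUE)
    pix <- c(pix[-big], sp$parts)
    dets <- bind_rows(dets[-big, ], halves)
  }
  dets
}

# deterministic 2-means on blob pixels: principal-axis bisection followed
# by Lloyd iterations (no random initialisation, so detection is a pure
# function of the frame)
split_blob <- function(pts, iter = 10) {
  if (nrow(pts) < 4) return(NULL)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  ev <- eigen(stats::cov(cen), symmetric = TRUE)$vectors[, 1]
  proj <- cen %*% ev
  grp <- as.integer(proj > stats::median(proj)) + 1L
  if (length(unique(grp)) < 2) return(NULL)
  for (k in seq_len(iter)) {
    c1 <- colMeans(pts[grp == 1L, , drop = FALSE])
    c2 <- colMeans(pts[grp == 2L, , drop = FALSE])
    d1 <- (pts[, 1] - c1[1])^2 + (pts[, 2] - c1[2])^2
    d2 <- (pts[, 1] - c2[1])^2 + (pts[, 2] - c2[2])^2
    new_grp <- ifelse(d1 <= d2, 1L, 2L)
    if (all(new_grp == grp)) break
    if (length(unique(new_grp)) < 2) break
    grp <- new_grp
  }
  list(centers = rbind(colMeans(pts[grp == 1L, , drop = FALSE]),
                       colMeans(pts[grp == 2L, , drop = FALSE])),
       sizes = c(sum(grp == 1L), sum(grp == 2L)),
       parts = split.data.frame(pts, grp))
}

#' Detect flies across a frame sequence
#'
#' Convenience wrapper: builds the temporal-median background from the
#' leading frames, then runs [detect_flies()] on every frame.
#'
#' @inheritParams detect_flies
#' @param frames named list of grayscale matrices (names = frame numbers).
#' @return tibble with columns `frame`, `x_px`, `y_px`, `area_px`, `merged`.
#' @export
detect_frames <- function(frames, arena, expected_n = 8, roi = 1, ...) {
  bg <- build_background(frames)
  fnum <- as.integer(names(frames) %||% (seq_along(frames) - 1L))
  purrr::map2_dfr(frames, fnum, function(fm, f) {
    d <- detect_flies(fm, arena, expected_n, background = bg, roi = roi, ...)
    if (nrow(d)) d$frame <- f else d$frame <- integer(0)
    d
  }) |> select("frame", dplyr::everything())
}

#' Link per-frame detections into identity-resolved trajectories
#'
#' Frame-to-frame identities are assigned by minimum total centroid
#' displacement (optimal bipartite assignment) with a hard gate at the
#' maximum plausible per-frame displacement. Tracks with no detection in a
#' frame coast at their last position (marked invalid) for up to
#' `coast_frames` frames, after which they may be re-acquired by any
#' unclaimed detection regardless of the gate. Output positions are in mm
#' relative to the ROI centre (x right, y up).
#'
#' @param dets detection table (`frame`, `x_px`, `y_px`) as from
#'   [detect_frames()].
#' @param arena an [arena_config()].
#' @param n_flies number of identities to maintain; default: the modal
#'   per-frame detection count.
#' @param max_speed_mm_s gating speed — per-frame displacements above
#'   `max_speed_mm_s / frame_rate` are forbidden pairings.
#' @param coast_frames frames a lost identity coasts before the gate is
#'   lifted.
#' @param roi ROI index used for the mm conversion.
#' @return trajectory tibble (`frame`, `time_s`, `fly_id`, `x_mm`, `y_mm`,
#'   `valid`).
#' @export
link_identities <- function(dets, arena, n_flies = NULL,
                            max_speed_mm_s = 50, coast_frames = 5, roi = 1) {
  if (nrow(dets) == 0) stopf("flycourt_input", "no detections to link")
  frames <- sort(unique(dets$frame))
  if (length(frames) < 2) stopf("flycourt_input", "need detections for >= 2 frames")
  counts <- dets |> dplyr::count(.data$frame)
  if (is.null(n_flies)) {
    tab <- table(counts$n)
    n_flies <- as.integer(names(tab)[which.max(tab)])
  }
  gate_px <- (max_speed_mm_s / arena$frame_rate) / arena$mm_per_px
  by_frame <- split(dets[, c("x_px", "y_px")], dets$frame)

  # initialise from the first frame with the full complement
  first_full <- which(vapply(by_frame, nrow, 0L) >= n_flies)[1]
  if (is.na(first_full)) first_full <- 1L
  init <- as.matrix(by_frame[[first_full]])[seq_len(min(n_flies, nrow(by_frame[[first_full]]))), , drop = FALSE]
  pos <- matrix(NA_real_, n_flies, 2)
  pos[seq_len(nrow(init)), ] <- init
  vel <- matrix(0, n_flies, 2)     # smoothed px/frame, for constant-velocity prediction
  miss <- rep(0L, n_flies)

  nF <- length(frames)
  out_x <- matrix(NA_real_, nF, n_flies)
  out_y <- matrix(NA_real_, nF, n_flies)
  out_v <- matrix(FALSE, nF, n_flies)

  for (fi in seq_len(nF)) {
    d <- as.matrix(by_frame[[fi]])
    nd <- nrow(d)
    m <- max(n_flies, nd)
    open_gate <- is.na(pos[, 1]) | miss > coast_frames
    # square cost with dummy rows/cols at 2x gate: a track pairs with a
    # dummy (stays unmatched) rather than accept a beyond-gate detection
    cost <- matrix(gate_px * 2, m, m)
    if (nd > 0) {
      for (i in seq_len(n_flies)) {
        if (is.na(pos[i, 1])) {
          cost[i, seq_len(nd)] <- gate_px       # unseeded track: take anything
        } else {
          pred <- pos[i, ] + vel[i, ]
          dd <- sqrt((d[, 1] - pred[1])^2 + (d[, 2] - pred[2])^2)
          if (open_gate[i]) {
            # gate lifted: compress distances below the gate, keeping order,
            # so a far detection is still preferred over staying lost
            dd <- gate_px * dd / (max(dd) + 1)
          } else {
            dd[dd > gate_px] <- gate_px * 4
          }
          cost[i, seq_len(nd)] <- dd
        }
      }
    }
    asg <- solve_assignment(cost)
    for (i in seq_len(n_flies)) {
      j <- asg[i]
      matched <- nd > 0 && j <= nd &&
        (cost[i, j] <= gate_px * 1.0005 || open_gate[i])
      if (matched) {
        if (!is.na(pos[i, 1]) && fi > 1L)
          vel[i, ] <- 0.6 * vel[i, ] + 0.4 * (d[j, ] - pos[i, ])
        pos[i, ] <- d[j, ]
        miss[i] <- 0L
        out_x[fi, i] <- d[j, 1]; out_y[fi, i] <- d[j, 2]; out_v[fi, i] <- TRUE
      } else {
        miss[i] <- miss[i] + 1L
        vel[i, ] <- vel[i, ] * 0.8
        out_x[fi, i] <- pos[i, 1]; out_y[fi, i] <- pos[i, 2]
      }
    }
  }

  cx <- arena$roi_centres_px[roi, 1]; cy <- arena$roi_centres_px[roi, 2]
  traj <- tibble(
    frame = rep(frames, times = n_flies),
    time_s = rep(frames, times = n_flies) / arena$frame_rate,
    fly_id = rep(seq_len(n_flies), each = nF),
    x_mm = (as.vector(out_x) - cx) * arena$mm_per_px,
    y_mm = (cy - as.vector(out_y)) * arena$mm_per_px,
    valid = as.vector(out_v))
  attr(traj, "frame_rate") <- arena$frame_rate
  traj
}

#' Calibrate the image scale from the arena outline
#'
#' Locates dark pixels (below the midpoint of the image intensity range)
#' and takes the larger of their horizontal and vertical extents as the
#' arena diameter in pixels.
#'
#' @param image grayscale matrix showing the circular arena boundary or
#'   disc darker than the background.
#' @param known_diameter_mm the physical arena diameter (26 mm in the
#'   standard plate).
#' @return the scale in mm per pixel.
#' @export
calibrate_scale <- function(image, known_diameter_mm = 26) {
  thr <- (max(image) + min(image)) / 2
  idx <- which(image < thr)
  if (length(idx) < 10) stopf("flycourt_calibration", "no arena circle found in image")
  rows <- (idx - 1) %% nrow(image) + 1
  cols <- (idx - 1) %/% nrow(image) + 1
  d_px <- max(max(cols) - min(cols), max(rows) - min(rows))
  if (d_px <= 0) stopf("flycourt_calibration", "degenerate arena extent")
  known_diameter_mm / d_px
}
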
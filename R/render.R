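#' Render trajectory frames as grayscale images
#'
#' Projects centroid trajectories into synthetic video frames: a light
#' background with one dark elliptical blob per fly, oriented along the
#' fly's displacement heading. Intended as a controllable fixture for the
#' detection/linking stage; not a photorealistic rendering.
#'
#' Pixel convention: images are matrices indexed `[row, col]`; a point at
#' `(x_mm, y_mm)` relative to the ROI centre maps to
#' `col = cx + x_mm / mm_per_px`, `row = cy - y_mm / mm_per_px` (y up).
#'
#' @param traj trajectory table (`frame`, `time_s`, `fly_id`, `x_mm`,
#'   `y_mm`); positions relative to the ROI centre.
#' @param arena an [arena_config()]; its first ROI is used.
#' @param frames which frame numbers to render (default all).
#' @param blob_length_mm,blob_width_mm blob ellipse axes (a fly body is
#'   roughly 2.5 x 1.2 mm).
#' @param fly_value,bg_value blob and background gray levels in [0, 1].
#' @param noise_sd per-pixel Gaussian noise standard deviation.
#' @param draw_arena if TRUE, draw the ROI boundary as a dark circle
#'   (useful for scale calibration).
#' @param seed optional seed for the pixel noise.
#' @return a list of numeric matrices in [0, 1], one per rendered frame,
#'   named by frame number, with the `arena_config` attached as attribute
#'   `arena`.
#' @export
render_frames <- function(traj, arena = arena_config(), frames = NULL,
                          blob_length_mm = 2.5, blob_width_mm = 1.2,
                          fly_value = 0.15, bg_value = 1.0,
                          noise_sd = 0.02, draw_arena = FALSE, seed = NULL) {
  if (arena$mm_per_px <= 0) stopf("flycourt_input", "mm_per_px must be positive")
  traj <- check_traj(traj)
  if (is.null(frames)) frames <- sort(unique(traj$frame))
  scale <- arena$mm_per_px
  cx <- arena$roi_centres_px[1, 1]
  cy <- arena$roi_centres_px[1, 2]
  dims <- arena$dim_px
  a_px <- (blob_length_mm / 2) / scale
  b_px <- (blob_width_mm / 2) / scale
  pad <- ceiling(a_px) + 1L

  w <- traj_wide(traj)
  mo <- traj_motion(w)

  base <- matrix(bg_value, dims[1], dims[2])
  if (draw_arena) {
    rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
    cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
    dcent <- sqrt((cc - cx)^2 + (rr - cy)^2)
    base[abs(dcent - arena$roi_radius_px) <= 1] <- fly_value
  }

  render_one <- function(f) {
    ti <- match(f, w$frames)
    img <- base
    if (!is.na(ti)) {
      for (j in seq_along(w$fly_ids)) {
        if (!w$V[ti, j]) next
        px <- cx + w$X[ti, j] / scale
        py <- cy - w$Y[ti, j] / scale
        # heading of the most recent displacement (0 when unknown)
        th <- mo$heading[ti, j]
        if (is.na(th) && ti < nrow(w$X)) th <- mo$heading[ti + 1L, j]
        if (is.na(th)) th <- 0
        th <- -th  # y axis is flipped in pixel space
        r0 <- max(1L, floor(py - pad)); r1 <- min(dims[1], ceiling(py + pad))
        c0 <- max(1L, floor(px - pad)); c1 <- min(dims[2], ceiling(px + pad))
        if (r0 > r1 || c0 > c1) next
        rs <- r0:r1; cs <- c0:c1
        dr <- matrix(rs - py, length(rs), length(cs))
        dc <- matrix(cs - px, length(rs), length(cs), byrow = TRUE)
        u <- dc * cos(th) + dr * sin(th)
        v <- -dc * sin(th) + dr * cos(th)
        inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
        sub <- img[rs, cs, drop = FALSE]
        sub[inside] <- fly_value
        img[rs, cs] <- sub
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
      img[img < 0] <- 0; img[img > 1] <- 1
    }
    img
  }

  run <- function() setNames(lapply(frames, render_one), frames)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "arena") <- arena
  out
}
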
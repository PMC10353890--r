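arena_01 <- arena_config(mm_per_px = 0.1, frame_rate = fr_default)

test_that("a rendered fly at the arena centre is detected within one pixel", {
  tr <- traj_from_xy(matrix(0, 5, 1), matrix(0, 5, 1))
  frames <- render_frames(tr, arena_01, noise_sd = 0)
  d <- detect_flies(frames[[1]], arena_01, expected_n = 1)
  expect_identical(nrow(d), 1L)
  expect_lt(abs(d$x_px - arena_01$roi_centres_px[1, 1]), 1)
  expect_lt(abs(d$y_px - arena_01$roi_centres_px[1, 2]), 1)
})

test_that("a blank frame yields zero detections without error", {
  blank <- matrix(1, arena_01$dim_px[1], arena_01$dim_px[2])
  d <- detect_flies(blank, arena_01, expected_n = 8)
  expect_identical(nrow(d), 0L)
})

test_that("eight well-separated flies render as exactly eight blobs", {
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  X <- matrix(8 * cos(th), 1, 8, byrow = TRUE)
  Y <- matrix(8 * sin(th), 1, 8, byrow = TRUE)
  tr <- traj_from_xy(X[rep(1, 3), ], Y[rep(1, 3), ])
  frames <- render_frames(tr, arena_01, noise_sd = 0)
  d <- detect_flies(frames[[1]], arena_01, expected_n = 8)
  expect_identical(nrow(d), 8L)
  expect_false(any(d$merged))
})

test_that("two flies rendered at sub-resolution separation are split and flagged", {
  X <- cbind(rep(-0.5, 3), rep(0.5, 3))   # 1 mm apart, blobs overlap
  tr <- traj_from_xy(X, matrix(0, 3, 2))
  frames <- render_frames(tr, arena_01, noise_sd = 0)
  d <- detect_flies(frames[[1]], arena_01, expected_n = 2)
  expect_identical(nrow(d), 2L)
  expect_true(any(d$merged))
})

test_that("frames smaller than the arena extent raise a geometry error", {
  expect_error(detect_flies(matrix(1, 10, 10), arena_01, 1),
               class = "flycourt_geometry")
})

test_that("scale calibration recovers mm per pixel from the arena outline", {
  draw_circle <- function(d_px, pad = 20) {
    n <- d_px + 2 * pad
    img <- matrix(1, n, n)
    ctr <- (n + 1) / 2
    rr <- matrix(seq_len(n), n, n); cc <- t(rr)
    ring <- abs(sqrt((rr - ctr)^2 + (cc - ctr)^2) - d_px / 2) <= 0.5
    img[ring] <- 0
    img
  }
  expect_equal(calibrate_scale(draw_circle(260), 26), 0.1, tolerance = 0.01)
  expect_equal(calibrate_scale(draw_circle(520), 26), 0.05, tolerance = 0.01)
  # round trip through the renderer's arena outline
  tr <- traj_from_xy(matrix(0, 1, 1), matrix(0, 1, 1))
  fr <- render_frames(tr, arena_01, frames = 0, noise_sd = 0,
                      draw_arena = TRUE, fly_value = 0)
  fr[[1]][fr[[1]] < 0.5 &
            abs(row(fr[[1]]) - arena_01$roi_centres_px[1, 2]) < 20 &
            abs(col(fr[[1]]) - arena_01$roi_centres_px[1, 1]) < 20] <- 1  # erase the fly
  expect_equal(calibrate_scale(fr[[1]], 26), 0.1, tolerance = 0.02)
  expect_error(calibrate_scale(matrix(1, 50, 50), 26),
               class = "flycourt_calibration")
})

test_that("two flies on parallel non-crossing lines keep constant identities", {
  n <- 100
  cx <- arena_01$roi_centres_px[1, 1]; cy <- arena_01$roi_centres_px[1, 2]
  dets <- tibble::tibble(
    frame = rep(0:(n - 1), each = 2),
    x_px = rep(cx - 50, 2 * n) + rep(0:(n - 1), each = 2),
    y_px = rep(c(cy - 50, cy + 50), n))
  tr <- link_identities(dets, arena_01, n_flies = 2)
  expect_identical(nrow(tr), 200L)
  y1 <- tr$y_mm[tr$fly_id == 1]
  expect_true(all(y1 == y1[1]))           # no swap: y stays on one line
  expect_true(all(tr$valid))
})

test_that("a single fly's linked trajectory equals its detections in mm", {
  n <- 50
  cx <- arena_01$roi_centres_px[1, 1]; cy <- arena_01$roi_centres_px[1, 2]
  dets <- tibble::tibble(frame = 0:(n - 1),
                         x_px = cx + (0:(n - 1)) * 0.5,
                         y_px = cy - (0:(n - 1)) * 0.25)
  tr <- link_identities(dets, arena_01, n_flies = 1)
  expect_equal(tr$x_mm, (0:(n - 1)) * 0.5 * 0.1)
  expect_equal(tr$y_mm, (0:(n - 1)) * 0.25 * 0.1)
})

test_that("shuffling detection order within frames leaves linking unchanged", {
  withr::with_seed(11, {
    sim <- simulate_arena(sim_params(seed = 31, protocol =
      light_protocol("high", 10, 18)))
    ar <- arena_01
    cx <- ar$roi_centres_px[1, 1]; cy <- ar$roi_centres_px[1, 2]
    dets <- dplyr::transmute(sim$trajectories,
                             frame = frame,
                             x_px = cx + x_mm / 0.1,
                             y_px = cy - y_mm / 0.1)
    shuf <- dets[sample(nrow(dets)), ]
    shuf <- shuf[order(shuf$frame), ]
    a <- link_identities(dets, ar, n_flies = 8)
    b <- link_identities(shuf, ar, n_flies = 8)
    # trajectories agree up to a permutation of the track labels
    cols <- c("frame", "x_mm", "y_mm", "valid")
    expect_equal(dplyr::arrange(a[, cols], frame, x_mm, y_mm),
                 dplyr::arrange(b[, cols], frame, x_mm, y_mm))
  })
})

test_that("linking refuses empty or single-frame input", {
  expect_error(link_identities(tibble::tibble(frame = integer(),
                                              x_px = numeric(),
                                              y_px = numeric()),
                               arena_01), class = "flycourt_input")
  expect_error(link_identities(tibble::tibble(frame = 0L, x_px = 1,
                                              y_px = 1), arena_01),
               class = "flycourt_input")
})
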
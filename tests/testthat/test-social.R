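test_that("coincident flies always interact; the 3.75 mm boundary is strict", {
  ig0 <- compute_interactogram(make_pair_traj(0))
  expect_true(all(ig0$in_proximity))
  ig_at <- compute_interactogram(make_pair_traj(3.75))
  expect_false(any(ig_at$in_proximity))
  ig_in <- compute_interactogram(make_pair_traj(3.749))
  expect_true(all(ig_in$in_proximity))
})

test_that("interactogram equals the brute-force oracle on random instances", {
  withr::with_seed(19, {
    for (rep in 1:10) {
      tr <- random_traj(n_flies = sample(3:6, 1), n_frames = 40)
      ig <- compute_interactogram(tr)
      bf <- brute_force_interactogram(tr)
      got <- dplyr::arrange(tibble::as_tibble(ig)[, c("frame", "fly_a", "fly_b", "in_proximity")],
                            fly_a, fly_b, frame)
      want <- dplyr::arrange(bf, fly_a, fly_b, frame)
      expect_identical(got$fly_a, want$fly_a)
      expect_identical(got$frame, want$frame)
      expect_identical(got$in_proximity, want$in_proximity)
    }
  })
})

test_that("masked (invalid) frames never register proximity", {
  tr <- make_pair_traj(1, n_frames = 10)
  tr$valid[tr$fly_id == 1 & tr$frame < 5] <- FALSE
  ig <- compute_interactogram(tr)
  expect_false(any(ig$in_proximity[ig$frame < 5]))
  expect_true(all(ig$in_proximity[ig$frame >= 5]))
})

test_that("enlarging the proximity criterion never removes a true entry", {
  withr::with_seed(23, {
    tr <- random_traj(5, 60)
    small <- compute_interactogram(tr, interaction_params(proximity_mm = 2.5))
    large <- compute_interactogram(tr, interaction_params(proximity_mm = 5))
    expect_true(all(large$in_proximity[small$in_proximity]))
  })
})

test_that("a sustained pursuit is detected as one chase with correct roles", {
  # chaser trails 2 mm behind its target; both move at 5 mm/s for 3 s
  n <- 45
  X <- cbind((0:(n - 1)) / fr_default * 5,        # target ahead
             (0:(n - 1)) / fr_default * 5 - 2)    # chaser behind
  tr <- traj_from_xy(X, matrix(0, n, 2))
  ch <- detect_chases(tr)
  expect_identical(nrow(ch), 1L)
  expect_identical(ch$chaser, 2L)
  expect_identical(ch$target, 1L)
  expect_gte(ch$duration_s, 1)
})

test_that("stationary proximity and sub-threshold runs yield no chases", {
  expect_identical(nrow(detect_chases(make_pair_traj(1))), 0L)
  # moving pursuit but only 0.5 s long: below the duration criterion
  n <- 45
  prox <- c(rep(8, 15), rep(0, 8), rep(8, 22))     # in range for 8 frames only
  X <- cbind((0:(n - 1)) / fr_default * 5,
             (0:(n - 1)) / fr_default * 5 - 2 - prox)
  tr <- traj_from_xy(X, matrix(0, n, 2))
  expect_identical(nrow(detect_chases(tr)), 0L)
})

test_that("a moving follow-line of four is a chain; three is not", {
  ch4 <- detect_chains(make_line_traj(4))
  expect_identical(nrow(ch4), 1L)
  expect_setequal(ch4$members[[1]], 1:4)
  expect_gte(ch4$mean_speed_mm_s, 2)
  expect_identical(nrow(detect_chains(make_line_traj(3))), 0L)
})

test_that("a stationary five-fly cluster fails the mobility criterion", {
  th <- seq(0, 2 * pi, length.out = 6)[1:5]
  X <- matrix(1.5 * cos(th), 30, 5, byrow = TRUE)
  Y <- matrix(1.5 * sin(th), 30, 5, byrow = TRUE)
  tr <- traj_from_xy(X, Y)
  ig <- compute_interactogram(tr)
  expect_true(any(ig$in_proximity))
  expect_identical(nrow(detect_chains(tr, ig)), 0L)
})

test_that("chase and chain detectors recover simulated ground truth", {
  # pooled event-level recall/precision over fixed seeds
  stats <- lapply(c(3, 11, 42), function(s) {
    sim <- simulate_arena(sim_params(seed = s))
    tr <- sim$trajectories
    ig <- compute_interactogram(tr)
    ch <- detect_chases(tr, ig)
    cn <- detect_chains(tr, ig)
    truth4 <- dplyr::mutate(
      dplyr::filter(sim$truth$chains, size >= 4),
      start_frame = start4_frame)
    list(ch = match_events(ch, sim$truth$chases, keys = c("chaser", "target")),
         cn = match_events(cn, truth4))
  })
  pool <- function(get_n, get_rate, which) {
    num <- sum(sapply(stats, function(s) {
      m <- s[[which]]
      r <- get_rate(m)
      if (is.na(r)) 0 else r * get_n(m)
    }))
    den <- sum(sapply(stats, function(s) get_n(s[[which]])))
    num / den
  }
  chase_recall <- pool(function(m) m$n_truth, function(m) m$recall, "ch")
  chase_prec <- pool(function(m) m$n_detected, function(m) m$precision, "ch")
  chain_recall <- pool(function(m) m$n_truth, function(m) m$recall, "cn")
  chain_prec <- pool(function(m) m$n_detected, function(m) m$precision, "cn")
  expect_gte(chase_recall, 0.9)
  expect_gte(chase_prec, 0.8)
  expect_gte(chain_recall, 0.9)
  expect_gte(chain_prec, 0.8)
})

test_that("interactogram figure has one band per fly and symmetric segments", {
  tr <- make_pair_traj(1, n_frames = 21)
  tr2 <- make_pair_traj(10, n_frames = 21)
  ig <- compute_interactogram(tr)
  p <- ggplot2::ggplot_build(autoplot(ig))
  expect_s3_class(p$plot, "ggplot")
  # all-false interactogram draws only the background bands
  ig_empty <- compute_interactogram(tr2)
  p2 <- ggplot2::ggplot_build(autoplot(ig_empty))
  expect_identical(length(p2$data), 1L)
})
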
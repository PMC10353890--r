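short_protocol <- light_protocol(c("low", "high"), c(20, 20), c(0.4, 18))

test_that("identical seeds reproduce the simulation bit for bit; seeds differ", {
  a <- simulate_arena(sim_params(seed = 7, protocol = short_protocol))
  b <- simulate_arena(sim_params(seed = 7, protocol = short_protocol))
  c <- simulate_arena(sim_params(seed = 8, protocol = short_protocol))
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$trajectories$x_mm, c$trajectories$x_mm))
})

test_that("positions stay confined to the arena disc at every frame", {
  for (s in c(1, 2, 3)) {
    sim <- simulate_arena(sim_params(seed = s, protocol = short_protocol))
    r <- with(sim$trajectories, sqrt(x_mm^2 + y_mm^2))
    expect_lte(max(r), 13.0)
  }
})

test_that("every fly covers every frame of the schedule", {
  sim <- simulate_arena(sim_params(seed = 2, protocol = short_protocol))
  tab <- table(sim$trajectories$fly_id)
  expect_true(all(tab == round(40 * 15)))
  expect_false(anyNA(sim$trajectories$x_mm))
})

test_that("a zero chase rate produces no chase and no chain events", {
  sim <- simulate_arena(sim_params(seed = 4, chase_rate = 0,
                                   protocol = short_protocol))
  expect_identical(nrow(sim$truth$chases), 0L)
  expect_identical(nrow(sim$truth$chains), 0L)
})

test_that("ground-truth event frames lie inside the simulated span", {
  sim <- simulate_arena(sim_params(seed = 5, protocol = short_protocol))
  nf <- round(40 * 15)
  ev <- sim$truth$chases
  expect_true(all(ev$start_frame >= 0 & ev$end_frame <= nf - 1))
  expect_true(all(ev$end_frame >= ev$start_frame))
  if (nrow(sim$truth$chains)) {
    expect_true(all(sim$truth$chains$size >= 2))
    expect_true(all(lengths(sim$truth$chains$members) ==
                      sim$truth$chains$size))
  }
})

test_that("mean chase count rises with light intensity over repeated seeds", {
  count_at <- function(klx, seeds) {
    sapply(seeds, function(s) {
      sim <- simulate_arena(sim_params(
        seed = s, protocol = light_protocol("x", 30, klx)))
      nrow(sim$truth$chases)
    })
  }
  lo <- count_at(0.4, 1:20)
  hi <- count_at(18, 1:20)
  expect_gt(mean(hi), mean(lo))
})

test_that("invalid simulator parameters are rejected", {
  expect_error(sim_params(n_flies = 0), class = "flycourt_input")
  expect_error(sim_params(arena_radius_mm = -1), class = "flycourt_input")
  expect_error(light_protocol("a", -5, 1), class = "flycourt_input")
  # decreasing dose-response curves are not allowed
  expect_error(sim_params(chase_rate = function(i) 1 / (i + 1)),
               class = "flycourt_input")
})

test_that("the default chase-rate curve is monotone with its rise in 2-6 klx", {
  grid <- c(0.1, 0.4, 1, 2, 4, 6, 10, 18, 50)
  r <- chase_rate_logistic(grid)
  expect_false(is.unsorted(r))
  rel <- diff(r) / head(r, -1)
  steep <- which.max(rel)
  expect_gte(grid[steep], 2)
  expect_lte(grid[steep + 1], 6)
})

test_that("song synthesis places pulse peaks at the specified spacing", {
  fs <- 10000
  au <- synthesize_song(pulse_bout(0.1, 10, 0.035), fs, 0.6)
  expect_identical(length(au$wave), as.integer(fs * 0.6))
  # locate the 10 largest well-separated local maxima of |wave|
  pk <- pracma::findpeaks(abs(au$wave), minpeakheight = 0.5,
                          minpeakdistance = round(0.02 * fs))
  pk_t <- sort((pk[, 2] - 1) / fs)
  expect_identical(length(pk_t), 10L)
  expect_true(all(abs(diff(pk_t) - 0.035) <= 1 / fs))
})

test_that("a synthesized sine element has its spectral peak at the carrier", {
  fs <- 10000
  au <- synthesize_song(sine_song(0.1, 0.5, 150), fs, 0.8)
  seg <- au$wave[round(0.15 * fs):round(0.55 * fs)]
  pg <- stats::spec.pgram(seg, taper = 0, plot = FALSE)
  fdom <- pg$freq[which.max(pg$spec)] * fs
  expect_lt(abs(fdom - 150), fs / length(seg) + 1e-9)
})

test_that("song element validation rejects overlap and out-of-range times", {
  expect_error(
    synthesize_song(rbind(pulse_bout(0.1, 5, 0.04), sine_song(0.2, 0.3, 150)),
                    10000, 1),
    class = "flycourt_overlap")
  expect_error(synthesize_song(sine_song(0.8, 0.5, 150), 10000, 1),
               class = "flycourt_range")
  au <- synthesize_song(NULL, 10000, 0.5)
  expect_true(all(au$wave == 0))
})
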
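# Fixtures are generated in code; no stored data files.

fr_default <- 15

# trajectory tibble from per-fly position matrices (frames x flies)
traj_from_xy <- function(X, Y, frame_rate = fr_default, valid = NULL) {
  nf <- nrow(X); ni <- ncol(X)
  if (is.null(valid)) valid <- matrix(TRUE, nf, ni)
  tr <- tibble::tibble(
    frame = rep(0:(nf - 1L), times = ni),
    time_s = rep(0:(nf - 1L), times = ni) / frame_rate,
    fly_id = rep(seq_len(ni), each = nf),
    x_mm = as.vector(X), y_mm = as.vector(Y), valid = as.vector(valid))
  attr(tr, "frame_rate") <- frame_rate
  tr
}

# k flies in a single-file line along x, spaced `spacing` mm, moving at
# `speed` mm/s for `duration_s`
make_line_traj <- function(k, spacing = 3, speed = 5, duration_s = 2,
                           frame_rate = fr_default) {
  nf <- round(duration_s * frame_rate)
  t_s <- (0:(nf - 1)) / frame_rate
  X <- outer(t_s * speed, -(seq_len(k) - 1) * spacing, `+`)
  Y <- matrix(0, nf, k)
  traj_from_xy(X, Y, frame_rate)
}

# two flies at a fixed centroid separation, stationary
make_pair_traj <- function(dist_mm, n_frames = 30, frame_rate = fr_default) {
  X <- cbind(rep(0, n_frames), rep(dist_mm, n_frames))
  Y <- matrix(0, n_frames, 2)
  traj_from_xy(X, Y, frame_rate)
}

# independent brute-force interactogram oracle: plain double loop over
# pairs and frames on the long table
brute_force_interactogram <- function(traj, proximity_mm = 3.75) {
  ids <- sort(unique(traj$fly_id))
  frames <- sort(unique(traj$frame))
  out <- list()
  for (ai in seq_along(ids)) for (bi in seq_along(ids)) {
    if (bi <= ai) next
    rows_a <- traj[traj$fly_id == ids[ai], ]
    rows_b <- traj[traj$fly_id == ids[bi], ]
    rows_a <- rows_a[order(rows_a$frame), ]
    rows_b <- rows_b[order(rows_b$frame), ]
    hit <- logical(length(frames))
    for (fi in seq_along(frames)) {
      d <- sqrt((rows_a$x_mm[fi] - rows_b$x_mm[fi])^2 +
                  (rows_a$y_mm[fi] - rows_b$y_mm[fi])^2)
      hit[fi] <- isTRUE(d < proximity_mm) &&
        rows_a$valid[fi] && rows_b$valid[fi]
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      frame = frames, fly_a = ids[ai], fly_b = ids[bi], in_proximity = hit)
  }
  dplyr::bind_rows(out)
}

# random trajectories of n flies inside the arena disc
random_traj <- function(n_flies, n_frames, radius = 13, frame_rate = fr_default) {
  r <- sqrt(matrix(runif(n_frames * n_flies), n_frames)) * radius
  th <- matrix(runif(n_frames * n_flies, 0, 2 * pi), n_frames)
  traj_from_xy(r * cos(th), r * sin(th), frame_rate)
}

# evaluate the simulate -> render -> detect -> link round trip on the
# first `n_frames` frames of a default simulation
roundtrip_eval <- function(seed, n_frames = 900) {
  sim <- simulate_arena(sim_params(seed = seed))
  tr <- dplyr::filter(sim$trajectories, frame < n_frames)
  ar <- arena_config(mm_per_px = 0.1, frame_rate = fr_default)
  frames <- render_frames(tr, ar, seed = seed + 1000)
  dets <- detect_frames(frames, ar, expected_n = 8)
  lk <- link_identities(dets, ar, n_flies = 8)

  L <- lk[order(lk$fly_id, lk$frame), ]
  T <- tr[order(tr$fly_id, tr$frame), ]
  n <- 8
  # global track correspondence by minimum mean distance
  cost <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- L[L$fly_id == i, ]; b <- T[T$fly_id == j, ]
    cost[i, j] <- mean(sqrt((a$x_mm - b$x_mm)^2 + (a$y_mm - b$y_mm)^2))
  }
  asg <- solve_assignment(cost)

  # per-frame distance of each true fly to its nearest true neighbour
  TX <- sapply(seq_len(n), function(j) T$x_mm[T$fly_id == j])
  TY <- sapply(seq_len(n), function(j) T$y_mm[T$fly_id == j])
  nn_sep <- sapply(seq_len(n), function(j) {
    dmin <- rep(Inf, nrow(TX))
    for (k in setdiff(seq_len(n), j))
      dmin <- pmin(dmin, sqrt((TX[, j] - TX[, k])^2 + (TY[, j] - TY[, k])^2))
    dmin
  })

  agree <- 0; tot <- 0; err_sep <- c()
  for (i in seq_len(n)) {
    a <- L[L$fly_id == i, ]
    dall <- sapply(seq_len(n), function(j) {
      b <- T[T$fly_id == j, ]
      sqrt((a$x_mm - b$x_mm)^2 + (a$y_mm - b$y_mm)^2)
    })
    nearest <- apply(dall, 1, which.min)
    agree <- agree + sum(nearest == asg[i]); tot <- tot + nrow(a)
    # position accuracy: distance to the nearest true fly, over detected
    # (valid) fly-frames where that fly is well separated (> 3 mm)
    dmin <- dall[cbind(seq_len(nrow(dall)), nearest)]
    sep <- nn_sep[cbind(seq_len(nrow(dall)), nearest)] > 3 & a$valid
    err_sep <- c(err_sep, dmin[sep])
  }
  list(agreement = agree / tot,
       rms_sep_mm = sqrt(mean(err_sep^2)),
       mm_per_px = ar$mm_per_px)
}
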
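#' Simulate a multi-fly arena under a light protocol
#'
#' Agent-based generator of centroid trajectories for a group of flies in a
#' circular arena, with light-dependent courtship chases and follow-line
#' chains, and a ground-truth event log against which detectors can be
#' validated. Undisturbed flies perform a correlated random walk with
#' intermittent pauses inside a reflecting circular boundary. At each frame
#' an unengaged fly may initiate a chase of its nearest free neighbour with
#' a per-second probability given by the light dose-response curve; during a
#' chase the pursuer steers towards its target with a capped turn rate,
#' holding a short following gap, while the target flees. An ongoing chase
#' may recruit further flies into a single-file follow-line (each recruit
#' steering at the line's tail), which is how chains of four or more
#' courting males arise at high light.
#'
#' @param params a [sim_params()] object.
#' @return a list of class `arena_sim` with elements
#'   \describe{
#'     \item{trajectories}{tibble `frame`, `time_s`, `fly_id`, `x_mm`,
#'       `y_mm`, `valid` (origin at the arena centre, x right, y up).}
#'     \item{truth}{list with tibbles `chases` (one row per pursuing pair:
#'       `chaser`, `target`, `start_frame`, `end_frame`) and `chains` (one
#'       row per follow-line that recruited at least one extra fly:
#'       list-column `members` in head-to-tail order, `size`,
#'       `start_frame`, `start4_frame` — the frame the line first reached
#'       four members, NA if it never did — and `end_frame`).}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' sim <- simulate_arena(sim_params(seed = 7, protocol =
#'   light_protocol("high", 30, 18)))
#' head(sim$trajectories)
#' @export
simulate_arena <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  withr::with_seed(params$seed, simulate_arena_impl(params))
}

simulate_arena_impl <- function(p) {
  fr <- p$frame_rate
  dt <- 1 / fr
  n <- p$n_flies
  total_s <- sum(p$protocol$duration_s)
  n_frames <- round(total_s * fr)
  time_s <- (seq_len(n_frames) - 1) * dt
  epoch_of <- findInterval(time_s, p$protocol$t_start)
  intensity <- p$protocol$intensity_klx[epoch_of]
  p_init <- p$chase_rate(p$protocol$intensity_klx)[epoch_of] * dt
  R <- p$arena_radius_mm

  # state
  r0 <- sqrt(runif(n)) * R * 0.85
  th0 <- runif(n, 0, 2 * pi)
  pos <- cbind(r0 * cos(th0), r0 * sin(th0))
  heading <- runif(n, 0, 2 * pi)
  mode <- rep("walk", n)          # walk | pause | chase | flee | follow
  pause_until <- rep(0L, n)
  engaged <- rep(0L, n)           # chase id or 0

  X <- matrix(NA_real_, n_frames, n)
  Y <- matrix(NA_real_, n_frames, n)
  X[1, ] <- pos[, 1]; Y[1, ] <- pos[, 2]

  chases <- list()                # active, keyed by as.character(id)
  next_id <- 1L
  chase_rows <- list()
  chain_rows <- list()
  max_turn <- 20 * dt             # rad per frame cap during pursuit

  close_chase <- function(ch, end_frame) {
    # one chase row per pursuing pair along the line
    line <- c(ch$target, ch$chaser, ch$followers)
    starts <- c(ch$start, ch$join_frames)
    for (k in 2:length(line)) {
      chase_rows[[length(chase_rows) + 1L]] <<- tibble(
        chaser = line[k], target = line[k - 1L],
        start_frame = starts[k - 1L], end_frame = end_frame)
    }
    if (length(ch$followers) >= 1) {
      chain_rows[[length(chain_rows) + 1L]] <<- tibble(
        members = list(line), size = length(line),
        start_frame = ch$join_frames[1L],
        start4_frame = if (length(line) >= 4) ch$join_frames[2L] else NA_integer_,
        end_frame = end_frame)
    }
  }

  for (t in seq_len(n_frames - 1L)) {
    # --- chase termination
    for (key in names(chases)) {
      ch <- chases[[key]]
      if (ch$end <= t) {
        members <- c(ch$target, ch$chaser, ch$followers)
        mode[members] <- "walk"
        engaged[members] <- 0L
        close_chase(ch, t)
        chases[[key]] <- NULL
      }
    }

    # --- chase initiation
    pi_t <- p_init[t]
    if (pi_t > 0 && n >= 2) {
      draws <- runif(n)
      for (i in seq_len(n)) {
        if (engaged[i] != 0L || draws[i] >= pi_t) next
        free <- which(engaged == 0L)
        free <- free[free != i]
        if (!length(free)) next
        d <- sqrt((pos[free, 1] - pos[i, 1])^2 + (pos[free, 2] - pos[i, 2])^2)
        if (min(d) > p$recruit_radius_mm) next
        j <- free[which.min(d)]
        dur <- p$chase_min_s + rexp(1, 1 / max(p$chase_mean_s - p$chase_min_s, 1e-6))
        id <- next_id; next_id <- next_id + 1L
        chases[[as.character(id)]] <- list(
          id = id, chaser = i, target = j, followers = integer(0),
          join_frames = integer(0), start = t, end = t + round(dur * fr))
        engaged[c(i, j)] <- id
        mode[i] <- "chase"; mode[j] <- "flee"
      }
    }

    # --- chain recruitment
    if (p$chain_rate > 0 && length(chases)) {
      for (key in names(chases)) {
        ch <- chases[[key]]
        if (runif(1) >= p$chain_rate * dt) next
        tail_fly <- if (length(ch$followers)) ch$followers[length(ch$followers)] else ch$chaser
        free <- which(engaged == 0L)
        if (!length(free)) next
        d <- sqrt((pos[free, 1] - pos[tail_fly, 1])^2 + (pos[free, 2] - pos[tail_fly, 2])^2)
        if (min(d) > p$recruit_radius_mm) next
        j <- free[which.min(d)]
        ch$followers <- c(ch$followers, j)
        ch$join_frames <- c(ch$join_frames, t)
        ch$end <- max(ch$end, t + round(2 * fr))
        chases[[key]] <- ch
        engaged[j] <- ch$id
        mode[j] <- "follow"
      }
    }

    # --- movement
    speed <- numeric(n)
    walkers <- which(mode == "walk")
    if (length(walkers)) {
      # walk -> pause transitions
      pz <- walkers[runif(length(walkers)) < p$pause_rate * dt]
      if (length(pz)) {
        mode[pz] <- "pause"
        pause_until[pz] <- t + pmax(1L, round(rexp(length(pz), 1 / p$pause_mean_s) * fr))
        walkers <- setdiff(walkers, pz)
      }
    }
    paused <- which(mode == "pause")
    if (length(paused)) {
      wake <- paused[pause_until[paused] <= t]
      if (length(wake)) { mode[wake] <- "walk"; walkers <- c(walkers, wake) }
    }
    if (length(walkers)) {
      heading[walkers] <- heading[walkers] +
        rnorm(length(walkers)) * p$turn_noise * sqrt(dt)
      # collision avoidance: steer away from the nearest fly when too close
      if (n >= 2 && p$avoid_radius_mm > 0) {
        for (i in walkers) {
          oth <- setdiff(seq_len(n), i)
          d2 <- (pos[oth, 1] - pos[i, 1])^2 + (pos[oth, 2] - pos[i, 2])^2
          jm <- oth[which.min(d2)]
          if (sqrt(min(d2)) < p$avoid_radius_mm) {
            away <- atan2(pos[i, 2] - pos[jm, 2], pos[i, 1] - pos[jm, 1])
            heading[i] <- heading[i] +
              pmin(pmax(ang_diff(away, heading[i]), -max_turn), max_turn)
          }
        }
      }
      speed[walkers] <- p$base_speed_mm_s
    }

    for (ch in chases) {
      line <- c(ch$target, ch$chaser, ch$followers)
      # head of the line flees its pursuer
      hd <- atan2(pos[line[1], 2] - pos[line[2], 2], pos[line[1], 1] - pos[line[2], 1])
      heading[line[1]] <- heading[line[1]] +
        pmin(pmax(ang_diff(hd, heading[line[1]]), -max_turn), max_turn) +
        rnorm(1) * 0.5 * p$turn_noise * sqrt(dt)
      # ... and steers the line around flies that are not part of it
      outsiders <- setdiff(seq_len(n), line)
      if (length(outsiders) && p$avoid_radius_mm > 0) {
        d2 <- (pos[outsiders, 1] - pos[line[1], 1])^2 +
          (pos[outsiders, 2] - pos[line[1], 2])^2
        jm <- outsiders[which.min(d2)]
        if (sqrt(min(d2)) < p$avoid_radius_mm) {
          away <- atan2(pos[line[1], 2] - pos[jm, 2], pos[line[1], 1] - pos[jm, 1])
          heading[line[1]] <- heading[line[1]] +
            pmin(pmax(ang_diff(away, heading[line[1]]), -max_turn), max_turn)
        }
      }
      speed[line[1]] <- p$base_speed_mm_s
      # pursuers steer at their predecessor, servoing the follow gap
      for (k in 2:length(line)) {
        i <- line[k]; pred <- line[k - 1L]
        gap_pref <- if (k == 2) 2 else p$follow_gap_mm
        dx <- pos[pred, 1] - pos[i, 1]; dy <- pos[pred, 2] - pos[i, 2]
        g <- sqrt(dx^2 + dy^2)
        bear <- atan2(dy, dx)
        heading[i] <- heading[i] +
          pmin(pmax(ang_diff(bear, heading[i]), -max_turn), max_turn)
        speed[i] <- max(0, min(p$chase_speed_mm_s,
                               p$base_speed_mm_s + (g - gap_pref) / dt * 0.5))
      }
    }

    pos[, 1] <- pos[, 1] + speed * dt * cos(heading)
    pos[, 2] <- pos[, 2] + speed * dt * sin(heading)
    # reflecting circular boundary (radial fold)
    r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    out <- which(r > R)
    if (length(out)) {
      th <- atan2(pos[out, 2], pos[out, 1])
      rn <- pmax(0, pmin(2 * R - r[out], R))
      pos[out, 1] <- rn * cos(th)
      pos[out, 2] <- rn * sin(th)
      heading[out] <- 2 * th + pi - heading[out]
    }
    X[t + 1L, ] <- pos[, 1]; Y[t + 1L, ] <- pos[, 2]
  }

  for (key in names(chases)) {
    ch <- chases[[key]]
    close_chase(ch, n_frames - 1L)
  }

  traj <- tibble(
    frame = rep(0:(n_frames - 1L), times = n),
    time_s = rep(time_s, times = n),
    fly_id = rep(seq_len(n), each = n_frames),
    x_mm = as.vector(X), y_mm = as.vector(Y), valid = TRUE)
  attr(traj, "frame_rate") <- fr

  chases_tb <- if (length(chase_rows)) bind_rows(chase_rows) else
    tibble(chaser = integer(), target = integer(),
           start_frame = integer(), end_frame = integer())
  chains_tb <- if (length(chain_rows)) bind_rows(chain_rows) else
    tibble(members = list(), size = integer(), start_frame = integer(),
           start4_frame = integer(), end_frame = integer())

  structure(list(trajectories = traj,
                 truth = list(chases = chases_tb, chains = chains_tb),
                 params = p),
            class = "arena_sim")
}

#' @export
print.arena_sim <- function(x, ...) {
  n <- length(unique(x$trajectories$fly_id))
  nf <- length(unique(x$trajectories$frame))
  cat(sprintf("<arena_sim> %d flies, %d frames (%.0f s at %g fps)\n",
              n, nf, nf / x$params$frame_rate, x$params$frame_rate))
  cat(sprintf("  ground truth: %d chase pair(s), %d chain(s)\n",
              nrow(x$truth$chases), nrow(x$truth$chains)))
  invisible(x)
}
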
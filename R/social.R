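#' Compute the interactogram of a trajectory set
#'
#' For every unordered pair of identified flies, marks the frames in which
#' their centroid distance is strictly less than the proximity criterion
#' (default 3.75 mm, chosen as optimal for capturing chasing events).
#' Frames in which either fly's position is interpolated or missing are
#' never marked.
#'
#' @param traj trajectory table (`frame`, `time_s`, `fly_id`, `x_mm`,
#'   `y_mm`, `valid`) with at least two flies.
#' @param params an [interaction_params()].
#' @return a tibble of class `fly_interactogram` with columns `frame`,
#'   `time_s`, `fly_a`, `fly_b` (`fly_a < fly_b`), `in_proximity`;
#'   attributes `fly_ids`, `frame_rate`, `proximity_mm`.
#' @export
compute_interactogram <- function(traj, params = interaction_params()) {
  w <- traj_wide(traj)
  ni <- length(w$fly_ids)
  if (ni < 2) stopf("flycourt_input", "need at least two flies")
  prs <- utils::combn(ni, 2)
  res <- purrr::map_dfr(seq_len(ncol(prs)), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    d <- sqrt((w$X[, a] - w$X[, b])^2 + (w$Y[, a] - w$Y[, b])^2)
    tibble(frame = w$frames, time_s = w$frames / w$frame_rate,
           fly_a = w$fly_ids[a], fly_b = w$fly_ids[b],
           in_proximity = !is.na(d) & d < params$proximity_mm &
             w$V[, a] & w$V[, b])
  })
  structure(res, class = c("fly_interactogram", class(res)),
            fly_ids = w$fly_ids, frame_rate = w$frame_rate,
            proximity_mm = params$proximity_mm)
}

# interactogram rows for the (unordered) pair (a, b), aligned to `frames`
ig_pair <- function(ig, a, b, frames) {
  lo <- min(a, b); hi <- max(a, b)
  sub <- ig[ig$fly_a == lo & ig$fly_b == hi, ]
  out <- logical(length(frames))
  out[match(sub$frame, frames)] <- sub$in_proximity
  out
}

#' Detect chase events from trajectories and an interactogram
#'
#' A chase is a maximal run, at least `min_chase_duration_s` long, in which
#' a pair of flies is (i) within the proximity criterion, (ii) both moving
#' at or above the mobility speed, and (iii) the chaser's displacement
#' heading points within `heading_alignment_deg` of its bearing to the
#' target. Roles are assigned by the bearing test, so in a follow-line each
#' fly is detected chasing the fly ahead of it.
#'
#' @param traj trajectory table.
#' @param ig interactogram from [compute_interactogram()] on the same
#'   trajectories (recomputed if NULL).
#' @param params an [interaction_params()].
#' @return tibble with columns `chaser`, `target`, `start_frame`,
#'   `end_frame`, `start_s`, `end_s`, `duration_s`.
#' @export
detect_chases <- function(traj, ig = NULL, params = interaction_params()) {
  w <- traj_wide(traj)
  if (is.null(ig)) ig <- compute_interactogram(traj, params)
  if (!identical(sort(unique(ig$frame)), w$frames))
    stopf("flycourt_alignment", "interactogram frame axis does not match trajectories")
  mo <- traj_motion(w)
  fr <- w$frame_rate
  min_frames <- max(1L, round(params$min_chase_duration_s * fr))
  align_rad <- params$heading_alignment_deg * pi / 180
  ni <- length(w$fly_ids)
  out <- list()
  for (a in seq_len(ni)) for (b in seq_len(ni)) {
    if (a == b) next
    prox <- ig_pair(ig, w$fly_ids[a], w$fly_ids[b], w$frames)
    moving <- mo$speed[, a] >= params$chain_min_speed_mm_s &
      mo$speed[, b] >= params$chain_min_speed_mm_s
    bear <- atan2(w$Y[, b] - w$Y[, a], w$X[, b] - w$X[, a])
    aligned <- abs(ang_diff(mo$heading[, a], bear)) <= align_rad
    cond <- prox & !is.na(moving) & moving & !is.na(aligned) & aligned
    runs <- true_runs(cond)
    runs <- runs[runs$end - runs$start + 1L >= min_frames, ]
    if (nrow(runs)) {
      out[[length(out) + 1L]] <- tibble(
        chaser = w$fly_ids[a], target = w$fly_ids[b],
        start_frame = w$frames[runs$start], end_frame = w$frames[runs$end])
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(chaser = integer(), target = integer(),
           start_frame = integer(), end_frame = integer())
  res |>
    mutate(start_s = .data$start_frame / fr, end_s = .data$end_frame / fr,
           duration_s = .data$end_s - .data$start_s) |>
    arrange(.data$start_frame, .data$chaser)
}

# longest simple path in a small undirected graph given by adjacency matrix
longest_path <- function(adj) {
  n <- nrow(adj)
  best <- integer(0)
  dfs <- function(path) {
    if (length(path) > length(best)) best <<- path
    nb <- which(adj[path[length(path)], ] & !(seq_len(n) %in% path))
    for (v in nb) dfs(c(path, v))
  }
  for (s in seq_len(n)) dfs(s)
  best
}

#' Detect mobile chains (follow-lines of four or more flies)
#'
#' Chaining is the formation of a mobile chain of four or more flies. Per
#' frame, the proximity graph is built from the interactogram; a frame is a
#' chain candidate when the graph contains a simple path of at least
#' `chain_min_size` flies (a follow-line, not merely a dense cluster). A
#' chain event is a maximal run of candidate frames, at least
#' `chain_min_duration_s` long, whose member sets overlap by at least 50%
#' frame-to-frame and whose members' mean speed meets the mobility
#' criterion.
#'
#' @inheritParams detect_chases
#' @return tibble with list-column `members` (path order), `size`,
#'   `start_frame`, `end_frame`, `start_s`, `end_s`, `duration_s`,
#'   `mean_speed_mm_s`.
#' @export
detect_chains <- function(traj, ig = NULL, params = interaction_params()) {
  w <- traj_wide(traj)
  if (is.null(ig)) ig <- compute_interactogram(traj, params)
  if (!identical(sort(unique(ig$frame)), w$frames))
    stopf("flycourt_alignment", "interactogram frame axis does not match trajectories")
  mo <- traj_motion(w)
  fr <- w$frame_rate
  ni <- length(w$fly_ids)
  nf <- length(w$frames)
  min_frames <- max(1L, round(params$chain_min_duration_s * fr))

  # adjacency stack: frames x pairs
  prs <- utils::combn(ni, 2)
  P <- matrix(FALSE, nf, ncol(prs))
  for (k in seq_len(ncol(prs)))
    P[, k] <- ig_pair(ig, w$fly_ids[prs[1, k]], w$fly_ids[prs[2, k]], w$frames)
  deg <- matrix(0L, nf, ni)
  for (k in seq_len(ncol(prs))) {
    deg[, prs[1, k]] <- deg[, prs[1, k]] + P[, k]
    deg[, prs[2, k]] <- deg[, prs[2, k]] + P[, k]
  }
  # candidate frames must have enough connected flies to host a path
  cand_frames <- which(rowSums(deg >= 1) >= params$chain_min_size)

  members <- vector("list", nf)
  for (f in cand_frames) {
    adj <- matrix(FALSE, ni, ni)
    on <- which(P[f, ])
    if (length(on) < params$chain_min_size - 1) next
    for (k in on) {
      adj[prs[1, k], prs[2, k]] <- TRUE
      adj[prs[2, k], prs[1, k]] <- TRUE
    }
    path <- longest_path(adj)
    if (length(path) >= params$chain_min_size) members[[f]] <- path
  }

  # stitch candidate frames whose member sets overlap by >= 50%
  events <- list()
  run_start <- NA_integer_
  prev_set <- NULL
  flush <- function(run_start, run_end) {
    if (is.na(run_start)) return()
    if (run_end - run_start + 1L < min_frames) return()
    rows <- run_start:run_end
    ids <- sort(unique(unlist(members[rows])))
    sp <- mo$speed[rows, ids, drop = FALSE]
    msp <- mean(sp, na.rm = TRUE)
    if (!is.finite(msp) || msp < params$chain_min_speed_mm_s) return()
    # representative order: the longest path seen during the run
    lens <- lengths(members[rows])
    ord <- members[[rows[which.max(lens)]]]
    events[[length(events) + 1L]] <<- tibble(
      members = list(w$fly_ids[ord]), size = length(ord),
      start_frame = w$frames[run_start], end_frame = w$frames[run_end])
  }
  for (f in seq_len(nf)) {
    cur <- members[[f]]
    if (is.null(cur)) {
      flush(run_start, f - 1L); run_start <- NA_integer_; prev_set <- NULL
      next
    }
    if (is.na(run_start)) {
      run_start <- f
    } else {
      ov <- length(intersect(cur, prev_set)) /
        min(length(cur), length(prev_set))
      if (ov < 0.5) { flush(run_start, f - 1L); run_start <- f }
    }
    prev_set <- cur
  }
  flush(run_start, nf)

  res <- if (length(events)) bind_rows(events) else
    tibble(members = list(), size = integer(),
           start_frame = integer(), end_frame = integer())
  res |>
    mutate(start_s = .data$start_frame / fr, end_s = .data$end_frame / fr,
           duration_s = .data$end_s - .data$start_s,
           mean_speed_mm_s = purrr::pmap_dbl(
             list(.data$start_frame, .data$end_frame, .data$members),
             function(s, e, mem) {
               rows <- match(s:e, w$frames)
               cols <- match(mem, w$fly_ids)
               mean(mo$speed[rows, cols, drop = FALSE], na.rm = TRUE)
             })) |>
    arrange(.data$start_frame)
}
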
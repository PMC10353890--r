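#' @importFrom rlang %||% abort
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows n across all_of distinct pull rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median mad sd t.test aov wilcox.test pairwise.t.test
#'   rnorm runif rexp quantile spec.pgram complete.cases setNames
#' @importFrom utils head tail
NULL

stopf <- function(class, fmt, ...) {
  rlang::abort(sprintf(fmt, ...), class = c(class, "flycourt_error"))
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# smallest signed angular difference a - b, wrapped to (-pi, pi]
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# centered rolling mean with shrinking windows at the edges
roll_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width <= 1L || length(x) < 2L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cnt <- cumsum(c(0, !is.na(x)))
  half <- width %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / pmax(cnt[hi + 1L] - cnt[lo], 1L)
}

# maximal runs of TRUE in a logical vector -> tibble(start, end) (1-based, inclusive)
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  stop_idx <- cumsum(r$lengths)
  start_idx <- stop_idx - r$lengths + 1L
  keep <- r$values
  tibble(start = start_idx[keep], end = stop_idx[keep])
}

# frame rate recovered from the time axis of a trajectory table
traj_frame_rate <- function(traj) {
  fr <- attr(traj, "frame_rate")
  if (!is.null(fr)) return(fr)
  ts <- sort(unique(traj$time_s))
  if (length(ts) < 2) stopf("flycourt_input", "cannot infer frame rate from < 2 frames")
  1 / stats::median(diff(ts))
}

check_traj <- function(traj) {
  need <- c("frame", "time_s", "fly_id", "x_mm", "y_mm")
  miss <- setdiff(need, names(traj))
  if (length(miss) > 0)
    stopf("flycourt_input", "trajectory table is missing column(s): %s",
          paste(miss, collapse = ", "))
  if (!"valid" %in% names(traj)) traj$valid <- TRUE
  traj
}

# trajectory long table -> aligned frames x flies matrices
traj_wide <- function(traj) {
  traj <- check_traj(traj)
  frames <- sort(unique(traj$frame))
  ids <- sort(unique(traj$fly_id))
  nf <- length(frames); ni <- length(ids)
  fi <- match(traj$frame, frames)
  ci <- match(traj$fly_id, ids)
  X <- matrix(NA_real_, nf, ni); Y <- X
  V <- matrix(FALSE, nf, ni)
  idx <- cbind(fi, ci)
  X[idx] <- traj$x_mm
  Y[idx] <- traj$y_mm
  V[idx] <- traj$valid & !is.na(traj$x_mm) & !is.na(traj$y_mm)
  list(X = X, Y = Y, V = V, frames = frames, fly_ids = ids,
       frame_rate = traj_frame_rate(traj))
}

# per-frame fly speeds (mm/s) and displacement headings (rad) from wide form;
# row t holds the displacement from frame t-1 to t (row 1 is NA)
traj_motion <- function(w) {
  nf <- nrow(w$X)
  dx <- rbind(NA_real_, diff(w$X))
  dy <- rbind(NA_real_, diff(w$Y))
  ok <- rbind(FALSE, w$V[-1, , drop = FALSE] & w$V[-nf, , drop = FALSE])
  sp <- sqrt(dx^2 + dy^2) * w$frame_rate
  sp[!ok] <- NA_real_
  hd <- atan2(dy, dx)
  hd[!ok] <- NA_real_
  list(speed = sp, heading = hd, ok = ok)
}

sig_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
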
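#' Per-fly locomotor kinematics
#'
#' Computes, for each identified fly, the distance travelled (sum of
#' frame-to-frame displacements over valid frames), mean speed (distance
#' over elapsed valid time) and percent time moving (fraction of valid
#' frames whose smoothed instantaneous speed meets the moving threshold).
#' Displacements across invalid (interpolated/missing) frames are excluded
#' from both numerator and denominator.
#'
#' @param traj trajectory table (`frame`, `time_s`, `fly_id`, `x_mm`,
#'   `y_mm`, `valid`).
#' @param moving_threshold_mm_s smoothed speed at or above which a fly
#'   counts as moving.
#' @param window_s width of the centered smoothing window applied to
#'   instantaneous speed.
#' @return tibble with one row per fly: `fly_id`, `distance_mm`,
#'   `mean_speed_mm_s`, `pct_time_moving`, `n_valid_steps`. Flies with no
#'   valid steps are dropped with a warning.
#' @examples
#' tr <- tibble::tibble(frame = 0:9, time_s = 0:9 / 5, fly_id = 1,
#'                      x_mm = 0:9, y_mm = 0, valid = TRUE)
#' compute_kinematics(tr)
#' @export
compute_kinematics <- function(traj, moving_threshold_mm_s = 1.0,
                               window_s = 0.2) {
  w <- traj_wide(traj)
  mo <- traj_motion(w)
  fr <- w$frame_rate
  width <- max(1L, round(window_s * fr))
  res <- purrr::map_dfr(seq_along(w$fly_ids), function(j) {
    sp <- mo$speed[, j]
    ok <- mo$ok[, j]
    if (!any(ok)) return(tibble())
    dist <- sum(sp[ok]) / fr
    elapsed <- sum(ok) / fr
    smoothed <- roll_mean(sp, width)
    moving <- smoothed[ok] >= moving_threshold_mm_s
    tibble(fly_id = w$fly_ids[j], distance_mm = dist,
           mean_speed_mm_s = dist / elapsed,
           pct_time_moving = 100 * mean(moving),
           n_valid_steps = sum(ok))
  })
  dropped <- setdiff(w$fly_ids, res$fly_id)
  if (length(dropped))
    warning(sprintf("fly/flies %s had no valid steps and were excluded",
                    paste(dropped, collapse = ", ")))
  res
}

#' Arena-level kinematics summary (mean and SEM across flies)
#'
#' @param kin per-fly table from [compute_kinematics()]; an optional `roi`
#'   column groups arenas.
#' @return tibble of per-metric `mean` and `sem`, by ROI when present.
#' @export
kinematics_summary <- function(kin) {
  grp <- if ("roi" %in% names(kin)) "roi" else character(0)
  kin |>
    tidyr::pivot_longer(c("distance_mm", "mean_speed_mm_s", "pct_time_moving"),
                        names_to = "metric", values_to = "value") |>
    group_by(across(all_of(c(grp, "metric")))) |>
    summarise(mean = mean(.data$value), sem = sem(.data$value),
              n_flies = dplyr::n(), .groups = "drop")
}
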
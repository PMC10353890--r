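#' @importFrom ggplot2 autoplot ggplot aes geom_rect geom_point geom_line
#'   geom_col geom_errorbar geom_path labs theme_minimal scale_fill_manual
#'   scale_colour_manual facet_wrap position_dodge
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

fly_palette <- function(ids) {
  pal <- grDevices::hcl.colors(max(length(ids), 3), "Dark 3")[seq_along(ids)]
  stats::setNames(pal, as.character(ids))
}

#' Plot an interactogram
#'
#' One horizontal colour band per fly; within each band, darker segments
#' mark the intervals during which each partner fly's centroid is within
#' the proximity criterion. Colour assignment is deterministic by fly id.
#'
#' @param object a `fly_interactogram` from [compute_interactogram()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fly_interactogram <- function(object, ...) {
  ids <- attr(object, "fly_ids")
  fr <- attr(object, "frame_rate")
  pal <- fly_palette(ids)
  n <- length(ids)
  bands <- tibble(fly = ids, ymin = match(ids, ids) - 0.45,
                  ymax = match(ids, ids) + 0.45)

  # each proximity frame appears in both partners' bands
  seg <- as_tibble(object) |>
    filter(.data$in_proximity)
  seg <- bind_rows(
    seg |> rename(band = "fly_a", partner = "fly_b"),
    seg |> rename(band = "fly_b", partner = "fly_a"))
  p <- ggplot() +
    geom_rect(data = bands,
              aes(xmin = -Inf, xmax = Inf, ymin = .data$ymin, ymax = .data$ymax,
                  fill = factor(.data$fly)), alpha = 0.25)
  if (nrow(seg)) {
    seg <- seg |>
      mutate(y0 = match(.data$band, ids) - 0.45 +
               0.9 * (match(.data$partner, ids) - 1) / n,
             y1 = .data$y0 + 0.9 / n)
    p <- p + geom_rect(data = seg,
                       aes(xmin = .data$time_s, xmax = .data$time_s + 1 / fr,
                           ymin = .data$y0, ymax = .data$y1,
                           fill = factor(.data$partner)))
  }
  p +
    ggplot2::scale_y_continuous(breaks = seq_len(n), labels = ids) +
    scale_fill_manual(values = pal, name = "fly") +
    labs(x = "time (s)", y = "fly band") +
    theme_minimal()
}

#' @rdname autoplot.fly_interactogram
#' @param ig a `fly_interactogram`.
#' @export
plot_interactogram <- function(ig, ...) autoplot(ig, ...)

#' Plot behaviour score time course across the light protocol
#'
#' @param object a `behavior_scores` sheet from [score_intervals()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.behavior_scores <- function(object, ...) {
  protocol <- attr(object, "protocol")
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = (.data$t_start + .data$t_end) / 2, y = .data$mark))
  if (!is.null(protocol)) {
    p <- p + geom_rect(data = protocol,
                       aes(xmin = .data$t_start, xmax = .data$t_end,
                           ymin = -Inf, ymax = Inf,
                           alpha = .data$intensity_klx),
                       fill = "gold", inherit.aes = FALSE) +
      ggplot2::scale_alpha_continuous(range = c(0.05, 0.35), guide = "none")
  }
  p + geom_line(aes(group = .data$behaviour)) + geom_point() +
    facet_wrap(~behaviour, ncol = 1) +
    labs(x = "time (s)", y = "bin mark (0/1)") +
    theme_minimal()
}

#' Plot per-intensity dose-response means with SEM
#'
#' @param object a `dose_response` from [dose_response()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot(object$by_intensity, aes(x = .data$intensity_klx, y = .data$mean)) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.05) +
    geom_line() + geom_point() +
    ggplot2::scale_x_log10() +
    labs(x = "light intensity (klx)", y = "mean total score") +
    theme_minimal()
}

#' Plot colour-coded locomotion tracks
#'
#' @param traj trajectory table.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_tracks <- function(traj, ...) {
  traj <- check_traj(traj)
  ids <- sort(unique(traj$fly_id))
  ggplot(traj, aes(x = .data$x_mm, y = .data$y_mm,
                   colour = factor(.data$fly_id))) +
    geom_path() +
    ggplot2::coord_fixed() +
    scale_colour_manual(values = fly_palette(ids), name = "fly") +
    labs(x = "x (mm)", y = "y (mm)") +
    theme_minimal()
}
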
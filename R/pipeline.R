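#' Run the social-behaviour analysis pipeline on one arena
#'
#' From identity-resolved trajectories: computes the interactogram,
#' detects chase and chain events, scores behaviour presence per 10-s bin
#' across the light protocol, and summarises per-fly kinematics.
#'
#' @param traj trajectory table for one ROI (from [simulate_arena()],
#'   [link_identities()] or [read_trajectories()]).
#' @param protocol a [light_protocol()].
#' @param params an [interaction_params()].
#' @param score_mode scoring mode passed to [score_intervals()].
#' @return list of class `arena_analysis`: `interactogram`, `chases`,
#'   `chains`, `events`, `scores`, `totals`, `kinematics`.
#' @export
analyze_arena <- function(traj, protocol = light_protocol(),
                          params = interaction_params(),
                          score_mode = "full") {
  traj <- check_traj(traj)
  ig <- compute_interactogram(traj, params)
  chases <- detect_chases(traj, ig, params)
  chains <- detect_chains(traj, ig, params)
  events <- bind_rows(
    chases |> mutate(behaviour = "chase") |>
      select("behaviour", "start_s", "end_s"),
    chains |> mutate(behaviour = "chain") |>
      select("behaviour", "start_s", "end_s"))
  # clip event tails that run past the protocol span
  span <- max(protocol$t_end)
  events <- events |>
    filter(.data$start_s < span) |>
    mutate(end_s = pmin(.data$end_s, span))
  scores <- score_intervals(events, protocol, mode = score_mode)
  structure(list(interactogram = ig, chases = chases, chains = chains,
                 events = events, scores = scores,
                 totals = epoch_totals(scores),
                 kinematics = compute_kinematics(traj)),
            class = "arena_analysis")
}

#' @export
print.arena_analysis <- function(x, ...) {
  cat(sprintf("<arena_analysis> %d chase(s), %d chain(s)\n",
              nrow(x$chases), nrow(x$chains)))
  print(x$totals)
  invisible(x)
}
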
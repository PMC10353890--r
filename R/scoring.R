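#' Score behaviour presence in 10-s bins across a light protocol
#'
#' Each epoch of the protocol is divided into 10-s bins and each behaviour
#' receives a 0/1 mark per bin: 1 iff any event of that behaviour overlaps
#' the bin's scoring window, however briefly. Per-epoch totals are the sum
#' of marks, so a 2-min epoch ranges from 0 to 12. In `mode = "alternating"`
#' each 10-s interval is divided into two 5-s scoring windows and only the
#' window assigned to this ROI (`roi_phase` 1 or 2) is consulted — the
#' protocol used when two arenas are scored alternately by one observer
#' pair; the automated pipeline defaults to the full bin.
#'
#' @param events tibble of events with columns `behaviour` (e.g. "chase",
#'   "wing_extension", "chain"), `start_s`, `end_s`.
#' @param protocol a [light_protocol()].
#' @param behaviours behaviours to score (rows appear even when absent from
#'   `events`).
#' @param bin_s scoring bin width in seconds.
#' @param mode `"full"` scores the whole bin; `"alternating"` only the
#'   ROI's 5-s half-window.
#' @param roi_phase which half-window this ROI owns in alternating mode.
#' @param window_s half-window width in alternating mode.
#' @return a tibble of class `behavior_scores`: `behaviour`, `epoch`,
#'   `label`, `bin`, `t_start`, `t_end`, `mark`.
#' @export
score_intervals <- function(events, protocol = light_protocol(),
                            behaviours = NULL, bin_s = 10,
                            mode = c("full", "alternating"),
                            roi_phase = 1, window_s = 5) {
  mode <- match.arg(mode)
  if (!all(c("behaviour", "start_s", "end_s") %in% names(events)))
    stopf("flycourt_input", "events need columns behaviour, start_s, end_s")
  span <- max(protocol$t_end)
  if (nrow(events) > 0 &&
      (any(events$start_s < 0) || any(events$end_s > span + 1e-9) ||
       any(events$end_s < events$start_s)))
    stopf("flycourt_range", "event times must lie within the recording span [0, %g] s", span)
  if (any(protocol$duration_s %% bin_s != 0))
    stopf("flycourt_input", "bin grid must divide each epoch evenly")
  behaviours <- behaviours %||%
    unique(c("chase", "wing_extension", "chain", events$behaviour))

  bins <- protocol |>
    group_by(.data$epoch, .data$label) |>
    dplyr::reframe(bin = seq_len(.data$duration_s / bin_s),
                   t_start = .data$t_start + (.data$bin - 1) * bin_s) |>
    mutate(t_end = .data$t_start + bin_s)
  if (mode == "alternating") {
    off <- (roi_phase - 1) * window_s
    bins <- bins |> mutate(w_start = .data$t_start + off,
                           w_end = .data$t_start + off + window_s)
  } else {
    bins <- bins |> mutate(w_start = .data$t_start, w_end = .data$t_end)
  }

  sheet <- tidyr::crossing(behaviour = behaviours, bins) |>
    mutate(mark = purrr::pmap_int(
      list(.data$behaviour, .data$w_start, .data$w_end),
      function(bh, ws, we) {
        ev <- events[events$behaviour == bh, ]
        if (nrow(ev) == 0) return(0L)
        hit <- (ev$end_s > ws & ev$start_s < we) |
          (ev$end_s == ev$start_s & ev$start_s >= ws & ev$start_s < we)
        as.integer(any(hit))
      })) |>
    select("behaviour", "epoch", "label", "bin", "t_start", "t_end", "mark") |>
    arrange(.data$behaviour, .data$epoch, .data$bin)
  class(sheet) <- c("behavior_scores", class(sheet))
  attr(sheet, "protocol") <- protocol
  sheet
}

#' Per-epoch total scores
#'
#' @param sheet a score sheet from [score_intervals()] (or several bound
#'   together with an extra `roi` column).
#' @return tibble of totals per behaviour and epoch (and ROI if present).
#' @export
epoch_totals <- function(sheet) {
  grp <- intersect(c("roi", "behaviour", "epoch", "label"), names(sheet))
  sheet |>
    as_tibble() |>
    group_by(across(all_of(grp))) |>
    summarise(total = sum(.data$mark), n_bins = dplyr::n(), .groups = "drop")
}

# paired t that tolerates zero-variance differences: identical samples give
# t = 0, p = 1; a constant non-zero difference is reported as t = +-Inf,
# p = 0 (the degenerate limit of the test)
paired_t <- function(x, y) {
  d <- x - y
  if (length(d) < 2) stopf("flycourt_replicates", "need >= 2 paired replicates")
  if (stats::sd(d) == 0) {
    return(tibble(estimate = mean(d),
                  statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                  p.value = if (mean(d) == 0) 1 else 0,
                  df = length(d) - 1))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         p.value = tt$p.value, df = unname(tt$parameter))
}

#' Compare behaviour scores across light epochs
#'
#' In `"paired"` design, per behaviour the per-ROI epoch totals are
#' compared with two-sided paired t-tests between consecutive epochs (low
#' vs high, and high vs recovery low in the three-epoch protocol), with
#' mean and SEM per epoch (the ROI is the replicate unit). In
#' `"multi_group"` design (a `group` column, e.g. genotype), per behaviour
#' and epoch a one-way ANOVA across groups is followed by
#' Bonferroni-corrected pairwise t-tests.
#'
#' @param totals tibble of per-ROI epoch totals: columns `roi`,
#'   `behaviour`, `epoch`, `label`, `total`, plus `group` for the
#'   multi-group design.
#' @param design `"paired"` or `"multi_group"`.
#' @return an object of class `epoch_comparison` with elements `summary`
#'   (mean, sem, n per cell), `tests` (tidy test rows with significance
#'   tiers at 0.05 / 0.01 / 0.001) and `design`; see [tidy.epoch_comparison()].
#' @export
compare_epochs <- function(totals, design = c("paired", "multi_group")) {
  design <- match.arg(design)
  need <- c("roi", "behaviour", "epoch", "total")
  if (!all(need %in% names(totals)))
    stopf("flycourt_input", "totals need columns %s", paste(need, collapse = ", "))
  if (!"label" %in% names(totals))
    totals$label <- as.character(totals$epoch)
  grp_cols <- intersect(c("group", "behaviour", "epoch", "label"), names(totals))
  summary <- totals |>
    group_by(across(all_of(grp_cols))) |>
    summarise(mean = mean(.data$total), sem = sem(.data$total),
              n = dplyr::n(), .groups = "drop")

  if (design == "paired") {
    if (dplyr::n_distinct(totals$roi) < 2)
      stopf("flycourt_replicates", "paired design needs >= 2 ROIs")
    epochs <- sort(unique(totals$epoch))
    contrasts <- tibble(e1 = epochs[-length(epochs)], e2 = epochs[-1])
    tests <- tidyr::crossing(behaviour = unique(totals$behaviour), contrasts) |>
      mutate(res = purrr::pmap(list(.data$behaviour, .data$e1, .data$e2),
        function(bh, e1, e2) {
          wide <- totals |>
            filter(.data$behaviour == bh, .data$epoch %in% c(e1, e2)) |>
            select("roi", "epoch", "total") |>
            tidyr::pivot_wider(names_from = "epoch", values_from = "total")
          paired_t(wide[[as.character(e2)]], wide[[as.character(e1)]])
        })) |>
      tidyr::unnest("res") |>
      mutate(method = "paired t-test", sig = sig_stars(.data$p.value))
  } else {
    if (!"group" %in% names(totals))
      stopf("flycourt_input", "multi_group design needs a 'group' column")
    cells <- distinct(totals, .data$behaviour, .data$epoch, .data$label)
    tests <- purrr::pmap_dfr(cells, function(behaviour, epoch, label) {
      sub <- totals[totals$behaviour == behaviour & totals$epoch == epoch, ]
      if (dplyr::n_distinct(sub$group) < 2) return(tibble())
      fit <- stats::aov(total ~ factor(group), data = sub)
      an <- summary(fit)[[1]]
      omni <- tibble(behaviour = behaviour, epoch = epoch, label = label,
                     comparison = "omnibus", method = "one-way ANOVA",
                     statistic = an$`F value`[1], df = an$Df[1],
                     p.value = an$`Pr(>F)`[1])
      pw <- stats::pairwise.t.test(sub$total, sub$group,
                                   p.adjust.method = "bonferroni")
      pv <- as.data.frame(as.table(pw$p.value))
      pv <- pv[stats::complete.cases(pv), ]
      pair_rows <- tibble(behaviour = behaviour, epoch = epoch, label = label,
                          comparison = paste(pv$Var1, "vs", pv$Var2),
                          method = "Bonferroni-corrected t-test",
                          statistic = NA_real_, df = NA_real_,
                          p.value = pv$Freq)
      bind_rows(omni, pair_rows)
    })
    tests <- tests |> mutate(sig = sig_stars(.data$p.value))
  }

  structure(list(summary = summary, tests = tests, design = design),
            class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat(sprintf("<epoch_comparison> design: %s\n", x$design))
  print(x$summary, n = 12)
  cat("tests:\n")
  print(x$tests, n = 12)
  invisible(x)
}

#' Tidy an epoch comparison
#'
#' @param x an `epoch_comparison` from [compare_epochs()].
#' @param ... unused.
#' @return `tidy()`: one row per test with statistic, p-value and
#'   significance tier; `glance()`: a one-row model summary.
#' @export
tidy.epoch_comparison <- function(x, ...) x$tests

#' @rdname tidy.epoch_comparison
#' @export
glance.epoch_comparison <- function(x, ...) {
  tibble(design = x$design,
         n_behaviours = dplyr::n_distinct(x$tests$behaviour),
         n_tests = nrow(x$tests),
         min_p = suppressWarnings(min(x$tests$p.value, na.rm = TRUE)))
}

#' Dose-response summary over light intensities
#'
#' Summarises total scores per intensity (mean and SEM) and locates the
#' pair of adjacent intensities with the steepest proportional increase in
#' mean score — the assay shows a monotonic intensity dependence with its
#' proportionally steepest rise between 2.0 and 6.0 klx.
#'
#' @param scores tibble with columns `intensity_klx` and `total` (several
#'   replicates per intensity allowed).
#' @return list of class `dose_response`: `by_intensity` (mean, sem, n),
#'   `steepest` (one-row tibble `from_klx`, `to_klx`, `rel_increase`, NA
#'   row when no interval shows an increase or the baseline mean is zero),
#'   `monotone` (is the mean non-decreasing in intensity).
#' @export
dose_response <- function(scores) {
  if (!all(c("intensity_klx", "total") %in% names(scores)))
    stopf("flycourt_input", "scores need columns intensity_klx, total")
  if (dplyr::n_distinct(scores$intensity_klx) < 3)
    stopf("flycourt_levels", "need >= 3 intensity levels")
  by_int <- scores |>
    group_by(.data$intensity_klx) |>
    summarise(mean = mean(.data$total), sem = sem(.data$total),
              n = dplyr::n(), .groups = "drop") |>
    arrange(.data$intensity_klx)
  m <- by_int$mean
  rel <- rep(NA_real_, length(m) - 1)
  pos <- m[-length(m)] > 0
  rel[pos] <- (m[-1][pos] - m[-length(m)][pos]) / m[-length(m)][pos]
  if (all(is.na(rel)) || max(rel, na.rm = TRUE) <= 0) {
    steepest <- tibble(from_klx = NA_real_, to_klx = NA_real_,
                       rel_increase = NA_real_)
  } else {
    k <- which.max(rel)
    steepest <- tibble(from_klx = by_int$intensity_klx[k],
                       to_klx = by_int$intensity_klx[k + 1],
                       rel_increase = rel[k])
  }
  structure(list(by_intensity = by_int, steepest = steepest,
                 monotone = !is.unsorted(m)),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("<dose_response>\n")
  print(x$by_intensity)
  if (is.na(x$steepest$from_klx[1])) {
    cat("no interval of proportional increase\n")
  } else {
    cat(sprintf("steepest proportional rise on (%g, %g] klx (+%.0f%%); monotone: %s\n",
                x$steepest$from_klx, x$steepest$to_klx,
                100 * x$steepest$rel_increase, x$monotone))
  }
  invisible(x)
}

#' Normalize an emission spectrum to its peak
#'
#' Divides each emission value by the maximum, so the peak wavelength maps
#' to exactly 1 (E(lambda) / E(peak)).
#'
#' @param spec tibble with columns `wavelength_nm` and `emission`.
#' @return the input with an added/replaced `normalized_emission` column.
#' @export
normalize_spectrum <- function(spec) {
  if (!all(c("wavelength_nm", "emission") %in% names(spec)))
    stopf("flycourt_input", "spectrum needs columns wavelength_nm, emission")
  peak <- max(spec$emission)
  if (!is.finite(peak) || peak <= 0)
    stopf("flycourt_degenerate", "spectrum has no positive emission")
  spec |> mutate(normalized_emission = .data$emission / peak)
}
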
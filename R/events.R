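#' Match detected events against ground truth by interval overlap
#'
#' A detected event matches a truth event when their frame intervals
#' overlap by at least `min_overlap` of the shorter interval and, if
#' identity columns are given, those agree. Reports event-level recall
#' (truth events matched) and precision (detections matched).
#'
#' @param detected,truth tibbles with `start_frame`, `end_frame`.
#' @param keys character vector of identity columns that must be equal in
#'   a matching pair (e.g. `c("chaser", "target")`), or NULL for
#'   interval-only matching.
#' @param min_overlap minimum overlap fraction of the shorter interval.
#' @return list with `recall`, `precision`, `n_detected`, `n_truth`.
#' @export
match_events <- function(detected, truth, keys = NULL, min_overlap = 0.5) {
  if (nrow(truth) == 0)
    return(list(recall = NA_real_,
                precision = if (nrow(detected)) 0 else NA_real_,
                n_detected = nrow(detected), n_truth = 0L))
  if (nrow(detected) == 0)
    return(list(recall = 0, precision = NA_real_,
                n_detected = 0L, n_truth = nrow(truth)))
  pair_ok <- function(d, t) {
    if (is.null(keys)) return(TRUE)
    all(vapply(keys, function(k) identical(d[[k]], t[[k]]), logical(1)))
  }
  overlap_ok <- function(d, t) {
    inter <- min(d$end_frame, t$end_frame) - max(d$start_frame, t$start_frame) + 1
    shorter <- min(d$end_frame - d$start_frame, t$end_frame - t$start_frame) + 1
    inter >= min_overlap * shorter
  }
  det_hit <- logical(nrow(detected))
  truth_hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    for (j in seq_len(nrow(detected))) {
      d <- detected[j, ]
      if (pair_ok(d, t) && overlap_ok(d, t)) {
        truth_hit[i] <- TRUE
        det_hit[j] <- TRUE
      }
    }
  }
  list(recall = mean(truth_hit), precision = mean(det_hit),
       n_detected = nrow(detected), n_truth = nrow(truth))
}
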
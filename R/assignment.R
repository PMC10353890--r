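# Linear assignment by the shortest-augmenting-path (Jonker-Volgenant)
# algorithm. O(n^3); used for frame-to-frame identity linking where the
# cost is gated Euclidean displacement. Non-finite costs are treated as
# forbidden pairings (replaced by a cost larger than any optimal total).

#' Minimum-cost assignment of rows to columns
#'
#' @param cost square numeric cost matrix; `Inf` entries mark forbidden
#'   pairings (they are only used when no feasible alternative exists).
#' @return integer vector `a` with `a[i]` the column assigned to row `i`,
#'   minimising the total cost.
#' @keywords internal
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (is.null(n) || n == 0) return(integer(0))
  if (ncol(cost) != n) stopf("flycourt_input", "cost matrix must be square")
  if (n == 1) return(1L)
  fin <- cost[is.finite(cost)]
  big <- (if (length(fin)) max(abs(fin)) else 1) * n + 1e6
  a <- cost
  a[!is.finite(a)] <- big

  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)  # index j+1 holds column j (0 virtual)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      jfree <- which(!used[-1L])
      idx <- jfree + 1L
      cur <- a[i0, jfree] - u[i0 + 1L] - v[idx]
      better <- cur < minv[idx]
      minv[idx[better]] <- cur[better]
      way[idx[better]] <- j0
      k <- which.min(minv[idx])
      delta <- minv[idx][k]
      j1 <- jfree[k]
      w <- which(used)
      u[p[w] + 1L] <- u[p[w] + 1L] + delta
      v[w] <- v[w] - delta
      nw <- which(!used)
      minv[nw] <- minv[nw] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  res <- integer(n)
  res[p[2:(n + 1)]] <- seq_len(n)
  res
}
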
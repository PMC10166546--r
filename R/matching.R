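#' Minimum-cost linear assignment (Hungarian algorithm)
#'
#' Solves the square assignment problem by the shortest-augmenting-path
#' Hungarian method with row/column potentials, O(n^3). Used to match fitted
#' archetypes to planted templates.
#'
#' @param cost square numeric cost matrix; entry (i, j) is the cost of
#'   assigning row i to column j.
#' @return integer vector `m` with `m[i]` = column assigned to row `i`.
#' @export
assignment_min <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n >= 1, all(is.finite(cost)))
  # column index n+1 plays the role of the virtual start column
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  m <- integer(n)
  for (j in seq_len(n)) m[p[j]] <- j
  m
}
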
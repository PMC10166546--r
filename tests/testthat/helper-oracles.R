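# Independent oracles used to check the solver paths. These deliberately use
# brute-force enumeration / naive arithmetic, not the package's solvers.

# all compositions of `units` indistinguishable balls into `parts` boxes,
# returned as a matrix of non-negative integers (rows sum to `units`)
compositions <- function(units, parts) {
  if (parts == 1) return(matrix(units, ncol = 1))
  out <- list()
  for (first in 0:units) {
    rest <- compositions(units - first, parts - 1)
    out[[length(out) + 1]] <- cbind(first, rest)
  }
  unname(do.call(rbind, out))
}

# exhaustive simplex grid search for the best convex decomposition of one
# field onto a k-archetype basis; step on the weight simplex
oracle_decompose_grid <- function(td, Z, step = 0.01) {
  k <- nrow(Z)
  W <- compositions(round(1 / step), k) * step
  resid <- sweep(W %*% Z, 2, td)
  rss <- rowSums(resid^2)
  i <- which.min(rss)
  list(w = W[i, ], rss = rss[i])
}

# brute-force archetypal analysis for k = 2, d = 2: enumerate both generator
# rows B over the simplex grid; for each candidate archetype pair the optimal
# simplex coefficients of a point are its projection onto the segment
oracle_aa_grid_rss <- function(X, step = 0.05) {
  stopifnot(ncol(X) == 2)
  n <- nrow(X)
  W <- compositions(round(1 / step), n) * step
  Zc <- W %*% X                     # candidate archetype points, m x 2
  m <- nrow(Zc)
  best <- Inf
  for (i in seq_len(m)) {
    z1 <- Zc[i, ]
    D <- sweep(Zc, 2, z1)           # segment directions z2 - z1
    dd <- rowSums(D^2)
    rss_tot <- numeric(m)
    for (p in seq_len(n)) {
      v <- X[p, ] - z1
      tt <- drop(D %*% v)
      tt <- ifelse(dd > 0, tt / ifelse(dd > 0, dd, 1), 0)
      tt <- pmin(pmax(tt, 0), 1)
      rss_tot <- rss_tot + (v[1] - tt * D[, 1])^2 + (v[2] - tt * D[, 2])^2
    }
    best <- min(best, min(rss_tot))
  }
  best
}

# naive Spearman: average ranks computed by pairwise counting, then the
# product-moment correlation of the ranks
naive_spearman <- function(x, y) {
  naive_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      smaller <- sum(v < v[i])
      ties <- sum(v == v[i])
      smaller + (ties + 1) / 2
    }, numeric(1))
  }
  rx <- naive_rank(x); ry <- naive_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force minimum-cost assignment by permutation enumeration (small n)
perms <- function(n) {
  if (n == 1) return(matrix(1))
  p <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(p >= i, p + 1, p))
  }))
}

brute_assignment <- function(cost) {
  n <- nrow(cost)
  pp <- perms(n)
  costs <- apply(pp, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  unname(pp[which.min(costs), ])
}

# greedy-free matched distance between two archetype sets (for small k):
# min over row permutations of the max row-wise distance
matched_max_dist <- function(Z1, Z2) {
  n <- nrow(Z1)
  pp <- perms(n)
  min(apply(pp, 1, function(p) {
    max(sqrt(rowSums((Z1 - Z2[p, , drop = FALSE])^2)))
  }))
}
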
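#' Fit options for archetypal analysis
#'
#' @param k number of archetypes.
#' @param max_iterations cap on alternating-least-squares iterations.
#' @param min_improvement relative RSS improvement below which the fit stops
#'   (default: square root of machine precision).
#' @param max_kappa condition-number bound for the unconstrained
#'   archetype-update solve; systems above it receive the smallest diagonal
#'   ridge bringing the condition estimate back to the bound.
#' @param penalty_weight magnitude of the sum-to-one penalty row appended to
#'   each constrained least-squares subproblem.
#' @param n_restarts number of random initializations; the best (lowest RSS)
#'   fit is returned, ties broken toward the lowest restart index.
#' @param max_polish cap on projected-gradient polish iterations run after
#'   the alternating scheme converges (the polish descends the true
#'   reconstruction objective directly and only ever lowers RSS; 0 disables).
#' @param seed integer seed driving all randomness of the fit.
#' @param weights reserved; only `NULL` or uniform weights are accepted
#'   (per-observation weighting is not implemented).
#' @return list of class `aa_fit_options`.
#' @export
fit_options <- function(k,
                        max_iterations = 100L,
                        min_improvement = sqrt(.Machine$double.eps),
                        max_kappa = 1000,
                        penalty_weight = 200,
                        n_restarts = 5L,
                        seed = 1L,
                        max_polish = 100L,
                        weights = NULL) {
  stopifnot(k >= 1, max_iterations >= 1, penalty_weight > 0, n_restarts >= 1,
            min_improvement >= 0, max_kappa > 1, max_polish >= 0)
  if (!is.null(weights)) {
    if (length(unique(weights)) != 1L) {
      stop("per-observation weights are not supported; supply NULL or uniform weights")
    }
  }
  structure(
    list(k = as.integer(k), max_iterations = as.integer(max_iterations),
         min_improvement = min_improvement, max_kappa = max_kappa,
         penalty_weight = penalty_weight, n_restarts = as.integer(n_restarts),
         seed = as.integer(seed), max_polish = as.integer(max_polish)),
    class = "aa_fit_options"
  )
}

#' Residual sum of squares of an archetype reconstruction
#'
#' @param X data matrix (n x d).
#' @param A coefficient matrix (n x k), rows on the simplex.
#' @param Z archetype matrix (k x d).
#' @param normalized if `TRUE`, return RSS / (n * d) for cross-cohort
#'   comparison.
#' @return non-negative scalar.
#' @export
compute_rss <- function(X, A, Z, normalized = FALSE) {
  X <- as.matrix(X); A <- as.matrix(A); Z <- as.matrix(Z)
  if (nrow(A) != nrow(X) || ncol(A) != nrow(Z) || ncol(Z) != ncol(X)) {
    stop("shape mismatch: X is ", nrow(X), "x", ncol(X), ", A is ",
         nrow(A), "x", ncol(A), ", Z is ", nrow(Z), "x", ncol(Z))
  }
  rss <- sum((X - A %*% Z)^2)
  if (normalized) rss / (nrow(X) * ncol(X)) else rss
}

#' Condition-number guard for ALS subproblem systems
#'
#' Estimates the condition number of a symmetric positive semi-definite
#' system matrix (via its eigenvalue range) and, if it exceeds `max_kappa`,
#' adds the smallest diagonal ridge bringing the estimate to the bound.
#'
#' @param M symmetric system matrix (e.g. a cross-product from an ALS step).
#' @param max_kappa condition-number bound.
#' @return `M`, possibly ridged, with attributes `ridge`, `kappa_before`,
#'   `kappa_after`.
#' @export
condition_guard <- function(M, max_kappa = 1000) {
  M <- as.matrix(M)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  emax <- max(ev)
  emin <- max(min(ev), 0)
  kappa <- if (emin > 0) emax / emin else Inf
  ridge <- 0
  if (is.finite(kappa) && kappa <= max_kappa) {
    out <- M
  } else {
    # (emax + r) / (emin + r) = max_kappa  =>  r = (emax - max_kappa*emin)/(max_kappa - 1)
    ridge <- (emax - max_kappa * emin) / (max_kappa - 1)
    if (!is.finite(ridge) || ridge < 0) ridge <- 0
    if (emax == 0) ridge <- 1e-12  # rank-0 guard
    out <- M + diag(ridge, nrow(M))
  }
  attr(out, "ridge") <- ridge
  attr(out, "kappa_before") <- kappa
  attr(out, "kappa_after") <- if (ridge > 0) (emax + ridge) / (emin + ridge) else kappa
  out
}

#' Simplex-constrained least squares, one solve per target column
#'
#' Solves `min ||basis %*% w - y||^2  s.t.  w >= 0, sum(w) = 1` for each
#' column `y` of `targets`, by appending a sum-to-one penalty row of
#' magnitude `penalty_weight` and solving the augmented problem by
#' non-negative least squares, then renormalizing to exact sum one.
#'
#' @param basis d x m matrix whose columns span the candidate combinations.
#' @param targets d x q matrix of targets.
#' @param penalty_weight penalty-row magnitude.
#' @return m x q matrix of simplex weights (columns sum to 1 exactly).
#' @keywords internal
simplex_lsq <- function(basis, targets, penalty_weight = 200) {
  basis <- as.matrix(basis); targets <- as.matrix(targets)
  stopifnot(nrow(basis) == nrow(targets))
  D <- rbind(basis, rep(penalty_weight, ncol(basis)))
  Y <- rbind(targets, rep(penalty_weight, ncol(targets)))
  W <- .nnls_multi(D, Y)
  s <- colSums(W)
  zero <- s <= 0
  if (any(zero)) {
    W[, zero] <- 1 / nrow(W)
    s[zero] <- 1
  }
  sweep(W, 2L, s, "/")
}

#' Fit an archetypal-analysis model
#'
#' Alternating constrained least squares for the factorization `X ~ A Z` with
#' `Z = B X`: rows of `A` (per-observation mixture weights) and rows of `B`
#' (per-archetype generator weights over observations) are constrained to the
#' probability simplex, so archetypes are convex combinations of observed
#' fields and every field is approximated by a convex combination of
#' archetypes. Each simplex-constrained subproblem is solved through the
#' penalty-row device with non-negative least squares; the unconstrained
#' archetype update is protected by [condition_guard()]. `B` is initialized
#' by selecting `k` distinct observations; among `n_restarts` random
#' initializations the lowest-RSS fit wins. A non-improving step restores the
#' previous iterate and stops the run with a warning, so the recorded RSS
#' trace is non-increasing.
#'
#' Archetypes of the returned model are ordered by descending relative weight
#' (RW, the mean percent weight of the archetype across the training fields,
#' obtained by decomposing `X` on the frozen basis); `avg_td` is the
#' unweighted mean of each archetype's values.
#'
#' @param X n x d data matrix (for visual fields, d = 52 TD values in grid
#'   active order); requires `n > k`.
#' @param opts an [fit_options()] object (or `k` if `opts` omitted).
#' @param init_indices optional list of integer vectors (length `k`) to use
#'   as deterministic initializations in place of random restarts.
#' @param mirrored logical flag recorded in the model metadata (whether OS
#'   fields were mirrored upstream).
#' @return object of class `archetype_model`: `k`, `archetypes` (k x d,
#'   descending RW), `A`, `B`, `rw`, `avg_td`, `normal_at`, `rss`,
#'   `rss_trace`, `iterations`, `restart`, `ridge_events`, `opts`, `mirrored`.
#' @export
fit_archetypes <- function(X, opts, init_indices = NULL, mirrored = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.numeric(opts) && length(opts) == 1L) opts <- fit_options(k = opts)
  stopifnot(inherits(opts, "aa_fit_options"))
  n <- nrow(X); d <- ncol(X); k <- opts$k
  if (!all(is.finite(X))) stop("X must be finite")
  if (n < k) stop("need at least as many observations as archetypes: n = ", n, ", k = ", k)
  if (all(abs(X) < 1e-300)) stop("degenerate data matrix: rank 0")

  if (is.null(init_indices)) {
    set.seed(opts$seed)
    init_indices <- lapply(seq_len(opts$n_restarts),
                           function(r) sample.int(n, k, replace = FALSE))
  }

  best <- NULL
  for (r in seq_along(init_indices)) {
    fit <- aa_single_fit(X, k, init_indices[[r]], opts)
    if (is.null(best) || fit$rss < best$rss - 1e-12) {
      fit$restart <- r
      best <- fit
    }
  }

  # RW and average TD from decomposition of X on the frozen basis
  W <- simplex_lsq(t(best$Z), t(X), opts$penalty_weight)   # k x n
  pw <- 100 * t(W)                                         # n x k
  rw <- colMeans(pw)
  ord <- order(rw, decreasing = TRUE)
  Z <- best$Z[ord, , drop = FALSE]
  rownames(Z) <- paste0("AT", seq_len(k))
  avg_td <- rowMeans(Z)
  normal_at <- which.max(avg_td)
  if (normal_at != which.max(rw[ord])) {
    warning("normal archetype (highest average TD) is not the highest-RW archetype; ",
            "using highest average TD (AT", normal_at, ")")
  }

  structure(
    list(
      k = k,
      archetypes = Z,
      A = best$A[, ord, drop = FALSE],
      B = best$B[ord, , drop = FALSE],
      rw = rw[ord],
      avg_td = avg_td,
      normal_at = as.integer(normal_at),
      rss = best$rss,
      rss_trace = best$rss_trace,
      iterations = best$iterations,
      restart = best$restart,
      ridge_events = best$ridge_events,
      opts = opts,
      mirrored = isTRUE(mirrored),
      d = d
    ),
    class = "archetype_model"
  )
}

#' @keywords internal
aa_single_fit <- function(X, k, init, opts) {
  n <- nrow(X)
  B <- matrix(0, k, n)
  B[cbind(seq_len(k), init)] <- 1
  Z <- B %*% X
  A <- NULL
  rss_prev <- Inf
  rss_trace <- numeric(0)
  ridge_events <- 0L
  iterations <- 0L
  A_prev <- NULL; B_prev <- NULL; Z_prev <- NULL

  # initial coefficients for the starting archetypes
  A <- t(simplex_lsq(t(Z), t(X), opts$penalty_weight))       # n x k

  for (it in seq_len(opts$max_iterations)) {
    # unconstrained ideal archetypes: min ||X - A Zhat||
    G <- condition_guard(crossprod(A), opts$max_kappa)
    if (attr(G, "ridge") > 0) ridge_events <- ridge_events + 1L
    Zhat <- solve(G, crossprod(A, X))

    # B-step: express each ideal archetype as a convex combination of fields
    B <- t(simplex_lsq(t(X), t(Zhat), opts$penalty_weight))  # k x n
    Z <- B %*% X

    # A-step: project each observation onto the simplex span of the new
    # archetypes, so the recorded RSS pairs a consistent (A, Z)
    A <- t(simplex_lsq(t(Z), t(X), opts$penalty_weight))     # n x k

    rss <- sum((X - A %*% Z)^2)
    if (rss > rss_prev * (1 + 1e-12) && it > 1) {
      warning("archetype fit stalled at iteration ", it, "; keeping previous iterate")
      A <- A_prev; B <- B_prev; Z <- Z_prev
      break
    }
    rss_trace <- c(rss_trace, rss)
    iterations <- it
    improvement <- if (!is.finite(rss_prev)) Inf
                   else if (rss_prev <= 0) 0
                   else (rss_prev - rss) / rss_prev
    A_prev <- A; B_prev <- B; Z_prev <- Z
    if (is.finite(rss_prev) && improvement >= 0 && improvement < opts$min_improvement) break
    rss_prev <- rss
  }

  # polish: the classical alternating scheme updates B against the ideal
  # archetypes, not the true objective, and its fixed points can be slightly
  # suboptimal. Descend the true objective ||X - A B X||^2 directly by
  # projected gradient on B (exact A-step in between); only improving steps
  # are accepted, so the recorded RSS stays non-increasing.
  rss <- tail(rss_trace, 1)
  eta <- 0.1 / max(sum(X^2), 1)
  for (it in seq_len(opts$max_polish)) {
    R <- X - A %*% (B %*% X)
    Gb <- -2 * crossprod(A, R) %*% t(X)           # d f / d B, A fixed
    B_try <- NULL
    for (bt in 1:20) {
      cand <- project_rows_simplex(B - eta * Gb)
      rss_try <- sum((X - A %*% (cand %*% X))^2)
      if (rss_try < rss) { B_try <- cand; break }
      eta <- eta / 2
    }
    if (is.null(B_try)) break
    Z_try <- B_try %*% X
    A_try <- t(simplex_lsq(t(Z_try), t(X), opts$penalty_weight))
    rss_new <- sum((X - A_try %*% Z_try)^2)
    if (rss_new > rss) break                       # keep the previous iterate
    B <- B_try; Z <- Z_try; A <- A_try
    rss_trace <- c(rss_trace, rss_new)
    converged <- (rss - rss_new) / max(rss, .Machine$double.xmin) < opts$min_improvement
    rss <- rss_new
    if (converged) break
    eta <- eta * 1.8
  }

  list(A = A, B = B, Z = Z, rss = rss, rss_trace = rss_trace,
       iterations = iterations, ridge_events = ridge_events)
}

#' Euclidean projection of each matrix row onto the probability simplex
#' @keywords internal
project_rows_simplex <- function(M) {
  t(apply(M, 1L, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    tau <- (1 - css[rho]) / rho
    pmax(v + tau, 0)
  }))
}

#' @export
print.archetype_model <- function(x, ...) {
  cat("Archetype model: k =", x$k, "(", x$d, "dims ), RSS =",
      format(x$rss, digits = 6), "\n")
  cat("  RW (%):    ", paste(sprintf("%.1f", x$rw), collapse = " "), "\n")
  cat("  avg TD (dB):", paste(sprintf("%.1f", x$avg_td), collapse = " "), "\n")
  cat("  normal archetype: AT", x$normal_at, "; restart ", x$restart,
      "; iterations ", x$iterations, "\n", sep = "")
  invisible(x)
}
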
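test_that("fit options validate and reject non-uniform weights", {
  expect_error(fit_options(0), "k")
  expect_error(fit_options(3, n_restarts = 0))
  expect_error(fit_options(3, weights = c(1, 2, 1)), "uniform")
  expect_silent(fit_options(3, weights = rep(2, 5)))
})

test_that("compute_rss matches hand arithmetic and is quadratic", {
  X <- diag(2); A <- diag(2); Z0 <- matrix(0, 2, 2)
  expect_equal(compute_rss(X, A, Z0), 2)               # 1^2 + 1^2
  expect_equal(compute_rss(X, A, X), 0)                # exact reconstruction
  # doubling residuals quadruples RSS
  Z <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  expect_equal(compute_rss(2 * X, A, 2 * Z), 4 * compute_rss(X, A, Z))
  expect_equal(compute_rss(X, A, Z0, normalized = TRUE), 2 / 4)
  expect_error(compute_rss(X, A, matrix(0, 3, 2)), "shape")
})

test_that("condition guard ridges ill-conditioned systems to the bound", {
  I2 <- diag(2)
  g <- condition_guard(I2)
  expect_equal(unclass(g), I2, ignore_attr = TRUE)
  expect_equal(attr(g, "ridge"), 0)

  singular <- matrix(c(1, 1, 1, 1), 2, 2)   # rank 1
  g2 <- condition_guard(singular, max_kappa = 1000)
  expect_gt(attr(g2, "ridge"), 0)
  ev <- eigen(g2, symmetric = TRUE, only.values = TRUE)$values
  expect_lte(max(ev) / min(ev), 1000 * (1 + 1e-8))

  # exactly at the bound: unchanged
  at_bound <- diag(c(1000, 1))
  g3 <- condition_guard(at_bound, max_kappa = 1000)
  expect_equal(attr(g3, "ridge"), 0)
})

test_that("a single archetype is the sample mean", {
  set.seed(10)
  X <- matrix(rnorm(30 * 7, sd = 3), 30, 7)
  m <- suppressWarnings(fit_archetypes(X, fit_options(1, n_restarts = 2)))
  expect_lt(max(abs(m$archetypes[1, ] - colMeans(X))), 1e-6)
})

test_that("triangle vertices are recovered exactly from vertex + interior data", {
  set.seed(2)
  V <- rbind(c(0, 0), c(1, 0), c(0, 1))
  W <- matrix(runif(150), 50, 3); W <- W / rowSums(W)
  X <- rbind(V, W %*% V)
  m <- suppressWarnings(fit_archetypes(X, fit_options(3, n_restarts = 5, seed = 2)))
  expect_lt(m$rss, 1e-8)
  expect_lt(matched_max_dist(m$archetypes, V), 1e-3)
})

test_that("n = k distinct points in general position reconstruct themselves", {
  set.seed(3)
  X <- matrix(rnorm(4 * 6), 4, 6)
  m <- suppressWarnings(fit_archetypes(X, fit_options(4, n_restarts = 4, seed = 3)))
  expect_lt(m$rss, 1e-10)
  expect_error(fit_archetypes(X, fit_options(5)), "at least as many")
  expect_error(fit_archetypes(matrix(0, 5, 3), fit_options(2)), "degenerate")
})

test_that("RSS trace is non-increasing and simplex rows stay feasible", {
  set.seed(4)
  for (rep in 1:4) {
    X <- matrix(rnorm(40 * 8), 40, 8)
    m <- suppressWarnings(fit_archetypes(X, fit_options(3, n_restarts = 1, seed = rep)))
    tr <- m$rss_trace
    expect_true(all(diff(tr) <= 1e-9 * head(tr, -1)))
    expect_true(all(m$A >= 0))
    expect_true(all(m$B >= 0))
    expect_lt(max(abs(rowSums(m$A) - 1)), 1e-8)
    expect_lt(max(abs(rowSums(m$B) - 1)), 1e-8)
    # archetypes are exact convex combinations of the data
    expect_lt(max(abs(m$B %*% X - m$archetypes)), 1e-10)
    # descending-RW order and RW normalization
    expect_true(all(diff(m$rw) <= 1e-9))
    expect_lt(abs(sum(m$rw) - 100), 0.1)
  }
})

test_that("ALS never does materially worse than brute-force grid search (d=2, k=2)", {
  set.seed(5)
  for (n in c(3, 4)) {
    X <- matrix(rnorm(n * 2), n, 2)
    oracle <- oracle_aa_grid_rss(X, step = 0.05)
    m <- suppressWarnings(fit_archetypes(X, fit_options(2, n_restarts = 5, seed = n)))
    expect_lte(m$rss, oracle + 1e-3)
  }
})

test_that("row permutation yields the same archetype set under mapped inits", {
  set.seed(6)
  X <- matrix(rnorm(25 * 5), 25, 5)
  perm <- sample(25)
  init <- list(c(2L, 11L, 24L))
  init_perm <- list(match(init[[1]], perm))
  m1 <- suppressWarnings(fit_archetypes(X, fit_options(3, n_restarts = 1), init_indices = init))
  m2 <- suppressWarnings(fit_archetypes(X[perm, ], fit_options(3, n_restarts = 1),
                                        init_indices = init_perm))
  expect_lt(matched_max_dist(m1$archetypes, m2$archetypes), 1e-6)
})

test_that("fits are deterministic given the seed", {
  set.seed(7)
  X <- matrix(rnorm(30 * 6), 30, 6)
  m1 <- suppressWarnings(fit_archetypes(X, fit_options(3, seed = 99)))
  m2 <- suppressWarnings(fit_archetypes(X, fit_options(3, seed = 99)))
  expect_identical(m1$archetypes, m2$archetypes)
  expect_identical(m1$rss, m2$rss)
})

test_that("models survive a JSON round trip", {
  set.seed(8)
  sim <- simulate_cohort(cohort_spec(n_patients = 12, seed = 8))
  m <- suppressWarnings(fit_archetypes(td_matrix(sim$records),
                                       fit_options(3, n_restarts = 2, seed = 1)))
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  back <- read_model_json(f)
  expect_equal(back$archetypes, m$archetypes, tolerance = 1e-12)
  expect_equal(back$rw, unname(m$rw))
  expect_equal(back$normal_at, m$normal_at)
  # decomposition against the reloaded model agrees
  td <- td_matrix(sim$records)[1, ]
  expect_equal(decompose(td, back)$pw, decompose(td, m)$pw, tolerance = 1e-9)
})
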
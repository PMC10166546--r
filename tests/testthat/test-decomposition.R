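test_that("archetypes decompose to unit percent weights on every fitted model", {
  sim <- simulate_cohort(cohort_spec(n_patients = 15, seed = 21))
  m <- suppressWarnings(fit_archetypes(td_matrix(sim$records),
                                       fit_options(4, n_restarts = 2, seed = 1)))
  for (j in seq_len(m$k)) {
    d <- decompose(m$archetypes[j, ], m)
    unit <- rep(0, m$k); unit[j] <- 100
    expect_lt(max(abs(d$pw - unit)), 1e-6)
    expect_equal(d$dominant_at, j)
  }
})

test_that("an exact two-archetype mixture is recovered at 50/50", {
  lib <- make_pattern_library()
  Z <- rbind(lib$normal$td, lib$inferior_altitudinal$td, lib$global_loss_severe$td)
  model <- as_frozen_model(Z)
  td <- 0.5 * Z[1, ] + 0.5 * Z[2, ]
  d <- decompose(td, model)
  expect_lt(max(abs(d$pw - c(50, 50, 0))), 1e-4)
  expect_lt(d$rss, 1e-12)
})

test_that("solver PW agrees with 0.01-step simplex grid search on k=3 bases", {
  set.seed(31)
  lib <- make_pattern_library()
  Z <- rbind(lib$normal$td, lib$superior_arcuate$td, lib$inferior_nasal_wedge$td)
  model <- as_frozen_model(Z)
  for (i in 1:5) {
    w <- rgamma(3, 1); w <- w / sum(w)
    td <- drop(w %*% Z) + rnorm(52, sd = 0.5)
    d <- decompose(td, model)
    o <- oracle_decompose_grid(td, Z, step = 0.01)
    expect_lt(max(abs(d$pw - 100 * o$w)), 1)
    expect_lte(d$rss, o$rss + 1e-6)
  }
})

test_that("noisy mixtures over well-separated archetypes recover true weights within 5 points", {
  set.seed(7)
  pats <- recovery_patterns()
  lib <- make_pattern_library()
  Z <- do.call(rbind, lapply(lib[pats], `[[`, "td"))
  model <- as_frozen_model(Z)
  worst <- 0
  for (i in 1:100) {
    w <- rgamma(5, 1); w <- w / sum(w)
    td <- drop(w %*% Z) + rnorm(52, sd = 0.25)
    d <- decompose(td, model)
    worst <- max(worst, max(abs(d$pw - 100 * w)))
  }
  expect_lt(worst, 5)
})

test_that("percent weights are convex and sum to 100", {
  set.seed(32)
  Z <- matrix(rnorm(4 * 52, sd = 5), 4, 52)
  model <- as_frozen_model(Z)
  tb <- tiny_vf_table(50, seed = 32)
  dec <- decompose_table(tb, model)
  pw <- as.matrix(dec[, paste0("pw_", 1:4)])
  expect_true(all(pw >= 0))
  expect_lt(max(abs(rowSums(pw) - 100)), 1e-6)
})

test_that("the meaningfulness cutoff is inclusive at 9 and excludes 8", {
  model <- as_frozen_model(matrix(rnorm(3 * 52), 3, 52), normal_at = 1)
  dec <- structure(list(pw = c(83, 9, 8), rss = 0, dominant_at = 1L,
                        meaningful_set = integer(), abnormal_meaningful_set = integer(),
                        cutoff_pct = 9, normal_at = 1L),
                   class = "vf_decomposition")
  expect_equal(meaningful_ats(dec), c(1L, 2L))
  expect_false(3L %in% meaningful_ats(dec))
  expect_true(2L %in% meaningful_ats(dec))   # 9.0 is meaningful
  # only AT1 meaningful -> abnormal set empty
  dec2 <- dec; dec2$pw <- c(95, 3, 2)
  expect_equal(meaningful_ats(dec2), 1L)
})

test_that("abnormal counts exclude the normal archetype", {
  mk_dec <- function(pw, normal_at = 1L) {
    meaningful <- which(pw >= 9)
    structure(list(pw = pw, rss = 0, dominant_at = which.max(pw),
                   meaningful_set = meaningful,
                   abnormal_meaningful_set = setdiff(meaningful, normal_at),
                   cutoff_pct = 9, normal_at = normal_at),
              class = "vf_decomposition")
  }
  expect_equal(count_abnormal(mk_dec(c(100, 0, 0))), 0L)
  expect_equal(count_abnormal(mk_dec(c(40, 30, 30))), 2L)
  expect_equal(count_abnormal(mk_dec(c(5, 50, 45))), 2L)
})

test_that("residual deficits require normal MD plus an abnormal meaningful archetype", {
  mk_dec <- function(pw) {
    meaningful <- which(pw >= 9)
    structure(list(pw = pw, rss = 0, dominant_at = which.max(pw),
                   meaningful_set = meaningful,
                   abnormal_meaningful_set = setdiff(meaningful, 1L),
                   cutoff_pct = 9, normal_at = 1L),
              class = "vf_decomposition")
  }
  expect_true(residual_deficit(-1, mk_dec(c(85, 15, 0))))
  expect_false(residual_deficit(-1, mk_dec(c(95, 5, 0))))
  expect_false(residual_deficit(-3, mk_dec(c(85, 15, 0))))
  expect_true(residual_deficit(-2, mk_dec(c(85, 15, 0))))   # -2.00 is "normal"
})

test_that("decompose validates dimensions and grid compatibility", {
  model <- as_frozen_model(matrix(rnorm(2 * 52), 2, 52))
  expect_error(decompose(rnorm(51), model), "52")
  model2 <- as_frozen_model(matrix(rnorm(2 * 10), 2, 10))
  expect_error(decompose(rnorm(52), model2), "10")
})
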
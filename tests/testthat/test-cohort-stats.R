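test_that("relative weights are mean percent weights and sum to 100", {
  Z <- matrix(rnorm(2 * 52, sd = 5), 2, 52)
  model <- as_frozen_model(Z)
  tb <- tiny_vf_table(2)
  tb[, sprintf("td_%02d", 1:52)] <- as.data.frame(Z)   # field i = archetype i
  dec <- decompose_table(tb, model)
  rw <- relative_weights(dec)
  expect_equal(unname(rw), c(50, 50), tolerance = 1e-6)

  # identical fields: RW equals that field's PW vector
  tb2 <- tiny_vf_table(4)
  mix <- 0.3 * Z[1, ] + 0.7 * Z[2, ]
  tb2[, sprintf("td_%02d", 1:52)] <- as.data.frame(matrix(mix, 4, 52, byrow = TRUE))
  dec2 <- decompose_table(tb2, model)
  rw2 <- relative_weights(dec2)
  expect_equal(unname(rw2), unname(unlist(dec2[1, c("pw_1", "pw_2")])), tolerance = 1e-9)
  expect_lt(abs(sum(rw2) - 100), 0.1)
  expect_error(relative_weights(tb2), "decompose_table")
})

test_that("RW of a Dirichlet cohort matches the analytic mixture mean", {
  pats <- recovery_patterns()
  alpha <- c(2, 1, 0.5, 0.5, 1)
  spec <- cohort_spec(n_patients = 250, eyes_per_patient = 2, visit_days = 0,
                      patterns = pats, mixing = stats::setNames(alpha, pats),
                      recovery_drift = 0, noise_sd = 0.5, seed = 11)
  sim <- simulate_cohort(spec)    # 500 single-visit fields
  model <- as_frozen_model(sim$truth$templates)
  dec <- decompose_table(sim$records, model)
  rw <- relative_weights(dec)
  expect_lt(max(abs(unname(rw) - 100 * alpha / sum(alpha))), 2)
})

test_that("average TD is the unweighted mean of the archetype", {
  expect_equal(average_td(rep(0, 52)), 0)
  expect_equal(average_td(rep(-30, 52)), -30)
  expect_equal(average_td(rep(2.4, 52)), 2.4)
})

test_that("prevalence counts fields with meaningful weight per archetype", {
  Z <- matrix(rnorm(3 * 52, sd = 6), 3, 52)
  model <- as_frozen_model(Z, normal_at = 1)
  tb <- tiny_vf_table(4)
  mixes <- rbind(c(1, 0, 0), c(0.8, 0.2, 0), c(0.7, 0.3, 0), c(0.5, 0, 0.5))
  tb[, sprintf("td_%02d", 1:52)] <- as.data.frame(mixes %*% Z)
  dec <- decompose_table(tb, model)
  prev <- at_prevalence(dec)
  expect_equal(prev$prevalence$n_meaningful[2], 2)   # AT2 meaningful in 2 of 4
  expect_equal(prev$prevalence$pct[2], 50)
  expect_equal(prev$pct_no_abnormal, 25)             # only the pure-AT1 field
  expect_warning(at_prevalence(dec, scope = "final"), "no fields")
})

test_that("Spearman correlation matches sign conventions and a naive oracle", {
  expect_equal(pw_md_correlation(1:10, (1:10)^2)$rho, 1)
  expect_equal(pw_md_correlation(1:10, -(1:10))$rho, -1)
  expect_equal(pw_md_correlation(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  set.seed(41)
  for (i in 1:6) {
    n <- sample(5:12, 1)
    x <- sample(1:6, n, replace = TRUE)   # ties exercised
    y <- rnorm(n)
    if (sd(x) == 0) next
    expect_equal(pw_md_correlation(x, y)$rho, naive_spearman(x, y), tolerance = 1e-12)
  }
  expect_error(pw_md_correlation(rep(1, 5), rnorm(5)), "constant")
})

test_that("group comparisons reproduce exact reference cases", {
  same <- c(1, 2, 3, 4, 5)
  expect_gt(compare_groups(same, same)$p, 0.9)
  sep <- compare_groups(1:20, 101:120)
  expect_equal(unname(sep$statistic), 0)   # complete separation: U = 0
  expect_lt(sep$p, 0.001)
  flat <- compare_groups(matrix(50, 2, 2), kind = "chisq")
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p, 1)
  expect_error(compare_groups(matrix(c(0, 0, 5, 5), 2, 2), kind = "chisq"), "expected cell")
})

test_that("prognosis split divides eyes at the mean presentation AT1 PW", {
  Z <- matrix(rnorm(2 * 52, sd = 5), 2, 52)
  model <- as_frozen_model(Z, normal_at = 1)
  tb <- tiny_vf_table(2)
  mixes <- rbind(c(0.4, 0.6), c(0.6, 0.4))
  tb[, sprintf("td_%02d", 1:52)] <- as.data.frame(mixes %*% Z)
  tb$patient_id <- c("A", "B")
  dec <- decompose_table(tb, model)
  ps <- prognosis_split(dec)
  expect_equal(ps$mean_at1_pw, 50, tolerance = 1e-6)
  expect_equal(sort(table(ps$groups$group)), sort(c(above = 1L, below = 1L)),
               ignore_attr = TRUE)

  # all eyes identical -> degenerate split
  tb2 <- tb; tb2[2, sprintf("td_%02d", 1:52)] <- tb2[1, sprintf("td_%02d", 1:52)]
  dec2 <- decompose_table(tb2, model)
  expect_error(prognosis_split(dec2), "degenerate")
})

test_that("a planted prognosis effect separates the groups on follow-up MD", {
  sim <- simulate_cohort(cohort_spec(n_patients = 120, eyes_per_patient = 1, seed = 21))
  model <- as_frozen_model(sim$truth$templates)
  dec <- decompose_table(sim$records, model)
  ps <- prognosis_split(dec)
  expect_gte(min(table(ps$groups$group)), 30)
  curve <- ps$md_curve
  fin <- curve[curve$window == "final", ]
  expect_gt(fin$mean_md[fin$group == "above"], fin$mean_md[fin$group == "below"])
  expect_lt(ps$tests$p_md[ps$tests$window == "final"], 0.05)
  # above-mean eyes keep a higher normal-archetype weight at final visit
  expect_gt(ps$final_at1_pw$mean_at1_pw[ps$final_at1_pw$group == "above"],
            ps$final_at1_pw$mean_at1_pw[ps$final_at1_pw$group == "below"])
})
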
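# Non-inferiority margin construction: DerSimonian-Laird pooling against an
# independent closed-form oracle, the A-B-C-D margin geometry, and the
# one-sided non-inferiority test.

test_that("single-study pooling reduces to the study itself", {
  expect_warning(
    pooled <- pool_random_effects(data.frame(effect = -2.0, se = 0.5)),
    "single study")
  expect_equal(pooled$estimate, -2.0)
  expect_equal(pooled$tau2, 0)
  expect_true(pooled$single_study)
  expect_equal(pooled$ci_lower, -2.0 - qnorm(0.975) * 0.5, tolerance = 1e-10)
  expect_equal(pooled$ci_upper, -2.0 + qnorm(0.975) * 0.5, tolerance = 1e-10)
  expect_error(pool_random_effects(data.frame(effect = numeric(), se = numeric())),
               "at least one")
})

test_that("identical studies force tau2 = 0 and inverse-variance pooling", {
  pooled <- pool_random_effects(data.frame(effect = c(-2, -2), se = 0.5))
  expect_equal(pooled$tau2, 0)
  expect_equal(pooled$estimate, -2.0)
  expect_equal(pooled$se, 0.5 / sqrt(2), tolerance = 1e-10)
})

test_that("DL pooling matches the closed-form oracle to 1e-10 relative error", {
  cases <- list(
    data.frame(effect = c(-1, -2, -3), se = 0.3),
    data.frame(effect = c(-2.1, -1.6, -2.8, -1.9, -2.4),
               se = c(0.45, 0.60, 0.52, 0.38, 0.70)),
    data.frame(effect = c(-0.5, -0.7), se = c(0.2, 0.35)),
    data.frame(effect = c(-3, -3.1, -2.9, -3.05), se = c(1, 0.8, 1.2, 0.9)))
  for (d in cases) {
    got <- pool_random_effects(d)
    want <- dl_pool_oracle(d$effect, d$se)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$tau2, want$tau2, tolerance = 1e-10)
    expect_equal(got$ci_lower, want$ci_lower, tolerance = 1e-10)
    expect_equal(got$ci_upper, want$ci_upper, tolerance = 1e-10)
  }
  # symmetric heterogeneous case: positive tau2, estimate -2 by symmetry
  got <- pool_random_effects(cases[[1]])
  expect_gt(got$tau2, 0)
  expect_equal(got$estimate, -2, tolerance = 1e-10)
})

test_that("when tau2 estimates to zero, pooling is fixed-effect inverse-variance", {
  # homogeneous data (Q <= k-1) truncates tau2 at 0, so the random-effects
  # weights collapse to the fixed-effect 1/v weights
  dh <- data.frame(effect = c(-2.0, -2.01, -1.99), se = c(1, 0.5, 0.8))
  got <- pool_random_effects(dh)
  expect_equal(got$tau2, 0)
  w <- 1 / dh$se^2
  expect_equal(got$estimate, sum(w * dh$effect) / sum(w), tolerance = 1e-10)
  expect_equal(got$se, sqrt(1 / sum(w)), tolerance = 1e-10)
})

test_that("margin geometry preserves the stated fraction of effect", {
  pooled <- structure(list(estimate = -2, se = 0.4, tau2 = 0,
                           ci_lower = -2.8, ci_upper = -1.2, k = 3,
                           level = 0.95, single_study = FALSE),
                      class = "pooled_effect")
  # lower-is-better: conservative bound is the upper CI limit (-1.2)
  m50 <- compute_margin(pooled, placebo_mean = 0, control_mean = -2,
                        preserved_fraction = 0.5)
  expect_equal(m50$B, -1.2)
  expect_equal(m50$D, (m50$B + m50$C) / 2)       # midpoint of B and C
  expect_equal(m50$margin, 0.5 * (m50$B - m50$C))
  m67 <- compute_margin(pooled, 0, -2, preserved_fraction = 0.67)
  expect_equal(m67$margin, 0.33 * (m67$B - m67$C), tolerance = 1e-12)
  m1 <- compute_margin(pooled, 0, -2, preserved_fraction = 1)
  expect_equal(m1$margin, 0)
  expect_equal(m1$D, m1$C)
  m0 <- compute_margin(pooled, 0, -2, preserved_fraction = 0)
  expect_equal(m0$D, m0$B)
  # linear and strictly decreasing in f
  fs <- seq(0, 1, by = 0.1)
  margins <- vapply(fs, function(f) compute_margin(pooled, 0, -2, f)$margin, 0)
  expect_equal(margins, (1 - fs) * (m50$B - m50$C), tolerance = 1e-12)
  expect_true(all(diff(margins) < 0))
  # control not shown effective: upper CI above zero
  bad <- pooled; bad$ci_upper <- 0.1
  expect_error(compute_margin(bad, 0, -2), "no non-inferiority margin")
})

test_that("one-sided NI p-value has the CI-test duality", {
  expect_equal(ni_pvalue(-0.3, 0.2, -0.3), 0.5)
  expect_equal(ni_pvalue(0.2 - 1.96 * 0.1, 0.1, 0.2), pnorm(-1.96))
  expect_equal(ni_pvalue(-0.5, 0.2, 0), pnorm(-2.5), tolerance = 1e-10)
  expect_equal(round(ni_pvalue(-0.5, 0.2, 0), 5), 0.00621)
  set.seed(5)
  for (rep in 1:200) {
    est <- rnorm(1); se <- runif(1, 0.05, 1); margin <- rnorm(1)
    p <- ni_pvalue(est, se, margin)
    upper <- est + qnorm(0.975) * se
    expect_identical(p < 0.025, upper < margin)
  }
})

test_that("study CSV reading validates its columns", {
  path <- system.file("extdata", "synthetic_historical_studies.csv",
                      package = "mtpgraph")
  d <- read_studies(path)
  expect_named(d, c("study_id", "effect", "se"))
  expect_equal(nrow(d), 5)
  bad <- tempfile(fileext = ".csv")
  writeLines("study_id,effect\nS1,-2", bad)
  expect_error(read_studies(bad), "columns")
  writeLines("study_id,effect,se\nS1,-2,0", bad)
  expect_error(read_studies(bad), "positive")
})
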
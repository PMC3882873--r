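# Trial simulator and Monte Carlo operating characteristics.

test_that("scenario validation catches impossible configurations", {
  expect_error(trial_scenario(n_per_arm = 1), "n_per_arm")
  expect_error(trial_scenario(sds = c(1, -1)), "sds")
  expect_error(trial_scenario(endpoint_correlation = 1.5), "correlation")
  expect_error(trial_scenario(means = matrix(0, 2, 2)), "3 x 2")
  expect_error(estimate_oc(trial_scenario(), build_holm(2)), "H1..H6")
})

test_that("identical seeds reproduce identical results", {
  s <- trial_scenario(n_reps = 500, seed = 99)
  a <- simulate_trial(s)
  b <- simulate_trial(s)
  expect_identical(a, b)
  oc1 <- estimate_oc(s, build_recycling())
  oc2 <- estimate_oc(s, build_recycling())
  expect_identical(oc1, oc2)
})

test_that("an enormous margin makes the NI p-values vanish", {
  s <- trial_scenario(n_reps = 200, margin = 50, seed = 2,
                      means = rbind(high = c(0, 0), low = c(0, 0), control = c(0, 0)))
  p <- simulate_trial(s)$p
  expect_lt(max(p[, c("H1", "H2")]), 1e-10)
})

test_that("null p-values are marginally uniform", {
  s <- trial_scenario(n_reps = 10000, margin = 0, seed = 3,
                      means = matrix(0, 3, 2))
  p <- simulate_trial(s)$p
  for (i in colnames(p)) {
    expect_gt(ks.test(p[, i], "punif")$p.value, 1e-4)
  }
})

test_that("swapping the endpoints swaps the superiority p-value distributions", {
  means <- rbind(high = c(-0.3, -0.1), low = c(-0.2, -0.05), control = c(0, 0))
  s1 <- trial_scenario(n_reps = 4000, seed = 4, means = means, sds = c(1, 2))
  s2 <- trial_scenario(n_reps = 4000, seed = 5,
                       means = means[, 2:1], sds = c(2, 1))
  p1 <- simulate_trial(s1)$p
  p2 <- simulate_trial(s2)$p
  expect_gt(ks.test(p1[, "H3"], p2[, "H4"])$p.value, 1e-4)
  expect_gt(ks.test(p1[, "H6"], p2[, "H5"])$p.value, 1e-4)
})

test_that("truth labels follow the margin and zero cutoffs", {
  s <- trial_scenario(margin = 0.2,
                      means = rbind(high = c(-0.5, -0.3), low = c(0.2, 0),
                                    control = c(0, 0)))
  truth <- simulate_trial(trial_scenario(n_reps = 10, seed = 1, margin = 0.2,
                                         means = s$means))$truth
  expect_identical(unname(truth),
                   c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("alpha = 0 rejects nothing and FWER is controlled at the boundary null", {
  s0 <- trial_scenario(n_reps = 1000, alpha = 0, seed = 6)
  oc0 <- estimate_oc(s0, build_gatekeeping())
  expect_equal(oc0$fwer, 0)
  s <- trial_scenario(n_reps = 20000, seed = 7)
  for (g in fixture_presets()) {
    oc <- estimate_oc(s, g)
    expect_lte(oc$fwer, s$alpha + 3 * oc$fwer_se)
    expect_true(all(oc$reject_rate >= 0 & oc$reject_rate <= 1))
  }
})

test_that("recycling beats gatekeeping for H2 when the high dose is fully effective", {
  means <- rbind(high = c(-0.6, -0.5), low = c(0.05, 0.2), control = c(0, 0))
  s <- trial_scenario(n_reps = 20000, seed = 8, means = means, margin = 0.2)
  oc_gate <- estimate_oc(s, build_gatekeeping())
  oc_rec <- estimate_oc(s, build_recycling())
  expect_gte(oc_rec$reject_rate[["H2"]], oc_gate$reject_rate[["H2"]])
  expect_gt(oc_rec$reject_rate[["H2"]], oc_gate$reject_rate[["H2"]] + 0.01)
})

test_that("the t option agrees with z at Phase III sample sizes", {
  means <- rbind(high = c(-0.4, -0.3), low = c(-0.1, 0), control = c(0, 0))
  sz <- trial_scenario(n_reps = 2000, seed = 9, means = means, method = "z")
  st <- trial_scenario(n_reps = 2000, seed = 10, means = means, method = "t")
  pz <- simulate_trial(sz)$p
  pt_ <- simulate_trial(st)$p
  for (i in c("H1", "H3", "H4")) {
    expect_lt(abs(mean(pz[, i] < 0.025) - mean(pt_[, i] < 0.025)), 0.05)
  }
})
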
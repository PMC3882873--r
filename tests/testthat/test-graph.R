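# Graph engine: local levels, the rejection-update rule, full runs, traces,
# adjusted p-values.

we <- worked_example()

test_that("initial local levels follow the alpha split", {
  lv <- local_levels(build_gatekeeping(), alpha = 0.05)
  expect_true(lv$H1 == ev(0.025))
  expect_true(lv$H2 == ev(0.025))
  for (i in paste0("H", 3:6)) expect_true(lv[[i]] == ev(0))
  # degenerate graph: all weights zero -> all levels zero
  g0 <- mtp_graph(c("A", "B"), c(0, 0))
  expect_true(all(vapply(local_levels(g0, 0.05), function(v) v == ev(0), TRUE)))
})

test_that("rejection updates reproduce the recycling walkthrough weights", {
  g <- build_recycling()
  g1 <- update_after_rejection(g, "H1")
  expect_true(g1$weights$H3 == ev("1/4"))
  expect_true(g1$weights$H4 == ev("1/4"))
  expect_true(g1$weights$H2 == ev("1/2"))
  lv <- local_levels(g1, 0.05)
  expect_equal(ev_limit(lv$H3), 0.0125)
  g2 <- update_after_rejection(g1, "H4")
  expect_true(g2$weights$H3 == ev("3/8"))
  expect_true(g2$weights$H2 == ev("5/8"))
})

test_that("a sink hypothesis consumes its level on rejection", {
  g <- mtp_graph(c("A", "B", "C"), c("1/2", "1/4", "1/4"),
                 data.frame(from = "B", to = "C", weight = "1"))
  g1 <- update_after_rejection(g, "A")  # A has no outgoing edges
  expect_true(g1$weights$B == ev("1/4"))
  expect_true(g1$weights$C == ev("1/4"))
  expect_true(active_weight_sum(g1) == ev("1/2"))
})

test_that("epsilon cross-over transition resolves to 1 in the limit", {
  g <- build_epsilon()
  g2 <- update_after_rejection(update_after_rejection(g, "H1"), "H4")
  expect_true(g2$trans[["H3"]][["H2"]] == ev(1))
  # numeric oracle: same transition with eps as a descending numeric value
  for (e in c(1e-4, 1e-6, 1e-8)) {
    num <- as_numeric_graph(g, e)
    w <- num$w; G <- num$G
    remaining <- rownames(G)
    # replicate the two updates numerically
    for (j in c("H1", "H4")) {
      remaining <- setdiff(remaining, j)
      act <- remaining
      w[act] <- w[act] + w[j] * G[j, act]
      G2 <- G
      for (l in act) for (k in setdiff(act, l)) {
        den <- 1 - G[l, j] * G[j, l]
        G2[l, k] <- if (den > 0) (G[l, k] + G[l, j] * G[j, k]) / den else 0
      }
      G2[j, ] <- 0; G2[, j] <- 0
      G <- G2; w[j] <- 0
    }
    expect_equal(G["H3", "H2"], 1, tolerance = 10 * e)
  }
})

test_that("full runs reproduce the printed rejection sets", {
  expect_setequal(rejections(build_gatekeeping(), we$pvalues, we$alpha),
                  c("H1", "H3", "H4"))
  tr <- run_procedure(build_recycling(), we$pvalues, we$alpha)
  expect_setequal(tr$final_rejections, c("H1", "H2", "H4"))
  expect_equal(ev_limit(trace_level(tr, "H6")), 5 * 0.05 / 16)
  expect_equal(ev_limit(trace_level(tr, "H3")), 3 * 0.05 / 8)
  expect_setequal(rejections(build_epsilon(), we$pvalues, we$alpha),
                  c("H1", "H2", "H3", "H4", "H6"))
  # nothing is rejected when every p-value is 1
  for (g in fixture_presets()) {
    expect_length(rejections(g, rep(1, 6), 0.05), 0)
  }
})

test_that("traces record each hypothesis exactly once with a decision", {
  for (g in fixture_presets()) {
    tr <- run_procedure(g, we$pvalues, we$alpha)
    ids <- vapply(tr$steps, `[[`, "", "id")
    expect_setequal(ids, g$ids)
    expect_false(anyDuplicated(ids) > 0)
    rej <- ids[vapply(tr$steps, `[[`, "", "decision") == "reject"]
    expect_setequal(rej, tr$final_rejections)
  }
})

test_that("invalid inputs are rejected with descriptive errors", {
  g <- build_gatekeeping()
  expect_error(run_procedure(g, c(we$pvalues[-6], H6 = 1.2)), "0, 1")
  expect_error(run_procedure(g, we$pvalues[-1]), "p-value")
  expect_error(run_procedure(g, we$pvalues, alpha = 0), "alpha")
  expect_error(update_after_rejection(g, "H9"), "unknown")
  expect_error(mtp_graph(c("A", "A"), c(1, 0)), "unique")
  expect_error(mtp_graph(c("A", "B"), c("3/4", "1/2")), "sum above 1")
  expect_error(
    mtp_graph(c("A", "B", "C"), c("1/2", "1/2", "0"),
              data.frame(from = c("A", "A"), to = c("B", "C"), weight = c("3/4", "1/2"))),
    "row sum.*A")
})

test_that("adjusted p-values match a Holm oracle and direct runs", {
  gh <- build_holm(2)
  adj <- adjusted_pvalues(gh, c(H1 = 0.01, H2 = 0.04))
  # textbook Holm: (2*min(p), max(max(p), 2*min(p)))
  expect_equal(unname(adj), c(0.02, 0.04), tolerance = 1e-4)

  g1 <- mtp_graph("A", list(1))
  expect_equal(unname(adjusted_pvalues(g1, c(A = 0.0317))), 0.0317, tolerance = 1e-4)

  g <- build_gatekeeping()
  adj <- adjusted_pvalues(g, we$pvalues)
  expect_lte(adj[["H1"]], 0.05)
  expect_gt(adj[["H5"]], 0.05)
  # duality: H rejected at alpha iff adjusted p <= alpha (within tolerance)
  for (a in c(0.01, 0.025, 0.05, 0.1, 0.2)) {
    rej <- rejections(g, we$pvalues, a)
    for (i in g$ids) {
      if (adj[[i]] <= a - 1e-5) expect_true(i %in% rej)
      if (adj[[i]] > a + 1e-5) expect_false(i %in% rej)
    }
  }
})
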
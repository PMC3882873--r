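# Independent oracles used across the suite.

# closed-form DerSimonian-Laird pooling, written from the moment-estimator
# formulas; deliberately shares no code with pool_random_effects()
dl_pool_oracle <- function(effect, se, level = 0.95) {
  v <- se^2
  w <- 1 / v
  k <- length(effect)
  mu_fe <- sum(w * effect) / sum(w)
  Q <- sum(w * (effect - mu_fe)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  wr <- 1 / (v + tau2)
  est <- sum(wr * effect) / sum(wr)
  sem <- sqrt(1 / sum(wr))
  z <- qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = sem, tau2 = tau2, Q = Q,
       ci_lower = est - z * sem, ci_upper = est + z * sem)
}

# textbook Holm on a p-vector (step-down weighted Bonferroni, equal weights)
holm_reject_oracle <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  rejected <- rep(FALSE, n)
  for (step in seq_len(n)) {
    i <- o[step]
    if (p[i] <= alpha / (n - step + 1)) rejected[i] <- TRUE else break
  }
  names(p)[rejected]
}

# sum of active weights of a graph, as an eps_value
active_weight_sum <- function(g) {
  ids <- setdiff(g$ids, g$rejected)
  total <- ev(0)
  for (i in ids) total <- total + g$weights[[i]]
  total
}

fixture_presets <- function(split = c("1/2", "1/2")) {
  list(gatekeeping = build_gatekeeping(split),
       recycling = build_recycling(split),
       epsilon = build_epsilon(split),
       `direct-path` = build_direct_path(split))
}
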
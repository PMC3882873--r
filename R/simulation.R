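# Monte Carlo verification of operating characteristics for the three-arm,
# two-endpoint design. Trials are simulated at the level of arm-by-endpoint
# sample means, drawn from their exact sampling distribution (bivariate
# normal with covariance Sigma/n per arm) -- distributionally identical to
# drawing subject-level data and summarizing, and fast enough for 1e5
# replicates. A t option draws subject-level data instead.

#' Define a simulation scenario for the three-arm, two-endpoint design
#'
#' Arms are `high`, `low` (the two doses) and `control`; endpoints are
#' `primary` and `secondary`, both change-from-baseline with negative values
#' meaning improvement. The six p-values map to the design hypotheses:
#' H1/H2 test each dose's primary-endpoint difference against the
#' non-inferiority margin (one-sided), H3..H6 test superiority (difference
#' against 0, one-sided).
#'
#' The default means put both doses exactly at the margin on the primary
#' endpoint and level with control on the secondary endpoint: the boundary
#' global null, where every hypothesis is true and family-wise error is at
#' its worst case.
#'
#' @param n_per_arm subjects per arm.
#' @param means 3 x 2 matrix of true means, rows `high`, `low`, `control`,
#'   columns `primary`, `secondary`.
#' @param sds length-2 positive SDs per endpoint.
#' @param endpoint_correlation correlation between the two endpoints within
#'   subject.
#' @param margin non-inferiority margin for the primary endpoint (allowed
#'   excess of dose over control; positive since lower is better).
#' @param alpha overall two-sided significance level.
#' @param n_reps Monte Carlo replicates.
#' @param seed RNG seed for reproducibility.
#' @param method `"z"` (known variance; arm means drawn directly) or `"t"`
#'   (subject-level data, Welch-free pooled two-sample t).
#' @return A `trial_scenario` list.
#' @export
trial_scenario <- function(n_per_arm = 200,
                           means = NULL,
                           sds = c(1, 1),
                           endpoint_correlation = 0.3,
                           margin = 0.2,
                           alpha = 0.05,
                           n_reps = 10000,
                           seed = 1L,
                           method = c("z", "t")) {
  method <- match.arg(method)
  if (is.null(means)) {
    means <- rbind(high = c(margin, 0), low = c(margin, 0), control = c(0, 0))
  }
  means <- as.matrix(means)
  if (!all(dim(means) == c(3, 2))) stop("means must be a 3 x 2 matrix")
  if (is.null(rownames(means))) rownames(means) <- c("high", "low", "control")
  if (is.null(colnames(means))) colnames(means) <- c("primary", "secondary")
  rho <- endpoint_correlation
  if (n_per_arm < 2 || any(sds <= 0) || abs(rho) > 1) {
    stop("invalid scenario: need n_per_arm >= 2, sds > 0, |correlation| <= 1")
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!all(dim(means) == c(3, 2))) stop("means must be a 3 x 2 matrix")
  structure(list(n_per_arm = as.integer(n_per_arm), means = means, sds = sds,
                 endpoint_correlation = rho, margin = margin, alpha = alpha,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 method = method),
            class = "trial_scenario")
}

# which of H1..H6 are true nulls under the scenario's means
scenario_truth <- function(s) {
  d <- s$means[c("high", "low"), , drop = FALSE] -
    rep(1, 2) %o% s$means["control", ]
  c(H1 = d["high", "primary"] >= s$margin,
    H2 = d["low", "primary"] >= s$margin,
    H3 = d["high", "primary"] >= 0,
    H4 = d["high", "secondary"] >= 0,
    H5 = d["low", "primary"] >= 0,
    H6 = d["low", "secondary"] >= 0)
}

# correlated pair of standard-normal matrices (reps x k) with correlation rho
.corr_normals <- function(reps, k, rho) {
  z1 <- matrix(stats::rnorm(reps * k), reps, k)
  z2 <- rho * z1 + sqrt(1 - rho^2) * matrix(stats::rnorm(reps * k), reps, k)
  list(z1, z2)
}

#' Simulate trial replicates and their six raw p-values
#'
#' @param s a [trial_scenario()].
#' @return List with `p`, an `n_reps` x 6 matrix of p-values (columns
#'   H1..H6), and `truth`, the logical vector of true nulls implied by the
#'   scenario means.
#' @export
simulate_trial <- function(s) {
  stopifnot(inherits(s, "trial_scenario"))
  set.seed(s$seed)
  n <- s$n_per_arm
  rho <- s$endpoint_correlation
  reps <- s$n_reps
  if (s$method == "z") {
    se_mean <- s$sds / sqrt(n)
    arm <- function(name) {
      z <- .corr_normals(reps, 1, rho)
      cbind(s$means[name, 1] + se_mean[1] * z[[1]],
            s$means[name, 2] + se_mean[2] * z[[2]])
    }
    mh <- arm("high"); ml <- arm("low"); mc <- arm("control")
    se_diff <- s$sds * sqrt(2 / n)
    pz <- function(diff, endpoint, shift) stats::pnorm((diff - shift) / se_diff[endpoint])
    p <- cbind(
      H1 = pz(mh[, 1] - mc[, 1], 1, s$margin),
      H2 = pz(ml[, 1] - mc[, 1], 1, s$margin),
      H3 = pz(mh[, 1] - mc[, 1], 1, 0),
      H4 = pz(mh[, 2] - mc[, 2], 2, 0),
      H5 = pz(ml[, 1] - mc[, 1], 1, 0),
      H6 = pz(ml[, 2] - mc[, 2], 2, 0))
  } else {
    p <- matrix(NA_real_, reps, 6,
                dimnames = list(NULL, paste0("H", 1:6)))
    Sig <- diag(s$sds) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(s$sds)
    ch <- chol(Sig)
    draw_arm <- function(name) {
      x <- matrix(stats::rnorm(2 * n), n, 2) %*% ch
      sweep(x, 2, s$means[name, ], "+")
    }
    for (r in seq_len(reps)) {
      xh <- draw_arm("high"); xl <- draw_arm("low"); xc <- draw_arm("control")
      tt <- function(x, y, endpoint, shift) {
        sp2 <- (stats::var(x[, endpoint]) + stats::var(y[, endpoint])) / 2
        stat <- (mean(x[, endpoint]) - mean(y[, endpoint]) - shift) / sqrt(sp2 * 2 / n)
        stats::pt(stat, df = 2 * n - 2)
      }
      p[r, ] <- c(tt(xh, xc, 1, s$margin), tt(xl, xc, 1, s$margin),
                  tt(xh, xc, 1, 0), tt(xh, xc, 2, 0),
                  tt(xl, xc, 1, 0), tt(xl, xc, 2, 0))
    }
  }
  list(p = p, truth = scenario_truth(s))
}

#' Numeric view of a graph with epsilon evaluated at a small value
#'
#' @param g an `mtp_graph`.
#' @param eps_num concrete value substituted for eps (default 1e-8).
#' @return List with numeric weight vector `w` and transition matrix `G`.
#' @export
as_numeric_graph <- function(g, eps_num = 1e-8) {
  n <- length(g$ids)
  w <- vapply(g$ids, function(i) ev_eval(g$weights[[i]], eps_num), 0)
  G <- matrix(0, n, n, dimnames = list(g$ids, g$ids))
  for (i in g$ids) for (j in g$ids) G[i, j] <- ev_eval(g$trans[[i]][[j]], eps_num)
  list(w = w, G = G)
}

#' Fast numeric rejection sets for a matrix of p-value vectors
#'
#' Runs the sequentially rejective procedure on each row of `p` using the
#' compiled numeric engine, with epsilon edges evaluated at `eps_num`.
#' Agrees with [run_procedure()] on every graph where no p-value falls
#' within `eps_num` of a knife-edge level (see the numeric-epsilon
#' equivalence property tests).
#'
#' @param g an `mtp_graph`.
#' @param p numeric matrix (replicates x hypotheses) or a single vector.
#' @param alpha overall significance level.
#' @param eps_num value substituted for eps.
#' @return Logical matrix of rejections, columns named by hypothesis.
#' @export
run_graph_numeric <- function(g, p, alpha = 0.05, eps_num = 1e-8) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  num <- as_numeric_graph(g, eps_num)
  out <- run_graph_many(num$w, num$G, unname(as.matrix(p)), alpha)
  colnames(out) <- g$ids
  out
}

#' Estimate operating characteristics of a procedure by Monte Carlo
#'
#' Simulates the scenario, applies the graph procedure to every replicate,
#' and reports the family-wise error rate (any true null rejected),
#' per-hypothesis rejection rates, and conjunctive/disjunctive power over
#' the false nulls, with Monte Carlo standard errors.
#'
#' @param s a [trial_scenario()].
#' @param g an `mtp_graph` whose hypotheses are H1..H6.
#' @param eps_num numeric epsilon used in the compiled engine.
#' @return An `mtp_oc` list: `fwer`, `fwer_se`, `reject_rate` (named),
#'   `power_conj`, `power_disj` (NA when no null is false), `n_reps`,
#'   `truth`.
#' @export
estimate_oc <- function(s, g, eps_num = 1e-8) {
  stopifnot(inherits(s, "trial_scenario"))
  if (!identical(g$ids, paste0("H", 1:6))) {
    stop("graph hypotheses must be H1..H6 to match the trial design")
  }
  sim <- simulate_trial(s)
  rej <- run_graph_numeric(g, sim$p, alpha = s$alpha, eps_num = eps_num)
  truth <- sim$truth
  fwer <- if (any(truth)) mean(rowSums(rej[, truth, drop = FALSE]) > 0) else 0
  rate <- colMeans(rej)
  false_nulls <- !truth
  conj <- if (any(false_nulls)) mean(rowSums(rej[, false_nulls, drop = FALSE]) == sum(false_nulls)) else NA_real_
  disj <- if (any(false_nulls)) mean(rowSums(rej[, false_nulls, drop = FALSE]) > 0) else NA_real_
  structure(list(fwer = fwer,
                 fwer_se = sqrt(fwer * (1 - fwer) / s$n_reps),
                 reject_rate = rate,
                 power_conj = conj, power_disj = disj,
                 n_reps = s$n_reps, truth = truth, alpha = s$alpha),
            class = "mtp_oc")
}

#' @export
print.mtp_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d replicates (alpha = %g)\n",
              x$n_reps, x$alpha))
  cat(sprintf("  FWER %.4f (MC SE %.4f); true nulls: %s\n", x$fwer, x$fwer_se,
              paste(names(x$truth)[x$truth], collapse = " ")))
  for (i in names(x$reject_rate)) {
    cat(sprintf("  %-3s rejected %.4f\n", i, x$reject_rate[[i]]))
  }
  if (!is.na(x$power_conj)) {
    cat(sprintf("  conjunctive power %.4f, disjunctive power %.4f\n",
                x$power_conj, x$power_disj))
  }
  invisible(x)
}

#' Generate a random small hypothesis graph with exact rational weights
#'
#' Weights are a random composition n_i/denom summing to 1; each transition
#' row is a random composition scaled to a random total at most 1. With
#' probability `eps_prob` a positive edge is replaced by a symbolic `eps`
#' edge. Used by the property-test suites (mass conservation, order
#' invariance, numeric-epsilon equivalence) on many random instances.
#'
#' @param n number of hypotheses.
#' @param denom denominator grid for the rational weights.
#' @param eps_prob probability of demoting a given positive edge to weight
#'   `eps`.
#' @return An `mtp_graph`. Uses the current RNG stream.
#' @export
random_mtp_graph <- function(n = 4, denom = 16, eps_prob = 0.15) {
  ids <- paste0("H", seq_len(n))
  wnum <- as.vector(stats::rmultinom(1, denom, rep(1, n)))
  w <- lapply(wnum, function(k) ev(k) / denom)
  edges <- NULL
  for (i in seq_len(n)) {
    tot <- sample(0:denom, 1)
    if (tot == 0) next
    enum <- as.vector(stats::rmultinom(1, tot, rep(1, n - 1)))
    targets <- setdiff(seq_len(n), i)
    for (t in seq_along(targets)) {
      if (enum[t] == 0) next
      wt <- if (stats::runif(1) < eps_prob) eps() else ev(enum[t]) / denom
      edges <- rbind(edges, data.frame(from = ids[i], to = ids[targets[t]],
                                       weight = I(list(wt))))
    }
  }
  mtp_graph(ids, w, edges)
}
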
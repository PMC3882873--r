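# Sequentially rejective graphical multiple testing engine.
#
# A graph holds hypotheses with significance-level weights w_i (fractions of
# alpha) and a transition matrix g[i][j] saying what fraction of a rejected
# hypothesis's level moves to each remaining one. Rejecting H_j applies
#   w_l <- w_l + w_j * g[j][l]
#   g[l][k] <- (g[l][k] + g[l][j]*g[j][k]) / (1 - g[l][j]*g[j][l])
# with the new transition set to 0 when the denominator vanishes. All
# quantities are exact eps_value scalars, so epsilon edges resolve in the
# limit eps -> 0+.

#' Construct a hypothesis graph for a sequentially rejective procedure
#'
#' @param hypotheses character vector of unique hypothesis ids, or a data
#'   frame with columns `id`, and optionally `label` and `family`.
#' @param weights initial weights (fractions of the overall alpha), one per
#'   hypothesis; numerics, weight strings (see [parse_weight()]) or
#'   `eps_value`s. Must be non-negative and sum to at most 1.
#' @param edges data frame with columns `from`, `to`, `weight` giving the
#'   transition fractions; omitted pairs are 0. Row sums must not exceed 1
#'   and self-edges are not allowed.
#' @return An object of class `mtp_graph`.
#' @examples
#' g <- mtp_graph(c("A", "B"), c("1/2", "1/2"),
#'                data.frame(from = c("A", "B"), to = c("B", "A"), weight = "1"))
#' run_procedure(g, c(A = 0.01, B = 0.04), alpha = 0.05)
#' @export
mtp_graph <- function(hypotheses, weights, edges = NULL) {
  if (is.data.frame(hypotheses)) {
    ids <- as.character(hypotheses$id)
    labels <- if ("label" %in% names(hypotheses)) as.character(hypotheses$label) else ids
    family <- if ("family" %in% names(hypotheses)) as.character(hypotheses$family) else rep(NA_character_, length(ids))
  } else {
    ids <- as.character(hypotheses)
    labels <- ids
    family <- rep(NA_character_, length(ids))
  }
  if (anyDuplicated(ids)) stop("hypothesis ids must be unique")
  n <- length(ids)
  if (length(weights) != n) stop("need one initial weight per hypothesis")
  w <- lapply(weights, ev)
  names(w) <- ids
  trans <- lapply(ids, function(i) {
    row <- rep(list(.ev_zero()), n)
    names(row) <- ids
    row
  })
  names(trans) <- ids
  if (!is.null(edges) && nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      fr <- as.character(edges$from[r]); to <- as.character(edges$to[r])
      if (!fr %in% ids || !to %in% ids) stop("edge refers to unknown hypothesis: ", fr, " -> ", to)
      if (fr == to) stop("self-edge not allowed on ", fr)
      trans[[fr]][[to]] <- ev(edges$weight[[r]])
    }
  }
  g <- structure(list(ids = ids, labels = labels, family = family,
                      weights = w, trans = trans,
                      rejected = character(0), K = n),
                 class = "mtp_graph")
  validate_mtp_graph(g)
  g
}

#' Validate the invariants of a hypothesis graph
#'
#' Checks that weights are non-negative and sum to at most 1 over
#' non-rejected hypotheses, that there are no self-transitions, and that
#' each row of the transition matrix sums to at most 1 (in the eps -> 0+
#' order). Errors name the offending hypothesis.
#'
#' @param g an `mtp_graph`.
#' @return `g`, invisibly.
#' @export
validate_mtp_graph <- function(g) {
  active <- setdiff(g$ids, g$rejected)
  total <- ev(0)
  for (i in active) {
    if (ev_compare(g$weights[[i]], 0) < 0) stop("negative weight on ", i)
    total <- total + g$weights[[i]]
  }
  if (ev_compare(total, 1) > 0) stop("weights of non-rejected hypotheses sum above 1")
  for (i in active) {
    rs <- ev(0)
    for (j in active) {
      gij <- g$trans[[i]][[j]]
      if (i == j) {
        if (!.ev_is_zero(gij)) stop("self-transition on ", i)
        next
      }
      if (ev_compare(gij, 0) < 0) stop("negative transition weight ", i, " -> ", j)
      rs <- rs + gij
    }
    if (ev_compare(rs, 1) > 0) stop("transition row sum above 1 for ", i)
  }
  invisible(g)
}

#' @export
print.mtp_graph <- function(x, ...) {
  active <- setdiff(x$ids, x$rejected)
  cat("Graphical MTP with", length(x$ids), "hypotheses",
      if (length(x$rejected)) paste0("(", length(x$rejected), " rejected)") else "", "\n")
  for (i in x$ids) {
    mark <- if (i %in% x$rejected) " [rejected]" else ""
    cat(sprintf("  %-4s w = %-18s%s\n", i, ev_to_string(x$weights[[i]]), mark))
  }
  for (i in active) for (j in active) {
    gij <- x$trans[[i]][[j]]
    if (!.ev_is_zero(gij)) cat(sprintf("  %s -> %s : %s\n", i, j, ev_to_string(gij)))
  }
  invisible(x)
}

.active_ids <- function(g) setdiff(g$ids, g$rejected)

#' Local significance levels alpha * w_i
#'
#' @param g an `mtp_graph`.
#' @param alpha overall significance level (numeric, string, or `eps_value`).
#' @return Named list of `eps_value` levels for the non-rejected hypotheses.
#' @export
local_levels <- function(g, alpha = 0.05) {
  a <- ev(alpha)
  out <- lapply(.active_ids(g), function(i) a * g$weights[[i]])
  names(out) <- .active_ids(g)
  out
}

#' Apply the rejection-update rule for one hypothesis
#'
#' Marks `j` rejected, transfers its weight along its outgoing edges and
#' renormalizes the transition matrix among the remaining hypotheses. The
#' input graph is not modified; an updated copy is returned.
#'
#' @param g an `mtp_graph`.
#' @param j id of the hypothesis to reject (not already rejected).
#' @return The updated `mtp_graph`.
#' @export
update_after_rejection <- function(g, j) {
  if (!j %in% g$ids) stop("unknown hypothesis id: ", j)
  if (j %in% g$rejected) stop(j, " is already rejected")
  active <- setdiff(.active_ids(g), j)
  K <- g$K
  wj <- g$weights[[j]]
  new_w <- g$weights
  new_t <- g$trans
  for (l in active) {
    new_w[[l]] <- .ev_mul(wj, g$trans[[j]][[l]], K = K) + g$weights[[l]]
  }
  new_w[[j]] <- .ev_zero()
  for (l in active) {
    glj <- g$trans[[l]][[j]]
    for (k in active) {
      if (l == k) next
      den <- ev(1) - .ev_mul(glj, g$trans[[j]][[l]], K = K)
      if (.ev_is_zero(den)) {
        new_t[[l]][[k]] <- .ev_zero()
      } else {
        num <- g$trans[[l]][[k]] + .ev_mul(glj, g$trans[[j]][[k]], K = K)
        new_t[[l]][[k]] <- ev_div_limit(num, den, K = K)
      }
    }
    new_t[[l]][[j]] <- .ev_zero()
  }
  new_t[[j]] <- lapply(new_t[[j]], function(x) .ev_zero())
  g$weights <- new_w
  g$trans <- new_t
  g$rejected <- c(g$rejected, j)
  g
}

.check_test_input <- function(g, pvalues, alpha) {
  n <- length(g$ids)
  p <- unlist(pvalues)
  if (is.null(names(p))) {
    if (length(p) != n) stop("need one p-value per hypothesis")
    names(p) <- g$ids
  } else {
    if (!setequal(names(p), g$ids)) stop("p-value names must match hypothesis ids")
    p <- p[g$ids]
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  a <- ev_limit(ev(alpha))
  if (a <= 0 || a > 1) stop("alpha must lie in (0, 1]")
  p
}

# ratio p_i / limit(level_i) used to order simultaneously testable
# hypotheses; a pure-epsilon level (limit 0) is only reachable by p = 0
.test_ratio <- function(p, level) {
  lim <- ev_limit(level)
  if (lim == 0) { if (p == 0) 0 else Inf } else p / lim
}

#' Run a sequentially rejective graphical procedure
#'
#' Repeatedly finds the hypotheses whose exact-rational p-value is at or
#' below their local level `alpha * w_i` (in the eps -> 0+ order), rejects
#' the one with the smallest ratio of p-value to the limit of its level
#' (ties broken by declaration order; the final rejection set does not
#' depend on this choice), applies [update_after_rejection()], and stops
#' when nothing more can be rejected. Remaining hypotheses are recorded as
#' retained, in increasing order of that same ratio.
#'
#' @param g an `mtp_graph`.
#' @param pvalues numeric vector of raw p-values, named by hypothesis id or
#'   in declaration order. Converted to exact rationals from their decimal
#'   representation.
#' @param alpha overall (two-sided) significance level in (0, 1].
#' @return An `mtp_trace`: steps with local levels and decisions, plus the
#'   final rejection set (`$final_rejections`) and final graph state.
#' @examples
#' g <- build_gatekeeping()
#' tr <- run_procedure(g, worked_example()$pvalues, alpha = 0.05)
#' tr$final_rejections
#' @export
run_procedure <- function(g, pvalues, alpha = 0.05) {
  p <- .check_test_input(g, pvalues, alpha)
  a <- ev(alpha)
  p_rat <- lapply(p, ev)
  steps <- list()
  state <- g
  repeat {
    active <- .active_ids(state)
    if (!length(active)) break
    levels <- local_levels(state, a)
    rejectable <- active[vapply(active, function(i) ev_compare(p_rat[[i]], levels[[i]]) <= 0, TRUE)]
    if (!length(rejectable)) {
      ratios <- vapply(active, function(i) .test_ratio(p[[i]], levels[[i]]), 0)
      for (i in active[order(ratios)]) {
        steps[[length(steps) + 1L]] <- list(
          id = i, level = levels[[i]], p = unname(p[[i]]),
          decision = "retain", ratio = ratios[[i]],
          weights_after = state$weights[.active_ids(state)])
      }
      break
    }
    ratios <- vapply(rejectable, function(i) .test_ratio(p[[i]], levels[[i]]), 0)
    j <- rejectable[which.min(ratios)]
    state <- update_after_rejection(state, j)
    steps[[length(steps) + 1L]] <- list(
      id = j, level = levels[[j]], p = unname(p[[j]]),
      decision = "reject", ratio = min(ratios),
      weights_after = state$weights[.active_ids(state)])
  }
  structure(list(steps = steps,
                 final_rejections = state$rejected,
                 alpha = ev_limit(a), alpha_ev = a,
                 pvalues = p, initial = g, final = state),
            class = "mtp_trace")
}

#' Final rejection set of a procedure run
#' @param g an `mtp_graph`.
#' @param pvalues,alpha as in [run_procedure()].
#' @return Character vector of rejected hypothesis ids.
#' @export
rejections <- function(g, pvalues, alpha = 0.05) {
  run_procedure(g, pvalues, alpha)$final_rejections
}

# "5*alpha/16"-style rendering of a level from the weight's rational limit
.alpha_fraction_string <- function(weight_ev) {
  r <- .ev_limit_rat(weight_ev)
  has_eps <- any(ev(weight_ev)$pow > 0)
  s <- if (r[1] == 0) "0"
    else if (r[1] == 1 && r[2] == 1) "alpha"
    else if (r[2] == 1) paste0(r[1], "*alpha")
    else if (r[1] == 1) paste0("alpha/", r[2])
    else paste0(r[1], "*alpha/", r[2])
  if (has_eps) paste0(s, " + eps terms") else s
}

#' @export
print.mtp_trace <- function(x, ...) {
  cat(sprintf("Sequentially rejective test at alpha = %s\n", format(x$alpha)))
  for (k in seq_along(x$steps)) {
    s <- x$steps[[k]]
    w <- s$level / x$alpha_ev  # level as fraction of alpha (alpha is rational)
    cat(sprintf("  step %d: %s at level %s = %.4f; p = %s -> %s\n",
                k, s$id, .alpha_fraction_string(w), ev_limit(s$level),
                format(s$p), s$decision))
  }
  cat("Rejected:", if (length(x$final_rejections)) paste(x$final_rejections, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Tested level of one hypothesis in a trace
#'
#' Returns the local level at the step where `id` was tested (rejected or
#' retained), as an `eps_value`, or `NULL` if it was never testable.
#' @param trace an `mtp_trace`.
#' @param id hypothesis id.
#' @export
trace_level <- function(trace, id) {
  for (s in trace$steps) if (s$id == id) return(s$level)
  NULL
}

#' Adjusted p-values by bisection over the overall alpha
#'
#' The adjusted p-value of a hypothesis is the smallest overall alpha at
#' which the full procedure rejects it, found by bisection to absolute
#' tolerance `tol` and capped at 1.
#'
#' @param g an `mtp_graph`.
#' @param pvalues raw p-values as in [run_procedure()].
#' @param tol absolute bisection tolerance.
#' @return Named numeric vector of adjusted p-values.
#' @export
adjusted_pvalues <- function(g, pvalues, tol = 1e-6) {
  p <- .check_test_input(g, pvalues, alpha = 0.5)
  rej_at <- function(a) rejections(g, p, alpha = round(a, 12))
  out <- rep(NA_real_, length(g$ids))
  names(out) <- g$ids
  at_one <- rej_at(1)
  for (i in g$ids) {
    if (!i %in% at_one) { out[[i]] <- 1; next }
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (i %in% rej_at(mid)) hi <- mid else lo <- mid
    }
    out[[i]] <- hi
  }
  out
}

#' Enumerate final rejection sets over every admissible testing order
#'
#' Explores, by depth-first search, every sequence of choices among the
#' simultaneously rejectable hypotheses. For graphical procedures the final
#' rejection set is invariant to this choice (tie robustness); the function
#' returns all distinct final sets so that property can be checked.
#'
#' @param g an `mtp_graph`.
#' @param pvalues,alpha as in [run_procedure()].
#' @return List of character vectors (sorted), one per distinct final set.
#' @export
enumerate_rejection_orders <- function(g, pvalues, alpha = 0.05) {
  p <- .check_test_input(g, pvalues, alpha)
  a <- ev(alpha)
  p_rat <- lapply(p, ev)
  results <- list()
  # deliberately no memoization: every admissible order is walked in full,
  # so the invariance claim is checked rather than assumed
  recurse <- function(state) {
    active <- .active_ids(state)
    levels <- local_levels(state, a)
    rejectable <- active[vapply(active, function(i) ev_compare(p_rat[[i]], levels[[i]]) <= 0, TRUE)]
    if (!length(rejectable)) {
      results[[length(results) + 1L]] <<- sort(state$rejected)
      return(invisible(NULL))
    }
    for (j in rejectable) recurse(update_after_rejection(state, j))
  }
  recurse(g)
  unique(results)
}
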
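# Preset graphs for a three-arm (high dose, low dose, active control),
# two-endpoint non-inferiority/superiority design with six hypotheses:
#   H1 high dose inferior to control, primary endpoint (NI)
#   H2 low dose inferior to control, primary endpoint (NI)
#   H3 high dose not superior to control, primary endpoint
#   H4 high dose not superior to control, secondary endpoint
#   H5 low dose not superior to control, primary endpoint
#   H6 low dose not superior to control, secondary endpoint
# Family F1 = {H1, H2} gatekeeps family F2 = {H3..H6}: H3/H4 are testable
# only once H1 is rejected, H5/H6 only once H2 is rejected.

.design_hypotheses <- function() {
  data.frame(
    id = paste0("H", 1:6),
    label = c(
      "high dose is inferior to active control in primary endpoint",
      "low dose is inferior to active control in primary endpoint",
      "high dose is not superior to active control in primary endpoint",
      "high dose is not superior to active control in secondary endpoint",
      "low dose is not superior to active control in primary endpoint",
      "low dose is not superior to active control in secondary endpoint"),
    family = c("F1", "F1", "F2", "F2", "F2", "F2"),
    stringsAsFactors = FALSE)
}

.check_split <- function(split) {
  stopifnot(length(split) == 2)
  s <- lapply(split, ev)
  if (ev_compare(s[[1]], 0) < 0 || ev_compare(s[[2]], 0) < 0) stop("split components must be >= 0")
  if (ev_compare(s[[1]] + s[[2]], 1) != 0) stop("split must sum to 1")
  s
}

.design_graph <- function(split, edges) {
  s <- .check_split(split)
  mtp_graph(.design_hypotheses(),
            list(s[[1]], s[[2]], 0, 0, 0, 0),
            edges)
}

.edge_df <- function(...) {
  rows <- list(...)
  data.frame(from = vapply(rows, `[[`, "", 1),
             to = vapply(rows, `[[`, "", 2),
             weight = I(lapply(rows, `[[`, 3)),
             stringsAsFactors = FALSE)
}

#' Tree-structured gatekeeping graph
#'
#' The overall alpha is split between the two primary non-inferiority
#' hypotheses H1 and H2. Each, when rejected, passes its level in equal
#' halves to its own dose's superiority pair (H3/H4 for high dose, H5/H6 for
#' low dose); within a pair the full level recycles to the partner. The two
#' dose paths are independent: no level moves between them.
#'
#' @param split initial allocation to (H1, H2); weight strings or numerics
#'   summing to 1. Default equal split.
#' @return An `mtp_graph` with six hypotheses and eight edges.
#' @examples
#' rejections(build_gatekeeping(), worked_example()$pvalues)
#' @export
build_gatekeeping <- function(split = c("1/2", "1/2")) {
  .design_graph(split, .edge_df(
    list("H1", "H3", "1/2"), list("H1", "H4", "1/2"),
    list("H2", "H5", "1/2"), list("H2", "H6", "1/2"),
    list("H3", "H4", "1"), list("H4", "H3", "1"),
    list("H5", "H6", "1"), list("H6", "H5", "1")))
}

#' Cross-dose alpha-recycling graph
#'
#' As [build_gatekeeping()], but each secondary-pair hypothesis returns half
#' of its level to the pair partner and half to the *other* dose's primary
#' non-inferiority hypothesis, so the level assigned to one dose path can be
#' reused on the other once that path succeeds (fully when both pair members
#' are rejected, one eighth of alpha when only one is).
#'
#' @inheritParams build_gatekeeping
#' @return An `mtp_graph`.
#' @export
build_recycling <- function(split = c("1/2", "1/2")) {
  .design_graph(split, .edge_df(
    list("H1", "H3", "1/2"), list("H1", "H4", "1/2"),
    list("H2", "H5", "1/2"), list("H2", "H6", "1/2"),
    list("H3", "H4", "1/2"), list("H3", "H2", "1/2"),
    list("H4", "H3", "1/2"), list("H4", "H2", "1/2"),
    list("H5", "H6", "1/2"), list("H5", "H1", "1/2"),
    list("H6", "H5", "1/2"), list("H6", "H1", "1/2")))
}

#' Epsilon-edge graph: complete one dose path before crossing over
#'
#' As [build_recycling()], but within each secondary pair nearly all of a
#' rejected hypothesis's level (weight `1 - eps`) goes to its pair partner
#' and only an infinitesimal fraction (`eps`) crosses to the other dose's
#' primary hypothesis. In the limit eps -> 0+ the cross-dose transfer
#' happens only after the whole pair is rejected, at which point the full
#' level crosses over.
#'
#' @inheritParams build_gatekeeping
#' @return An `mtp_graph` with symbolic epsilon edge weights.
#' @export
build_epsilon <- function(split = c("1/2", "1/2")) {
  .design_graph(split, .edge_df(
    list("H1", "H3", "1/2"), list("H1", "H4", "1/2"),
    list("H2", "H5", "1/2"), list("H2", "H6", "1/2"),
    list("H3", "H4", "1-eps"), list("H3", "H2", "eps"),
    list("H4", "H3", "1-eps"), list("H4", "H2", "eps"),
    list("H5", "H6", "1-eps"), list("H5", "H1", "eps"),
    list("H6", "H5", "1-eps"), list("H6", "H1", "eps")))
}

#' Direct-path graph: prioritize non-inferiority of both doses
#'
#' Puts a direct edge of weight `1 - 2*eps` in each direction between H1 and
#' H2, so that rejecting one dose's primary non-inferiority hypothesis sends
#' essentially its whole level to the other's; the edges from each primary
#' hypothesis to its own superiority pair carry only infinitesimal weight
#' `eps` each. Secondary pairs are wired as in [build_epsilon()].
#'
#' @inheritParams build_gatekeeping
#' @return An `mtp_graph`.
#' @export
build_direct_path <- function(split = c("1/2", "1/2")) {
  .design_graph(split, .edge_df(
    list("H1", "H2", "1-2*eps"), list("H1", "H3", "eps"), list("H1", "H4", "eps"),
    list("H2", "H1", "1-2*eps"), list("H2", "H5", "eps"), list("H2", "H6", "eps"),
    list("H3", "H4", "1-eps"), list("H3", "H2", "eps"),
    list("H4", "H3", "1-eps"), list("H4", "H2", "eps"),
    list("H5", "H6", "1-eps"), list("H5", "H1", "eps"),
    list("H6", "H5", "1-eps"), list("H6", "H1", "eps")))
}

#' Build a preset design graph by name
#'
#' @param name one of `"gatekeeping"`, `"recycling"`, `"epsilon"`,
#'   `"direct-path"`.
#' @inheritParams build_gatekeeping
#' @return An `mtp_graph`.
#' @export
graph_preset <- function(name, split = c("1/2", "1/2")) {
  switch(match.arg(name, c("gatekeeping", "recycling", "epsilon", "direct-path")),
         "gatekeeping" = build_gatekeeping(split),
         "recycling" = build_recycling(split),
         "epsilon" = build_epsilon(split),
         "direct-path" = build_direct_path(split))
}

#' Graphical Holm procedure
#'
#' Weighted Holm as a graph: weights `w`, transitions
#' `g[i][j] = w[j] / (1 - w[i])`, so a rejected hypothesis's level is
#' redistributed proportionally among the rest.
#'
#' @param weights numeric/string weights summing to 1; equal by default.
#' @param n number of hypotheses when `weights` is not given.
#' @param ids hypothesis ids.
#' @return An `mtp_graph`.
#' @export
build_holm <- function(n = 2, weights = NULL, ids = paste0("H", seq_len(n))) {
  if (is.null(weights)) weights <- rep(list(ev(1) / n), n)
  w <- lapply(weights, ev)
  n <- length(w)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(setdiff(seq_len(n), i), function(j) {
      data.frame(from = ids[i], to = ids[j],
                 weight = I(list(ev_div_limit(w[[j]], ev(1) - w[[i]], K = n))))
    }))
  }))
  mtp_graph(ids, w, edges)
}

#' Hochberg step-up test for a family of two hypotheses
#'
#' Rejects both hypotheses if the larger p-value is at or below `level`;
#' otherwise rejects the one with the smaller p-value if it is at or below
#' `level / 2`; otherwise rejects neither.
#'
#' @param p numeric vector of two raw p-values, optionally named.
#' @param level the level available to the pair (e.g. alpha/2 passed down by
#'   a gatekeeper).
#' @return Character vector of rejected names (subset of `names(p)`).
#' @examples
#' hochberg_pair(c(H3 = 0.020, H4 = 0.009), level = 0.025)
#' @export
hochberg_pair <- function(p, level) {
  stopifnot(length(p) == 2, level > 0, level <= 1)
  if (is.null(names(p))) names(p) <- c("A", "B")
  if (max(p) <= level) return(names(p))
  if (min(p) <= level / 2) return(names(p)[which.min(p)])
  character(0)
}

#' The worked six-hypothesis example
#'
#' The fixture p-values and overall level used throughout the package
#' examples: p = (0.005, 0.027, 0.020, 0.009, 0.133, 0.018) for H1..H6 at
#' two-sided alpha 0.05.
#'
#' @return List with elements `pvalues` (named numeric) and `alpha`.
#' @export
worked_example <- function() {
  list(pvalues = c(H1 = 0.005, H2 = 0.027, H3 = 0.020,
                   H4 = 0.009, H5 = 0.133, H6 = 0.018),
       alpha = 0.05)
}
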
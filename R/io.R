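# Graph JSON schema:
#   {"hypotheses": [{"id", "label", "family", "weight": <weight-string>}],
#    "edges":      [{"from", "to", "weight": <weight-string>}]}
# Weight strings use the exact grammar of parse_weight(), so round-trips
# preserve rationals and epsilon terms bit-exactly.

#' Save a hypothesis graph as JSON
#' @param g an `mtp_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_graph <- function(g, path) {
  hyp <- lapply(seq_along(g$ids), function(i) {
    list(id = g$ids[i], label = g$labels[i], family = g$family[i],
         weight = ev_to_string(g$weights[[g$ids[i]]]))
  })
  edges <- list()
  for (i in g$ids) for (j in g$ids) {
    w <- g$trans[[i]][[j]]
    if (!.ev_is_zero(w)) {
      edges[[length(edges) + 1L]] <- list(from = i, to = j, weight = ev_to_string(w))
    }
  }
  jsonlite::write_json(list(hypotheses = hyp, edges = edges), path,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a hypothesis graph from JSON
#'
#' Validates the schema, parses the weight grammar, and checks the graph
#' invariants (weights summing to at most 1, transition row sums at most 1),
#' naming the offending hypothesis in errors.
#'
#' @param path JSON file path.
#' @return An `mtp_graph`.
#' @export
load_graph <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$hypotheses)) stop("graph JSON must have a 'hypotheses' array")
  ids <- vapply(x$hypotheses, function(h) as.character(h$id %||% stop("hypothesis without id")), "")
  labels <- vapply(x$hypotheses, function(h) as.character(h$label %||% h$id), "")
  family <- vapply(x$hypotheses, function(h) as.character(h$family %||% NA_character_), "")
  weights <- lapply(x$hypotheses, function(h) parse_weight(as.character(h$weight %||% "0")))
  edges <- NULL
  if (length(x$edges)) {
    edges <- data.frame(
      from = vapply(x$edges, function(e) as.character(e$from), ""),
      to = vapply(x$edges, function(e) as.character(e$to), ""),
      weight = I(lapply(x$edges, function(e) parse_weight(as.character(e$weight)))),
      stringsAsFactors = FALSE)
  }
  mtp_graph(data.frame(id = ids, label = labels, family = family,
                       stringsAsFactors = FALSE),
            weights, edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a graph in DOT format
#'
#' Nodes are labelled with the hypothesis id and its current weight (as a
#' fraction of alpha); edges with their weight strings, the symbolic
#' infinitesimal rendered as the Greek letter epsilon.
#'
#' @param g an `mtp_graph`.
#' @param path optional file to write; when `NULL` the DOT text is returned.
#' @return The DOT source as a character scalar (invisibly when written).
#' @export
export_dot <- function(g, path = NULL) {
  pretty <- function(v) gsub("eps", "ε", ev_to_string(v), fixed = TRUE)
  lines <- c("digraph mtp {", "  rankdir=LR;")
  for (i in g$ids) {
    lines <- c(lines, sprintf("  %s [label=\"%s\\n%s\"];", i, i, pretty(g$weights[[i]])))
  }
  for (i in g$ids) for (j in g$ids) {
    w <- g$trans[[i]][[j]]
    if (!.ev_is_zero(w)) {
      lines <- c(lines, sprintf("  %s -> %s [label=\"%s\"];", i, j, pretty(w)))
    }
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Export a test trace as JSON
#'
#' Each step records the hypothesis tested, its local level (exact weight
#' string and decimal limit), the p-value, the decision, and the weights
#' after the step.
#'
#' @param trace an `mtp_trace`.
#' @param path optional output file.
#' @return The trace as a list (invisibly when written).
#' @export
trace_to_json <- function(trace, path = NULL) {
  steps <- lapply(seq_along(trace$steps), function(k) {
    s <- trace$steps[[k]]
    list(step = k, hypothesis = s$id,
         level = ev_to_string(s$level),
         level_limit = ev_limit(s$level),
         level_of_alpha = .alpha_fraction_string(s$level / trace$alpha_ev),
         p = s$p, decision = s$decision,
         weights_after = lapply(s$weights_after, ev_to_string))
  })
  out <- list(alpha = trace$alpha, steps = steps,
              final_rejections = as.list(trace$final_rejections))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}
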
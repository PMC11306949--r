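# Graph filtering: prune nodes and edges to the most relevant ones.
#
# The AAG method states only THAT nodes and edges are filtered by
# their statistical parameters; the concrete procedure is not public. The
# rules and defaults below are this package's own choices, selected to
# suppress unstable small-count ratios, and are fully configurable.

#' Filter rules for an attribute association graph
#'
#' @param min_abs_count keep a node only if its larger group count
#'   `max(c_d, c_c)` reaches this many participants (non-authorial default
#'   10).
#' @param min_max_share keep a node only if its maximum relative attribute
#'   share reaches this fraction (default 0.01).
#' @param keep_low_edges keep edges of type `low_cond_diff` (default
#'   `FALSE`).
#' @param min_cooccurrence keep an edge only if `max(o_d, o_c)` reaches this
#'   many participants (default 10).
#' @param node_whitelist attribute ids always kept (exempt from node rules).
#' @param node_blacklist attribute ids always removed.
#' @return A list of class `filter_rules`.
#' @export
filter_rules <- function(min_abs_count = 10, min_max_share = 0.01,
                         keep_low_edges = FALSE, min_cooccurrence = 10,
                         node_whitelist = character(0),
                         node_blacklist = character(0)) {
  stopifnot(is_count(min_abs_count), is_count(min_cooccurrence),
            is.numeric(min_max_share), min_max_share >= 0, min_max_share <= 1,
            is.logical(keep_low_edges))
  structure(list(min_abs_count = min_abs_count, min_max_share = min_max_share,
                 keep_low_edges = keep_low_edges,
                 min_cooccurrence = min_cooccurrence,
                 node_whitelist = as.character(node_whitelist),
                 node_blacklist = as.character(node_blacklist)),
            class = "filter_rules")
}

#' Permissive rules that keep everything
#' @return A `filter_rules` object that leaves any graph unchanged.
#' @export
no_filter <- function() {
  filter_rules(min_abs_count = 0, min_max_share = 0, keep_low_edges = TRUE,
               min_cooccurrence = 0)
}

#' Prune an AAG by statistical relevance rules
#'
#' Nodes failing any node rule are removed together with their incident
#' edges; surviving statistics are untouched (the result is a subgraph).
#' A per-rule removal report is attached as attribute `"filter_report"` and
#' stored in the graph's provenance.
#'
#' @param graph an `aag` (see [build_aag()]).
#' @param rules a [filter_rules()] object.
#' @return The filtered `aag`.
#' @export
filter_aag <- function(graph, rules = filter_rules()) {
  stopifnot(inherits(graph, "aag"), inherits(rules, "filter_rules"))
  nodes <- graph$nodes
  edges <- graph$edges
  p_max <- pmax(nodes$p_d, nodes$p_c)
  c_max <- pmax(nodes$c_d, nodes$c_c)
  fail_count <- c_max < rules$min_abs_count
  fail_share <- is.na(p_max) | p_max < rules$min_max_share
  keep_node <- !(fail_count | fail_share)
  keep_node[nodes$attribute_id %in% rules$node_whitelist] <- TRUE
  fail_blacklist <- nodes$attribute_id %in% rules$node_blacklist
  keep_node[fail_blacklist] <- FALSE

  kept_ids <- nodes$attribute_id[keep_node]
  endpoint_gone <- !(edges$source_id %in% kept_ids & edges$target_id %in% kept_ids)
  fail_low <- !rules$keep_low_edges & edges$edge_type == "low_cond_diff"
  fail_cooc <- pmax(edges$o_d, edges$o_c) < rules$min_cooccurrence
  keep_edge <- !(endpoint_gone | fail_low | fail_cooc)

  report <- list(
    nodes_removed = sum(!keep_node),
    nodes_removed_min_abs_count = sum(fail_count & !keep_node),
    nodes_removed_min_max_share = sum(fail_share & !keep_node),
    nodes_removed_blacklist = sum(fail_blacklist),
    edges_removed = sum(!keep_edge),
    edges_removed_endpoint = sum(endpoint_gone),
    edges_removed_low_type = sum(fail_low & !endpoint_gone),
    edges_removed_min_cooccurrence = sum(fail_cooc & !endpoint_gone & !fail_low),
    rules = unclass(rules)
  )
  graph$nodes <- nodes[keep_node, , drop = FALSE]
  graph$edges <- edges[keep_edge, , drop = FALSE]
  rownames(graph$nodes) <- rownames(graph$edges) <- NULL
  graph$provenance$filter_report <- report
  attr(graph, "filter_report") <- report
  graph
}

#' Write a filter report as JSON
#'
#' @param graph a filtered `aag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(graph, path) {
  rep <- graph$provenance$filter_report
  if (is.null(rep)) aag_stop("graph has no filter report", "aag_contract_error")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
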
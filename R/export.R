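# Export: property-graph bulk import CSVs + load script, GraphML, JSON,
# visual-encoding style sheet. List-valued properties are ordered control
# group (group 1, negGroup) first, disease group (group 2, posGroup) second.

#' Visual encoding of labels
#'
#' Node color follows the distinction label, node size rank the frequency
#' label, edge thickness rank the edge type.
#'
#' @return Nested list with `node_color`, `node_size_rank`,
#'   `edge_thickness_rank`.
#' @export
visual_encoding <- function() {
  list(
    node_color = list(
      highly_related = "red", related = "orange", unrelated = "vanilla",
      inverse = "turquoise", highly_inverse = "blue"
    ),
    node_size_rank = list(
      highly_frequent = 3L, frequent = 2L, infrequent = 1L
    ),
    edge_thickness_rank = list(
      high_cond_diff = 3L, medium_cond_diff = 2L, low_cond_diff = 1L
    )
  )
}

edge_type_to_export <- function(x) toupper(x)
edge_type_from_export <- function(x) tolower(x)

# Canonical plain-list representation used by the JSON exporter (and as the
# reference for what the other exporters must carry).
aag_to_list <- function(graph) {
  n <- graph$nodes
  e <- graph$edges
  nodes <- lapply(seq_len(nrow(n)), function(i) {
    list(
      id = n$attribute_id[i],
      name = n$variable[i],
      value = n$value[i],
      description = n$description[i],
      refLower = n$ref_lower[i],
      refUpper = n$ref_upper[i],
      labels = as.list(c(n$broad_labels[[i]], n$frequency_label[i],
                         n$distinction_label[i])),
      groupAbsCounts = c(n$c_c[i], n$c_d[i]),
      groupRelShareTotals = c(n$rel_total_c[i], n$rel_total_d[i]),
      groupRelShareAttrs = c(n$p_c[i], n$p_d[i]),
      diffRelShareAttr = n$delta[i],
      quotRelShareAttr = n$gamma[i],
      direction = n$direction[i]
    )
  })
  edges <- lapply(seq_len(nrow(e)), function(i) {
    list(
      startId = e$source_id[i],
      endId = e$target_id[i],
      type = edge_type_to_export(e$edge_type[i]),
      groupAbsCoOccurs = c(e$o_c[i], e$o_d[i]),
      groupRelShareConds = c(e$q_c[i], e$q_d[i]),
      groupDiffTargets = c(e$dprime_c[i], e$dprime_d[i]),
      groupQuotTargets = c(e$gprime_c[i], e$gprime_d[i])
    )
  })
  list(
    posGroup = graph$groups$disease_name,
    negGroup = graph$groups$control_name,
    groupSizes = c(graph$groups$g_c, graph$groups$g_d),
    config = unclass(graph$config),
    nodes = nodes,
    edges = edges,
    style = visual_encoding()
  )
}

num_or_na <- function(x) {
  if (is.null(x)) return(NA_real_)
  x <- unlist(x)
  if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)
}

# JSON has no Inf literal; encode infinite quotients as strings ("Inf"),
# which as.numeric() restores on import.
encode_inf <- function(x) {
  if (is.list(x)) return(lapply(x, encode_inf))
  if (is.numeric(x) && any(is.infinite(x))) {
    if (length(x) == 1L) return(if (x > 0) "Inf" else "-Inf")
    return(lapply(x, function(v) {
      if (is.infinite(v)) (if (v > 0) "Inf" else "-Inf") else v
    }))
  }
  x
}

aag_from_list <- function(x) {
  nodes <- x$nodes
  g_d_in <- as.integer(x$groupSizes[2])
  g_c_in <- as.integer(x$groupSizes[1])
  n <- data.frame(
    attribute_id = vapply(nodes, function(v) v$id, ""),
    variable = vapply(nodes, function(v) v$name, ""),
    value = vapply(nodes, function(v) v$value, ""),
    description = vapply(nodes, function(v) v$description, ""),
    ref_lower = vapply(nodes, function(v) num_or_na(v$refLower), 0),
    ref_upper = vapply(nodes, function(v) num_or_na(v$refUpper), 0),
    c_d = vapply(nodes, function(v) as.integer(v$groupAbsCounts[2]), 0L),
    c_c = vapply(nodes, function(v) as.integer(v$groupAbsCounts[1]), 0L),
    g_d = rep(g_d_in, length(nodes)),
    g_c = rep(g_c_in, length(nodes)),
    rel_total_d = vapply(nodes, function(v) num_or_na(v$groupRelShareTotals[2]), 0),
    rel_total_c = vapply(nodes, function(v) num_or_na(v$groupRelShareTotals[1]), 0),
    p_d = vapply(nodes, function(v) num_or_na(v$groupRelShareAttrs[2]), 0),
    p_c = vapply(nodes, function(v) num_or_na(v$groupRelShareAttrs[1]), 0),
    delta = vapply(nodes, function(v) num_or_na(v$diffRelShareAttr), 0),
    gamma = vapply(nodes, function(v) num_or_na(v$quotRelShareAttr), 0),
    direction = vapply(nodes, function(v) v$direction, ""),
    stringsAsFactors = FALSE
  )
  # the last two entries of `labels` are frequency and distinction
  labels <- lapply(nodes, function(v) as.character(unlist(v$labels)))
  k <- lengths(labels)
  n$frequency_label <- vapply(seq_along(labels),
                              function(i) labels[[i]][k[i] - 1L], "")
  n$distinction_label <- vapply(seq_along(labels),
                                function(i) labels[[i]][k[i]], "")
  n$broad_labels <- lapply(seq_along(labels),
                           function(i) labels[[i]][seq_len(max(k[i] - 2L, 0L))])
  # n_d / n_c are recoverable from c and p when p > 0; NA otherwise
  n$n_d <- as.integer(ifelse(!is.na(n$p_d) & n$p_d > 0, round(n$c_d / n$p_d), NA))
  n$n_c <- as.integer(ifelse(!is.na(n$p_c) & n$p_c > 0, round(n$c_c / n$p_c), NA))
  edges <- x$edges
  if (length(edges)) {
    e <- data.frame(
      source_id = vapply(edges, function(v) v$startId, ""),
      target_id = vapply(edges, function(v) v$endId, ""),
      o_d = vapply(edges, function(v) as.integer(v$groupAbsCoOccurs[2]), 0L),
      o_c = vapply(edges, function(v) as.integer(v$groupAbsCoOccurs[1]), 0L),
      q_d = vapply(edges, function(v) num_or_na(v$groupRelShareConds[2]), 0),
      q_c = vapply(edges, function(v) num_or_na(v$groupRelShareConds[1]), 0),
      dprime_d = vapply(edges, function(v) num_or_na(v$groupDiffTargets[2]), 0),
      dprime_c = vapply(edges, function(v) num_or_na(v$groupDiffTargets[1]), 0),
      gprime_d = vapply(edges, function(v) num_or_na(v$groupQuotTargets[2]), 0),
      gprime_c = vapply(edges, function(v) num_or_na(v$groupQuotTargets[1]), 0),
      edge_type = vapply(edges, function(v) edge_type_from_export(v$type), ""),
      stringsAsFactors = FALSE
    )
  } else {
    e <- empty_edge_table()
  }
  cfg <- do.call(aag_config, x$config[setdiff(names(x$config), character(0))])
  structure(
    list(nodes = n, edges = e, config = cfg,
         groups = list(disease_name = x$posGroup, control_name = x$negGroup,
                       g_d = g_d_in, g_c = g_c_in),
         provenance = list(imported = TRUE)),
    class = "aag"
  )
}

#' Export an AAG as JSON
#'
#' Numbers are serialized at full round-trip precision; infinite share
#' quotients appear as the JSON string `"Inf"`. The node and edge property
#' names follow the standard AAG property-graph vocabulary (`groupAbsCounts`,
#' `groupRelShareTotals`, `groupRelShareAttrs`, `diffRelShareAttr`,
#' `quotRelShareAttr`, `groupAbsCoOccurs`, `groupRelShareConds`,
#' `groupDiffTargets`, `groupQuotTargets`, `posGroup`, `negGroup`), with
#' list-valued properties ordered control group first.
#'
#' @param graph an `aag`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
export_json <- function(graph, path) {
  stopifnot(inherits(graph, "aag"))
  json <- jsonlite::toJSON(encode_inf(aag_to_list(graph)), auto_unbox = TRUE,
                           digits = I(17), null = "null", na = "null",
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Import an AAG from JSON
#'
#' Inverse of [export_json()]: reconstructs every statistic, label and type
#' exactly (`import(export(g))` followed by `export` is byte-identical).
#'
#' @param path path to a JSON file written by [export_json()].
#' @return An `aag`.
#' @export
import_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  # jsonlite reads "Inf" back as the string "Inf"; numeric coercion restores it
  aag_from_list(x)
}

# GraphML -------------------------------------------------------------------

graphml_node_keys <- c(
  name = "string", value = "string", description = "string",
  refLower = "double", refUpper = "double", labels = "string",
  groupAbsCounts = "string", groupRelShareTotals = "string",
  groupRelShareAttrs = "string", diffRelShareAttr = "double",
  quotRelShareAttr = "double", direction = "string"
)
graphml_edge_keys <- c(
  type = "string", groupAbsCoOccurs = "string", groupRelShareConds = "string",
  groupDiffTargets = "string", groupQuotTargets = "string"
)

fmt_num <- function(x) {
  # %.17g always carries enough digits to reproduce the exact double
  vapply(x, function(v) if (is.na(v)) "NA" else sprintf("%.17g", v), "")
}
fmt_list <- function(x) paste(fmt_num(x), collapse = ";")
parse_num <- function(s) {
  s[s == "NA"] <- NA_character_
  as.numeric(s)
}
parse_list <- function(s) parse_num(strsplit(s, ";", fixed = TRUE)[[1L]])

#' Export an AAG as GraphML
#'
#' List-valued properties (GraphML has no array type) are encoded as
#' semicolon-separated strings, control group first. Numbers use the
#' shortest representation that parses back to the identical double, so the
#' round trip via [import_graphml()] is lossless.
#'
#' @param graph an `aag`.
#' @param path output path (`.graphml`).
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "aag"))
  rep <- aag_to_list(graph)
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns",
    "xmlns:xsi" = "http://www.w3.org/2001/XMLSchema-instance",
    "xsi:schemaLocation" = paste("http://graphml.graphdrawing.org/xmlns",
                                 "http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd")
  )
  add_key <- function(id, domain, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = domain,
                        attr.name = id, attr.type = type)
  }
  for (k in names(graphml_node_keys)) add_key(k, "node", graphml_node_keys[[k]])
  for (k in names(graphml_edge_keys)) add_key(k, "edge", graphml_edge_keys[[k]])
  add_key("posGroup", "graph", "string")
  add_key("negGroup", "graph", "string")
  add_key("groupSizes", "graph", "string")
  g <- xml2::xml_add_child(doc, "graph", id = "aag", edgedefault = "directed")
  add_data <- function(parent, key, value) {
    d <- xml2::xml_add_child(parent, "data", key = key)
    xml2::xml_text(d) <- value
  }
  add_data(g, "posGroup", rep$posGroup)
  add_data(g, "negGroup", rep$negGroup)
  add_data(g, "groupSizes", fmt_list(rep$groupSizes))
  for (nd in rep$nodes) {
    el <- xml2::xml_add_child(g, "node", id = nd$id)
    add_data(el, "name", nd$name)
    add_data(el, "value", nd$value)
    add_data(el, "description", nd$description)
    add_data(el, "refLower", fmt_num(nd$refLower))
    add_data(el, "refUpper", fmt_num(nd$refUpper))
    add_data(el, "labels", paste(unlist(nd$labels), collapse = ";"))
    add_data(el, "groupAbsCounts", fmt_list(nd$groupAbsCounts))
    add_data(el, "groupRelShareTotals", fmt_list(nd$groupRelShareTotals))
    add_data(el, "groupRelShareAttrs", fmt_list(nd$groupRelShareAttrs))
    add_data(el, "diffRelShareAttr", fmt_num(nd$diffRelShareAttr))
    add_data(el, "quotRelShareAttr", fmt_num(nd$quotRelShareAttr))
    add_data(el, "direction", nd$direction)
  }
  for (ed in rep$edges) {
    el <- xml2::xml_add_child(g, "edge", source = ed$startId, target = ed$endId)
    add_data(el, "type", ed$type)
    add_data(el, "groupAbsCoOccurs", fmt_list(ed$groupAbsCoOccurs))
    add_data(el, "groupRelShareConds", fmt_list(ed$groupRelShareConds))
    add_data(el, "groupDiffTargets", fmt_list(ed$groupDiffTargets))
    add_data(el, "groupQuotTargets", fmt_list(ed$groupQuotTargets))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import an AAG from GraphML
#'
#' @param path path to a file written by [export_graphml()].
#' @return An `aag` reproducing all statistics, labels and encodings.
#' @export
import_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  g <- xml2::xml_find_first(doc, ".//graph")
  get_data <- function(el, key) {
    d <- xml2::xml_find_first(el, sprintf("./data[@key='%s']", key))
    if (inherits(d, "xml_missing")) NULL else xml2::xml_text(d)
  }
  split_labels <- function(s) {
    if (is.null(s) || !nzchar(s)) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1L]]
  }
  nodes <- lapply(xml2::xml_find_all(g, "./node"), function(el) {
    list(
      id = xml2::xml_attr(el, "id"),
      name = get_data(el, "name"),
      value = get_data(el, "value"),
      description = get_data(el, "description"),
      refLower = parse_num(get_data(el, "refLower")),
      refUpper = parse_num(get_data(el, "refUpper")),
      labels = as.list(split_labels(get_data(el, "labels"))),
      groupAbsCounts = parse_list(get_data(el, "groupAbsCounts")),
      groupRelShareTotals = parse_list(get_data(el, "groupRelShareTotals")),
      groupRelShareAttrs = parse_list(get_data(el, "groupRelShareAttrs")),
      diffRelShareAttr = parse_num(get_data(el, "diffRelShareAttr")),
      quotRelShareAttr = parse_num(get_data(el, "quotRelShareAttr")),
      direction = get_data(el, "direction")
    )
  })
  edges <- lapply(xml2::xml_find_all(g, "./edge"), function(el) {
    list(
      startId = xml2::xml_attr(el, "source"),
      endId = xml2::xml_attr(el, "target"),
      type = get_data(el, "type"),
      groupAbsCoOccurs = parse_list(get_data(el, "groupAbsCoOccurs")),
      groupRelShareConds = parse_list(get_data(el, "groupRelShareConds")),
      groupDiffTargets = parse_list(get_data(el, "groupDiffTargets")),
      groupQuotTargets = parse_list(get_data(el, "groupQuotTargets"))
    )
  })
  aag_from_list(list(
    posGroup = get_data(g, "posGroup"),
    negGroup = get_data(g, "negGroup"),
    groupSizes = parse_list(get_data(g, "groupSizes")),
    config = list(),
    nodes = nodes,
    edges = edges
  ))
}

# Property-graph bulk import -------------------------------------------------

csv_round <- function(x, digits = 4) {
  ifelse(is.na(x), NA_real_, signif(x, digits))
}

#' Export an AAG as property-graph bulk-import files
#'
#' Writes `nodes.csv` and `edges.csv` in the typed-header bulk-import
#' dialect (`id:ID`, `:LABEL`, `:START_ID`, `:END_ID`, `:TYPE`, array
#' columns like `groupAbsCounts:long[]` with `;` separators, control group
#' first), a `load.cypher` script that reproduces the graph in a
#' property-graph database, a statement-per-element `create.cypher` for
#' small graphs, and `style.json` ([visual_encoding()]). Shares in the CSVs
#' are rounded to 4 significant digits for readability; use [export_json()]
#' for full precision.
#'
#' @param graph an `aag`.
#' @param out_dir output directory, created if needed.
#' @param max_create_statements emit `create.cypher` only when the graph has
#'   at most this many nodes (default 500).
#' @return Character vector of the written paths, invisibly.
#' @export
export_property_graph <- function(graph, out_dir, max_create_statements = 500L) {
  stopifnot(inherits(graph, "aag"))
  if (nrow(graph$nodes) == 0L) {
    aag_stop("refusing to export an empty graph", "aag_export_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- graph$nodes
  e <- graph$edges
  labels <- vapply(seq_len(nrow(n)), function(i) {
    paste(c(n$broad_labels[[i]], n$frequency_label[i], n$distinction_label[i]),
          collapse = ";")
  }, "")
  arr <- function(a, b, digits = NA) {
    if (!is.na(digits)) { a <- csv_round(a, digits); b <- csv_round(b, digits) }
    paste(a, b, sep = ";")
  }
  nodes_df <- data.frame(
    `id:ID` = n$attribute_id,
    name = n$variable,
    value = n$value,
    description = n$description,
    `refLower:double` = csv_round(n$ref_lower),
    `refUpper:double` = csv_round(n$ref_upper),
    `:LABEL` = labels,
    `groupAbsCounts:long[]` = arr(n$c_c, n$c_d),
    `groupRelShareTotals:double[]` = arr(n$rel_total_c, n$rel_total_d, 4),
    `groupRelShareAttrs:double[]` = arr(n$p_c, n$p_d, 4),
    `diffRelShareAttr:double` = csv_round(n$delta),
    `quotRelShareAttr:double` = csv_round(n$gamma),
    posGroup = graph$groups$disease_name,
    negGroup = graph$groups$control_name,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  edges_df <- data.frame(
    `:START_ID` = e$source_id,
    `:END_ID` = e$target_id,
    `:TYPE` = edge_type_to_export(e$edge_type),
    `groupAbsCoOccurs:long[]` = arr(e$o_c, e$o_d),
    `groupRelShareConds:double[]` = arr(e$q_c, e$q_d, 4),
    `groupDiffTargets:double[]` = arr(e$dprime_c, e$dprime_d, 4),
    `groupQuotTargets:double[]` = arr(e$gprime_c, e$gprime_d, 4),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  nodes_path <- file.path(out_dir, "nodes.csv")
  edges_path <- file.path(out_dir, "edges.csv")
  write.csv(nodes_df, nodes_path, row.names = FALSE, na = "")
  write.csv(edges_df, edges_path, row.names = FALSE, na = "")

  load_script <- c(
    "// Bulk import of an attribute association graph.",
    "// Option A (offline): neo4j-admin database import full \\",
    "//   --nodes=Attribute=nodes.csv --relationships=edges.csv <db>",
    "// Option B (online) -- LOAD CSV:",
    "LOAD CSV WITH HEADERS FROM 'file:///nodes.csv' AS row",
    "CREATE (a:Attribute {id: row.`id:ID`, name: row.name, value: row.value,",
    "  description: row.description,",
    "  refLower: toFloat(row.`refLower:double`),",
    "  refUpper: toFloat(row.`refUpper:double`),",
    "  groupAbsCounts: [x IN split(row.`groupAbsCounts:long[]`, ';') | toInteger(x)],",
    "  groupRelShareTotals: [x IN split(row.`groupRelShareTotals:double[]`, ';') | toFloat(x)],",
    "  groupRelShareAttrs: [x IN split(row.`groupRelShareAttrs:double[]`, ';') | toFloat(x)],",
    "  diffRelShareAttr: toFloat(row.`diffRelShareAttr:double`),",
    "  quotRelShareAttr: toFloat(row.`quotRelShareAttr:double`),",
    "  posGroup: row.posGroup, negGroup: row.negGroup});",
    "CREATE INDEX attr_id IF NOT EXISTS FOR (a:Attribute) ON (a.id);",
    "LOAD CSV WITH HEADERS FROM 'file:///edges.csv' AS row",
    "MATCH (s:Attribute {id: row.`:START_ID`}), (t:Attribute {id: row.`:END_ID`})",
    "CALL apoc.create.relationship(s, row.`:TYPE`, {",
    "  groupAbsCoOccurs: [x IN split(row.`groupAbsCoOccurs:long[]`, ';') | toInteger(x)],",
    "  groupRelShareConds: [x IN split(row.`groupRelShareConds:double[]`, ';') | toFloat(x)],",
    "  groupDiffTargets: [x IN split(row.`groupDiffTargets:double[]`, ';') | toFloat(x)],",
    "  groupQuotTargets: [x IN split(row.`groupQuotTargets:double[]`, ';') | toFloat(x)]",
    "}, t) YIELD rel RETURN count(rel);"
  )
  load_path <- file.path(out_dir, "load.cypher")
  writeLines(load_script, load_path)

  paths <- c(nodes_path, edges_path, load_path)
  if (nrow(n) <= max_create_statements) {
    q <- function(x) gsub("'", "\\\\'", x)
    lab_cypher <- vapply(seq_len(nrow(n)), function(i) {
      paste(sprintf("`%s`", c("Attribute", n$broad_labels[[i]],
                              n$frequency_label[i], n$distinction_label[i])),
            collapse = ":")
    }, "")
    stmts <- sprintf(
      "CREATE (`n%d`:%s {id: '%s', name: '%s', value: '%s', groupRelShareAttrs: [%s, %s]});",
      seq_len(nrow(n)), lab_cypher, q(n$attribute_id), q(n$variable), q(n$value),
      csv_round(n$p_c), csv_round(n$p_d))
    estmts <- if (nrow(e)) sprintf(
      paste0("MATCH (s {id: '%s'}), (t {id: '%s'}) ",
             "CREATE (s)-[:%s {groupRelShareConds: [%s, %s]}]->(t);"),
      q(e$source_id), q(e$target_id), edge_type_to_export(e$edge_type),
      csv_round(e$q_c), csv_round(e$q_d)) else character(0)
    create_path <- file.path(out_dir, "create.cypher")
    writeLines(c(stmts, estmts), create_path)
    paths <- c(paths, create_path)
  }
  style_path <- file.path(out_dir, "style.json")
  jsonlite::write_json(visual_encoding(), style_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, style_path))
}
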
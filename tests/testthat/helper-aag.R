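# Shared fixtures and independent brute-force oracles. The oracles recount
# every statistic directly from raw table rows (band comparisons, equality
# tests, sums over logical vectors) and never touch the package's incidence
# matrix / crossprod code path.

# A tiny deterministic cohort used across unit tests.
toy_meta <- function() {
  variable_meta(
    name = c("chol", "smoker", "nyha"),
    data_kind = c("metric", "binary", "categorical"),
    description = c("Total cholesterol (mg/dL)", "Current smoker", "NYHA class"),
    categories = list(character(0), c("yes", "no"), c("I", "II", "III")),
    broad_labels = list("Laboratory", "Lifestyle", "Cardiac")
  )
}

toy_table <- function() {
  df <- data.frame(
    chol = c(150, 210, 180, NA, 250, 190, 175, 230, 160, 205),
    smoker = c("yes", "no", "yes", "yes", NA, "no", "no", "yes", "no", "no"),
    nyha = c("I", "II", "I", "III", "II", "I", NA, "II", "I", "I"),
    stringsAsFactors = FALSE
  )
  cohort_table_from_df(df, toy_meta(), sprintf("P%02d", 1:10))
}

toy_spec <- function() {
  cohort_spec(list(
    list(variable = "nyha", comparator = "in_set", value = c("II", "III"))
  ), disease_name = "hf", control_name = "ctrl")
}

# Build a minimal aag_attributes object directly from a status matrix,
# bypassing derive_attributes (used to test node/edge statistics against
# hand-constructed member/non-member/missing patterns).
attrs_from_status <- function(status, variables = NULL) {
  ids <- colnames(status)
  if (is.null(variables)) variables <- ids
  at <- data.frame(attribute_id = ids, variable = variables, value = ids,
                   description = ids, ref_lower = NA_real_, ref_upper = NA_real_,
                   stringsAsFactors = FALSE)
  at$broad_labels <- rep(list(character(0)), length(ids))
  structure(list(attributes = at, status = status), class = "aag_attributes")
}

assignment_from_groups <- function(ids_d, ids_c) {
  membership <- c(rep("disease", length(ids_d)), rep("control", length(ids_c)))
  names(membership) <- c(ids_d, ids_c)
  structure(list(membership = membership, g_d = length(ids_d),
                 g_c = length(ids_c),
                 disease_name = "disease", control_name = "control"),
            class = "cohort_assignment")
}

# --- oracles ---------------------------------------------------------------

# Membership of one participant value in one attribute (logical / NA).
oracle_member <- function(col, value, ref_lower = NA, ref_upper = NA) {
  if (!is.na(ref_lower)) {
    switch(value,
           low = ifelse(is.na(col), NA, col < ref_lower),
           normal = ifelse(is.na(col), NA, col >= ref_lower & col <= ref_upper),
           high = ifelse(is.na(col), NA, col > ref_upper))
  } else {
    ifelse(is.na(col), NA, col == value)
  }
}

# Reference range by the direct formula (explicit n-1 variance).
oracle_range <- function(values) {
  v <- values[!is.na(values)]
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  c(lower = m - s, upper = m + s)
}

# Node statistics recounted from raw columns for one attribute.
oracle_node <- function(table, membership, variable, value,
                        ref_lower = NA, ref_upper = NA) {
  col <- table$data[[variable]]
  mem <- oracle_member(col, value, ref_lower, ref_upper)
  out <- list()
  for (g in c("d", "c")) {
    gi <- membership == (if (g == "d") "disease" else "control")
    m <- mem[gi]
    out[[paste0("g_", g)]] <- sum(gi)
    out[[paste0("c_", g)]] <- sum(m, na.rm = TRUE)
    out[[paste0("n_", g)]] <- sum(!is.na(m))
    out[[paste0("rel_total_", g)]] <- sum(m, na.rm = TRUE) / sum(gi)
    out[[paste0("p_", g)]] <- sum(m, na.rm = TRUE) / sum(!is.na(m))
  }
  out$delta <- abs(out$p_d - out$p_c)
  hi <- max(out$p_d, out$p_c); lo <- min(out$p_d, out$p_c)
  out$gamma <- if (hi == 0) 1 else hi / lo
  out
}

# Edge statistics recounted from raw columns for one ordered pair.
oracle_edge <- function(table, membership, src, tgt, p_tgt_d, p_tgt_c) {
  ms <- oracle_member(table$data[[src$variable]], src$value,
                      src$ref_lower, src$ref_upper)
  mt <- oracle_member(table$data[[tgt$variable]], tgt$value,
                      tgt$ref_lower, tgt$ref_upper)
  out <- list()
  for (g in c("d", "c")) {
    gi <- membership == (if (g == "d") "disease" else "control")
    both <- sum(ms[gi] & mt[gi], na.rm = TRUE)
    cx <- sum(ms[gi], na.rm = TRUE)
    py <- if (g == "d") p_tgt_d else p_tgt_c
    q <- if (cx > 0) both / cx else NA_real_
    out[[paste0("o_", g)]] <- both
    out[[paste0("q_", g)]] <- q
    defined <- !is.na(q) && !is.na(py) && py > 0
    out[[paste0("dprime_", g)]] <- if (defined) q - py else NA_real_
    out[[paste0("gprime_", g)]] <- if (defined) q / py else NA_real_
  }
  out
}

# Random cohort spec generator for property-style tests.
random_sim_spec <- function(seed, n_vars = 5, g_d = 150, g_c = 350) {
  set.seed(seed)
  vars <- lapply(seq_len(n_vars), function(i) {
    kind <- sample(c("binary", "categorical", "metric"), 1)
    name <- sprintf("v%02d", i)
    md <- stats::runif(1, 0, 0.3)
    mc <- stats::runif(1, 0, 0.3)
    if (kind == "binary") {
      sim_variable(name, "binary", prob_d = stats::runif(1, 0.05, 0.95),
                   prob_c = stats::runif(1, 0.05, 0.95),
                   missing_d = md, missing_c = mc)
    } else if (kind == "categorical") {
      p1 <- as.vector(stats::runif(3)); p1 <- p1 / sum(p1)
      p2 <- as.vector(stats::runif(3)); p2 <- p2 / sum(p2)
      sim_variable(name, "categorical", categories = c("a", "b", "c"),
                   probs_d = p1, probs_c = p2, missing_d = md, missing_c = mc)
    } else {
      sim_variable(name, "metric",
                   mean_d = stats::runif(1, -5, 5), sd_d = stats::runif(1, 0.5, 3),
                   mean_c = stats::runif(1, -5, 5), sd_c = stats::runif(1, 0.5, 3),
                   missing_d = md, missing_c = mc)
    }
  })
  simulation_spec(g_d, g_c, vars, seed = seed)
}

# Full-graph oracle check: recounts every node and edge statistic from raw
# rows and returns a character vector describing the mismatches (empty when
# the graph agrees with the oracle exactly).
graph_oracle_mismatches <- function(graph, table, assignment) {
  membership <- assignment$membership[table$participant_ids]
  nd <- graph$nodes
  bad <- character(0)
  note <- function(what) bad <<- c(bad, what)
  same_num <- function(a, b) {
    (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
  }
  # reference bounds must agree with the direct-formula oracle
  for (v in unique(nd$variable[!is.na(nd$ref_lower)])) {
    rng <- oracle_range(table$data[[v]])
    i <- which(nd$variable == v)[1]
    if (abs(nd$ref_lower[i] - rng["lower"]) > 1e-9 ||
        abs(nd$ref_upper[i] - rng["upper"]) > 1e-9) {
      note(sprintf("range %s", v))
    }
  }
  for (i in seq_len(nrow(nd))) {
    o <- oracle_node(table, membership, nd$variable[i], nd$value[i],
                     nd$ref_lower[i], nd$ref_upper[i])
    for (f in c("c_d", "c_c", "n_d", "n_c", "g_d", "g_c",
                "rel_total_d", "rel_total_c", "p_d", "p_c", "delta", "gamma")) {
      if (!same_num(as.numeric(nd[[f]][i]), as.numeric(o[[f]]))) {
        note(sprintf("node %s field %s: %s != %s", nd$attribute_id[i], f,
                     nd[[f]][i], o[[f]]))
      }
    }
  }
  ed <- graph$edges
  defs <- nd[, c("attribute_id", "variable", "value", "ref_lower", "ref_upper")]
  rownames(defs) <- defs$attribute_id
  for (i in seq_len(nrow(ed))) {
    src <- as.list(defs[ed$source_id[i], ])
    tgt <- as.list(defs[ed$target_id[i], ])
    j <- match(ed$target_id[i], nd$attribute_id)
    o <- oracle_edge(table, membership, src, tgt, nd$p_d[j], nd$p_c[j])
    for (f in c("o_d", "o_c", "q_d", "q_c", "dprime_d", "dprime_c",
                "gprime_d", "gprime_c")) {
      if (!same_num(as.numeric(ed[[f]][i]), as.numeric(o[[f]]))) {
        note(sprintf("edge %s->%s field %s: %s != %s", ed$source_id[i],
                     ed$target_id[i], f, ed[[f]][i], o[[f]]))
      }
    }
  }
  bad
}

expect_graph_matches_oracle <- function(graph, table, assignment) {
  bad <- graph_oracle_mismatches(graph, table, assignment)
  expect_identical(bad, character(0))
  invisible(TRUE)
}
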
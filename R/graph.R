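# Graph core: node statistics, edge statistics, label/type rules, assembly.

#' AAG configuration
#'
#' Thresholds default to the standard AAG constants: frequency labels switch at
#' maximum relative attribute share 0.5 and 0.1; distinction labels and edge
#' types switch at difference 0.2 / quotient 2.0 (strong band) and 0.1 / 1.5
#' (middle band).
#'
#' @param freq_high,freq_mid frequency-label thresholds on the maximum
#'   relative attribute share (`highly_frequent` at >= `freq_high`,
#'   `frequent` at >= `freq_mid`).
#' @param delta_high,gamma_high thresholds for the strong distinction band
#'   and the high edge type.
#' @param delta_mid,gamma_mid thresholds for the middle band.
#' @param edge_aggregation how the two per-group conditional effects combine
#'   into one edge type: `"max"` (default; strongest group decides),
#'   `"disease"` or `"control"` (that group alone decides).
#' @param signed_edge_magnitude when `TRUE` (default) an edge's type is
#'   driven by the magnitude of the conditional effect, `|delta'|` and
#'   `max(gamma', 1/gamma')`, so suppressive (negative) relations are
#'   surfaced too; when `FALSE` only positive effects count.
#' @param same_variable_edges include edges between attributes of the same
#'   variable (default `FALSE`: bands of one variable are mutually exclusive
#'   and produce degenerate zero-co-occurrence edges).
#' @return A list of class `aag_config`.
#' @export
aag_config <- function(freq_high = 0.5, freq_mid = 0.1,
                       delta_high = 0.2, gamma_high = 2.0,
                       delta_mid = 0.1, gamma_mid = 1.5,
                       edge_aggregation = c("max", "disease", "control"),
                       signed_edge_magnitude = TRUE,
                       same_variable_edges = FALSE) {
  edge_aggregation <- match.arg(edge_aggregation)
  stopifnot(freq_high >= freq_mid, delta_high >= delta_mid,
            gamma_high >= gamma_mid, gamma_mid >= 1)
  structure(list(freq_high = freq_high, freq_mid = freq_mid,
                 delta_high = delta_high, gamma_high = gamma_high,
                 delta_mid = delta_mid, gamma_mid = gamma_mid,
                 edge_aggregation = edge_aggregation,
                 signed_edge_magnitude = signed_edge_magnitude,
                 same_variable_edges = same_variable_edges),
            class = "aag_config")
}

#' Assign the frequency label
#'
#' @param p_max maximum relative attribute share of a node across the two
#'   groups; vectorized.
#' @param config an [aag_config()].
#' @return Character vector in `{highly_frequent, frequent, infrequent}`.
#' @export
assign_frequency_label <- function(p_max, config = aag_config()) {
  if (any(!is.na(p_max) & (p_max < 0 | p_max > 1))) {
    aag_stop("p_max must lie in [0, 1]", "aag_contract_error")
  }
  ifelse(is.na(p_max), NA_character_,
         ifelse(p_max >= config$freq_high, "highly_frequent",
                ifelse(p_max >= config$freq_mid, "frequent", "infrequent")))
}

#' Compare two relative attribute shares
#'
#' Computes the absolute share difference `delta = |p_d - p_c|`, the share
#' quotient `gamma = max(p_d, p_c) / min(p_d, p_c)`, the direction, and the
#' resulting distinction label. `gamma` is `Inf` when one share is zero and
#' the other positive (treated as exceeding every quotient threshold) and 1
#' when both are zero.
#'
#' @param p_d,p_c relative attribute shares in the disease and control
#'   group; vectorized.
#' @param config an [aag_config()].
#' @return data.frame with columns `delta`, `gamma`, `direction`
#'   (`disease_higher`/`control_higher`/`equal`) and `distinction_label`.
#' @examples
#' compare_shares(0.163, 0.055)  # highly_related, gamma ~ 2.96
#' compare_shares(0.473, 0.612)  # inverse, delta = 0.139
#' @export
compare_shares <- function(p_d, p_c, config = aag_config()) {
  n <- max(length(p_d), length(p_c))
  p_d <- rep_len(p_d, n); p_c <- rep_len(p_c, n)
  delta <- abs(p_d - p_c)
  hi <- pmax(p_d, p_c); lo <- pmin(p_d, p_c)
  gamma <- ifelse(hi == 0, 1, hi / lo)   # 0/0 -> equal; x/0 -> Inf
  direction <- ifelse(p_d > p_c, "disease_higher",
                      ifelse(p_d < p_c, "control_higher", "equal"))
  strong <- delta >= config$delta_high | gamma >= config$gamma_high
  mid <- delta >= config$delta_mid | gamma >= config$gamma_mid
  label <- ifelse(direction == "equal", "unrelated",
           ifelse(strong,
                  ifelse(direction == "disease_higher", "highly_related", "highly_inverse"),
           ifelse(mid,
                  ifelse(direction == "disease_higher", "related", "inverse"),
                  "unrelated")))
  label[is.na(p_d) | is.na(p_c)] <- NA_character_
  data.frame(delta = delta, gamma = gamma, direction = direction,
             distinction_label = label, stringsAsFactors = FALSE)
}

#' Assign the distinction label
#'
#' Convenience wrapper around [compare_shares()] returning only the label.
#'
#' @inheritParams compare_shares
#' @return Character vector in `{highly_related, related, unrelated,
#'   inverse, highly_inverse}`.
#' @export
assign_distinction_label <- function(p_d, p_c, config = aag_config()) {
  compare_shares(p_d, p_c, config)$distinction_label
}

# Per-group count summaries over the incidence matrix.
group_counts <- function(attrs, assignment) {
  mem <- assignment$membership[rownames(attrs$status)]
  if (anyNA(mem)) {
    aag_stop("incidence matrix participants not covered by the assignment",
             "aag_contract_error")
  }
  lapply(c(disease = "disease", control = "control"), function(g) {
    S <- attrs$status[mem == g, , drop = FALSE]
    list(g = nrow(S),
         c = colSums(S == 1L, na.rm = TRUE),
         n = colSums(!is.na(S)),
         member = (S == 1L) & !is.na(S))
  })
}

#' Compute node statistics for every attribute
#'
#' For each attribute and each group i in {disease, control} this yields the
#' absolute count `c_i`, the group size `g_i`, the valid (non-missing) count
#' `n_i`, the relative total share `c_i / g_i`, and the missing-value
#' adjusted relative attribute share `p_i = c_i / n_i`; across groups the
#' share difference `delta`, quotient `gamma`, direction, frequency label
#' and distinction label. Groups with `n_i = 0` get `NA` shares and the node
#' is left unlabeled (with a warning).
#'
#' @param attrs an `aag_attributes` object ([derive_attributes()]).
#' @param assignment a `cohort_assignment` ([assign_cohorts()]).
#' @param config an [aag_config()].
#' @return data.frame, one row per attribute.
#' @export
node_statistics_table <- function(attrs, assignment, config = aag_config()) {
  gc <- group_counts(attrs, assignment)
  d <- gc$disease; cg <- gc$control
  p_d <- ifelse(d$n > 0, d$c / d$n, NA_real_)
  p_c <- ifelse(cg$n > 0, cg$c / cg$n, NA_real_)
  if (anyNA(p_d) || anyNA(p_c)) {
    bad <- colnames(attrs$status)[is.na(p_d) | is.na(p_c)]
    warning(sprintf("attribute(s) with no valid values in a group left unlabeled: %s",
                    paste(bad, collapse = ", ")), call. = FALSE)
  }
  cmp <- compare_shares(p_d, p_c, config)
  out <- cbind(
    attrs$attributes[setdiff(names(attrs$attributes), "broad_labels")],
    data.frame(
      c_d = as.integer(unname(d$c)), c_c = as.integer(unname(cg$c)),
      g_d = d$g, g_c = cg$g,
      n_d = as.integer(unname(d$n)), n_c = as.integer(unname(cg$n)),
      rel_total_d = unname(if (d$g > 0) d$c / d$g else rep(NA_real_, length(d$c))),
      rel_total_c = unname(if (cg$g > 0) cg$c / cg$g else rep(NA_real_, length(cg$c))),
      p_d = unname(p_d), p_c = unname(p_c),
      stringsAsFactors = FALSE
    ),
    cmp
  )
  out$frequency_label <- assign_frequency_label(pmax(p_d, p_c), config)
  out$broad_labels <- attrs$attributes$broad_labels
  rownames(out) <- NULL
  out
}

#' Node statistics for a single attribute
#'
#' @inheritParams node_statistics_table
#' @param attribute_id id of the attribute (`variable=value`).
#' @return One-row data.frame (see [node_statistics_table()]).
#' @export
node_statistics <- function(attrs, assignment, attribute_id, config = aag_config()) {
  if (!attribute_id %in% colnames(attrs$status)) {
    aag_stop(sprintf("unknown attribute '%s'", attribute_id), "aag_contract_error")
  }
  tab <- node_statistics_table(attrs, assignment, config)
  tab[tab$attribute_id == attribute_id, , drop = FALSE]
}

#' Assign edge types from per-group conditional effects
#'
#' Per group the conditional effect is summarised as a magnitude pair
#' (`|delta'|`, `max(gamma', 1/gamma')`) when `signed_edge_magnitude` is on,
#' or (`delta'`, `gamma'`) otherwise. The per-group pairs are aggregated
#' (default: maximum over the defined groups) and thresholded: high if
#' delta' >= 0.2 or gamma' >= 2.0; medium if delta' >= 0.1 or gamma' >= 1.5
#' (and below the high band); low otherwise.
#'
#' @param dprime_d,dprime_c signed conditional-vs-unconditional target share
#'   differences per group (`NA` when undefined); vectorized.
#' @param gprime_d,gprime_c the corresponding quotients.
#' @param config an [aag_config()].
#' @return Character vector in `{high_cond_diff, medium_cond_diff,
#'   low_cond_diff}`; `NA` when both groups are undefined.
#' @export
assign_edge_type <- function(dprime_d, dprime_c, gprime_d, gprime_c,
                             config = aag_config()) {
  mag <- function(dp, gp) {
    if (config$signed_edge_magnitude) {
      dp <- abs(dp)
      gp <- ifelse(is.na(gp), NA_real_, ifelse(gp == 0, Inf, pmax(gp, 1 / gp)))
    }
    list(dp = dp, gp = gp)
  }
  md <- mag(dprime_d, gprime_d)
  mc <- mag(dprime_c, gprime_c)
  agg <- switch(config$edge_aggregation,
    max = list(dp = pmax(md$dp, mc$dp, na.rm = TRUE),
               gp = pmax(md$gp, mc$gp, na.rm = TRUE)),
    disease = md,
    control = mc
  )
  # pmax(NA, NA, na.rm=TRUE) yields -Inf for doubles; normalise to NA
  agg$dp[!is.finite(agg$dp) & agg$dp < 0] <- NA_real_
  agg$gp[!is.finite(agg$gp) & agg$gp < 0] <- NA_real_
  undefined <- is.na(agg$dp) & is.na(agg$gp)
  dp <- ifelse(is.na(agg$dp), -Inf, agg$dp)
  gp <- ifelse(is.na(agg$gp), -Inf, agg$gp)
  type <- ifelse(dp >= config$delta_high | gp >= config$gamma_high, "high_cond_diff",
          ifelse(dp >= config$delta_mid | gp >= config$gamma_mid, "medium_cond_diff",
                 "low_cond_diff"))
  type[undefined] <- NA_character_
  type
}

#' Compute edge statistics for all attribute pairs
#'
#' For an ordered pair (source x, target y) and each group i, the absolute
#' co-occurrence `o_i` counts group members holding both attributes; the
#' relative conditional share `q_i = o_i / c_i^x` is the fraction of source
#' members also holding the target attribute (the analogue of confidence in
#' association rule learning); `delta'_i = q_i - p_i^y` and `gamma'_i =
#' q_i / p_i^y` measure the impact of conditioning against the target's
#' unconditional share. Values are `NA` where `c_i^x = 0` or `p_i^y` is
#' zero/undefined.
#'
#' @inheritParams node_statistics_table
#' @param node_stats the table from [node_statistics_table()] (recomputed
#'   when `NULL`).
#' @return data.frame, one row per ordered pair of attributes from distinct
#'   variables (all pairs when `config$same_variable_edges`), with the
#'   per-group statistics and the aggregated `edge_type`.
#' @export
edge_statistics_table <- function(attrs, assignment, node_stats = NULL,
                                  config = aag_config()) {
  if (is.null(node_stats)) node_stats <- node_statistics_table(attrs, assignment, config)
  gc <- group_counts(attrs, assignment)
  A <- ncol(attrs$status)
  ids <- colnames(attrs$status)
  if (A < 2L) {
    return(empty_edge_table())
  }
  src <- rep(seq_len(A), each = A)
  tgt <- rep(seq_len(A), times = A)
  keep <- src != tgt
  if (!config$same_variable_edges) {
    vars <- attrs$attributes$variable
    keep <- keep & vars[src] != vars[tgt]
  }
  src <- src[keep]; tgt <- tgt[keep]
  per_group <- function(g, p_tgt) {
    M <- g$member * 1L
    O <- crossprod(M)                      # O[x, y] = joint member count
    o <- O[cbind(src, tgt)]
    cx <- g$c[src]
    q <- ifelse(cx > 0, o / cx, NA_real_)
    py <- p_tgt[tgt]
    dp <- ifelse(!is.na(q) & !is.na(py) & py > 0, q - py, NA_real_)
    gp <- ifelse(!is.na(q) & !is.na(py) & py > 0, q / py, NA_real_)
    list(o = o, q = q, dp = dp, gp = gp)
  }
  d <- per_group(gc$disease, node_stats$p_d)
  cg <- per_group(gc$control, node_stats$p_c)
  out <- data.frame(
    source_id = ids[src], target_id = ids[tgt],
    o_d = as.integer(d$o), o_c = as.integer(cg$o),
    q_d = d$q, q_c = cg$q,
    dprime_d = d$dp, dprime_c = cg$dp,
    gprime_d = d$gp, gprime_c = cg$gp,
    stringsAsFactors = FALSE
  )
  out$edge_type <- assign_edge_type(out$dprime_d, out$dprime_c,
                                    out$gprime_d, out$gprime_c, config)
  dropped <- is.na(out$edge_type)
  if (any(dropped)) {
    warning(sprintf("%d edge(s) dropped: conditional statistics undefined in both groups",
                    sum(dropped)), call. = FALSE)
    out <- out[!dropped, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

empty_edge_table <- function() {
  data.frame(source_id = character(0), target_id = character(0),
             o_d = integer(0), o_c = integer(0),
             q_d = numeric(0), q_c = numeric(0),
             dprime_d = numeric(0), dprime_c = numeric(0),
             gprime_d = numeric(0), gprime_c = numeric(0),
             edge_type = character(0), stringsAsFactors = FALSE)
}

#' Edge statistics for a single ordered pair
#'
#' @inheritParams edge_statistics_table
#' @param source_id,target_id attribute ids; must differ (and come from
#'   different variables unless `config$same_variable_edges`).
#' @return One-row data.frame (see [edge_statistics_table()]); zero rows if
#'   the edge was dropped as undefined.
#' @export
edge_statistics <- function(attrs, assignment, source_id, target_id,
                            node_stats = NULL, config = aag_config()) {
  if (source_id == target_id) {
    aag_stop("self-edges are not defined", "aag_contract_error")
  }
  tab <- suppressWarnings(
    edge_statistics_table(attrs, assignment, node_stats, config))
  tab[tab$source_id == source_id & tab$target_id == target_id, , drop = FALSE]
}

#' Build the full attribute association graph
#'
#' Runs the whole pipeline: cohort assignment, reference ranges (+ manual
#' overrides), attribute derivation, node statistics with frequency and
#' distinction labels, edge statistics with types, and provenance capture.
#' The result is unfiltered; see [filter_aag()].
#'
#' @param table a `cohort_table`.
#' @param spec a `cohort_spec`.
#' @param config an [aag_config()].
#' @param overrides optional named list or data.frame of manual
#'   reference-range overrides (see [apply_overrides()]).
#' @return A list of class `aag` with `nodes`, `edges`, `config`, `groups`
#'   (names and sizes) and `provenance`.
#' @export
build_aag <- function(table, spec, config = aag_config(), overrides = NULL) {
  stopifnot(inherits(table, "cohort_table"), inherits(spec, "cohort_spec"))
  assignment <- assign_cohorts(table, spec)
  if (assignment$g_d == 0L || assignment$g_c == 0L) {
    aag_stop(sprintf("degenerate cohort split (%s: %d, %s: %d); both groups must be non-empty",
                     assignment$disease_name, assignment$g_d,
                     assignment$control_name, assignment$g_c),
             "aag_build_error")
  }
  ranges <- reference_ranges(table)
  if (!is.null(overrides)) ranges <- apply_overrides(ranges, overrides)
  attrs <- derive_attributes(table, ranges)
  nodes <- node_statistics_table(attrs, assignment, config)
  edges <- edge_statistics_table(attrs, assignment, nodes, config)
  structure(
    list(nodes = nodes, edges = edges, config = config,
         groups = list(disease_name = assignment$disease_name,
                       control_name = assignment$control_name,
                       g_d = assignment$g_d, g_c = assignment$g_c),
         provenance = list(
           g_total = table$g_total,
           n_variables = ncol(table$data),
           ranges = lapply(ranges, unclass),
           created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           package_version = as.character(utils::packageVersion("aagraph"))
         )),
    class = "aag"
  )
}

#' @export
print.aag <- function(x, ...) {
  cat(sprintf("<aag> %d nodes, %d edges | %s: %d vs %s: %d\n",
              nrow(x$nodes), nrow(x$edges),
              x$groups$disease_name, x$groups$g_d,
              x$groups$control_name, x$groups$g_c))
  if (nrow(x$nodes)) {
    lab <- table(factor(x$nodes$distinction_label,
                        levels = c("highly_related", "related", "unrelated",
                                   "inverse", "highly_inverse")))
    cat("  distinction:", paste(sprintf("%s=%d", names(lab), lab), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.aag <- function(object, ...) {
  print(object)
  if (nrow(object$edges)) {
    cat("  edge types:",
        paste(sprintf("%s=%d", names(table(object$edges$edge_type)),
                      table(object$edges$edge_type)), collapse = " "), "\n")
  }
  invisible(object)
}
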
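test_that("node statistics match hand-counted member/valid tallies", {
  # disease: member, member, non_member, missing
  # control: member, non_member, non_member, non_member, missing
  status <- matrix(c(1L, 1L, 0L, NA, 1L, 0L, 0L, 0L, NA), ncol = 1,
                   dimnames = list(paste0("P", 1:9), "a"))
  at <- attrs_from_status(status)
  asg <- assignment_from_groups(paste0("P", 1:4), paste0("P", 5:9))
  ns <- node_statistics(at, asg, "a")
  expect_identical(ns$c_d, 2L)
  expect_identical(ns$n_d, 3L)
  expect_identical(ns$rel_total_d, 0.5)
  expect_equal(ns$p_d, 2 / 3, tolerance = 1e-15)
  expect_identical(ns$c_c, 1L)
  expect_identical(ns$n_c, 4L)
  expect_identical(ns$rel_total_c, 0.2)
  expect_identical(ns$p_c, 0.25)
  expect_equal(ns$delta, 2 / 3 - 0.25, tolerance = 1e-15)   # 0.41667
  expect_equal(ns$gamma, (2 / 3) / 0.25, tolerance = 1e-15) # 2.6667
  expect_identical(ns$direction, "disease_higher")
})

test_that("saturated and missing-free cases behave as documented", {
  status <- matrix(rep(1L, 6), ncol = 1, dimnames = list(paste0("P", 1:6), "a"))
  at <- attrs_from_status(status)
  asg <- assignment_from_groups(paste0("P", 1:3), paste0("P", 4:6))
  ns <- node_statistics(at, asg, "a")
  expect_identical(c(ns$p_d, ns$p_c), c(1, 1))
  expect_identical(ns$delta, 0)
  expect_identical(ns$gamma, 1)
  expect_identical(ns$direction, "equal")
  expect_identical(ns$distinction_label, "unrelated")
  # no missing anywhere: rel_total equals p
  expect_identical(ns$rel_total_d, ns$p_d)
  expect_identical(ns$rel_total_c, ns$p_c)
})

test_that("frequency labels switch at the standard thresholds", {
  expect_identical(assign_frequency_label(0.5), "highly_frequent")
  expect_identical(assign_frequency_label(0.1), "frequent")
  expect_identical(assign_frequency_label(0.09), "infrequent")
  expect_identical(assign_frequency_label(c(0.499, 0.0999)),
                   c("frequent", "infrequent"))
  expect_error(assign_frequency_label(1.2), class = "aag_contract_error")
  expect_error(assign_frequency_label(-0.1), class = "aag_contract_error")
})

test_that("distinction labels reproduce the reference worked examples", {
  # low total cholesterol: 16.3% vs 5.5% -> highly related
  expect_identical(assign_distinction_label(0.163, 0.055), "highly_related")
  # high total cholesterol: 47.3% vs 61.2% -> inverse
  expect_identical(assign_distinction_label(0.473, 0.612), "inverse")
  expect_identical(assign_distinction_label(0.3, 0.3), "unrelated")
  # delta exactly at 0.2 meets the >= rule
  expect_identical(assign_distinction_label(0.5, 0.3), "highly_related")
  expect_identical(assign_distinction_label(0.3, 0.5), "highly_inverse")
  # quotient route: 0.04 vs 0.09 has delta 0.05 but gamma 2.25
  expect_identical(assign_distinction_label(0.04, 0.09), "highly_inverse")
  # middle band via quotient only
  expect_identical(assign_distinction_label(0.09, 0.055), "related")
  # zero share against positive share: gamma treated as infinite
  cmp <- compare_shares(0.2, 0)
  expect_identical(cmp$gamma, Inf)
  expect_identical(cmp$distinction_label, "highly_related")
  expect_identical(compare_shares(0, 0)$distinction_label, "unrelated")
})

test_that("edge statistics match hand-counted co-occurrence", {
  # disease: 4 source members, 3 of them target members; target p_d = 0.5
  ids <- paste0("P", 1:16)
  src <- c(1,1,1,1,0,0,0,0,  1,1,0,0,0,0,0,0)
  tgt <- c(1,1,1,0,1,0,0,0,  1,0,1,1,0,0,0,0)
  status <- cbind(`x=a` = as.integer(src), `y=b` = as.integer(tgt))
  rownames(status) <- ids
  at <- attrs_from_status(status, variables = c("x", "y"))
  asg <- assignment_from_groups(ids[1:8], ids[9:16])
  ns <- node_statistics_table(at, asg)
  expect_identical(ns$p_d[ns$attribute_id == "y=b"], 0.5)
  es <- edge_statistics(at, asg, "x=a", "y=b")
  expect_identical(es$o_d, 3L)
  expect_identical(es$q_d, 0.75)
  expect_identical(es$dprime_d, 0.25)
  expect_identical(es$gprime_d, 1.5)
})

test_that("identical and disjoint memberships give the degenerate edges", {
  ids <- paste0("P", 1:12)
  a <- c(1,1,0,0,1,0, 1,0,0,1,0,0)
  status <- cbind(`x=a` = as.integer(a), `y=same` = as.integer(a),
                  `z=disj` = as.integer(1 - a))
  rownames(status) <- ids
  at <- attrs_from_status(status, variables = c("x", "y", "z"))
  asg <- assignment_from_groups(ids[1:6], ids[7:12])
  ns <- node_statistics_table(at, asg)
  es <- edge_statistics_table(at, asg, ns)
  same <- es[es$source_id == "x=a" & es$target_id == "y=same", ]
  p_same_d <- ns$p_d[ns$attribute_id == "y=same"]
  expect_identical(same$q_d, 1)
  expect_identical(same$dprime_d, 1 - p_same_d)
  disj <- es[es$source_id == "x=a" & es$target_id == "z=disj", ]
  p_disj_d <- ns$p_d[ns$attribute_id == "z=disj"]
  expect_identical(disj$o_d, 0L)
  expect_identical(disj$q_d, 0)
  expect_identical(disj$dprime_d, -p_disj_d)
})

test_that("edge types follow the thresholds with max-over-groups aggregation", {
  expect_identical(assign_edge_type(0.25, 0.05, 1.3, 1.2), "high_cond_diff")
  expect_identical(assign_edge_type(0.05, 0.04, 1.6, 1.4), "medium_cond_diff")
  expect_identical(assign_edge_type(0.02, 0.01, 1.1, 1.05), "low_cond_diff")
  # boundary: delta' exactly 0.2 / gamma' exactly 2.0 are high
  expect_identical(assign_edge_type(0.2, 0, 1, 1), "high_cond_diff")
  expect_identical(assign_edge_type(0, 0, 2, 1), "high_cond_diff")
  # suppressive relation surfaces via magnitude
  expect_identical(assign_edge_type(-0.25, 0, 1, 1), "high_cond_diff")
  expect_identical(assign_edge_type(0.05, 0.05, 0.4, 1), "high_cond_diff") # 1/0.4 = 2.5
  # signed mode ignores negative effects
  cfg <- aag_config(signed_edge_magnitude = FALSE)
  expect_identical(assign_edge_type(-0.25, -0.2, 0.4, 0.5, cfg), "low_cond_diff")
  # one undefined group falls back to the other
  expect_identical(assign_edge_type(NA, 0.25, NA, 1.2), "high_cond_diff")
  expect_identical(assign_edge_type(NA, NA, NA, NA), NA_character_)
  # group-restricted aggregation
  cfg_d <- aag_config(edge_aggregation = "disease")
  expect_identical(assign_edge_type(0.05, 0.3, 1.2, 3, cfg_d), "low_cond_diff")
})

test_that("build_aag assembles the documented node and edge sets", {
  m <- variable_meta(c("grp", "a", "b"), c("binary", "binary", "binary"),
                     categories = list(c("d", "c"), c("yes", "no"), c("yes", "no")))
  df <- data.frame(grp = rep(c("d", "c"), 5),
                   a = rep(c("yes", "no"), each = 5),
                   b = c("yes", "no", "yes", "no", "yes",
                         "no", "yes", "no", "yes", "no"),
                   stringsAsFactors = FALSE)
  tab <- cohort_table_from_df(df, m, 1:10)
  spec <- cohort_spec(list(list(variable = "grp", comparator = "equals", value = "d")))
  # the perfectly separating grp indicator yields some undefined edges
  g <- suppressWarnings(build_aag(tab, spec))
  # grp contributes 2 nodes, a and b 2 each
  expect_identical(nrow(g$nodes), 6L)
  ab_nodes <- g$nodes$attribute_id[g$nodes$variable %in% c("a", "b")]
  expect_identical(length(ab_nodes), 4L)
  # ordered cross-variable pairs among 3 variables x 2 attributes
  expect_lte(nrow(g$edges), 24L)
  expect_true(all(g$edges$source_id != g$edges$target_id))

  # single metric variable -> 3 nodes, no cross-variable pair, no edges
  m2 <- variable_meta(c("grp", "x"), c("binary", "metric"),
                      categories = list(c("d", "c"), character(0)))
  df2 <- data.frame(grp = rep(c("d", "c"), 10), x = rnorm(20),
                    stringsAsFactors = FALSE)
  tab2 <- cohort_table_from_df(df2, m2, 1:20)
  g2 <- suppressWarnings(build_aag(tab2, spec))
  expect_identical(sum(g2$nodes$variable == "x"), 3L)
  expect_identical(nrow(g2$edges[g2$edges$source_id %in%
    g2$nodes$attribute_id[g2$nodes$variable == "x"] &
    g2$edges$target_id %in%
    g2$nodes$attribute_id[g2$nodes$variable == "x"], ]), 0L)

  # an empty group is a build error
  spec_none <- cohort_spec(list(list(variable = "grp", comparator = "equals",
                                     value = "zzz")))
  expect_error(build_aag(tab, spec_none), class = "aag_build_error")
})

test_that("graph equals the brute-force oracle on random synthetic cohorts", {
  for (seed in c(101, 202, 303)) {
    sim <- simulate_cohort(random_sim_spec(seed, n_vars = 5,
                                           g_d = 80, g_c = 160))
    g <- suppressWarnings(build_aag(sim$table, sim$cohort_spec))
    expect_graph_matches_oracle(g, sim$table, sim$assignment)
  }
})

test_that("rel_total is bounded by p, with equality iff no missing values", {
  sim <- simulate_cohort(random_sim_spec(5, n_vars = 6))
  g <- suppressWarnings(build_aag(sim$table, sim$cohort_spec))
  nd <- g$nodes
  ok_d <- !is.na(nd$p_d)
  expect_true(all(nd$rel_total_d[ok_d] <= nd$p_d[ok_d] + 1e-12))
  expect_true(all(nd$rel_total_c[!is.na(nd$p_c)] <=
                  nd$p_c[!is.na(nd$p_c)] + 1e-12))
  no_miss <- nd$n_d == nd$g_d
  expect_identical(nd$rel_total_d[no_miss], nd$p_d[no_miss])
})

test_that("the graph is invariant to row and column permutations", {
  sim <- simulate_cohort(random_sim_spec(17, n_vars = 4))
  tab <- sim$table
  g1 <- suppressWarnings(build_aag(tab, sim$cohort_spec))
  set.seed(1)
  rperm <- sample(tab$g_total)
  cperm <- sample(ncol(tab$data))
  tab2 <- cohort_table_from_df(tab$data[rperm, cperm, drop = FALSE],
                               tab$meta[match(names(tab$data)[cperm], tab$meta$name), ],
                               tab$participant_ids[rperm])
  g2 <- suppressWarnings(build_aag(tab2, sim$cohort_spec))
  key1 <- order(g1$nodes$attribute_id)
  key2 <- order(g2$nodes$attribute_id)
  for (f in c("c_d", "c_c", "p_d", "p_c", "delta", "gamma",
              "frequency_label", "distinction_label")) {
    expect_identical(g1$nodes[[f]][key1], g2$nodes[[f]][key2])
  }
  e1 <- g1$edges[order(g1$edges$source_id, g1$edges$target_id), ]
  e2 <- g2$edges[order(g2$edges$source_id, g2$edges$target_id), ]
  for (f in c("source_id", "target_id", "o_d", "o_c", "q_d", "q_c", "edge_type")) {
    expect_identical(unname(e1[[f]]), unname(e2[[f]]))
  }
})

test_that("swapping disease and control mirrors the labels (duality)", {
  m <- variable_meta(c("grp", "a"), c("binary", "binary"),
                     categories = list(c("g1", "g2"), c("yes", "no")))
  set.seed(9)
  df <- data.frame(grp = sample(c("g1", "g2"), 400, replace = TRUE),
                   a = sample(c("yes", "no"), 400, replace = TRUE,
                              prob = c(0.3, 0.7)),
                   stringsAsFactors = FALSE)
  df$a[df$grp == "g1"] <- sample(c("yes", "no"), sum(df$grp == "g1"),
                                 replace = TRUE, prob = c(0.6, 0.4))
  tab <- cohort_table_from_df(df, m, 1:400)
  s1 <- cohort_spec(list(list(variable = "grp", comparator = "equals", value = "g1")))
  s2 <- cohort_spec(list(list(variable = "grp", comparator = "equals", value = "g2")))
  g1 <- build_aag(tab, s1)
  g2 <- build_aag(tab, s2)
  swap <- c(highly_related = "highly_inverse", related = "inverse",
            unrelated = "unrelated", inverse = "related",
            highly_inverse = "highly_related")
  k1 <- order(g1$nodes$attribute_id); k2 <- order(g2$nodes$attribute_id)
  expect_identical(unname(swap[g1$nodes$distinction_label[k1]]),
                   g2$nodes$distinction_label[k2])
  expect_identical(g1$nodes$frequency_label[k1], g2$nodes$frequency_label[k2])
  e1 <- g1$edges[order(g1$edges$source_id, g1$edges$target_id), ]
  e2 <- g2$edges[order(g2$edges$source_id, g2$edges$target_id), ]
  expect_identical(unname(e1$o_d), unname(e2$o_c))
  expect_identical(unname(e1$o_c), unname(e2$o_d))
})

test_that("every labeled node has one frequency and one distinction label", {
  sim <- simulate_cohort(random_sim_spec(23, n_vars = 5))
  g <- suppressWarnings(build_aag(sim$table, sim$cohort_spec))
  labeled <- !is.na(g$nodes$p_d) & !is.na(g$nodes$p_c)
  expect_true(all(g$nodes$frequency_label[labeled] %in%
                  c("highly_frequent", "frequent", "infrequent")))
  expect_true(all(g$nodes$distinction_label[labeled] %in%
                  c("highly_related", "related", "unrelated",
                    "inverse", "highly_inverse")))
  expect_true(all(g$edges$edge_type %in%
                  c("high_cond_diff", "medium_cond_diff", "low_cond_diff")))
})
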
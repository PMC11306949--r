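test_that("simulation is reproducible and seed-sensitive", {
  spec <- random_sim_spec(8, n_vars = 4)
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(s1$table$data, s2$table$data)
  expect_identical(s1$assignment$membership, s2$assignment$membership)
  s3 <- simulate_cohort(spec, seed = 1234)
  expect_false(identical(s1$table$data, s3$table$data))
})

test_that("empirical shares track the planted probabilities", {
  spec <- simulation_spec(5000, 5000, list(
    sim_variable("a", "binary", prob_d = 0.6, prob_c = 0.2)
  ), seed = 101)
  sim <- simulate_cohort(spec)
  g <- build_aag(sim$table, sim$cohort_spec)
  nd <- g$nodes[g$nodes$attribute_id == "a=yes", ]
  expect_lt(abs(nd$p_d - 0.6), 0.02)
  expect_lt(abs(nd$p_c - 0.2), 0.02)
  expect_identical(nd$distinction_label, "highly_related")   # gamma truth 3.0
  truth <- sim$truth$nodes[sim$truth$nodes$attribute_id == "a=yes", ]
  expect_identical(truth$distinction_label, "highly_related")
  expect_equal(truth$gamma, 3, tolerance = 1e-12)
})

test_that("zero missingness makes total and attribute shares coincide", {
  spec <- simulation_spec(400, 600, list(
    sim_variable("a", "binary", prob_d = 0.5, prob_c = 0.3),
    sim_variable("m", "metric", mean_d = 1, sd_d = 1, mean_c = 0, sd_c = 1)
  ), seed = 7)
  sim <- simulate_cohort(spec)
  g <- build_aag(sim$table, sim$cohort_spec)
  expect_identical(g$nodes$rel_total_d, g$nodes$p_d)
  expect_identical(g$nodes$rel_total_c, g$nodes$p_c)
})

test_that("MCAR missingness leaves p unbiased while shrinking rel_total", {
  spec <- simulation_spec(5000, 5000, list(
    sim_variable("a", "binary", prob_d = 0.6, prob_c = 0.2,
                 missing_d = 0.3, missing_c = 0.3)
  ), seed = 13)
  sim <- simulate_cohort(spec)
  g <- build_aag(sim$table, sim$cohort_spec)
  nd <- g$nodes[g$nodes$attribute_id == "a=yes", ]
  expect_lt(abs(nd$p_d - 0.6), 0.03)
  expect_lt(abs(nd$p_c - 0.2), 0.03)
  expect_lt(abs(nd$rel_total_d - 0.7 * 0.6), 0.03)
  expect_lt(abs(nd$rel_total_c - 0.7 * 0.2), 0.03)
  expect_lte(nd$rel_total_d, nd$p_d)
  expect_lte(nd$rel_total_c, nd$p_c)
})

test_that("planted conditionals hit their expected edge statistics", {
  spec <- simulation_spec(4000, 4000, list(
    sim_variable("s", "binary", prob_d = 0.5, prob_c = 0.5),
    sim_variable("t", "binary", prob_d = 0.5, prob_c = 0.5)
  ), seed = 21)
  spec <- plant_conditional(spec, "s", "t", q_d = 0.75, q_c = 0.75)
  sim <- simulate_cohort(spec)
  g <- build_aag(sim$table, sim$cohort_spec)
  ed <- g$edges[g$edges$source_id == "s=yes" & g$edges$target_id == "t=yes", ]
  expect_lt(abs(ed$q_d - 0.75), 0.03)
  expect_lt(abs(ed$dprime_d - 0.25), 0.03)   # truth: q - p = 0.25, gamma' = 1.5
  tr <- sim$truth$edges
  expect_identical(tr$dprime_d, 0.25)
  expect_identical(tr$gprime_d, 1.5)
  # delta' = 0.25 meets the >= 0.2 rule, so the planted edge is high type
  expect_identical(tr$edge_type, "high_cond_diff")
  # marginal of the target is preserved
  nd <- g$nodes[g$nodes$attribute_id == "t=yes", ]
  expect_lt(abs(nd$p_d - 0.5), 0.03)

  # q = 1: perfect implication, o equals the source count
  spec2 <- simulation_spec(500, 500, list(
    sim_variable("s", "binary", prob_d = 0.4, prob_c = 0.4),
    sim_variable("t", "binary", prob_d = 0.6, prob_c = 0.6)
  ), seed = 22)
  spec2 <- plant_conditional(spec2, "s", "t", q_d = 1, q_c = 1)
  sim2 <- simulate_cohort(spec2)
  g2 <- build_aag(sim2$table, sim2$cohort_spec)
  ed2 <- g2$edges[g2$edges$source_id == "s=yes" & g2$edges$target_id == "t=yes", ]
  c_src_d <- g2$nodes$c_d[g2$nodes$attribute_id == "s=yes"]
  expect_identical(ed2$o_d, c_src_d)
  expect_identical(ed2$q_d, 1)

  # conditional equal to the marginal: independence, low type at large n
  spec3 <- simulation_spec(4000, 4000, list(
    sim_variable("s", "binary", prob_d = 0.5, prob_c = 0.5),
    sim_variable("t", "binary", prob_d = 0.5, prob_c = 0.5)
  ), seed = 23)
  spec3 <- plant_conditional(spec3, "s", "t", q_d = 0.5, q_c = 0.5)
  sim3 <- simulate_cohort(spec3)
  g3 <- build_aag(sim3$table, sim3$cohort_spec)
  ed3 <- g3$edges[g3$edges$source_id == "s=yes" & g3$edges$target_id == "t=yes", ]
  expect_identical(ed3$edge_type, "low_cond_diff")
  expect_identical(sim3$truth$edges$edge_type, "low_cond_diff")
})

test_that("infeasible conditional probabilities raise config errors", {
  spec <- simulation_spec(100, 100, list(
    sim_variable("s", "binary", prob_d = 0.9, prob_c = 0.9),
    sim_variable("t", "binary", prob_d = 0.1, prob_c = 0.1)
  ))
  # s prob 0.9, q 0.5 implies P(t | !s) = (0.1 - 0.45) / 0.1 < 0
  expect_error(plant_conditional(spec, "s", "t", q_d = 0.5, q_c = 0.5),
               class = "aag_config_error")
  expect_error(plant_conditional(spec, "s", "missing_var", 0.5, 0.5),
               class = "aag_config_error")
  expect_error(sim_variable("x", "binary", prob_d = 1.5, prob_c = 0.5),
               class = "aag_config_error")
  expect_error(simulation_spec(0, 10, list()), class = "aag_config_error")
})

test_that("simulated cohorts round-trip through the file interface", {
  spec <- random_sim_spec(31, n_vars = 3)
  sim <- simulate_cohort(spec)
  out <- withr::local_tempdir()
  write_simulated_cohort(sim, out)
  meta <- read_variable_meta(file.path(out, "meta.csv"))
  tab <- load_cohort_table(file.path(out, "data.csv"), meta)
  cspec <- read_cohort_spec(file.path(out, "cohort.json"))
  expect_identical(tab$g_total, sim$table$g_total)
  # categorical columns identical; metric columns equal at CSV precision
  for (v in names(sim$table$data)) {
    kind <- sim$table$meta$data_kind[sim$table$meta$name == v]
    if (kind == "metric") {
      expect_equal(tab$data[[v]], sim$table$data[[v]], tolerance = 1e-10)
    } else {
      expect_identical(tab$data[[v]], sim$table$data[[v]])
    }
  }
  asg <- assign_cohorts(tab, cspec)
  expect_identical(asg$g_d, sim$assignment$g_d)
})

test_that("simulation specs load from YAML", {
  ym <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "g_d: 50", "g_c: 150", "seed: 4",
    "variables:",
    "  - name: a", "    kind: binary", "    prob_d: 0.6", "    prob_c: 0.2",
    "  - name: t", "    kind: binary", "    prob_d: 0.5", "    prob_c: 0.5",
    "conditionals:",
    "  - source: a", "    target: t", "    q_d: 0.7", "    q_c: 0.6"
  ), ym)
  spec <- read_simulation_spec(ym)
  expect_s3_class(spec, "simulation_spec")
  expect_identical(spec$g_d, 50L)
  expect_identical(length(spec$conditionals), 1L)
  sim <- simulate_cohort(spec)
  expect_identical(sim$table$g_total, 200L)
})
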
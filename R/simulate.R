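# Synthetic cohort simulator: group-dependent attribute probabilities,
# group-dependent normal metric variables, MCAR missingness, and planted
# conditional dependencies -- all with analytically known ground truth, so
# every pipeline stage can be tested without external data.

#' Declare a variable for the cohort simulator
#'
#' @param name variable name.
#' @param kind "binary", "categorical" or "metric".
#' @param prob_d,prob_c binary: probability of the "yes" value per group.
#' @param categories,probs_d,probs_c categorical: labels and per-group
#'   probability vectors (each summing to 1).
#' @param mean_d,sd_d,mean_c,sd_c metric: per-group normal parameters.
#' @param missing_d,missing_c per-group MCAR missingness probabilities.
#' @return A list describing the variable, for [simulation_spec()].
#' @export
sim_variable <- function(name, kind = c("binary", "categorical", "metric"),
                         prob_d = NULL, prob_c = NULL,
                         categories = NULL, probs_d = NULL, probs_c = NULL,
                         mean_d = NULL, sd_d = NULL, mean_c = NULL, sd_c = NULL,
                         missing_d = 0, missing_c = 0) {
  kind <- match.arg(kind)
  chk_prob <- function(p, what) {
    if (is.null(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
      aag_stop(sprintf("variable '%s': invalid %s", name, what), "aag_config_error")
    }
  }
  if (kind == "binary") {
    chk_prob(prob_d, "prob_d"); chk_prob(prob_c, "prob_c")
    categories <- c("yes", "no")
    probs_d <- c(prob_d, 1 - prob_d)
    probs_c <- c(prob_c, 1 - prob_c)
  } else if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2L) {
      aag_stop(sprintf("variable '%s': need >= 2 categories", name), "aag_config_error")
    }
    chk_prob(probs_d, "probs_d"); chk_prob(probs_c, "probs_c")
    if (abs(sum(probs_d) - 1) > 1e-8 || abs(sum(probs_c) - 1) > 1e-8) {
      aag_stop(sprintf("variable '%s': category probabilities must sum to 1", name),
               "aag_config_error")
    }
  } else {
    if (is.null(mean_d) || is.null(sd_d) || is.null(mean_c) || is.null(sd_c) ||
        sd_d < 0 || sd_c < 0) {
      aag_stop(sprintf("variable '%s': metric needs mean/sd per group (sd >= 0)", name),
               "aag_config_error")
    }
  }
  chk_prob(missing_d, "missing_d"); chk_prob(missing_c, "missing_c")
  list(name = name, kind = kind, categories = categories,
       probs_d = probs_d, probs_c = probs_c,
       mean_d = mean_d, sd_d = sd_d, mean_c = mean_c, sd_c = sd_c,
       missing_d = missing_d, missing_c = missing_c)
}

#' Construct a simulation specification
#'
#' @param g_d,g_c disease and control group sizes.
#' @param variables list of [sim_variable()] entries (unique names).
#' @param seed integer seed making [simulate_cohort()] deterministic.
#' @param disease_name,control_name group display names.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(g_d, g_c, variables, seed = 1L,
                            disease_name = "disease", control_name = "control") {
  if (!is_count(g_d) || !is_count(g_c) || g_d < 1 || g_c < 1) {
    aag_stop("g_d and g_c must be positive integers", "aag_config_error")
  }
  nms <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    aag_stop("variable names must be unique", "aag_config_error")
  }
  if ("group" %in% nms) {
    aag_stop("'group' is reserved for the cohort indicator", "aag_config_error")
  }
  structure(list(g_d = as.integer(g_d), g_c = as.integer(g_c),
                 variables = variables, conditionals = list(),
                 seed = as.integer(seed),
                 disease_name = disease_name, control_name = control_name),
            class = "simulation_spec")
}

#' Plant a conditional dependency between two binary variables
#'
#' The target is regenerated conditional on the source so that, per group,
#' `P(target = yes | source = yes) = q` while the target's marginal
#' probability stays at its declared value. The implied probability
#' `P(target = yes | source = no) = (t - s q) / (1 - s)` must lie in [0, 1]
#' (`s`, `t` the source/target marginals), otherwise the combination is
#' infeasible and a config error is raised. Expected edge statistics follow
#' in closed form: `delta' = q - t`, `gamma' = q / t`.
#'
#' @param spec a `simulation_spec`.
#' @param source_var,target_var names of binary variables in `spec`.
#' @param q_d,q_c target conditional probabilities per group.
#' @return The updated `simulation_spec`.
#' @export
plant_conditional <- function(spec, source_var, target_var, q_d, q_c) {
  stopifnot(inherits(spec, "simulation_spec"))
  nms <- vapply(spec$variables, `[[`, "", "name")
  for (v in c(source_var, target_var)) {
    i <- match(v, nms)
    if (is.na(i) || spec$variables[[i]]$kind != "binary") {
      aag_stop(sprintf("'%s' must be a binary variable in the spec", v),
               "aag_config_error")
    }
  }
  if (any(vapply(spec$conditionals, function(cd) cd$target == target_var, TRUE))) {
    aag_stop(sprintf("'%s' is already the target of a conditional", target_var),
             "aag_config_error")
  }
  src <- spec$variables[[match(source_var, nms)]]
  tgt <- spec$variables[[match(target_var, nms)]]
  for (g in c("d", "c")) {
    s <- src[[paste0("probs_", g)]][1]
    t <- tgt[[paste0("probs_", g)]][1]
    q <- if (g == "d") q_d else q_c
    if (q < 0 || q > 1) {
      aag_stop("conditional probabilities must lie in [0, 1]", "aag_config_error")
    }
    p0 <- (t - s * q) / (1 - s)
    if (is.na(p0) || p0 < -1e-12 || p0 > 1 + 1e-12) {
      aag_stop(sprintf(
        "infeasible conditional for group %s: P(target|no source) = %.4f outside [0, 1]",
        g, p0), "aag_config_error")
    }
  }
  spec$conditionals <- c(spec$conditionals,
                         list(list(source = source_var, target = target_var,
                                   q_d = q_d, q_c = q_c)))
  spec
}

sim_draw_cat <- function(n, categories, probs) {
  if (n == 0L) return(character(0))
  categories[sample.int(length(categories), n, replace = TRUE, prob = probs)]
}

#' Simulate a cohort table with known ground truth
#'
#' Generates `g_d + g_c` participants: a dedicated `group` indicator
#' variable (referenced by the emitted cohort spec), per-group categorical
#' draws, per-group normal metric values, planted conditional targets, and
#' finally MCAR missingness. Deterministic for a fixed seed.
#'
#' @param spec a `simulation_spec`.
#' @param seed overrides `spec$seed` when given.
#' @return A list of class `simulated_cohort`:
#'   * `table`: a `cohort_table` (including the `group` column),
#'   * `cohort_spec`: a `cohort_spec` selecting `group == disease`,
#'   * `truth`: list with `nodes` (expected p_d, p_c, delta, gamma,
#'     frequency and distinction labels per attribute at infinite n) and
#'     `edges` (expected q, delta', gamma' and type for planted
#'     conditionals),
#'   * `assignment`: the true group assignment.
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  n <- spec$g_d + spec$g_c
  grp <- rep(c("disease", "control"), c(spec$g_d, spec$g_c))
  is_d <- grp == "disease"
  data <- list(group = grp)
  nms <- vapply(spec$variables, `[[`, "", "name")
  cond_targets <- vapply(spec$conditionals, `[[`, "", "target")
  # independent variables first, conditional targets afterwards
  for (v in spec$variables) {
    if (v$name %in% cond_targets) next
    data[[v$name]] <- if (v$kind == "metric") {
      x <- numeric(n)
      x[is_d] <- stats::rnorm(spec$g_d, v$mean_d, v$sd_d)
      x[!is_d] <- stats::rnorm(spec$g_c, v$mean_c, v$sd_c)
      x
    } else {
      x <- character(n)
      x[is_d] <- sim_draw_cat(spec$g_d, v$categories, v$probs_d)
      x[!is_d] <- sim_draw_cat(spec$g_c, v$categories, v$probs_c)
      x
    }
  }
  for (cd in spec$conditionals) {
    tgt <- spec$variables[[match(cd$target, nms)]]
    src_yes <- data[[cd$source]] == "yes"
    x <- character(n)
    for (g in c("disease", "control")) {
      gi <- grp == g
      s <- spec$variables[[match(cd$source, nms)]][[
        if (g == "disease") "probs_d" else "probs_c"]][1]
      t <- tgt[[if (g == "disease") "probs_d" else "probs_c"]][1]
      q <- if (g == "disease") cd$q_d else cd$q_c
      p0 <- min(max((t - s * q) / (1 - s), 0), 1)
      p <- ifelse(src_yes[gi], q, p0)
      x[gi] <- ifelse(stats::runif(sum(gi)) < p, "yes", "no")
    }
    data[[cd$target]] <- x
  }
  # MCAR missingness after value generation
  for (v in spec$variables) {
    if (v$missing_d > 0 || v$missing_c > 0) {
      miss <- stats::runif(n) < ifelse(is_d, v$missing_d, v$missing_c)
      data[[v$name]][miss] <- NA
    }
  }
  meta <- variable_meta(
    name = c("group", nms),
    data_kind = c("categorical",
                  vapply(spec$variables, `[[`, "", "kind")),
    description = c("simulated cohort indicator",
                    sprintf("simulated %s variable",
                            vapply(spec$variables, `[[`, "", "kind"))),
    categories = c(list(c("disease", "control")),
                   lapply(spec$variables, function(v) v$categories %||% character(0)))
  )
  df <- as.data.frame(data, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- sprintf("P%06d", seq_len(n))
  table <- cohort_table_from_df(df, meta, ids)
  cspec <- cohort_spec(
    list(list(variable = "group", comparator = "equals", value = "disease")),
    disease_name = spec$disease_name, control_name = spec$control_name)
  structure(
    list(table = table, cohort_spec = cspec,
         truth = simulation_truth(spec),
         assignment = assign_cohorts(table, cspec)),
    class = "simulated_cohort"
  )
}

# Closed-form expectations for planted attributes and conditionals.
simulation_truth <- function(spec, config = aag_config()) {
  node_rows <- list()
  for (v in spec$variables) {
    if (v$kind == "metric") next
    for (k in seq_along(v$categories)) {
      p_d <- v$probs_d[k]; p_c <- v$probs_c[k]
      cmp <- compare_shares(p_d, p_c, config)
      node_rows[[length(node_rows) + 1L]] <- data.frame(
        attribute_id = paste(v$name, v$categories[k], sep = "="),
        p_d = p_d, p_c = p_c, delta = cmp$delta, gamma = cmp$gamma,
        frequency_label = assign_frequency_label(max(p_d, p_c), config),
        distinction_label = cmp$distinction_label,
        stringsAsFactors = FALSE)
    }
  }
  nms <- vapply(spec$variables, `[[`, "", "name")
  edge_rows <- lapply(spec$conditionals, function(cd) {
    tgt <- spec$variables[[match(cd$target, nms)]]
    t_d <- tgt$probs_d[1]; t_c <- tgt$probs_c[1]
    data.frame(
      source_id = paste0(cd$source, "=yes"),
      target_id = paste0(cd$target, "=yes"),
      q_d = cd$q_d, q_c = cd$q_c,
      dprime_d = cd$q_d - t_d, dprime_c = cd$q_c - t_c,
      gprime_d = cd$q_d / t_d, gprime_c = cd$q_c / t_c,
      edge_type = assign_edge_type(cd$q_d - t_d, cd$q_c - t_c,
                                   cd$q_d / t_d, cd$q_c / t_c, config),
      stringsAsFactors = FALSE)
  })
  list(
    nodes = if (length(node_rows)) do.call(rbind, node_rows) else NULL,
    edges = if (length(edge_rows)) do.call(rbind, edge_rows) else NULL
  )
}

#' Read a simulation spec from YAML/JSON
#'
#' Expected fields: `g_d`, `g_c`, `seed`, `variables` (sequence of
#' [sim_variable()] field mappings) and optional `conditionals` (sequence of
#' `{source, target, q_d, q_c}`).
#'
#' @param path file path.
#' @return A `simulation_spec`.
#' @export
read_simulation_spec <- function(path) {
  x <- read_structured(path)
  vars <- lapply(x$variables, function(v) do.call(sim_variable, v))
  spec <- simulation_spec(x$g_d, x$g_c, vars, seed = x$seed %||% 1L,
                          disease_name = x$disease_name %||% "disease",
                          control_name = x$control_name %||% "control")
  for (cd in x$conditionals %||% list()) {
    spec <- plant_conditional(spec, cd$source, cd$target, cd$q_d, cd$q_c)
  }
  spec
}

#' Write a simulated cohort to disk
#'
#' Emits `data.csv` (participant table with explicit empty missing cells),
#' `meta.csv`, `cohort.json` (the any-of cohort spec) and `truth.json`.
#'
#' @param sim a `simulated_cohort`.
#' @param out_dir output directory.
#' @return Paths written, invisibly.
#' @export
write_simulated_cohort <- function(sim, out_dir) {
  stopifnot(inherits(sim, "simulated_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_path <- file.path(out_dir, "data.csv")
  df <- cbind(participant_id = sim$table$participant_ids, sim$table$data)
  write.csv(df, data_path, row.names = FALSE, na = "")
  meta_path <- file.path(out_dir, "meta.csv")
  m <- sim$table$meta
  meta_df <- data.frame(
    name = m$name, data_kind = m$data_kind, description = m$description,
    categories = vapply(m$categories, collapse_pipe, ""),
    broad_labels = vapply(m$broad_labels, collapse_pipe, ""),
    vocab_code = m$vocab_code, stringsAsFactors = FALSE)
  write.csv(meta_df, meta_path, row.names = FALSE, na = "")
  spec_path <- file.path(out_dir, "cohort.json")
  jsonlite::write_json(unclass(sim$cohort_spec), spec_path, auto_unbox = TRUE,
                       pretty = TRUE)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(data_path, meta_path, spec_path, truth_path))
}
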
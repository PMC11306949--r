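# Dashboard preparation: binned distributions per group, bin summarization,
# normalized per-variable group averages, conditional bin averages.

.bin_widths <- c(0.1, 0.5, 1, 5, 10, 50)

#' Choose a histogram bin width from the group standard deviation
#'
#' Values are rounded to multiples of 0.1, 0.5, 1, 5, 10 or 50 depending on
#' the SD within the group. The mapping used here -- the largest admissible
#' width not exceeding SD/3, floored at 0.1 -- targets roughly six or more
#' bins across +/- 1 SD; the AAG method fixes the admissible widths but
#' not the mapping, so the mapping is a package choice.
#'
#' @param sd non-negative standard deviation; vectorized.
#' @return Bin width, one of 0.1, 0.5, 1, 5, 10, 50.
#' @examples
#' bin_width_for(30)  # 10
#' bin_width_for(2)   # 0.5
#' @export
bin_width_for <- function(sd) {
  if (any(is.na(sd)) || any(sd < 0)) {
    aag_stop("sd must be non-negative", "aag_contract_error")
  }
  vapply(sd, function(s) {
    ok <- .bin_widths[.bin_widths <= s / 3]
    if (length(ok)) max(ok) else 0.1
  }, 0)
}

# Round to the nearest multiple of `w`, halves away from zero; returns the
# integer multiple so bin identity is exact in floating point.
round_to_multiple <- function(x, w) {
  sign(x) * floor(abs(x) / w + 0.5)
}

#' Bin a metric variable's values for the dashboard
#'
#' Values are rounded to the nearest multiple of the bin width (halves away
#' from zero). Bins holding fewer than 3 participants or less than 0.5% of
#' the group are summarized: their counts are merged into the nearest
#' retained bin on the side toward the distribution center, and the total
#' number of merged participants is recorded. A distribution with no
#' retained bin at all is flagged as removed.
#'
#' @param values numeric vector (one group's values), `NA` allowed.
#' @param bin_width bin width; computed via [bin_width_for()] from the
#'   sample SD when `NULL`.
#' @param variable,group identification strings stored on the result.
#' @return A list of class `binned_distribution` with `variable`, `group`,
#'   `bin_width`, `bins` (data.frame `value`, `count`, ordered by value),
#'   `summarized_count`, `removed` and `n_valid`.
#' @export
binned_distribution <- function(values, bin_width = NULL,
                                variable = "", group = "all") {
  v <- values[!is.na(values)]
  n <- length(v)
  if (is.null(bin_width)) {
    s <- if (n >= 2L) stats::sd(v) else 0
    bin_width <- bin_width_for(s)
  }
  out <- list(variable = variable, group = group, bin_width = bin_width,
              bins = data.frame(value = numeric(0), count = integer(0)),
              summarized_count = 0L, removed = FALSE, n_valid = n)
  class(out) <- "binned_distribution"
  if (n == 0L) {
    out$removed <- TRUE
    return(out)
  }
  mult <- round_to_multiple(v, bin_width)
  tab <- table(mult)
  idx <- as.numeric(names(tab))
  cnt <- as.integer(tab)
  keep <- cnt >= 3L & cnt / n >= 0.005
  if (!any(keep)) {
    out$removed <- TRUE
    out$summarized_count <- n
    return(out)
  }
  center <- sum(idx * cnt) / n
  kept_idx <- idx[keep]
  kept_cnt <- cnt[keep]
  merged <- 0L
  for (j in which(!keep)) {
    b <- idx[j]
    dist <- abs(kept_idx - b)
    cand <- which(dist == min(dist))
    if (length(cand) > 1L) {
      # tie: prefer the retained bin closer to the distribution center
      cand <- cand[which.min(abs(kept_idx[cand] - center))]
    }
    kept_cnt[cand] <- kept_cnt[cand] + cnt[j]
    merged <- merged + cnt[j]
  }
  ord <- order(kept_idx)
  out$bins <- data.frame(value = kept_idx[ord] * bin_width,
                         count = kept_cnt[ord])
  out$summarized_count <- merged
  out
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf("<binned_distribution> %s [%s]: width %g, %d bin(s), n=%d, %d summarized%s\n",
              x$variable, x$group, x$bin_width, nrow(x$bins), x$n_valid,
              x$summarized_count, if (x$removed) " (removed)" else ""))
  invisible(x)
}

group_values <- function(table, assignment, variable, group) {
  col <- table$data[[variable]]
  if (group == "all") return(col)
  col[assignment$membership[table$participant_ids] == group]
}

#' Normalized per-variable group averages
#'
#' For every metric variable the mean is computed in the disease group, the
#' control group, and over all participants (missing values excluded); the
#' three means are then divided by their maximum so that the largest maps
#' to 1 and groups become comparable within one figure.
#'
#' @param table a `cohort_table`.
#' @param assignment a `cohort_assignment`.
#' @return data.frame with columns `variable`, `mean_disease`,
#'   `mean_control`, `mean_all`, `norm_disease`, `norm_control`, `norm_all`.
#' @export
normalized_group_averages <- function(table, assignment) {
  metric <- table$meta$name[table$meta$data_kind == "metric"]
  rows <- lapply(metric, function(v) {
    m <- vapply(c("disease", "control", "all"), function(g) {
      x <- group_values(table, assignment, v, g)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, 0)
    mx <- suppressWarnings(max(m, na.rm = TRUE))
    norm <- if (is.finite(mx) && mx != 0) m / mx else rep(NA_real_, 3)
    data.frame(variable = v, mean_disease = m[1], mean_control = m[2],
               mean_all = m[3], norm_disease = norm[1], norm_control = norm[2],
               norm_all = norm[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conditional bin averages for a pair of metric variables
#'
#' Participants of the chosen group with both values present are binned by
#' the first variable (per [binned_distribution()] rules); within each
#' retained bin the arithmetic mean of the second variable is reported.
#' This powers the dashboard's "average of y per rounded x" figure.
#'
#' @param table a `cohort_table`.
#' @param assignment a `cohort_assignment`.
#' @param v1 binning variable (x-axis), metric.
#' @param v2 averaged variable (y-axis), metric.
#' @param group one of "disease", "control", "all".
#' @return data.frame with columns `bin_value`, `n` and `mean_v2`, ordered
#'   by bin value.
#' @export
conditional_bin_averages <- function(table, assignment, v1, v2,
                                     group = c("all", "disease", "control")) {
  group <- match.arg(group)
  for (v in c(v1, v2)) {
    if (!identical(table$meta$data_kind[table$meta$name == v], "metric")) {
      aag_stop(sprintf("'%s' must be a metric variable", v), "aag_contract_error")
    }
  }
  x <- group_values(table, assignment, v1, group)
  y <- group_values(table, assignment, v2, group)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  bd <- binned_distribution(x, variable = v1, group = group)
  if (bd$removed || nrow(bd$bins) == 0L) {
    return(data.frame(bin_value = numeric(0), n = integer(0), mean_v2 = numeric(0)))
  }
  mult <- round_to_multiple(x, bd$bin_width)
  retained <- round(bd$bins$value / bd$bin_width)
  keep <- mult %in% retained
  mult <- mult[keep]; y <- y[keep]
  agg <- tapply(y, mult, mean)
  nper <- tapply(y, mult, length)
  vals <- as.numeric(names(agg)) * bd$bin_width
  ord <- order(vals)
  data.frame(bin_value = vals[ord], n = as.integer(nper[ord]),
             mean_v2 = as.numeric(agg[ord]))
}

#' Assemble all dashboard artifacts
#'
#' Computes binned distributions per metric variable for the disease,
#' control and all-participants groups, the normalized group averages, and
#' (optionally) conditional bin average series for given variable pairs.
#'
#' @param table a `cohort_table`.
#' @param assignment a `cohort_assignment`.
#' @param pairs optional list of `c(v1, v2)` pairs for conditional series.
#' @return A list of class `aag_dashboard` with `group_sizes`,
#'   `distributions`, `averages`, `conditional`.
#' @export
dashboard_data <- function(table, assignment, pairs = list()) {
  metric <- table$meta$name[table$meta$data_kind == "metric"]
  dists <- list()
  for (v in metric) {
    for (g in c("disease", "control", "all")) {
      bd <- binned_distribution(group_values(table, assignment, v, g),
                                variable = v, group = g)
      if (!bd$removed) dists[[paste(v, g, sep = "|")]] <- bd
    }
  }
  cond <- lapply(pairs, function(p) {
    list(v1 = p[[1]], v2 = p[[2]],
         series = lapply(stats::setNames(nm = c("disease", "control", "all")),
                         function(g) conditional_bin_averages(table, assignment,
                                                              p[[1]], p[[2]], g)))
  })
  structure(
    list(group_sizes = list(disease = assignment$g_d, control = assignment$g_c,
                            all = assignment$g_d + assignment$g_c),
         distributions = dists,
         averages = normalized_group_averages(table, assignment),
         conditional = cond),
    class = "aag_dashboard"
  )
}

#' Write dashboard artifacts as JSON (plus CSV mirrors)
#'
#' @param dash an `aag_dashboard` from [dashboard_data()].
#' @param out_dir output directory.
#' @return Paths written, invisibly.
#' @export
write_dashboard <- function(dash, out_dir) {
  stopifnot(inherits(dash, "aag_dashboard"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(out_dir, "dashboard.json")
  ser <- list(
    group_sizes = dash$group_sizes,
    distributions = lapply(dash$distributions, function(b) {
      list(variable = b$variable, group = b$group, bin_width = b$bin_width,
           bins = b$bins, summarized_count = b$summarized_count,
           n_valid = b$n_valid)
    }),
    averages = dash$averages,
    conditional = dash$conditional
  )
  jsonlite::write_json(ser, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  avg_path <- file.path(out_dir, "averages.csv")
  write.csv(dash$averages, avg_path, row.names = FALSE)
  dist_path <- file.path(out_dir, "distributions.csv")
  dist_df <- do.call(rbind, lapply(dash$distributions, function(b) {
    if (nrow(b$bins) == 0L) return(NULL)
    data.frame(variable = b$variable, group = b$group, bin_width = b$bin_width,
               bin_value = b$bins$value, count = b$bins$count,
               stringsAsFactors = FALSE)
  }))
  if (is.null(dist_df)) {
    dist_df <- data.frame(variable = character(0), group = character(0),
                          bin_width = numeric(0), bin_value = numeric(0),
                          count = integer(0))
  }
  write.csv(dist_df, dist_path, row.names = FALSE)
  invisible(c(json_path, avg_path, dist_path))
}
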
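# Attribute derivation: reference ranges, low/normal/high bands, categorical
# expansion, and the participant x attribute incidence matrix.

#' Compute a data-driven reference range
#'
#' The reference range of a metric variable is the interval mean +/- SD of
#' all non-missing values in the whole data set (both groups pooled). The
#' sample standard deviation (n-1 denominator) is used.
#'
#' @param values numeric vector, possibly with `NA`.
#' @param variable variable name recorded on the result.
#' @return A list of class `reference_range` with `variable`, `lower`,
#'   `upper` and `source = "computed"`.
#' @examples
#' compute_reference_range(c(1, 2, 3, 4, 5))  # 3 +/- 1.5811
#' @export
compute_reference_range <- function(values, variable = "") {
  v <- values[!is.na(values)]
  if (length(v) < 2L) {
    aag_stop(sprintf("variable '%s': need >= 2 non-missing values for a reference range",
                     variable), "aag_range_error")
  }
  m <- mean(v)
  s <- stats::sd(v)
  structure(list(variable = variable, lower = m - s, upper = m + s,
                 source = "computed"),
            class = "reference_range")
}

#' Compute reference ranges for all metric variables of a table
#'
#' Variables with fewer than 2 non-missing values are skipped with a warning.
#'
#' @param table a `cohort_table`.
#' @return Named list of `reference_range` objects (metric variables only).
#' @export
reference_ranges <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  metric <- table$meta$name[table$meta$data_kind == "metric"]
  out <- list()
  for (v in metric) {
    rr <- tryCatch(compute_reference_range(table$data[[v]], v),
                   aag_range_error = function(e) {
                     warning(conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (!is.null(rr)) out[[v]] <- rr
  }
  out
}

#' Apply manual reference-range overrides
#'
#' Data-driven ranges can deviate from clinical reference intervals when the
#' cohort itself is unusual; overrides substitute literature values (e.g.
#' from a diagnosis manual) for selected variables.
#'
#' @param ranges named list of `reference_range` objects.
#' @param overrides named list (or data.frame with columns `variable`,
#'   `lower`, `upper`) mapping variable to `c(lower, upper)`.
#' @return The updated list; overridden entries have `source =
#'   "manual_override"`.
#' @export
apply_overrides <- function(ranges, overrides) {
  if (is.data.frame(overrides)) {
    overrides <- stats::setNames(
      lapply(seq_len(nrow(overrides)),
             function(i) c(overrides$lower[i], overrides$upper[i])),
      overrides$variable)
  }
  if (length(overrides) == 0L) return(ranges)
  for (v in names(overrides)) {
    if (!v %in% names(ranges)) {
      aag_stop(sprintf("override for unknown variable '%s'", v), "aag_config_error")
    }
    b <- as.numeric(overrides[[v]])
    if (length(b) != 2L || anyNA(b) || !all(is.finite(b))) {
      aag_stop(sprintf("override for '%s' must be two finite numbers", v),
               "aag_config_error")
    }
    if (b[1L] > b[2L]) {
      aag_stop(sprintf("override for '%s': lower (%g) > upper (%g)", v, b[1L], b[2L]),
               "aag_config_error")
    }
    ranges[[v]] <- structure(list(variable = v, lower = b[1L], upper = b[2L],
                                  source = "manual_override"),
                             class = "reference_range")
  }
  ranges
}

#' Read a reference-range override file
#'
#' CSV with columns `variable`, `lower`, `upper`, or YAML mapping
#' variable to `[lower, upper]` (or `{lower:, upper:}`).
#'
#' @param path file path.
#' @return Named list mapping variable to `c(lower, upper)`.
#' @export
read_overrides <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    stats::setNames(lapply(seq_len(nrow(df)), function(i) c(df$lower[i], df$upper[i])),
                    df$variable)
  } else {
    x <- read_structured(path)
    lapply(x, function(e) {
      if (is.list(e)) c(e$lower, e$upper) else as.numeric(e)
    })
  }
}

#' Derive binary attributes and the incidence matrix
#'
#' Metric variables yield three attributes: `low` (value strictly below the
#' reference range), `normal` (inside the closed interval), `high` (strictly
#' above). Categorical and binary variables yield one attribute per category
#' value. Each participant is a member of exactly one attribute per variable,
#' a non-member of that variable's other attributes, and missing in all of
#' them when the underlying value is missing.
#'
#' @param table a `cohort_table`.
#' @param ranges named list of `reference_range`s covering every metric
#'   variable (see [reference_ranges()], [apply_overrides()]).
#' @return A list of class `aag_attributes` with:
#'   * `attributes`: data.frame (attribute_id, variable, value, description,
#'     ref_lower, ref_upper, plus list-column broad_labels),
#'   * `status`: integer matrix participants x attributes with entries
#'     1 (member), 0 (non-member), `NA` (missing).
#' @export
derive_attributes <- function(table, ranges) {
  stopifnot(inherits(table, "cohort_table"))
  meta <- table$meta
  defs <- list()
  cols <- list()
  for (j in seq_len(nrow(meta))) {
    v <- meta$name[j]
    kind <- meta$data_kind[j]
    desc <- meta$description[j]
    blab <- meta$broad_labels[[j]]
    col <- table$data[[v]]
    if (kind == "metric") {
      rr <- ranges[[v]]
      if (is.null(rr)) {
        aag_stop(sprintf("metric variable '%s' has no reference range", v),
                 "aag_range_error")
      }
      band <- ifelse(is.na(col), NA_character_,
                     ifelse(col < rr$lower, "low",
                            ifelse(col > rr$upper, "high", "normal")))
      for (val in c("low", "normal", "high")) {
        id <- paste(v, val, sep = "=")
        defs[[id]] <- list(attribute_id = id, variable = v, value = val,
                           description = desc, ref_lower = rr$lower,
                           ref_upper = rr$upper, broad_labels = blab)
        cols[[id]] <- ifelse(is.na(band), NA_integer_, as.integer(band == val))
      }
    } else {
      cats <- meta$categories[[j]]
      if (!length(cats)) cats <- sort(unique(col[!is.na(col)]))
      for (val in cats) {
        id <- paste(v, val, sep = "=")
        defs[[id]] <- list(attribute_id = id, variable = v, value = val,
                           description = desc, ref_lower = NA_real_,
                           ref_upper = NA_real_, broad_labels = blab)
        cols[[id]] <- ifelse(is.na(col), NA_integer_, as.integer(col == val))
      }
    }
  }
  status <- do.call(cbind, cols)
  rownames(status) <- table$participant_ids
  attributes_df <- data.frame(
    attribute_id = vapply(defs, `[[`, "", "attribute_id"),
    variable = vapply(defs, `[[`, "", "variable"),
    value = vapply(defs, `[[`, "", "value"),
    description = vapply(defs, `[[`, "", "description"),
    ref_lower = vapply(defs, `[[`, 0, "ref_lower"),
    ref_upper = vapply(defs, `[[`, 0, "ref_upper"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attributes_df$broad_labels <- lapply(defs, `[[`, "broad_labels")
  structure(list(attributes = attributes_df, status = status),
            class = "aag_attributes")
}

#' @export
print.aag_attributes <- function(x, ...) {
  cat(sprintf("<aag_attributes> %d attributes from %d variables, %d participants\n",
              nrow(x$attributes), length(unique(x$attributes$variable)),
              nrow(x$status)))
  invisible(x)
}

#' Export the attribute catalogue as CSV
#'
#' @param attrs an `aag_attributes` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_attribute_catalogue <- function(attrs, path) {
  df <- attrs$attributes
  df$broad_labels <- vapply(df$broad_labels, collapse_pipe, "")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
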
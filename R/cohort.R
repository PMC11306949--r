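# Cohort model: variable metadata, cohort table loading, disease/control split.

#' Construct a variable metadata set
#'
#' Metadata describe every column of the cohort table: what kind of data it
#' holds (`metric`, `binary` or `categorical`), a human-readable description
#' including units, broad category tags used as extra node labels (e.g.
#' "Laboratory", "Medical History"), and an optional clinical terminology code
#' (SNOMED CT or LOINC).
#'
#' @param name character vector of unique variable identifiers.
#' @param data_kind character vector, each one of "metric", "binary",
#'   "categorical".
#' @param description free-text descriptions (include units for metric
#'   variables); recycled if length 1.
#' @param categories list of character vectors giving the admissible category
#'   labels; required (non-empty) for categorical variables, optional for
#'   binary ones (observed values are used when absent).
#' @param broad_labels list of character vectors of broad group tags.
#' @param vocab_code optional character vector of terminology codes.
#' @return A data.frame of class `aag_meta` with list-columns `categories`
#'   and `broad_labels`.
#' @examples
#' variable_meta(
#'   name = c("chol", "smoker"),
#'   data_kind = c("metric", "binary"),
#'   description = c("Total cholesterol (mg/dL)", "Current smoker"),
#'   categories = list(character(0), c("yes", "no")),
#'   broad_labels = list("Laboratory", "Lifestyle")
#' )
#' @export
variable_meta <- function(name, data_kind,
                          description = name,
                          categories = vector("list", length(name)),
                          broad_labels = vector("list", length(name)),
                          vocab_code = rep(NA_character_, length(name))) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    aag_stop(sprintf("duplicate variable name(s): %s",
                     paste(unique(name[duplicated(name)]), collapse = ", ")),
             "aag_meta_error")
  }
  data_kind <- match.arg(as.character(data_kind),
                         c("metric", "binary", "categorical"),
                         several.ok = TRUE)
  if (length(data_kind) != length(name)) {
    aag_stop("`name` and `data_kind` must have the same length", "aag_meta_error")
  }
  description <- rep_len(as.character(description), length(name))
  vocab_code <- rep_len(as.character(vocab_code), length(name))
  categories <- lapply(categories, as.character)
  broad_labels <- lapply(broad_labels, as.character)
  bad <- data_kind == "categorical" & lengths(categories) == 0L
  if (any(bad)) {
    aag_stop(sprintf("categorical variable(s) without categories: %s",
                     paste(name[bad], collapse = ", ")), "aag_meta_error")
  }
  bad <- data_kind != "categorical" & data_kind != "binary" & lengths(categories) > 0L
  if (any(bad)) {
    aag_stop(sprintf("metric variable(s) must not declare categories: %s",
                     paste(name[bad], collapse = ", ")), "aag_meta_error")
  }
  out <- data.frame(name = name, data_kind = data_kind,
                    description = description, vocab_code = vocab_code,
                    stringsAsFactors = FALSE)
  out$categories <- categories
  out$broad_labels <- broad_labels
  class(out) <- c("aag_meta", "data.frame")
  out
}

#' Read variable metadata from CSV or YAML
#'
#' CSV files need columns `name` and `data_kind`; optional columns
#' `description`, `categories`, `broad_labels` (both pipe-separated within a
#' cell) and `vocab_code`. YAML files hold a list of per-variable mappings
#' with the same field names (`categories`/`broad_labels` as sequences).
#'
#' @param path path to a `.csv`, `.tsv`, `.yaml`/`.yml` or `.json` file.
#' @return An `aag_meta` data.frame (see [variable_meta()]).
#' @export
read_variable_meta <- function(path) {
  if (!file.exists(path)) {
    aag_stop(sprintf("metadata file not found: %s", path), "aag_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) {
    df <- data.table::fread(path, sep = if (ext == "tsv") "\t" else ",",
                            colClasses = "character", data.table = FALSE,
                            na.strings = NULL)
    need <- setdiff(c("name", "data_kind"), names(df))
    if (length(need)) {
      aag_stop(sprintf("metadata file lacks column(s): %s", paste(need, collapse = ", ")),
               "aag_meta_error")
    }
    variable_meta(
      name = df$name,
      data_kind = df$data_kind,
      description = if ("description" %in% names(df)) df$description else df$name,
      categories = if ("categories" %in% names(df)) lapply(df$categories, split_pipe)
                   else vector("list", nrow(df)),
      broad_labels = if ("broad_labels" %in% names(df)) lapply(df$broad_labels, split_pipe)
                     else vector("list", nrow(df)),
      vocab_code = if ("vocab_code" %in% names(df)) df$vocab_code
                   else rep(NA_character_, nrow(df))
    )
  } else {
    entries <- read_structured(path)
    variable_meta(
      name = vapply(entries, `[[`, "", "name"),
      data_kind = vapply(entries, `[[`, "", "data_kind"),
      description = vapply(entries, function(e) e$description %||% e$name, ""),
      categories = lapply(entries, function(e) as.character(e$categories %||% character(0))),
      broad_labels = lapply(entries, function(e) as.character(e$broad_labels %||% character(0))),
      vocab_code = vapply(entries, function(e) as.character(e$vocab_code %||% NA_character_), "")
    )
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a participant-by-variable cohort table
#'
#' Reads a delimited text file with one row per participant, types every
#' column according to its metadata entry, and normalises missing cells.
#' Cells matching a missing marker become `NA`; cells in metric columns that
#' fail numeric parsing are also treated as missing and counted in the
#' returned warning tally.
#'
#' @param data_path path to a CSV/TSV file with a header row; a participant
#'   identifier column (`id_col`) must be present.
#' @param meta an `aag_meta` set covering every non-id column.
#' @param missing_markers character vector of strings encoding missingness.
#' @param id_col name of the identifier column (default "participant_id").
#' @param sep field separator; `NULL` (default) picks by extension.
#' @return A list of class `cohort_table` with elements `data` (typed
#'   data.frame), `participant_ids`, `meta`, `g_total` and `parse_warnings`
#'   (named count of coerced-to-missing cells per metric column).
#' @export
load_cohort_table <- function(data_path, meta,
                              missing_markers = c("", "NA", "NaN"),
                              id_col = "participant_id",
                              sep = NULL) {
  stopifnot(inherits(meta, "aag_meta"))
  if (!file.exists(data_path)) {
    aag_stop(sprintf("data file not found: %s", data_path), "aag_io_error")
  }
  if (is.null(sep)) {
    sep <- if (tolower(tools::file_ext(data_path)) == "tsv") "\t" else ","
  }
  raw <- data.table::fread(data_path, sep = sep, colClasses = "character",
                           data.table = FALSE, na.strings = NULL)
  if (!id_col %in% names(raw)) {
    aag_stop(sprintf("identifier column '%s' not found", id_col), "aag_load_error")
  }
  ids <- raw[[id_col]]
  if (anyDuplicated(ids)) {
    aag_stop(sprintf("duplicate participant id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "aag_load_error")
  }
  vars <- setdiff(names(raw), id_col)
  unknown <- setdiff(vars, meta$name)
  if (length(unknown)) {
    aag_stop(sprintf("column(s) without metadata: %s", paste(unknown, collapse = ", ")),
             "aag_load_error")
  }
  cohort_table_from_df(raw[vars], meta, ids, missing_markers = missing_markers)
}

#' Build a cohort table from an in-memory data.frame
#'
#' Programmatic counterpart of [load_cohort_table()]; used by the simulator
#' and by tests. Columns may already be typed; character columns are coerced
#' per metadata.
#'
#' @param df data.frame of participant values (no id column).
#' @param meta an `aag_meta` set.
#' @param participant_ids identifiers, unique, one per row.
#' @param missing_markers strings treated as missing in character columns.
#' @return A `cohort_table`.
#' @export
cohort_table_from_df <- function(df, meta, participant_ids = seq_len(nrow(df)),
                                 missing_markers = c("", "NA", "NaN")) {
  stopifnot(inherits(meta, "aag_meta"))
  participant_ids <- as.character(participant_ids)
  if (anyDuplicated(participant_ids)) {
    aag_stop("participant ids must be unique", "aag_load_error")
  }
  if (length(participant_ids) != nrow(df)) {
    aag_stop("participant_ids must match the number of rows", "aag_load_error")
  }
  unknown <- setdiff(names(df), meta$name)
  if (length(unknown)) {
    aag_stop(sprintf("column(s) without metadata: %s", paste(unknown, collapse = ", ")),
             "aag_load_error")
  }
  warn <- integer(0)
  out <- df
  for (v in names(df)) {
    kind <- meta$data_kind[meta$name == v]
    col <- df[[v]]
    if (is.character(col)) col[col %in% missing_markers] <- NA_character_
    if (kind == "metric") {
      if (!is.numeric(col)) {
        num <- suppressWarnings(as.numeric(col))
        n_bad <- sum(is.na(num) & !is.na(col))
        if (n_bad > 0L) {
          warn[v] <- n_bad
          warning(sprintf("column '%s': %d unparseable metric cell(s) treated as missing",
                          v, n_bad), call. = FALSE)
        }
        col <- num
      }
    } else {
      col <- as.character(col)
      cats <- meta$categories[[which(meta$name == v)]]
      if (length(cats)) {
        bad <- !is.na(col) & !col %in% cats
        if (any(bad)) {
          aag_stop(sprintf("column '%s': value(s) outside declared categories: %s",
                           v, paste(unique(col[bad]), collapse = ", ")),
                   "aag_load_error")
        }
      }
    }
    out[[v]] <- col
  }
  structure(
    list(data = out, participant_ids = participant_ids,
         meta = meta[meta$name %in% names(df), , drop = FALSE],
         g_total = nrow(out), parse_warnings = warn),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d participants x %d variables (%s)\n",
              x$g_total, ncol(x$data),
              paste(sprintf("%d %s", table(x$meta$data_kind),
                            names(table(x$meta$data_kind))), collapse = ", ")))
  invisible(x)
}

.comparators <- c("equals", "not_equals", "less_than", "greater_than", "in_set")

#' Construct a cohort specification
#'
#' A cohort spec lists any-of inclusion criteria: a participant belongs to
#' the disease group as soon as at least one criterion evaluates to `TRUE`
#' on a non-missing value; all remaining participants form the control group.
#'
#' @param criteria list of criteria, each `list(variable=, comparator=,
#'   value=)` with comparator one of `equals`, `not_equals`, `less_than`,
#'   `greater_than`, `in_set`.
#' @param disease_name,control_name display names for the two groups.
#' @return A list of class `cohort_spec`.
#' @examples
#' cohort_spec(list(
#'   list(variable = "mi_history", comparator = "equals", value = "yes"),
#'   list(variable = "ef", comparator = "less_than", value = 40)
#' ))
#' @export
cohort_spec <- function(criteria, disease_name = "disease", control_name = "control") {
  if (!is.list(criteria) || length(criteria) == 0L) {
    aag_stop("criteria list must be non-empty", "aag_spec_error")
  }
  criteria <- lapply(criteria, function(cr) {
    if (is.null(cr$variable) || is.null(cr$comparator) || is.null(cr$value)) {
      aag_stop("each criterion needs fields variable, comparator, value", "aag_spec_error")
    }
    if (!cr$comparator %in% .comparators) {
      aag_stop(sprintf("unknown comparator '%s' (use %s)", cr$comparator,
                       paste(.comparators, collapse = ", ")), "aag_spec_error")
    }
    cr[c("variable", "comparator", "value")]
  })
  structure(list(criteria = criteria, disease_name = disease_name,
                 control_name = control_name),
            class = "cohort_spec")
}

#' Read a cohort specification from YAML or JSON
#'
#' Expected fields: `disease_name`, `control_name` (optional) and
#' `criteria`, a sequence of `{variable, comparator, value}` mappings.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  x <- read_structured(path)
  cohort_spec(x$criteria,
              disease_name = x$disease_name %||% "disease",
              control_name = x$control_name %||% "control")
}

# Evaluate one criterion over a typed column; missing values never satisfy.
eval_criterion <- function(col, comparator, value, kind, variable) {
  numeric_cmp <- comparator %in% c("less_than", "greater_than")
  if (numeric_cmp && kind != "metric") {
    aag_stop(sprintf("criterion on '%s': comparator '%s' requires a metric variable",
                     variable, comparator), "aag_spec_error")
  }
  if (!numeric_cmp && kind == "metric" && comparator %in% c("equals", "not_equals", "in_set")) {
    value <- suppressWarnings(as.numeric(value))
    if (anyNA(value)) {
      aag_stop(sprintf("criterion on metric '%s': non-numeric reference value", variable),
               "aag_spec_error")
    }
  }
  hit <- switch(comparator,
    equals = col == value,
    not_equals = col != value,
    less_than = col < as.numeric(value),
    greater_than = col > as.numeric(value),
    in_set = col %in% unlist(value)
  )
  hit & !is.na(col)
}

#' Split participants into disease and control groups
#'
#' Any-of semantics: a participant is in the disease group iff at least one
#' criterion is satisfied on a non-missing value. Participants missing every
#' criterion variable fall into the control group (the control group is
#' defined by the absence of findings).
#'
#' @param table a `cohort_table`.
#' @param spec a `cohort_spec`.
#' @return A list of class `cohort_assignment` with `membership` (character
#'   vector "disease"/"control" named by participant id), `g_d`, `g_c`,
#'   and the group display names.
#' @export
assign_cohorts <- function(table, spec) {
  stopifnot(inherits(table, "cohort_table"), inherits(spec, "cohort_spec"))
  vars <- vapply(spec$criteria, `[[`, "", "variable")
  missing_vars <- setdiff(vars, names(table$data))
  if (length(missing_vars)) {
    aag_stop(sprintf("criterion variable(s) not in table: %s",
                     paste(missing_vars, collapse = ", ")), "aag_spec_error")
  }
  hit <- rep(FALSE, table$g_total)
  for (cr in spec$criteria) {
    kind <- table$meta$data_kind[table$meta$name == cr$variable]
    hit <- hit | eval_criterion(table$data[[cr$variable]], cr$comparator,
                                cr$value, kind, cr$variable)
  }
  membership <- ifelse(hit, "disease", "control")
  names(membership) <- table$participant_ids
  structure(list(membership = membership,
                 g_d = sum(hit), g_c = sum(!hit),
                 disease_name = spec$disease_name,
                 control_name = spec$control_name),
            class = "cohort_assignment")
}

#' @export
print.cohort_assignment <- function(x, ...) {
  cat(sprintf("<cohort_assignment> %s: %d, %s: %d\n",
              x$disease_name, x$g_d, x$control_name, x$g_c))
  invisible(x)
}
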
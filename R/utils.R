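# Internal helpers shared across modules.

#' Structured condition constructor
#'
#' All user-facing errors raised by the package carry the class
#' `aag_error` plus a subclass naming the failing stage, so callers (and the
#' CLI) can distinguish input problems from bugs.
#'
#' @param msg message text.
#' @param class error subclass, e.g. "aag_load_error".
#' @param ... fields stored on the condition object.
#' @noRd
aag_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "aag_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Test for whole-number scalars
#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

#' Serialize a double at full (round-trip safe) precision
#' @noRd
num_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Collapse a character vector into a pipe-separated field
#' @noRd
collapse_pipe <- function(x) paste(x, collapse = "|")

#' Split a pipe-separated field into a character vector
#' @noRd
split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1L]]
}

#' Read a config-ish file by extension (YAML or JSON)
#' @noRd
read_structured <- function(path) {
  if (!file.exists(path)) {
    aag_stop(sprintf("file not found: %s", path), "aag_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    aag_stop(sprintf("unsupported config format '.%s' (use YAML or JSON): %s", ext, path),
             "aag_io_error")
  }
}
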
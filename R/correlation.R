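# Inferential companion: Pearson correlation with one-tailed confidence
# bounds via the Fisher z transformation, as used to cross-check graph
# findings against standard statistical inference.

#' Pearson correlation with a one-tailed Fisher-transform CI
#'
#' Computes the Pearson coefficient on pairwise-complete observations, then
#' a one-sided confidence bound via the Fisher transformation: with
#' `z = atanh(r)` and standard error `1/sqrt(n - 3)`, the lower bound at
#' level `level` for side "greater" is `tanh(z - q * SE)` (upper bound
#' fixed at 1), and symmetrically for side "less". The one-tailed p-value
#' for the null of independence comes from the standard normal tail of
#' `z / SE`. The side defaults to the sign of the point estimate, matching
#' the practice of reporting intervals fully above or fully below zero.
#'
#' @param x,y numeric (or 0/1 indicator) vectors of equal length.
#' @param level confidence level, default 0.95.
#' @param side "greater", "less", or `NULL` (default: chosen by `sign(r)`,
#'   "greater" when `r >= 0`).
#' @return A list of class `correlation_result`: `r`, `n`, `ci_lower`,
#'   `ci_upper`, `p_value`, `side`, `level`, `degenerate`.
#' @examples
#' set.seed(1)
#' x <- rnorm(100); y <- x + rnorm(100)
#' pearson_ci(x, y)
#' @export
pearson_ci <- function(x, y, level = 0.95, side = NULL) {
  stopifnot(length(x) == length(y), level > 0, level < 1)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) {
    aag_stop("need >= 4 pairwise-complete observations", "aag_contract_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, n = n, ci_lower = NA_real_,
                          ci_upper = NA_real_, p_value = NA_real_,
                          side = NA_character_, level = level,
                          degenerate = TRUE),
                     class = "correlation_result"))
  }
  r <- stats::cor(x, y)
  if (is.null(side)) side <- if (r >= 0) "greater" else "less"
  side <- match.arg(side, c("greater", "less"))
  if (abs(r) >= 1 - 1e-15) {
    return(structure(list(r = r, n = n, ci_lower = r, ci_upper = r,
                          p_value = 0, side = side, level = level,
                          degenerate = TRUE),
                     class = "correlation_result"))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(level)
  if (side == "greater") {
    ci <- c(tanh(z - q * se), 1)
    p <- stats::pnorm(z / se, lower.tail = FALSE)
  } else {
    ci <- c(-1, tanh(z + q * se))
    p <- stats::pnorm(z / se, lower.tail = TRUE)
  }
  structure(list(r = r, n = n, ci_lower = ci[1], ci_upper = ci[2],
                 p_value = p, side = side, level = level, degenerate = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r=%.4f (n=%d), %s%% one-sided [%.4f, %.4f], p=%.3g (%s)%s\n",
              x$r, x$n, format(100 * x$level), x$ci_lower, x$ci_upper,
              x$p_value, x$side, if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Correlation between an attribute and group membership
#'
#' Encodes attribute membership (1 = member, 0 = non-member) and disease
#' membership as indicators over the participants with a valid value for
#' the attribute, then applies [pearson_ci()]. A strictly positive lower
#' bound supports the attribute being more frequent in the disease group.
#'
#' @param attrs an `aag_attributes` object.
#' @param assignment a `cohort_assignment`.
#' @param attribute_id the attribute to test.
#' @param level,side passed to [pearson_ci()].
#' @return A `correlation_result`.
#' @export
attribute_group_correlation <- function(attrs, assignment, attribute_id,
                                        level = 0.95, side = NULL) {
  if (!attribute_id %in% colnames(attrs$status)) {
    aag_stop(sprintf("unknown attribute '%s'", attribute_id), "aag_contract_error")
  }
  a <- attrs$status[, attribute_id]
  g <- as.integer(assignment$membership[rownames(attrs$status)] == "disease")
  pearson_ci(as.numeric(a), g, level = level, side = side)
}

#' Correlation table for a set of attributes
#'
#' Convenience wrapper producing one row per attribute, mirroring a
#' supplementary correlation table: coefficient, pairwise-complete n,
#' one-sided bounds, p-value and side.
#'
#' @param attrs an `aag_attributes`.
#' @param assignment a `cohort_assignment`.
#' @param attribute_ids attributes to test (default: all).
#' @param level confidence level.
#' @return data.frame with columns `attribute_id`, `r`, `n`, `ci_lower`,
#'   `ci_upper`, `p_value`, `side`, `degenerate`.
#' @export
correlation_table <- function(attrs, assignment,
                              attribute_ids = colnames(attrs$status),
                              level = 0.95) {
  rows <- lapply(attribute_ids, function(id) {
    res <- tryCatch(attribute_group_correlation(attrs, assignment, id, level),
                    aag_contract_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(attribute_id = id, r = res$r, n = res$n,
               ci_lower = res$ci_lower, ci_upper = res$ci_upper,
               p_value = res$p_value,
               side = if (is.na(res$side)) NA_character_ else res$side,
               degenerate = res$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(attribute_id = character(0), r = numeric(0), n = integer(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      p_value = numeric(0), side = character(0),
                      degenerate = logical(0))
  }
  rownames(out) <- NULL
  out
}
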
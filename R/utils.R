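#' @importFrom rlang %||% abort warn inform
#' @importFrom stats sd mad median quantile rnorm runif setNames
#' @importFrom utils head combn
NULL

# stop unless all named columns are present; error names the offenders
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Convert a long intensity table to a samples-by-features matrix
#'
#' Helper used by the multivariate and biomarker modules. Blank samples are
#' dropped; the value column defaults to the processed intensity.
#'
#' @param data Long tibble with `sample_id`, `feature_id` and a value column.
#' @param value Name of the value column (default `"intensity"`).
#' @return Numeric matrix, rows = samples (rownames from `sample_id`),
#'   columns = features.
#' @export
metab_matrix <- function(data, value = "intensity") {
  check_columns(data, c("sample_id", "feature_id", value), "intensity table")
  if ("is_blank" %in% names(data)) {
    data <- dplyr::filter(data, !.data$is_blank)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(data, "sample_id", "feature_id", dplyr::all_of(value)),
    names_from = "feature_id", values_from = dplyr::all_of(value)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

# sample (n-1) sd that returns 0 instead of NA for a single value
sd0 <- function(x) {
  if (length(x) < 2) return(0)
  stats::sd(x)
}
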
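#' @name preprocess
#' @title GC-MS metabolite preprocessing chain
#' @description
#' The preprocessing chain applied to raw peak intensities, per sampling
#' timepoint: raw normalization (fresh weight, internal standard, detector
#' batch), blank filtering (keep features more than 2-fold above blanks),
#' presence filtering (keep features quantified in at least 80% of
#' samples), imputation of missing values with 1/5 of the per-feature
#' minimum, removal of the 25% of features with the highest relative
#' standard deviation, per-sample median normalization, log10 transform and
#' Pareto scaling. Each filtering step returns the data together with a
#' report row, and [preprocess_pipeline()] chains them with telescoping
#' counts.
NULL

report_row <- function(step, n_in, removed, params = NA_character_) {
  tibble::tibble(step = step, n_in = n_in, n_removed = length(removed),
                 n_out = n_in - length(removed),
                 removed = list(removed), params = params)
}

n_features_of <- function(data) dplyr::n_distinct(data$feature_id)

#' Normalize raw intensities for sample-level factors
#'
#' Divides each intensity by the product of the sample's fresh weight,
#' internal-standard response factor and batch/detector factor (a simple
#' per-sample multiplicative correction). Samples with a zero or missing
#' factor are excluded with a warning.
#'
#' @param data Long intensity tibble with `fresh_weight`, `istd_response`
#'   and optionally a `batch_factor` column (default 1).
#' @return The normalized tibble.
#' @export
normalize_raw <- function(data) {
  check_columns(data, c("sample_id", "feature_id", "intensity",
                        "fresh_weight", "istd_response"), "intensity table")
  bf <- if ("batch_factor" %in% names(data)) data$batch_factor else 1
  factor <- data$fresh_weight * data$istd_response * bf
  bad <- unique(data$sample_id[is.na(factor) | factor == 0])
  if (length(bad) > 0) {
    rlang::warn(sprintf("excluding %d sample(s) with zero normalization factor",
                        length(bad)))
    keep <- !data$sample_id %in% bad
    data <- data[keep, , drop = FALSE]
    factor <- factor[keep]
  }
  data$intensity <- data$intensity / factor
  data
}

#' Blank filter: keep features clearly above blank samples
#'
#' A feature is kept iff its mean leaf-sample intensity is strictly greater
#' than `fold` times its mean blank intensity. Features absent from all
#' blanks are always kept. With no blank samples the step is skipped.
#'
#' @param data Long intensity tibble with an `is_blank` column.
#' @param fold Fold threshold (default 2).
#' @return List with `data` (blank samples removed along with failing
#'   features) and `report` (one row).
#' @export
blank_filter <- function(data, fold = 2) {
  check_columns(data, c("feature_id", "intensity", "is_blank"),
                "intensity table")
  n_in <- n_features_of(data)
  leaf <- dplyr::filter(data, !.data$is_blank)
  blank <- dplyr::filter(data, .data$is_blank)
  if (nrow(blank) == 0) {
    rlang::inform("no blank samples: blank filter skipped")
    return(list(data = leaf,
                report = report_row("blank_filter", n_in, character(0),
                                    "skipped: no blanks")))
  }
  lm_ <- dplyr::summarise(dplyr::group_by(leaf, .data$feature_id),
                          m = mean(.data$intensity, na.rm = TRUE),
                          .groups = "drop")
  bm <- dplyr::summarise(dplyr::group_by(blank, .data$feature_id),
                         m = mean(.data$intensity, na.rm = TRUE),
                         .groups = "drop")
  j <- dplyr::left_join(lm_, bm, by = "feature_id",
                        suffix = c("_leaf", "_blank"))
  removed <- j$feature_id[!is.na(j$m_blank) & is.finite(j$m_blank) &
                            !(j$m_leaf > fold * j$m_blank)]
  out <- dplyr::filter(leaf, !.data$feature_id %in% removed)
  list(data = out,
       report = report_row("blank_filter", n_in, sort(removed),
                           sprintf("fold=%g", fold)))
}

#' Presence filter: remove sparsely quantified features
#'
#' Keeps a feature iff it is observed (non-missing, non-zero) in at least
#' `min_frac` of the samples.
#'
#' @param data Long intensity tibble (blanks excluded).
#' @param min_frac Minimum observed fraction (default 0.8).
#' @return List with `data` and `report`.
#' @export
presence_filter <- function(data, min_frac = 0.8) {
  n_in <- n_features_of(data)
  pres <- dplyr::summarise(
    dplyr::group_by(data, .data$feature_id),
    frac = mean(!is.na(.data$intensity) & .data$intensity != 0),
    .groups = "drop"
  )
  removed <- pres$feature_id[pres$frac < min_frac]
  list(data = dplyr::filter(data, !.data$feature_id %in% removed),
       report = report_row("presence_filter", n_in, sort(removed),
                           sprintf("min_frac=%g", min_frac)))
}

#' Impute missing values with a fraction of the feature minimum
#'
#' Missing entries of each feature are replaced by `frac` times the
#' minimum observed value of that feature.
#'
#' @param data Long intensity tibble.
#' @param frac Fraction of the per-feature minimum (default 1/5).
#' @return The imputed tibble.
#' @export
impute_min_fraction <- function(data, frac = 0.2) {
  out <- dplyr::mutate(
    dplyr::group_by(data, .data$feature_id),
    .min = if (all(is.na(.data$intensity))) NA_real_ else
      min(.data$intensity, na.rm = TRUE),
    intensity = dplyr::coalesce(.data$intensity, frac * .data$.min)
  )
  out <- dplyr::ungroup(out)
  if (anyNA(out$intensity)) {
    rlang::abort("all-missing feature: run presence_filter first")
  }
  dplyr::select(out, -".min")
}

#' Remove the most variable features by relative standard deviation
#'
#' Computes per-feature RSD (sd/mean, sample sd) on the current
#' intensities and removes the `floor(n * top_frac)` features with the
#' highest RSD. A zero mean gives infinite RSD (removed first); ties are
#' broken by feature ID order so removal is deterministic. With
#' `scope = "within_groups"` the RSD is the average of within-group RSDs
#' over the supplied grouping columns, so treatment-level shifts do not
#' count as variability.
#'
#' @param data Long intensity tibble (imputation done).
#' @param top_frac Fraction of features to remove (default 0.25).
#' @param scope `"global"` (default) or `"within_groups"`.
#' @param group_cols Grouping columns for `"within_groups"` scope.
#' @return List with `data` and `report`; the report's `removed` carries
#'   the dropped feature IDs in removal order.
#' @export
rsd_filter <- function(data, top_frac = 0.25, scope = c("global", "within_groups"),
                       group_cols = c("treatment")) {
  scope <- match.arg(scope)
  n_in <- n_features_of(data)
  n_remove <- floor(n_in * top_frac)
  if (n_remove == 0) {
    return(list(data = data,
                report = report_row("rsd_filter", n_in, character(0),
                                    sprintf("top_frac=%g", top_frac))))
  }
  rsd_of <- function(x) {
    m <- mean(x, na.rm = TRUE)
    if (is.na(m) || m == 0) return(Inf)
    sd0(x[!is.na(x)]) / m
  }
  if (scope == "global") {
    rsd <- dplyr::summarise(dplyr::group_by(data, .data$feature_id),
                            rsd = rsd_of(.data$intensity),
                            .groups = "drop")
  } else {
    per_group <- dplyr::summarise(
      dplyr::group_by(data, .data$feature_id,
                      dplyr::across(dplyr::all_of(group_cols))),
      rsd = rsd_of(.data$intensity), .groups = "drop"
    )
    rsd <- dplyr::summarise(dplyr::group_by(per_group, .data$feature_id),
                            rsd = mean(.data$rsd), .groups = "drop")
  }
  ord <- order(-rsd$rsd, rsd$feature_id)
  removed <- rsd$feature_id[ord][seq_len(n_remove)]
  list(data = dplyr::filter(data, !.data$feature_id %in% removed),
       report = report_row("rsd_filter", n_in, removed,
                           sprintf("top_frac=%g, scope=%s", top_frac, scope)))
}

#' Median normalization: divide each sample by its median intensity
#'
#' After this step every sample's median intensity equals 1. Samples with a
#' zero median are flagged with a warning and left unscaled.
#'
#' @param data Long intensity tibble.
#' @return The normalized tibble.
#' @export
median_normalize <- function(data) {
  med <- dplyr::summarise(dplyr::group_by(data, .data$sample_id),
                          med = stats::median(.data$intensity, na.rm = TRUE),
                          .groups = "drop")
  zero <- med$sample_id[med$med == 0]
  if (length(zero) > 0) {
    rlang::warn(sprintf("%d sample(s) with zero median left unscaled",
                        length(zero)))
    med$med[med$med == 0] <- 1
  }
  out <- dplyr::left_join(data, med, by = "sample_id")
  out$intensity <- out$intensity / out$med
  dplyr::select(out, -"med")
}

#' Elementwise log10 transform
#'
#' @param data Long intensity tibble; all values must be strictly
#'   positive.
#' @return The transformed tibble.
#' @export
log10_transform <- function(data) {
  bad <- which(!is.na(data$intensity) & data$intensity <= 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "non-positive intensity at sample %s, feature %s",
      data$sample_id[bad[1]], data$feature_id[bad[1]]
    ))
  }
  data$intensity <- log10(data$intensity)
  data
}

#' Pareto scaling: centre each feature and divide by the square root of
#' its standard deviation
#'
#' An intermediate between no scaling and autoscaling: after Pareto
#' scaling a feature's variance equals its original standard deviation, so
#' large-variance features are damped but not equalized. Constant features
#' are left centred (all zero) and flagged.
#'
#' @param data Long intensity tibble.
#' @return The scaled tibble; constant features recorded in attribute
#'   `"constant_features"`.
#' @export
pareto_scale <- function(data) {
  out <- dplyr::mutate(
    dplyr::group_by(data, .data$feature_id),
    .sd = sd0(.data$intensity[!is.na(.data$intensity)]),
    intensity = ifelse(.data$.sd > 0,
                       (.data$intensity - mean(.data$intensity, na.rm = TRUE)) /
                         sqrt(.data$.sd),
                       .data$intensity - mean(.data$intensity, na.rm = TRUE))
  )
  const <- unique(dplyr::filter(out, .data$.sd == 0)$feature_id)
  out <- dplyr::select(dplyr::ungroup(out), -".sd")
  attr(out, "constant_features") <- const
  out
}

#' Row normalization: per-feature z-score across samples
#'
#' Centres and scales each feature to unit variance across samples (the
#' display transform used for heatmaps). Constant features become zeros.
#'
#' @param data Long intensity tibble.
#' @return The row-normalized tibble.
#' @export
row_normalize <- function(data) {
  out <- dplyr::mutate(
    dplyr::group_by(data, .data$feature_id),
    .sd = sd0(.data$intensity[!is.na(.data$intensity)]),
    intensity = ifelse(.data$.sd > 0,
                       (.data$intensity - mean(.data$intensity, na.rm = TRUE)) /
                         .data$.sd,
                       0)
  )
  dplyr::select(dplyr::ungroup(out), -".sd")
}

#' Run the full preprocessing chain, independently per sampling timepoint
#'
#' blank filter, presence filter, minimum-fraction imputation, RSD filter,
#' median normalization, log10 transform and Pareto scaling, applied to
#' each sampling timepoint's slice separately (retained feature sets may
#' therefore differ between timepoints). The returned table carries both
#' the fully processed values (`intensity`) and the median-normalized
#' pre-log values (`intensity_norm`) used for fold-change computation.
#'
#' @param data Long intensity tibble with blanks and a `timepoint` column.
#' @param blank_fold,min_frac,impute_frac,rsd_top_frac,rsd_scope
#'   Step parameters (defaults 2, 0.8, 0.2, 0.25, `"global"`).
#' @return List with `data` (processed long tibble) and `report` (tibble
#'   with a `timepoint` column; counts telescope within each timepoint).
#' @export
preprocess_pipeline <- function(data, blank_fold = 2, min_frac = 0.8,
                                impute_frac = 0.2, rsd_top_frac = 0.25,
                                rsd_scope = "global") {
  check_columns(data, c("sample_id", "feature_id", "intensity",
                        "timepoint", "is_blank"), "intensity table")
  tps <- sort(unique(data$timepoint))
  pieces <- lapply(tps, function(tp) {
    slice <- dplyr::filter(data, .data$timepoint == tp)
    s1 <- blank_filter(slice, fold = blank_fold)
    s2 <- presence_filter(s1$data, min_frac = min_frac)
    s3 <- impute_min_fraction(s2$data, frac = impute_frac)
    s4 <- rsd_filter(s3, top_frac = rsd_top_frac, scope = rsd_scope)
    s5 <- median_normalize(s4$data)
    s5$intensity_norm <- s5$intensity
    s6 <- log10_transform(s5)
    s7 <- pareto_scale(s6)
    rep <- dplyr::bind_rows(s1$report, s2$report, s4$report)
    rep$timepoint <- tp
    list(data = s7, report = rep)
  })
  list(
    data = dplyr::bind_rows(lapply(pieces, `[[`, "data")),
    report = dplyr::bind_rows(lapply(pieces, `[[`, "report"))
  )
}
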
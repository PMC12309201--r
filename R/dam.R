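#' Log2 fold change of drought over control means
#'
#' @param mean_drought,mean_control Group means on the normalized, pre-log
#'   intensity scale; both must be positive.
#' @return `log2(mean_drought / mean_control)`.
#' @export
log2_fold_change <- function(mean_drought, mean_control) {
  out <- ifelse(mean_drought > 0 & mean_control > 0,
                log2(mean_drought / mean_control), NA_real_)
  if (anyNA(out)) rlang::warn("non-positive mean: fold change undefined for some features")
  out
}

pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * sd0(a)^2 + (nb - 1) * sd0(b)^2) / (na + nb - 2)
  if (sp2 == 0) {
    return(list(t = 0, df = na + nb - 2, p = 1, flag = TRUE))
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), flag = FALSE)
}

#' Differential metabolite accumulation between treatments
#'
#' Per feature within one timepoint: equal-variance (pooled) two-sample
#' t-test of drought versus control on the processed intensities, with
#' Benjamini-Hochberg FDR across the features of that timepoint, plus the
#' log2 fold change of the group means on the normalized pre-log scale
#' (column `intensity_norm` when present, otherwise `intensity`).
#'
#' Features with zero pooled variance get t = 0, p = 1 and a flag.
#'
#' @param data Processed long intensity tibble with `treatment`.
#' @param timepoint Optional single timepoint to test (default: data must
#'   contain one timepoint).
#' @return Tibble of class `dam_tbl`: `feature_id`, `timepoint`,
#'   `mean_drought`, `mean_control`, `log2_fc`, `t_stat`, `df`, `p`,
#'   `fdr`, `zero_var`.
#' @export
ttest_dam <- function(data, timepoint = NULL) {
  check_columns(data, c("feature_id", "treatment", "intensity"), "data")
  if (!is.null(timepoint)) {
    data <- dplyr::filter(data, .data$timepoint == !!timepoint)
  }
  tp <- if ("timepoint" %in% names(data)) unique(data$timepoint) else NA
  if (length(tp) > 1) rlang::abort("one timepoint at a time: pass `timepoint`")
  fc_col <- if ("intensity_norm" %in% names(data)) "intensity_norm" else
    "intensity"
  res <- dplyr::summarise(
    dplyr::group_by(data, .data$feature_id),
    .test = list(pooled_t(.data$intensity[.data$treatment == "drought"],
                          .data$intensity[.data$treatment == "control"])),
    mean_drought = mean(.data[[fc_col]][.data$treatment == "drought"]),
    mean_control = mean(.data[[fc_col]][.data$treatment == "control"]),
    n_drought = sum(.data$treatment == "drought"),
    n_control = sum(.data$treatment == "control"),
    .groups = "drop"
  )
  if (any(res$n_drought < 2 | res$n_control < 2)) {
    rlang::abort("need at least 2 values per group per feature")
  }
  res$t_stat <- vapply(res$.test, `[[`, numeric(1), "t")
  res$df <- vapply(res$.test, `[[`, numeric(1), "df")
  res$p <- vapply(res$.test, `[[`, numeric(1), "p")
  res$zero_var <- vapply(res$.test, `[[`, logical(1), "flag")
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$log2_fc <- suppressWarnings(
    log2_fold_change(res$mean_drought, res$mean_control)
  )
  res$timepoint <- if (length(tp) == 1 && !all(is.na(tp))) tp else NA
  out <- dplyr::select(
    res, "feature_id", "timepoint", "mean_drought", "mean_control",
    "log2_fc", "t_stat", "df", "p", "fdr", "zero_var"
  )
  class(out) <- c("dam_tbl", class(out))
  out
}

#' Volcano gating of differential accumulation records
#'
#' Adds a `direction` column: `"up"` iff `fdr < alpha` and
#' `log2_fc > fc_cut`, `"down"` iff `fdr < alpha` and `log2_fc < -fc_cut`,
#' otherwise `"ns"`.
#'
#' @param records A `dam_tbl` from [ttest_dam()].
#' @param alpha FDR threshold (default 0.05).
#' @param fc_cut Absolute log2 fold-change threshold (default 1).
#' @return The records with a `direction` factor.
#' @export
classify_volcano <- function(records, alpha = 0.05, fc_cut = 1) {
  check_columns(records, c("fdr", "log2_fc"), "records")
  records$direction <- dplyr::case_when(
    records$fdr < alpha & records$log2_fc > fc_cut ~ "up",
    records$fdr < alpha & records$log2_fc < -fc_cut ~ "down",
    TRUE ~ "ns"
  )
  records
}

#' Venn region counts across feature sets
#'
#' For named sets (e.g. per-timepoint up-regulated DAM sets) returns the
#' count of features falling in every exclusive Venn region, identified by
#' the sets that contain them.
#'
#' @param sets Named list of character vectors.
#' @return Tibble with `region` (set names joined by `&`), `n`, and the
#'   member features.
#' @export
overlap_counts <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  region <- apply(membership, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  combos <- unlist(lapply(seq_along(sets), function(k) {
    apply(utils::combn(names(sets), k), 2, paste, collapse = "&")
  }))
  counts <- table(factor(region, levels = combos))
  tibble::tibble(
    region = names(counts),
    n = as.integer(counts),
    features = lapply(names(counts), function(r) universe[region == r])
  )
}

#' Per-genotype differential accumulation with VIP gating
#'
#' Drought-versus-control t-test restricted to one genotype at one
#' timepoint, intersected with OPLS-DA importance: features pass iff
#' FDR < `alpha` and VIP > `vip_cut`, reported split by the sign of the
#' effect.
#'
#' @param data Processed long intensity tibble.
#' @param genotype Genotype (or vector of genotypes pooled as one class).
#' @param timepoint Timepoint to test.
#' @param vip Named numeric vector of VIP scores (from [vip_scores()]) for
#'   the same contrast.
#' @param alpha FDR threshold (default 0.05).
#' @param vip_cut VIP threshold (default 1).
#' @return Tibble with `feature_id`, `log2_fc`, `fdr`, `vip`, `direction`
#'   for the passing features.
#' @export
genotype_dam <- function(data, genotype, timepoint, vip,
                         alpha = 0.05, vip_cut = 1) {
  sub <- dplyr::filter(data, .data$genotype %in% !!genotype,
                       .data$timepoint == !!timepoint)
  if (nrow(sub) == 0) rlang::abort("no data for that genotype/timepoint")
  dam <- ttest_dam(sub)
  dam$vip <- unname(vip[dam$feature_id])
  hit <- dplyr::filter(dam, .data$fdr < alpha,
                       !is.na(.data$vip), .data$vip > vip_cut)
  hit$direction <- ifelse(hit$t_stat > 0, "up", "down")
  dplyr::select(hit, "feature_id", "log2_fc", "fdr", "vip", "direction")
}

#' Sign-consistent consensus across pairwise genotype comparisons
#'
#' Given differential-accumulation results for several pairwise
#' tolerant-versus-non-tolerant comparisons, returns the features that
#' appear with a consistent direction in at least `k` of them. Features
#' appearing with both signs are excluded.
#'
#' @param dam_sets List of tibbles with `feature_id` and `direction`
#'   (`"up"`/`"down"`), one per pairwise comparison.
#' @param k Minimum number of supporting comparisons.
#' @return Tibble with `feature_id`, `direction`, `n_comparisons`.
#' @export
pairwise_consensus <- function(dam_sets, k) {
  if (k > length(dam_sets)) rlang::abort("k cannot exceed the number of comparisons")
  all_hits <- dplyr::bind_rows(lapply(seq_along(dam_sets), function(i) {
    d <- dplyr::filter(dam_sets[[i]], .data$direction %in% c("up", "down"))
    tibble::tibble(feature_id = d$feature_id, direction = d$direction,
                   comparison = i)
  }))
  if (nrow(all_hits) == 0) {
    return(tibble::tibble(feature_id = character(), direction = character(),
                          n_comparisons = integer()))
  }
  tallied <- dplyr::summarise(
    dplyr::group_by(all_hits, .data$feature_id),
    n_up = dplyr::n_distinct(.data$comparison[.data$direction == "up"]),
    n_down = dplyr::n_distinct(.data$comparison[.data$direction == "down"]),
    .groups = "drop"
  )
  consistent <- dplyr::filter(tallied, .data$n_up == 0 | .data$n_down == 0)
  consistent$direction <- ifelse(consistent$n_up > 0, "up", "down")
  consistent$n_comparisons <- pmax(consistent$n_up, consistent$n_down)
  out <- dplyr::filter(consistent, .data$n_comparisons >= k)
  dplyr::select(out, "feature_id", "direction", "n_comparisons")
}
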
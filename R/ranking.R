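#' Rank genotypes within each trait
#'
#' Rank 1 is the best genotype: the largest value when the trait's
#' `higher_is_better` flag is `TRUE`, the smallest otherwise. Ties receive
#' average ranks.
#'
#' @param data Tibble with `genotype`, `trait`, `value` (one genotype-mean
#'   value per genotype per trait).
#' @param higher_is_better Named logical vector per trait, or a single
#'   value recycled to all traits (default `TRUE`).
#' @return Tibble with `genotype`, `trait`, `rank`.
#' @export
rank_traits <- function(data, higher_is_better = TRUE) {
  check_columns(data, c("genotype", "trait", "value"), "data")
  if (anyNA(data$value)) rlang::abort("missing genotype value")
  traits <- unique(data$trait)
  counts <- dplyr::count(data, .data$trait, .data$genotype)
  if (any(counts$n != 1) ||
      any(table(data$trait) != dplyr::n_distinct(data$genotype))) {
    rlang::abort("need exactly one value per genotype per trait")
  }
  hib <- if (length(higher_is_better) == 1) {
    stats::setNames(rep(higher_is_better, length(traits)), traits)
  } else higher_is_better
  if (!all(traits %in% names(hib))) {
    rlang::abort("higher_is_better must name every trait")
  }
  out <- dplyr::mutate(
    dplyr::group_by(data, .data$trait),
    rank = if (hib[[dplyr::cur_group()$trait]]) {
      rank(-.data$value, ties.method = "average")
    } else {
      rank(.data$value, ties.method = "average")
    }
  )
  dplyr::select(dplyr::ungroup(out), "genotype", "trait", "rank")
}

#' Aggregate per-trait genotype ranks by rank product
#'
#' The rank product of a genotype is the product of its per-trait ranks;
#' the total rank orders genotypes by ascending rank product (average
#' ranks on ties). Unlike mean-rank aggregation, the product rewards
#' consistently strong performance: a single rank 1 can outweigh several
#' middling ranks.
#'
#' @param ranks Tibble with `genotype`, `trait`, `rank` (from
#'   [rank_traits()], or ranks supplied directly).
#' @return Tibble with `genotype`, one `rank_*` column per trait,
#'   `rank_product`, `total_rank`, ordered by total rank.
#' @export
rank_product_total <- function(ranks) {
  check_columns(ranks, c("genotype", "trait", "rank"), "ranks")
  if (anyNA(ranks$rank)) rlang::abort("incomplete rank matrix")
  wide <- tidyr::pivot_wider(ranks, names_from = "trait",
                             values_from = "rank", names_prefix = "rank_")
  if (anyNA(wide)) rlang::abort("incomplete rank matrix")
  rank_cols <- setdiff(names(wide), "genotype")
  wide$rank_product <- apply(wide[rank_cols], 1, prod)
  wide$total_rank <- rank(wide$rank_product, ties.method = "average")
  dplyr::arrange(wide, .data$total_rank)
}
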
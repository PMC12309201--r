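#' Hypergeometric over-representation analysis of a metabolite set
#'
#' One-sided hypergeometric tail test per pathway: the probability of
#' drawing at least the observed overlap when sampling `n = |dam_set|`
#' features without replacement from a universe of size `N` containing
#' `K` pathway members. Benjamini-Hochberg FDR across pathways. This is a
#' transparent local-annotation ORA; it is deliberately not a KEGG
#' network-diffusion method.
#'
#' @param dam_set Character vector of selected feature IDs (must be a
#'   subset of the universe).
#' @param pathway_map Tibble with `feature_id`, `pathway_id`.
#' @param universe Character vector of all measurable feature IDs.
#' @param alpha FDR threshold used for the `enriched` flag (default
#'   0.05).
#' @return Tibble with `pathway_id`, `k` (overlap), `K` (pathway size),
#'   `n` (set size), `N` (universe size), `p`, `fdr`, `enriched`.
#' @export
ora_hypergeometric <- function(dam_set, pathway_map, universe,
                               alpha = 0.05) {
  check_columns(pathway_map, c("feature_id", "pathway_id"), "pathway map")
  if (length(universe) == 0) rlang::abort("empty universe")
  if (!all(dam_set %in% universe)) {
    rlang::abort("dam_set must be a subset of the universe")
  }
  pm <- dplyr::filter(pathway_map, .data$feature_id %in% universe)
  N <- length(unique(universe))
  n <- length(unique(dam_set))
  res <- dplyr::summarise(
    dplyr::group_by(pm, .data$pathway_id),
    K = dplyr::n_distinct(.data$feature_id),
    k = dplyr::n_distinct(intersect(.data$feature_id, dam_set)),
    .groups = "drop"
  )
  res$n <- n
  res$N <- N
  res$p <- stats::phyper(res$k - 1, res$K, N - res$K, n,
                         lower.tail = FALSE)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- res$fdr < alpha
  dplyr::select(res, "pathway_id", "k", "K", "n", "N", "p", "fdr",
                "enriched")
}
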
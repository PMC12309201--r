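#' Volcano plot of differential metabolite accumulation
#'
#' @param records A classified `dam_tbl` (see [classify_volcano()]).
#' @param alpha FDR line (default 0.05).
#' @param fc_cut Fold-change lines (default 1).
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, alpha = 0.05, fc_cut = 1) {
  check_columns(records, c("log2_fc", "fdr"), "records")
  if (!"direction" %in% names(records)) {
    records <- classify_volcano(records, alpha, fc_cut)
  }
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$log2_fc,
                               y = -log10(.data$fdr),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-fc_cut, fc_cut), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")
    ) +
    ggplot2::labs(x = "log2 fold change (drought / control)",
                  y = "-log10 FDR-adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Score plot of a PCA of metabolite profiles
#'
#' @param object A `pca_metab` object.
#' @param colour Optional vector (recycled over samples) to colour by,
#'   e.g. treatment.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_metab <- function(object, colour = NULL, ...) {
  d <- object$scores
  d$colour <- colour %||% "sample"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = .data$colour)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Score plot of an OPLS-DA model
#'
#' Predictive score against the first orthogonal score (or sample index
#' when no orthogonal component was fitted), coloured by class.
#'
#' @param object An `opls_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opls_model <- function(object, ...) {
  cls <- object$levels[(object$y_coded > 0) + 1]
  d <- tibble::tibble(
    t_pred = object$t_p,
    t_ortho = if (object$n_ortho > 0) object$T_o[, 1] else
      seq_along(object$t_p),
    class = cls
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_pred, y = .data$t_ortho,
                                  colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "predictive score",
                  y = if (object$n_ortho > 0) "orthogonal score 1" else
                    "sample index",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plant growth curves by treatment
#'
#' @param series Phenotype time series tibble.
#' @param trait Trait to plot (default `"Biomass"`).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(series, trait = "Biomass") {
  d <- dplyr::filter(series, .data$trait == !!trait)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$value,
                                  group = .data$plant_id,
                                  colour = .data$treatment)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "days after onset of drought", y = trait,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
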
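#' Variance components from a genotype-by-experiment trial
#'
#' Method-of-moments estimates from the expected mean squares of the
#' two-way (genotype, experiment, interaction) ANOVA:
#' \eqn{\sigma^2_E = MS_E}, \eqn{\sigma^2_{gxe} = (MS_{GxE} - MS_E)/r},
#' \eqn{\sigma^2_g = (MS_G - MS_{GxE})/(re)}, with negatives truncated to
#' zero. `r` is the (average) number of replicates per
#' genotype-by-experiment cell and `e` the number of experiments.
#'
#' @param data Tibble with `genotype`, `experiment`, `value`.
#' @return A `variance_components` list: `sigma2_g`, `sigma2_gxe`,
#'   `sigma2_E`, `e`, `r`.
#' @export
fit_variance_components <- function(data) {
  check_columns(data, c("genotype", "experiment", "value"), "data")
  data <- dplyr::filter(data, !is.na(.data$value))
  g <- factor(data$genotype)
  ex <- factor(data$experiment)
  if (nlevels(g) < 2) rlang::abort("need at least 2 genotypes")
  e <- nlevels(ex)
  r <- nrow(data) / (nlevels(g) * e)
  if (e < 2) {
    rlang::warn("single experiment: sigma2_gxe undefined, returned as 0")
    fit <- stats::aov(value ~ g, data = data.frame(value = data$value, g = g))
    tab <- summary(fit)[[1]]
    ms_g <- tab["g", "Mean Sq"]
    ms_e <- if ("Residuals" %in% rownames(tab)) {
      tab["Residuals", "Mean Sq"]
    } else 0
    if (is.na(ms_e)) ms_e <- 0
    vc <- list(sigma2_g = max((ms_g - ms_e) / r, 0), sigma2_gxe = 0,
               sigma2_E = ms_e, e = 1, r = r)
    return(structure(vc, class = "variance_components"))
  }
  fit <- stats::aov(value ~ g * ex,
                    data = data.frame(value = data$value, g = g, ex = ex))
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  ms <- stats::setNames(tab[, "Mean Sq"], rn)
  ms_e <- if ("Residuals" %in% rn) ms[["Residuals"]] else 0
  if (is.na(ms_e)) ms_e <- 0
  ms_gxe <- ms[["g:ex"]]
  ms_g <- ms[["g"]]
  structure(list(
    sigma2_g = max((ms_g - ms_gxe) / (r * e), 0),
    sigma2_gxe = max((ms_gxe - ms_e) / r, 0),
    sigma2_E = ms_e, e = e, r = r
  ), class = "variance_components")
}

#' Broad-sense heritability across experiments
#'
#' \deqn{H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{gxe}/e +
#'   \sigma^2_E/(re)}}
#' with \eqn{\sigma^2_g} the genetic variance, \eqn{\sigma^2_{gxe}} the
#' genotype-by-experiment interaction variance, \eqn{\sigma^2_E} the error
#' variance, `e` the number of experiments and `r` the number of
#' replicates.
#'
#' @param vc A `variance_components` object (or a list with the same
#'   fields).
#' @return H-squared in \[0, 1\].
#' @export
heritability <- function(vc) {
  stopifnot(all(c("sigma2_g", "sigma2_gxe", "sigma2_E", "e", "r") %in%
                  names(vc)))
  denom <- vc$sigma2_g + vc$sigma2_gxe / vc$e +
    vc$sigma2_E / (vc$r * vc$e)
  if (denom <= 0) rlang::abort("heritability undefined: all variance components are zero")
  vc$sigma2_g / denom
}

#' Relative loss of a trait under drought
#'
#' `100 * (1 - drought_mean / control_mean)`, in percent. Positive values
#' mean the trait is reduced under drought; negative values are possible
#' when drought increases the trait.
#'
#' @param drought_mean,control_mean Trait means under the two treatments.
#' @return Loss in percent.
#' @export
loss_of_trait <- function(drought_mean, control_mean) {
  if (any(control_mean == 0)) rlang::abort("loss undefined for zero control mean")
  100 * (1 - drought_mean / control_mean)
}

#' Two-way genotype-by-treatment ANOVA
#'
#' Fixed-effects two-way ANOVA with interaction; Type II sums of squares so
#' that unbalanced designs (unequal replication) are handled sensibly.
#'
#' @param data Tibble with `genotype`, `treatment`, `value` (one row per
#'   plant).
#' @return Tibble with `term`, `sumsq`, `df`, `statistic`, `p.value`.
#' @export
anova_gxt <- function(data) {
  check_columns(data, c("genotype", "treatment", "value"), "data")
  data <- dplyr::filter(data, !is.na(.data$value))
  d <- data.frame(value = data$value,
                  genotype = factor(data$genotype),
                  treatment = factor(data$treatment))
  if (nlevels(d$genotype) < 2 || nlevels(d$treatment) < 2) {
    rlang::abort("need at least 2 levels per factor")
  }
  cells <- table(d$genotype, d$treatment)
  if (any(cells == 0)) {
    rlang::abort("empty genotype x treatment cells: interaction inestimable")
  }
  fit <- stats::lm(value ~ genotype * treatment, data = d)
  tab <- car::Anova(fit, type = 2)
  tt <- as.data.frame(tab)
  tibble::tibble(
    term = rownames(tt),
    sumsq = tt[["Sum Sq"]],
    df = tt[["Df"]],
    statistic = tt[["F value"]],
    p.value = tt[["Pr(>F)"]]
  )
}

#' First day of significant treatment divergence
#'
#' Runs the per-day two-way genotype-by-treatment ANOVA on a single trait
#' and returns the first day whose treatment effect is significant at
#' `alpha`. With `persistent = TRUE` (default) the treatment effect must
#' also be significant on the following observed day, which guards the
#' onset estimate against isolated false positives among the pre-onset
#' days.
#'
#' @param series Phenotype time series (`genotype`, `treatment`, `day`,
#'   `trait`, `value`).
#' @param trait Trait name to test.
#' @param alpha Significance level (default 0.05).
#' @param persistent Require significance on two consecutive observed days.
#' @return The day label, or `NA` if no day is significant. Per-day
#'   p-values are attached as attribute `"p_by_day"`.
#' @export
onset_day <- function(series, trait = "Biomass", alpha = 0.05,
                      persistent = TRUE) {
  check_columns(series, c("genotype", "treatment", "day", "trait", "value"),
                "series")
  s <- dplyr::filter(series, .data$trait == !!trait, !is.na(.data$value))
  days <- sort(unique(s$day))
  p <- vapply(days, function(d) {
    sub <- dplyr::filter(s, .data$day == d)
    if (dplyr::n_distinct(sub$treatment) < 2) return(NA_real_)
    a <- anova_gxt(sub)
    a$p.value[a$term == "treatment"]
  }, numeric(1))
  sig <- !is.na(p) & p < alpha
  hit <- NA_real_
  for (i in seq_along(days)) {
    if (!sig[i]) next
    if (!persistent || (i < length(days) && sig[i + 1]) ||
        (persistent && i == length(days))) {
      hit <- days[i]
      break
    }
  }
  structure(hit, p_by_day = tibble::tibble(day = days, p = p))
}

# insert-and-absorb compact letter display from a logical "differs" matrix
letters_from_pairs <- function(groups, differs) {
  sets <- list(groups)
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1)) {
      if (!differs[i, j]) next
      gi <- groups[i]; gj <- groups[j]
      hit <- vapply(sets, function(s) gi %in% s && gj %in% s, logical(1))
      if (!any(hit)) next
      new_sets <- list()
      for (k in seq_along(sets)) {
        if (!hit[k]) {
          new_sets[[length(new_sets) + 1]] <- sets[[k]]
        } else {
          new_sets[[length(new_sets) + 1]] <- setdiff(sets[[k]], gi)
          new_sets[[length(new_sets) + 1]] <- setdiff(sets[[k]], gj)
        }
      }
      # absorb: drop sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[b] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  ord <- order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))
  sets <- sets[ord]
  lab <- letters[seq_along(sets)]
  vapply(groups, function(g) {
    paste(lab[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "")
  }, character(1))
}

#' Compact letter display from Tukey's honest significant difference test
#'
#' All-pairs Tukey HSD at level `alpha` on a one-way layout, with letters
#' assigned by the insert-and-absorb algorithm: groups sharing a letter are
#' not significantly different.
#'
#' @param data Tibble with `group` and `value` columns.
#' @param alpha Familywise significance level (default 0.01).
#' @return Tibble with `group`, `mean`, `letters`.
#' @export
tukey_letters <- function(data, alpha = 0.01) {
  check_columns(data, c("group", "value"), "data")
  d <- data.frame(value = data$value, group = factor(data$group))
  groups <- levels(d$group)
  means <- tapply(d$value, d$group, mean)
  if (length(groups) < 2) {
    return(tibble::tibble(group = groups, mean = as.numeric(means),
                          letters = "a"))
  }
  fit <- stats::aov(value ~ group, data = d)
  # conf.level only shapes the unused interval bounds; keep it valid for
  # extreme alpha
  hsd <- stats::TukeyHSD(fit,
                         conf.level = min(max(1 - alpha, 0.5), 0.999))$group
  differs <- matrix(FALSE, length(groups), length(groups),
                    dimnames = list(groups, groups))
  prs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  for (k in seq_along(prs)) {
    a <- prs[[k]][1]; b <- prs[[k]][2]
    if (!is.na(hsd[k, "p adj"]) && hsd[k, "p adj"] < alpha) {
      differs[a, b] <- differs[b, a] <- TRUE
    }
  }
  tibble::tibble(group = groups, mean = as.numeric(means[groups]),
                 letters = unname(letters_from_pairs(groups, differs)))
}

#' Spearman rank correlation of genotype means across experiments
#'
#' @param means_exp1,means_exp2 Paired per-genotype means (same order).
#' @return Spearman's rho (average ranks for ties).
#' @export
cross_experiment_spearman <- function(means_exp1, means_exp2) {
  ok <- !is.na(means_exp1) & !is.na(means_exp2)
  if (sum(ok) < 3) rlang::abort("need at least 3 paired genotype means")
  stats::cor(means_exp1[ok], means_exp2[ok], method = "spearman")
}

#' PSII plasticity: ratio of quantum yields under high and low light
#'
#' @param qy_high,qy_low Quantum yield after high- and low-light
#'   adaptation.
#' @return `qy_high / qy_low`.
#' @export
qy_ratio <- function(qy_high, qy_low) {
  if (any(qy_low == 0)) rlang::abort("qy_low must be non-zero")
  qy_high / qy_low
}
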
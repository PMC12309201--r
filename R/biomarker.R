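#' Build the four genotype-level metabolite-phenotype datasets
#'
#' Pairs genotype-mean metabolite intensities at 22 days after onset of
#' drought with genotype-mean phenotypes or per-genotype loss-of-trait
#' values, producing the four tagged datasets used for the correlation
#' screen and PLSR ranking: CC (metabolites under control vs phenotypes
#' under control), DD (drought vs drought), LC (control metabolites vs
#' loss of trait) and LD (drought metabolites vs loss of trait). The unit
#' of analysis is the genotype.
#'
#' @param metab Processed long metabolite tibble at 22 DAD (columns
#'   `genotype`, `treatment`, `feature_id`, `intensity`).
#' @param phenotypes Per-plant phenotype tibble (`genotype`, `treatment`,
#'   `trait`, `value`).
#' @return Named list of four `paired_dataset` objects, each with `tag`,
#'   `X` (tibble: `genotype` + one column per feature) and `y` (tibble:
#'   `genotype` + one column per trait). Genotypes missing from either
#'   table are dropped with a warning.
#' @export
build_paired_datasets <- function(metab, phenotypes) {
  check_columns(metab, c("genotype", "treatment", "feature_id", "intensity"),
                "metabolite table")
  check_columns(phenotypes, c("genotype", "treatment", "trait", "value"),
                "phenotype table")
  mg <- dplyr::summarise(
    dplyr::group_by(metab, .data$genotype, .data$treatment,
                    .data$feature_id),
    intensity = mean(.data$intensity, na.rm = TRUE), .groups = "drop"
  )
  pg <- dplyr::summarise(
    dplyr::group_by(phenotypes, .data$genotype, .data$treatment,
                    .data$trait),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop"
  )
  common <- Reduce(intersect, list(unique(mg$genotype), unique(pg$genotype)))
  dropped <- setdiff(union(unique(mg$genotype), unique(pg$genotype)), common)
  if (length(dropped) > 0) {
    rlang::warn(sprintf("dropping genotype(s) missing from one table: %s",
                        paste(dropped, collapse = ", ")))
    mg <- dplyr::filter(mg, .data$genotype %in% common)
    pg <- dplyr::filter(pg, .data$genotype %in% common)
  }
  wide_x <- function(trt) {
    d <- dplyr::filter(mg, .data$treatment == trt)
    out <- tidyr::pivot_wider(dplyr::select(d, -"treatment"),
                              names_from = "feature_id",
                              values_from = "intensity")
    dplyr::arrange(out, .data$genotype)
  }
  wide_y <- function(trt) {
    d <- dplyr::filter(pg, .data$treatment == trt)
    out <- tidyr::pivot_wider(dplyr::select(d, -"treatment"),
                              names_from = "trait", values_from = "value")
    dplyr::arrange(out, .data$genotype)
  }
  yc <- wide_y("control")
  yd <- wide_y("drought")
  stopifnot(identical(yc$genotype, yd$genotype))
  loss <- yc
  for (tr in setdiff(names(yc), "genotype")) {
    loss[[tr]] <- loss_of_trait(yd[[tr]], yc[[tr]])
  }
  xc <- wide_x("control")
  xd <- wide_x("drought")
  mk <- function(tag, X, y) {
    stopifnot(identical(X$genotype, y$genotype))
    structure(list(tag = tag, X = X, y = y), class = "paired_dataset")
  }
  list(CC = mk("CC", xc, yc), DD = mk("DD", xd, yd),
       LC = mk("LC", xc, loss), LD = mk("LD", xd, loss))
}

#' Correlation screen between metabolites and phenotypes
#'
#' For every feature-by-trait pair of a paired dataset: Spearman's rho
#' with its t-approximation p-value, Benjamini-Hochberg FDR across all
#' records of the dataset, and R-squared from the ordinary least-squares
#' fit of the trait on the feature (the squared Pearson correlation;
#' deliberately not the squared Spearman rho). Records with p below
#' `p_cut` are flagged significant. Constant features or traits are
#' skipped.
#'
#' @param ds A `paired_dataset` from [build_paired_datasets()].
#' @param p_cut Significance cutoff on the raw p-value (default 0.001).
#' @return Tibble with `tag`, `feature_id`, `trait`, `rho`, `p`, `fdr`,
#'   `r2`, `significant`.
#' @export
correlate_metab_pheno <- function(ds, p_cut = 0.001) {
  stopifnot(inherits(ds, "paired_dataset"))
  feats <- setdiff(names(ds$X), "genotype")
  traits <- setdiff(names(ds$y), "genotype")
  if (nrow(ds$X) < 5) rlang::abort("need at least 5 genotypes")
  grid <- tidyr::expand_grid(feature_id = feats, trait = traits)
  res <- purrr::pmap_dfr(grid, function(feature_id, trait) {
    x <- ds$X[[feature_id]]
    y <- ds$y[[trait]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 5 || sd0(x[ok]) == 0 || sd0(y[ok]) == 0) return(NULL)
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
    )
    tibble::tibble(
      tag = ds$tag, feature_id = feature_id, trait = trait,
      rho = unname(ct$estimate), p = ct$p.value,
      r2 = stats::cor(x[ok], y[ok])^2
    )
  })
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < p_cut
  res
}

#' Leave-genotypes-out PLSR rank-product biomarker ranking
#'
#' The genotypes are partitioned (seeded shuffle) into disjoint test folds
#' of `fold_size`; for each fold a partial least squares regression of the
#' trait on all features is fitted on the remaining training genotypes,
#' with the number of components chosen by inner `inner_folds`-fold
#' cross-validated RMSEP (up to `ncomp_max`). Features are ranked within
#' each fold by absolute regression coefficient (rank 1 = largest); the
#' rank product across folds gives the final ranking, lower meaning a
#' consistently strong predictor. Test-fold predictions are emitted for
#' assessing predictive ability.
#'
#' @param ds A `paired_dataset`.
#' @param trait Trait (column of `ds$y`) to predict.
#' @param fold_size Genotypes per outer test fold (default 3).
#' @param ncomp_max Maximum PLS components (default 3).
#' @param inner_folds Inner CV folds for component selection (default 4).
#' @param seed Integer seed for the fold assignment.
#' @return Tibble with `feature_id`, per-fold ranks (`rank_fold*`),
#'   `rank_product` and `final_rank`; test predictions in attribute
#'   `"predictions"` (tibble: `genotype`, `fold`, `observed`,
#'   `predicted`), chosen component counts in attribute `"ncomp"`.
#' @export
plsr_rank_product <- function(ds, trait, fold_size = 3, ncomp_max = 3,
                              inner_folds = 4, seed = 1L) {
  stopifnot(inherits(ds, "paired_dataset"))
  if (!trait %in% names(ds$y)) rlang::abort("unknown trait")
  genos <- ds$X$genotype
  G <- length(genos)
  if (G < 2 * fold_size) rlang::abort("too few genotypes for this fold size")
  y <- ds$y[[trait]]
  if (sd0(y) == 0) rlang::abort("constant response: nothing to regress")
  X <- as.matrix(ds$X[, setdiff(names(ds$X), "genotype"), drop = FALSE])
  rownames(X) <- genos

  set.seed(seed)
  shuffled <- sample(genos)
  n_folds <- ceiling(G / fold_size)
  folds <- split(shuffled, rep(seq_len(n_folds), each = fold_size,
                               length.out = G))

  rank_mat <- matrix(NA_real_, ncol(X), n_folds,
                     dimnames = list(colnames(X), NULL))
  preds <- list()
  ncomps <- integer(n_folds)
  for (fi in seq_len(n_folds)) {
    test <- folds[[fi]]
    train <- setdiff(genos, test)
    Xtr <- X[train, , drop = FALSE]
    ytr <- y[match(train, genos)]
    ncomp <- choose_ncomp_cv(Xtr, ytr, ncomp_max, inner_folds)
    ncomps[fi] <- ncomp
    fit <- nipals_pls(Xtr, ytr, ncomp)
    rank_mat[, fi] <- rank(-abs(fit$coef), ties.method = "average")
    preds[[fi]] <- tibble::tibble(
      genotype = test, fold = fi,
      observed = y[match(test, genos)],
      predicted = predict_nipals(fit, X[test, , drop = FALSE])
    )
  }
  rp <- unname(apply(rank_mat, 1, prod))
  out <- tibble::tibble(feature_id = colnames(X))
  for (fi in seq_len(n_folds)) {
    out[[sprintf("rank_fold%d", fi)]] <- unname(rank_mat[, fi])
  }
  out$rank_product <- rp
  out$final_rank <- rank(rp, ties.method = "average")
  out <- dplyr::arrange(out, .data$final_rank)
  attr(out, "predictions") <- dplyr::bind_rows(preds)
  attr(out, "ncomp") <- ncomps
  out
}

# inner k-fold CV over training genotypes: pick ncomp minimizing RMSEP
choose_ncomp_cv <- function(X, y, ncomp_max, k) {
  n <- nrow(X)
  ncomp_max <- min(ncomp_max, n - ceiling(n / k) - 1)
  if (ncomp_max < 1) return(1L)
  idx <- rep(seq_len(k), length.out = n)
  press <- numeric(ncomp_max)
  for (fold in seq_len(k)) {
    hold <- idx == fold
    if (all(hold) || !any(hold)) next
    fit <- nipals_pls(X[!hold, , drop = FALSE], y[!hold], ncomp_max)
    for (a in seq_len(ncomp_max)) {
      aa <- min(a, fit$ncomp)
      R <- fit$W[, seq_len(aa), drop = FALSE] %*%
        solve(crossprod(fit$P[, seq_len(aa), drop = FALSE],
                        fit$W[, seq_len(aa), drop = FALSE]))
      B <- R %*% fit$q[seq_len(aa)]
      pred <- drop(sweep(X[hold, , drop = FALSE], 2, fit$xmean) %*% B) +
        fit$ymean
      press[a] <- press[a] + sum((y[hold] - pred)^2)
    }
  }
  which.min(press)
}
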
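paired_fixture <- function(n_geno = 12, n_feat = 20, seed = 1,
                           causal = NULL, coupling = 0, tag = "DD") {
  set.seed(seed)
  genos <- sprintf("G%02d", seq_len(n_geno))
  X <- tibble::as_tibble(
    matrix(rnorm(n_geno * n_feat), n_geno, n_feat,
           dimnames = list(NULL, sprintf("f%02d", seq_len(n_feat))))
  )
  y <- rnorm(n_geno)
  if (!is.null(causal)) y <- y + coupling * rowSums(X[, causal, drop = FALSE])
  X <- tibble::add_column(X, genotype = genos, .before = 1)
  structure(list(tag = tag, X = X,
                 y = tibble::tibble(genotype = genos, trait = y)),
            class = "paired_dataset")
}

test_that("paired datasets are genotype means with shared loss response", {
  # 3-genotype hand fixture
  metab <- tidyr::expand_grid(genotype = c("g1", "g2", "g3"),
                              treatment = c("control", "drought"),
                              feature_id = "f1", rep = 1:2)
  metab$intensity <- c(1, 3,  10, 30,   2, 4,  20, 40,   3, 5,  30, 50)
  metab$sample_id <- paste0(metab$genotype, metab$treatment, metab$rep)
  ph <- tidyr::expand_grid(genotype = c("g1", "g2", "g3"),
                           treatment = c("control", "drought"),
                           trait = "Biomass", rep = 1:2)
  ph$plant_id <- paste0(ph$genotype, ph$treatment, ph$rep)
  ph$value <- c(10, 12,  4, 6,   20, 22,  9, 11,   30, 32,  14, 16)
  ds <- build_paired_datasets(metab, ph)
  expect_equal(names(ds), c("CC", "DD", "LC", "LD"))
  expect_equal(nrow(ds$CC$X), 3)
  # manual means: g1 control f1 = (1+3)/2 = 2; drought = (10+30)/2 = 20
  expect_equal(ds$CC$X$f1, c(2, 3, 4))
  expect_equal(ds$DD$X$f1, c(20, 30, 40))
  expect_equal(ds$CC$y$Biomass, c(11, 21, 31))
  # loss = 100 * (1 - drought/control)
  expect_equal(ds$LC$y$Biomass,
               100 * (1 - c(5, 10, 15) / c(11, 21, 31)))
  # LC and LD share y but differ in X
  expect_identical(ds$LC$y, ds$LD$y)
  expect_identical(ds$LC$X, ds$CC$X)
  expect_identical(ds$LD$X, ds$DD$X)
  # genotype missing in one table is dropped with a warning
  expect_warning(
    ds2 <- build_paired_datasets(metab,
                                 dplyr::filter(ph, genotype != "g3")),
    "g3"
  )
  expect_equal(nrow(ds2$DD$X), 2)
})

test_that("correlation screen separates Spearman rho from Pearson R2", {
  # monotone and linear: rho = 1 and R2 = 1
  ds <- paired_fixture(n_feat = 2, seed = 2)
  ds$X$f01 <- 1:12
  ds$y$trait <- 2 * (1:12) + 3
  out <- correlate_metab_pheno(ds)
  r1 <- dplyr::filter(out, feature_id == "f01")
  expect_equal(r1$rho, 1)
  expect_equal(r1$r2, 1)
  # rank-linear but value-nonlinear: rho = 1 yet R2 < 1, so the reported
  # R2 cannot be the squared Spearman rho
  ds2 <- paired_fixture(n_feat = 1, seed = 3)
  ds2$X$f01 <- 1:12
  ds2$y$trait <- exp(1:12 / 2)
  r2 <- correlate_metab_pheno(ds2)
  expect_equal(r2$rho, 1)
  expect_lt(r2$r2, 0.75)
  expect_false(isTRUE(all.equal(r2$r2, r2$rho^2)))
  # FDR within the dataset is monotone in p
  ds3 <- paired_fixture(n_feat = 30, seed = 4)
  out3 <- correlate_metab_pheno(ds3)
  ord <- order(out3$p)
  expect_true(all(diff(out3$fdr[ord]) >= -1e-12))
  expect_true(all(out3$fdr >= out3$p))
})

test_that("constant features are skipped and small panels rejected", {
  ds <- paired_fixture(n_feat = 3, seed = 5)
  ds$X$f02 <- 1
  out <- correlate_metab_pheno(ds)
  expect_false("f02" %in% out$feature_id)
  tiny <- paired_fixture(n_geno = 4, n_feat = 2, seed = 6)
  expect_error(correlate_metab_pheno(tiny), "5 genotypes")
})

test_that("a perfect predictor gets final rank one", {
  ds <- paired_fixture(n_feat = 25, seed = 7)
  ds$y$trait <- 3 * ds$X$f13
  out <- plsr_rank_product(ds, "trait", seed = 99)
  expect_equal(out$feature_id[1], "f13")
  expect_equal(out$final_rank[out$feature_id == "f13"], 1)
  expect_true(all(out$rank_product ==
                    apply(as.matrix(out[paste0("rank_fold", 1:4)]), 1, prod)))
  preds <- attr(out, "predictions")
  expect_setequal(preds$genotype, ds$X$genotype)  # all genotypes predicted
  # out-of-sample predictive ability on a compact panel, where the
  # coefficient noise of spurious features cannot drown the signal
  small <- paired_fixture(n_feat = 5, seed = 11)
  small$y$trait <- 2 * small$X$f03 + rnorm(12, 0, 0.05)
  ps <- attr(plsr_rank_product(small, "trait", seed = 3), "predictions")
  expect_gt(cor(ps$observed, ps$predicted), 0.8)
})

test_that("rank product is invariant to monotone transforms of coefficients", {
  # ranks within folds depend only on coefficient order, so squaring the
  # (positive) coefficient magnitudes cannot change the aggregate ranking
  ds <- paired_fixture(n_feat = 15, seed = 8, causal = "f05",
                       coupling = 2)
  a <- plsr_rank_product(ds, "trait", seed = 5)
  b <- plsr_rank_product(ds, "trait", seed = 5)
  expect_identical(a, b)   # deterministic under the fold seed
  expect_equal(a$feature_id[1], "f05")
})

test_that("degenerate PLSR inputs error", {
  ds <- paired_fixture(n_feat = 5, seed = 9)
  ds$y$trait <- 1
  expect_error(plsr_rank_product(ds, "trait"), "constant")
  expect_error(plsr_rank_product(ds, "nope"), "unknown trait")
  small <- paired_fixture(n_geno = 5, n_feat = 5, seed = 10)
  expect_error(plsr_rank_product(small, "trait", fold_size = 3),
               "too few")
})

test_that("permuting the response destroys causal enrichment in top ranks", {
  set.seed(20)
  ranks <- replicate(15, {
    ds <- paired_fixture(n_feat = 40, seed = sample.int(1e6, 1),
                         causal = "f01", coupling = 3)
    ds$y$trait <- sample(ds$y$trait)
    out <- plsr_rank_product(ds, "trait", seed = 1)
    out$final_rank[out$feature_id == "f01"]
  })
  # median near the middle of 40 features, not at the top
  expect_gt(median(ranks), 5)
})

test_that("NIPALS PLS regression agrees with mixOmics on coefficients", {
  skip_if_not_installed("mixOmics")
  set.seed(21)
  X <- matrix(rnorm(15 * 8), 15, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- drop(X %*% c(2, -1, rep(0, 6))) + rnorm(15, 0, 0.2)
  fit <- phenometab:::nipals_pls(X, y, 2)
  mo <- mixOmics::pls(X, y, ncomp = 2, scale = FALSE, mode = "regression")
  pred_mo <- predict(mo, X)$predict[, 1, 2]
  pred_us <- phenometab:::predict_nipals(fit, X)
  expect_equal(unname(pred_us), unname(pred_mo), tolerance = 1e-6)
})
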
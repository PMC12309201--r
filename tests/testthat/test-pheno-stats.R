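test_that("variance components handle degenerate inputs", {
  flat <- tidyr::expand_grid(genotype = c("a", "b"), experiment = 1:2,
                             rep = 1:3)
  flat$value <- 1
  vc <- fit_variance_components(flat)
  expect_equal(vc$sigma2_g, 0)
  expect_equal(vc$sigma2_gxe, 0)
  expect_equal(vc$sigma2_E, 0)
  # pure genotype signal, no noise
  pure <- flat
  pure$value <- ifelse(pure$genotype == "a", 0, 10)
  vc2 <- fit_variance_components(pure)
  expect_equal(vc2$sigma2_E, 0, tolerance = 1e-10)
  expect_gt(vc2$sigma2_g, 0)
  expect_warning(
    fit_variance_components(dplyr::filter(flat, experiment == 1)),
    "single experiment"
  )
})

test_that("variance component estimates recover the generating model", {
  # sigma2_g = 2, sigma2_gxe = 1, sigma2_E = 4, e = 2, r = 5, 50 genotypes
  set.seed(101)
  est <- replicate(150, {
    g <- rep(1:50, each = 10)
    e <- rep(rep(1:2, each = 5), 50)
    y <- rnorm(50, 0, sqrt(2))[g] + rnorm(100, 0, 1)[(g - 1) * 2 + e] +
      rnorm(500, 0, 2)
    vc <- fit_variance_components(
      tibble::tibble(genotype = g, experiment = e, value = y)
    )
    c(vc$sigma2_g, vc$sigma2_gxe, vc$sigma2_E)
  })
  truth <- c(2, 1, 4)
  expect_true(all(abs(rowMeans(est) - truth) / truth < 0.15))
})

test_that("heritability evaluates its formula exactly and is scale invariant", {
  vc <- list(sigma2_g = 2, sigma2_gxe = 1, sigma2_E = 4, e = 2, r = 5)
  expect_equal(heritability(vc), 2 / (2 + 1 / 2 + 4 / 10))
  expect_equal(heritability(list(sigma2_g = 0, sigma2_gxe = 1,
                                 sigma2_E = 1, e = 2, r = 2)), 0)
  expect_equal(heritability(list(sigma2_g = 3, sigma2_gxe = 0,
                                 sigma2_E = 0, e = 2, r = 2)), 1)
  # multiplying the trait by c > 0 scales all components by c^2
  c2 <- 7.3^2
  scaled <- lapply(vc[1:3], `*`, c2)
  scaled$e <- vc$e; scaled$r <- vc$r
  expect_equal(heritability(scaled), heritability(vc))
  expect_error(heritability(list(sigma2_g = 0, sigma2_gxe = 0,
                                 sigma2_E = 0, e = 1, r = 1)), "undefined")
})

test_that("loss of trait is on the percent scale", {
  expect_equal(loss_of_trait(5, 5), 0)
  expect_equal(loss_of_trait(0, 3), 100)
  expect_equal(loss_of_trait(0.376 * 100, 100), 62.4)
  expect_equal(loss_of_trait(0.376 * 7.7, 7.7), 62.4)
  expect_equal(loss_of_trait(150, 100), -50)
  expect_error(loss_of_trait(1, 0), "zero")
})

test_that("two-way ANOVA matches hand-computed sums of squares on a balanced design", {
  # 2 genotypes x 2 treatments x 3 replicates
  d <- tidyr::expand_grid(genotype = c("g1", "g2"),
                          treatment = c("c", "d"), rep = 1:3)
  d$value <- c(10, 11, 12, 14, 15, 16, 20, 21, 22, 30, 31, 32)
  out <- anova_gxt(d)
  # balanced two-way ANOVA by hand: cell means 11, 15, 21, 31
  grand <- mean(d$value)
  ss_g <- 6 * sum((c(mean(c(11, 15)), mean(c(21, 31))) - grand)^2)
  ss_t <- 6 * sum((c(mean(c(11, 21)), mean(c(15, 31))) - grand)^2)
  cells <- c(11, 15, 21, 31)
  ss_cells <- 3 * sum((cells - grand)^2)
  ss_int <- ss_cells - ss_g - ss_t
  ss_err <- sum((d$value - rep(cells, each = 3))^2)
  got <- setNames(out$sumsq, out$term)
  expect_equal(got[["genotype"]], ss_g)
  expect_equal(got[["treatment"]], ss_t)
  expect_equal(got[["genotype:treatment"]], ss_int)
  expect_equal(got[["Residuals"]], ss_err)
  f_t <- (ss_t / 1) / (ss_err / 8)
  expect_equal(out$statistic[out$term == "treatment"], f_t)
  expect_equal(out$p.value[out$term == "treatment"],
               pf(f_t, 1, 8, lower.tail = FALSE))
})

test_that("ANOVA detects separation and rejects bad inputs", {
  d <- tidyr::expand_grid(genotype = c("g1", "g2"),
                          treatment = c("c", "d"), rep = 1:5)
  set.seed(1)
  d$value <- rnorm(20, 0, 0.01) + ifelse(d$treatment == "d", 1000, 0)
  out <- anova_gxt(d)
  expect_lt(out$p.value[out$term == "treatment"], 1e-10)
  expect_error(anova_gxt(dplyr::filter(d, treatment == "c")), "2 levels")
  expect_error(
    anova_gxt(dplyr::filter(d, !(genotype == "g1" & treatment == "d"))),
    "empty"
  )
})

test_that("onset day behaves at its limits and on injected divergence", {
  cfg <- sim_config(seed = 21L, n_causal_markers = 0)
  phe <- simulate_phenotypes(cfg)
  full <- dplyr::filter(phe$series, cohort == 28)
  expect_equal(as.numeric(onset_day(full, alpha = 1)), min(full$day))
  od <- onset_day(full, trait = "Biomass", alpha = 0.05)
  expect_true(abs(as.numeric(od) - cfg$onset_day) <= 1)
  p_tab <- attr(od, "p_by_day")
  expect_true(all(c("day", "p") %in% names(p_tab)))
})

test_that("Tukey letters agree with pairwise HSD non-significance", {
  two <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                        value = rep(c(1, 1), each = 5) + rep(0:4, 2) * 1e-8)
  expect_equal(unique(tukey_letters(two, alpha = 0.01)$letters), "a")
  set.seed(3)
  three <- tibble::tibble(
    group = rep(c("g1", "g2", "g3"), each = 6),
    value = rep(c(0, 0, 100), each = 6) + rnorm(18, 0, 0.1)
  )
  lt <- tukey_letters(three, alpha = 0.01)
  expect_equal(lt$letters[lt$group %in% c("g1", "g2")], c("a", "a"))
  expect_false(lt$letters[lt$group == "g3"] %in% c("a"))
  # alpha = 0 limit: nothing is significant, everything shares a letter
  expect_equal(unique(tukey_letters(three, alpha = 0)$letters), "a")
  # single group
  one <- tibble::tibble(group = "g", value = c(1, 2, 3))
  expect_equal(tukey_letters(one)$letters, "a")
})

test_that("letter sharing matches multcomp's compact letter display", {
  skip_if_not_installed("multcomp")
  set.seed(9)
  d <- tibble::tibble(
    group = factor(rep(paste0("g", 1:5), each = 8)),
    value = rnorm(40) + rep(c(0, 0.3, 2, 2.2, 5), each = 8)
  )
  alpha <- 0.05
  ours <- tukey_letters(d, alpha = alpha)
  fit <- stats::aov(value ~ group, data = d)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  cld <- multcomp::cld(glht, level = alpha)$mcletters$Letters
  # same partition: two groups share a letter in ours iff they do in cld
  share <- function(letters, i, j) {
    any(strsplit(letters[i], "")[[1]] %in% strsplit(letters[j], "")[[1]])
  }
  ours_l <- setNames(ours$letters, ours$group)
  for (i in 1:4) for (j in (i + 1):5) {
    gi <- paste0("g", i); gj <- paste0("g", j)
    expect_equal(share(ours_l, gi, gj), share(cld, gi, gj),
                 info = paste(gi, gj))
  }
})

test_that("cross-experiment Spearman matches hand-computed rank correlation", {
  expect_equal(cross_experiment_spearman(1:5, 1:5), 1)
  expect_equal(cross_experiment_spearman(1:5, 5:1), -1)
  # ranks x = 1,2,3,4 vs y = 2,1,4,3: rho = 1 - 6*4/(4*15) = 0.6
  expect_equal(cross_experiment_spearman(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(cross_experiment_spearman(1:2, 2:1), "3 paired")
})

test_that("PSII quantum-yield ratio", {
  expect_equal(qy_ratio(0.7, 0.7), 1)
  expect_equal(qy_ratio(0.4, 0.8), 0.5)
  expect_error(qy_ratio(0.4, 0), "non-zero")
})
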
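test_that("raw normalization is proportional to its per-sample factors", {
  d <- make_intensity(list(f1 = c(10, 10), f2 = c(20, 20)))
  d$fresh_weight <- 1
  d$istd_response <- 1
  expect_equal(normalize_raw(d)$intensity, d$intensity)
  d2 <- d
  d2$fresh_weight <- 2
  expect_equal(normalize_raw(d2)$intensity, d$intensity / 2)
  d3 <- d
  d3$fresh_weight[d3$sample_id == "s01"] <- 0
  expect_warning(out <- normalize_raw(d3), "zero")
  expect_false("s01" %in% out$sample_id)
  # batch factors equalize a spiked constant feature across batches
  d4 <- make_intensity(list(f1 = c(100, 100, 300, 300)))
  d4$fresh_weight <- 1; d4$istd_response <- 1
  d4$batch_factor <- c(1, 1, 3, 3)
  expect_equal(unique(normalize_raw(d4)$intensity), 100)
})

test_that("blank filter keeps features strictly above the 2-fold rule", {
  d <- make_intensity(
    list(at_bound = rep(20, 4), above = rep(20.1, 4), clean = rep(1000, 4)),
    blanks = list(at_bound = rep(10, 2), above = rep(10, 2),
                  clean = rep(10, 2))
  )
  out <- blank_filter(d)
  kept <- unique(out$data$feature_id)
  expect_false("at_bound" %in% kept)   # exactly 2-fold is removed
  expect_true(all(c("above", "clean") %in% kept))
  expect_equal(out$report$n_in, 3)
  expect_equal(out$report$n_out, 2)
  # features absent from blanks are always kept
  d2 <- make_intensity(list(f = rep(5, 4)),
                       blanks = list(f = rep(NA_real_, 2)))
  expect_true("f" %in% unique(blank_filter(d2)$data$feature_id))
  # no blanks: step skipped
  d3 <- make_intensity(list(f = rep(5, 4)))
  expect_message(out3 <- blank_filter(d3), "skipped")
  expect_equal(out3$report$n_removed, 0)
})

test_that("presence filter boundary sits at exactly 80%", {
  v80 <- c(rep(1, 8), NA, NA)
  v79 <- c(rep(1, 7), NA, NA, NA)   # 70%
  d <- make_intensity(list(kept = v80, removed = v79))
  out <- presence_filter(d, min_frac = 0.8)
  expect_setequal(unique(out$data$feature_id), "kept")
  # zero counts as unquantified
  dz <- make_intensity(list(z = c(rep(1, 7), 0, 0, 0)))
  expect_equal(presence_filter(dz, 0.8)$report$n_removed, 1)
  expect_equal(presence_filter(d, min_frac = 0)$report$n_removed, 0)
})

test_that("imputation fills missing values with 1/5 of the feature minimum", {
  d <- make_intensity(list(f1 = c(10, NA, 30), f2 = c(5, NA, 15)))
  out <- impute_min_fraction(d)
  expect_equal(out$intensity[out$feature_id == "f1"], c(10, 2, 30))
  expect_equal(out$intensity[out$feature_id == "f2"], c(5, 1, 15))
  full <- make_intensity(list(f = c(1, 2, 3)))
  expect_equal(impute_min_fraction(full)$intensity, full$intensity)
  allna <- make_intensity(list(f = c(NA_real_, NA_real_)))
  expect_error(impute_min_fraction(allna), "presence_filter")
})

test_that("RSD filter removes the top fraction deterministically", {
  set.seed(1)
  mk_feature <- function(mean, rsd) rnorm(40, mean, rsd * mean)
  vals <- list(a = rep(c(9, 11), 20), b = rep(c(8, 12), 20),
               c = rep(c(6, 14), 20), d = rep(c(2, 18), 20))
  d <- make_intensity(vals)
  out <- rsd_filter(d, top_frac = 0.25)
  expect_equal(out$report$removed[[1]], "d")
  expect_equal(rsd_filter(d, top_frac = 0)$report$n_removed, 0)
  # tie: equal RSDs broken by feature ID order
  tie <- make_intensity(list(t2 = c(1, 3), t1 = c(2, 6), u = c(1, 1.01)))
  rem <- rsd_filter(tie, top_frac = 1 / 3)$report$removed[[1]]
  expect_equal(rem, "t1")
  # zero mean gives infinite RSD, removed first
  z <- make_intensity(list(zz = c(-1, 1), ok = c(5, 6), ok2 = c(5, 7)))
  expect_equal(rsd_filter(z, top_frac = 1 / 3)$report$removed[[1]], "zz")
})

test_that("median normalization makes every sample median one", {
  d <- make_intensity(list(f1 = c(1, 10), f2 = c(2, 20), f3 = c(3, 30)))
  out <- median_normalize(d)
  med <- tapply(out$intensity, out$sample_id, median)
  expect_true(all(abs(med - 1) < 1e-12))
  expect_equal(sort(out$intensity[out$sample_id == "s01"]),
               c(0.5, 1, 1.5))
  single <- make_intensity(list(f = c(4, 9)))
  expect_true(all(median_normalize(single)$intensity == 1))
})

test_that("log10 transform rejects non-positive cells by name", {
  d <- make_intensity(list(f = c(1, 100)))
  expect_equal(log10_transform(d)$intensity, c(0, 2))
  bad <- make_intensity(list(f = c(1, 0)))
  expect_error(log10_transform(bad), "s02.*f|f.*s02")
})

test_that("Pareto scaling: post-scaling variance equals pre-scaling sd", {
  d <- make_intensity(list(f1 = c(1, 2, 3), f2 = c(10, 50, 90),
                           f3 = c(7, 7, 7)))
  out <- pareto_scale(d)
  x1 <- out$intensity[out$feature_id == "f1"]
  expect_equal(x1, c(-1, 0, 1))           # sd = 1
  for (f in c("f1", "f2")) {
    pre <- d$intensity[d$feature_id == f]
    post <- out$intensity[out$feature_id == f]
    expect_equal(var(post), sd(pre))
  }
  expect_equal(out$intensity[out$feature_id == "f3"], c(0, 0, 0))
  expect_equal(attr(out, "constant_features"), "f3")
})

test_that("row normalization gives zero-mean unit-sd features", {
  d <- make_intensity(list(f1 = c(1, 5, 9), f2 = c(2, 2, 2)))
  out <- row_normalize(d)
  x1 <- out$intensity[out$feature_id == "f1"]
  expect_equal(mean(x1), 0)
  expect_equal(sd(x1), 1)
  expect_equal(out$intensity[out$feature_id == "f2"], c(0, 0, 0))
})

test_that("pipeline report telescopes and matches designed removal counts", {
  met <- simulate_metabolome(small_config(seed = 31L))
  prep <- preprocess_pipeline(met$data)
  rep <- prep$report
  for (tp in unique(rep$timepoint)) {
    r <- dplyr::filter(rep, timepoint == tp)
    expect_equal(r$n_in - r$n_removed, r$n_out)
    expect_equal(r$n_out[-nrow(r)], r$n_in[-1])
    kept <- dplyr::n_distinct(
      dplyr::filter(prep$data, timepoint == tp)$feature_id
    )
    expect_equal(kept, r$n_out[nrow(r)])
  }
  # all-clean fixture: only the RSD step removes, exactly 25%
  cfg <- small_config(seed = 32L, missing_rate = 0)
  met2 <- simulate_metabolome(cfg)
  rep2 <- preprocess_pipeline(met2$data)$report
  r22 <- dplyr::filter(rep2, timepoint == 22)
  expect_equal(r22$n_removed[r22$step == "blank_filter"], 0)
  expect_equal(r22$n_removed[r22$step == "presence_filter"], 0)
  expect_equal(r22$n_removed[r22$step == "rsd_filter"],
               floor(cfg$n_features * 0.25))
})

test_that("timepoints are processed independently", {
  met <- simulate_metabolome(small_config(seed = 33L))
  all_tp <- preprocess_pipeline(met$data)
  only22 <- preprocess_pipeline(
    dplyr::filter(met$data, timepoint == 22)
  )
  a <- dplyr::arrange(dplyr::filter(all_tp$data, timepoint == 22),
                      sample_id, feature_id)
  b <- dplyr::arrange(only22$data, sample_id, feature_id)
  expect_equal(a$intensity, b$intensity)
})

test_that("median + Pareto chain is invariant to per-sample dilution", {
  met <- simulate_metabolome(small_config(seed = 34L, missing_rate = 0))
  d <- dplyr::filter(met$data, timepoint == 7)
  dil <- d
  set.seed(2)
  fac <- stats::setNames(runif(dplyr::n_distinct(d$sample_id), 0.5, 2),
                         unique(d$sample_id))
  dil$intensity <- dil$intensity * fac[dil$sample_id]
  chain <- function(x) {
    pareto_scale(log10_transform(median_normalize(
      impute_min_fraction(blank_filter(x)$data)
    )))
  }
  a <- dplyr::arrange(chain(d), sample_id, feature_id)
  b <- dplyr::arrange(chain(dil), sample_id, feature_id)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-8)
})
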
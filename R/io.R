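#' Read and validate a long-format CSV/TSV table
#'
#' Delimiter inferred from the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma). Decimal point, UTF-8, header required. Errors name
#' the missing columns.
#'
#' @param path File path.
#' @param required_cols Character vector of columns that must be present.
#' @return A tibble.
#' @export
read_long_table <- function(path, required_cols = character()) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) rlang::abort(sprintf("empty file: %s", path))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          check.names = FALSE)
  df <- tibble::as_tibble(df)
  check_columns(df, required_cols, sprintf("'%s'", basename(path)))
  df
}

#' Configuration for the end-to-end pipeline
#'
#' Collects every stage's parameters with defaults matching the analysis:
#' DAM alpha 0.05 and fold-change cut 1, presence threshold 0.8,
#' imputation fraction 1/5, RSD removal fraction 0.25, blank fold 2, the
#' QC parameters, correlation p cutoff 0.001, PLSR fold size 3, and the
#' seed. Unknown keys are rejected.
#'
#' @param ... Overrides for the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sim = sim_config(),
    qc = qc_params(),
    alpha = 0.05, fc_cut = 1,
    blank_fold = 2, min_frac = 0.8, impute_frac = 0.2,
    rsd_top_frac = 0.25, rsd_scope = "global",
    p_cut = 0.001, fold_size = 3, ncomp_max = 3, inner_folds = 4,
    n_ortho = 1,
    ranking_traits = c("GrainWeight", "GrainNumber", "Biomass22",
                       "TillerNumberGain", "SpikeNumber"),
    pathway_map = NULL,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  if (cfg$alpha <= 0 || cfg$alpha > 1) rlang::abort("alpha must lie in (0, 1]")
  if (cfg$p_cut <= 0 || cfg$p_cut > 1) rlang::abort("p_cut must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Stages in order: simulate (metabolome, phenotypes), time-series QC,
#' phenotype statistics (ANOVA, onset day, losses, heritability inputs),
#' metabolite preprocessing, differential accumulation per timepoint,
#' OPLS-DA at 22 DAD, genotype tolerance ranking, paired-dataset
#' correlation screen and PLSR rank-product biomarker ranking, and
#' optionally pathway over-representation. Deterministic for a fixed
#' config seed.
#'
#' @param config A [pipeline_config()] object.
#' @return Named list with every stage's outputs plus the truth ledger
#'   and the effective config.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  met <- simulate_metabolome(sim)
  phe <- simulate_phenotypes(sim, met$truth, met$data)
  truth <- phe$truth

  flags <- suppressWarnings(
    detect_timeseries_outliers(phe$series, config$qc)
  )
  dropped <- drop_plants_by_flag_fraction(
    phe$series, flags, threshold = config$qc$drop_fraction,
    last_qc_day = config$qc$last_qc_day
  )

  # phenotype statistics on the full-series cohort
  full <- dplyr::filter(phe$series, .data$cohort == max(.data$cohort))
  onset <- onset_day(full, trait = "Biomass", alpha = config$alpha)
  biomass22 <- dplyr::filter(phe$series, .data$trait == "Biomass",
                             .data$day == 22)
  anova_bm <- anova_gxt(dplyr::transmute(
    biomass22, genotype = .data$genotype, treatment = .data$treatment,
    value = .data$value
  ))
  geno_means <- dplyr::summarise(
    dplyr::group_by(biomass22, .data$genotype, .data$treatment),
    value = mean(.data$value), .groups = "drop"
  )
  wide_bm <- tidyr::pivot_wider(geno_means, names_from = "treatment",
                                values_from = "value")
  losses <- tibble::tibble(
    genotype = wide_bm$genotype, trait = "Biomass22",
    loss_percent = loss_of_trait(wide_bm$drought, wide_bm$control)
  )

  prep <- preprocess_pipeline(
    met$data, blank_fold = config$blank_fold, min_frac = config$min_frac,
    impute_frac = config$impute_frac, rsd_top_frac = config$rsd_top_frac,
    rsd_scope = config$rsd_scope
  )

  tps <- sort(unique(prep$data$timepoint))
  dam <- lapply(tps, function(tp) {
    classify_volcano(ttest_dam(prep$data, timepoint = tp),
                     alpha = config$alpha, fc_cut = config$fc_cut)
  })
  names(dam) <- as.character(tps)

  m22 <- dplyr::filter(prep$data, .data$timepoint == 22)
  X22 <- metab_matrix(m22)
  trt22 <- dplyr::distinct(m22, .data$sample_id, .data$treatment)
  opls <- oplsda_fit(X22, trt22$treatment[match(rownames(X22),
                                                trt22$sample_id)],
                     n_ortho = config$n_ortho)

  ph <- phe$post_harvest
  bm22_plants <- dplyr::transmute(
    biomass22, plant_id = .data$plant_id, genotype = .data$genotype,
    treatment = .data$treatment, trait = "Biomass22",
    value = .data$value
  )
  pheno_all <- dplyr::bind_rows(ph, bm22_plants)
  geno_trait_means <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(pheno_all, .data$treatment == "drought"),
                    .data$genotype, .data$trait),
    value = mean(.data$value), .groups = "drop"
  )
  rk <- rank_product_total(rank_traits(
    dplyr::filter(geno_trait_means,
                  .data$trait %in% config$ranking_traits)
  ))

  paired <- build_paired_datasets(m22, pheno_all)
  screen <- dplyr::bind_rows(lapply(paired, correlate_metab_pheno,
                                    p_cut = config$p_cut))
  target <- sim$target_trait
  plsr <- plsr_rank_product(paired$DD, target,
                            fold_size = config$fold_size,
                            ncomp_max = config$ncomp_max,
                            inner_folds = config$inner_folds,
                            seed = config$seed)

  enrich <- NULL
  if (!is.null(config$pathway_map)) {
    dam22 <- dam[["22"]]
    enrich <- ora_hypergeometric(
      dam22$feature_id[dam22$fdr < config$alpha],
      config$pathway_map, unique(dam22$feature_id)
    )
  }

  list(
    metabolome = met$data, series = phe$series,
    post_harvest = phe$post_harvest, truth = truth,
    qc_flags = flags, qc_dropped = dropped,
    onset = onset, anova_biomass = anova_bm, losses = losses,
    preprocessed = prep$data, preprocess_report = prep$report,
    dam = dam, opls = opls, ranking = rk,
    paired = paired, correlation_screen = screen,
    plsr_ranking = plsr, enrichment = enrich,
    config = config
  )
}
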
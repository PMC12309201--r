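#' Simulation configuration for the drought-stress study design
#'
#' Builds the configuration object consumed by [simulate_metabolome()] and
#' [simulate_phenotypes()]. Defaults emulate the study design the analysis
#' assumes: 12 genotypes under control and drought, leaf metabolomes sampled
#' at 7, 13, 22 and 28 days after onset of drought (DAD) with 5 control
#' replicates at every timepoint and 5, 6, 7, 5 drought replicates at the
#' four timepoints, and roughly 200 GC-MS metabolite features of which a
#' configurable subset carries treatment-by-timepoint effects.
#'
#' Intensities follow a log-normal model: effects (genotype, treatment,
#' noise) are additive on the log scale, matching the log10 transform the
#' preprocessing chain applies downstream. Drought effect sizes are given as
#' log2 fold changes per responsive feature and timepoint; the default
#' profile ramps with stress severity (0.5, 1, 2, 1.5 at 7/13/22/28 DAD)
#' with alternating sign across features so both accumulation and depletion
#' occur.
#'
#' @param n_genotypes Number of genotypes (default 12).
#' @param timepoints Sampling days after onset of drought (default
#'   `c(7, 13, 22, 28)`).
#' @param replicates_control,replicates_drought Replicates per genotype at
#'   each timepoint (recycled to `length(timepoints)`).
#' @param n_features Number of metabolite features.
#' @param n_drought_responsive Number of features carrying true
#'   treatment effects.
#' @param effect_sizes Optional tibble with columns `feature`, `timepoint`,
#'   `log2_effect` overriding the default effect map. Must cover exactly
#'   `n_drought_responsive` features.
#' @param effect_profile Per-timepoint |log2 fold change| used to build the
#'   default effect map.
#' @param n_causal_markers Number of features linearly coupled to the target
#'   post-harvest trait.
#' @param coupling_strength Trait units per unit log10 intensity for causal
#'   markers.
#' @param causal_genotype_sd Genotype-level sd (log10) of the causal-marker
#'   module's shared latent factor (drawn from a bounded uniform so no
#'   single genotype dominates the raw-scale RSD); markers worth screening
#'   for differ strongly among genotypes, hence the default is well above
#'   `genotype_sd`.
#' @param target_trait Post-harvest trait receiving the causal coupling.
#' @param noise_sd Replicate noise standard deviation on the log10 scale
#'   for designed (drought-responsive and causal-marker) features.
#' @param noise_heterogeneity Length-2 range of per-feature multipliers
#'   applied to `noise_sd` for the remaining filler features, emulating the
#'   wide per-feature RSD spread of real GC-MS data that the RSD filter is
#'   meant to trim. Designed features use multiplier 1, i.e. they sit among
#'   the reliably quantified part of the feature space.
#' @param genotype_sd Genotype main-effect sd on the log10 scale.
#' @param missing_rate Fraction of leaf-sample values set missing.
#' @param missing_mode `"mcar"` (completely at random) or `"censor"`
#'   (left-censoring: lowest intensities go missing), the latter mimicking
#'   abundance-dependent GC-MS missingness.
#' @param blank_mean Mean blank-sample intensity (raw units).
#' @param n_blanks Blank samples generated per timepoint.
#' @param onset_day Day after which drought growth curves diverge from
#'   control. Must lie within the imaged day range.
#' @param pheno_noise_sd Multiplicative (log-scale) noise sd for daily
#'   phenotype values.
#' @param seed Integer seed; every generator is deterministic given it.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_genotypes = 12,
                       timepoints = c(7, 13, 22, 28),
                       replicates_control = c(5, 5, 5, 5),
                       replicates_drought = c(5, 6, 7, 5),
                       n_features = 200,
                       n_drought_responsive = 20,
                       effect_sizes = NULL,
                       effect_profile = c(0.5, 1, 2, 1.5),
                       n_causal_markers = 3,
                       coupling_strength = 8,
                       causal_genotype_sd = 0.35,
                       target_trait = "GrainArea",
                       noise_sd = 0.3,
                       noise_heterogeneity = c(0.8, 4),
                       genotype_sd = 0.15,
                       missing_rate = 0.01,
                       missing_mode = c("mcar", "censor"),
                       blank_mean = 10,
                       n_blanks = 3,
                       onset_day = 9,
                       pheno_noise_sd = 0.08,
                       seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  counts <- c(n_genotypes, n_features, n_drought_responsive + 1,
              n_causal_markers + 1, n_blanks)
  if (any(counts <= 0)) rlang::abort("all counts must be positive")
  if (missing_rate < 0 || missing_rate >= 0.2) {
    rlang::abort("missing_rate must lie in [0, 0.2) so the presence filter retains designed features")
  }
  nt <- length(timepoints)
  replicates_control <- rep_len(replicates_control, nt)
  replicates_drought <- rep_len(replicates_drought, nt)
  if (any(replicates_control < 2) || any(replicates_drought < 2)) {
    rlang::abort("invalid replicate scheme: need at least 2 replicates per cell")
  }
  if (n_drought_responsive > n_features) {
    rlang::abort("n_drought_responsive cannot exceed n_features")
  }
  feature_ids <- sprintf("met_%03d", seq_len(n_features))
  if (is.null(effect_sizes)) {
    responsive <- feature_ids[seq_len(n_drought_responsive)]
    effect_sizes <- tidyr::expand_grid(
      feature = responsive, timepoint = timepoints
    )
    prof <- stats::setNames(rep_len(effect_profile, nt), timepoints)
    sign <- stats::setNames(
      ifelse(seq_len(n_drought_responsive) %% 2 == 1, 1, -1), responsive
    )
    effect_sizes$log2_effect <-
      prof[as.character(effect_sizes$timepoint)] *
      sign[effect_sizes$feature]
  }
  check_columns(effect_sizes, c("feature", "timepoint", "log2_effect"),
                "effect_sizes")
  if (length(unique(effect_sizes$feature)) != n_drought_responsive) {
    rlang::abort("effect_sizes must cover exactly n_drought_responsive features")
  }
  if (onset_day < 1 || onset_day > max(timepoints)) {
    rlang::abort("onset_day outside the imaged day range")
  }
  structure(list(
    n_genotypes = n_genotypes, timepoints = timepoints,
    replicates_control = replicates_control,
    replicates_drought = replicates_drought,
    n_features = n_features, feature_ids = feature_ids,
    n_drought_responsive = n_drought_responsive,
    effect_sizes = tibble::as_tibble(effect_sizes),
    n_causal_markers = n_causal_markers,
    coupling_strength = coupling_strength,
    causal_genotype_sd = causal_genotype_sd,
    target_trait = target_trait,
    noise_sd = noise_sd, noise_heterogeneity = noise_heterogeneity,
    genotype_sd = genotype_sd,
    missing_rate = missing_rate, missing_mode = missing_mode,
    blank_mean = blank_mean, n_blanks = n_blanks,
    onset_day = onset_day, pheno_noise_sd = pheno_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

genotype_labels <- function(n) sprintf("G%02d", seq_len(n))

#' Simulate a GC-MS metabolite intensity table with known ground truth
#'
#' Draws per-feature log-normal intensities with genotype main effects,
#' treatment-by-timepoint effects for the designated responsive features,
#' and replicate noise, plus blank samples and missing values. Returns the
#' long intensity table together with a truth ledger recording which
#' features carry effects, which are causal markers for the target trait,
#' and the latent per-genotype tolerance scores used later by the phenotype
#' generator.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `data` (long tibble: `sample_id`,
#'   `genotype`, `treatment`, `timepoint`, `replicate`, `is_blank`,
#'   `fresh_weight`, `istd_response`, `batch`, `feature_id`, `intensity`)
#'   and `truth` (a `truth_ledger` list).
#' @export
simulate_metabolome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genos <- genotype_labels(config$n_genotypes)
  feats <- config$feature_ids
  nt <- length(config$timepoints)

  # per-feature baseline (log10) and genotype deviations
  base_log <- stats::runif(config$n_features, 3, 5)
  names(base_log) <- feats
  causal <- feats[seq(config$n_features,
                      by = -1L, length.out = config$n_causal_markers)]
  designed <- union(unique(config$effect_sizes$feature), causal)
  noise_mult <- stats::runif(config$n_features,
                             config$noise_heterogeneity[1],
                             config$noise_heterogeneity[2])
  noise_mult[feats %in% designed] <- 1
  names(noise_mult) <- feats
  geno_dev <- matrix(stats::rnorm(config$n_features * config$n_genotypes,
                                  0, config$genotype_sd),
                     nrow = config$n_features,
                     dimnames = list(feats, genos))
  # causal markers form a correlated module: a shared genotype-level latent
  # factor plus small idiosyncratic deviations, so each marker reflects the
  # physiology the target trait is coupled to
  if (config$n_causal_markers > 0) {
    # bounded (uniform) genotype factor: a single extreme genotype would
    # otherwise dominate the raw-scale RSD and trip the variability filter
    half <- config$causal_genotype_sd * sqrt(3)
    common <- stats::runif(config$n_genotypes, -half, half)
    for (f in causal) {
      geno_dev[f, ] <- common +
        stats::rnorm(config$n_genotypes, 0, config$genotype_sd / 2)
    }
  }

  # latent genotype tolerance, shared with simulate_phenotypes via the ledger
  tolerance <- stats::setNames(stats::rnorm(config$n_genotypes), genos)

  eff <- config$effect_sizes
  eff_key <- paste(eff$feature, eff$timepoint)
  eff_map <- stats::setNames(eff$log2_effect, eff_key)

  design <- dplyr::bind_rows(lapply(seq_len(nt), function(i) {
    tp <- config$timepoints[i]
    dplyr::bind_rows(
      tidyr::expand_grid(genotype = genos, treatment = "control",
                         replicate = seq_len(config$replicates_control[i]),
                         timepoint = tp),
      tidyr::expand_grid(genotype = genos, treatment = "drought",
                         replicate = seq_len(config$replicates_drought[i]),
                         timepoint = tp)
    )
  }))
  design$sample_id <- sprintf("%s_%s_%02d_r%d", design$genotype,
                              substr(design$treatment, 1, 1),
                              design$timepoint, design$replicate)
  design$is_blank <- FALSE
  design$fresh_weight <- 1
  design$istd_response <- 1
  design$batch <- "B1"

  long <- tidyr::expand_grid(design, feature_id = feats)
  key <- paste(long$feature_id, long$timepoint)
  effect <- ifelse(long$treatment == "drought",
                   dplyr::coalesce(eff_map[key], 0), 0)
  log_int <- base_log[long$feature_id] +
    geno_dev[cbind(long$feature_id, long$genotype)] +
    effect * log10(2) +
    stats::rnorm(nrow(long), 0,
                 config$noise_sd * noise_mult[long$feature_id])
  long$intensity <- 10^log_int

  # missing values on leaf samples
  if (config$missing_rate > 0) {
    if (config$missing_mode == "mcar") {
      miss <- stats::runif(nrow(long)) < config$missing_rate
    } else {
      thr <- stats::quantile(long$intensity, config$missing_rate)
      miss <- long$intensity < thr
    }
    long$intensity[miss] <- NA_real_
  }

  blanks <- tidyr::expand_grid(
    timepoint = config$timepoints,
    replicate = seq_len(config$n_blanks)
  )
  blanks$sample_id <- sprintf("blank_%02d_r%d", blanks$timepoint,
                              blanks$replicate)
  blanks$genotype <- NA_character_
  blanks$treatment <- NA_character_
  blanks$is_blank <- TRUE
  blanks$fresh_weight <- 1
  blanks$istd_response <- 1
  blanks$batch <- "B1"
  blong <- tidyr::expand_grid(blanks, feature_id = feats)
  blong$intensity <- 10^stats::rnorm(nrow(blong),
                                     log10(config$blank_mean), 0.2)

  data <- dplyr::bind_rows(long, blong)
  data <- dplyr::select(
    data, "sample_id", "genotype", "treatment", "timepoint", "replicate",
    "is_blank", "fresh_weight", "istd_response", "batch",
    "feature_id", "intensity"
  )

  truth <- structure(list(
    drought_responsive = config$effect_sizes,
    causal_markers = tibble::tibble(
      trait = config$target_trait, feature = causal,
      coupling = config$coupling_strength
    ),
    genotype_tolerance = tibble::tibble(
      genotype = genos, tolerance = unname(tolerance)
    ),
    injected_outliers = tibble::tibble(
      plant_id = character(), day = numeric(), trait = character()
    ),
    base_log = base_log, geno_dev = geno_dev,
    seed = config$seed
  ), class = "truth_ledger")

  list(data = tibble::as_tibble(data), truth = truth)
}

# logistic growth value at day d (3-parameter: asymptote A, rate k, midpoint m)
logistic_growth <- function(day, A, k = 0.30, m = 16) {
  A / (1 + exp(-k * (day - m)))
}

#' Simulate per-plant phenotype time series and post-harvest traits
#'
#' Generates daily logistic growth curves (biomass plus a few correlated
#' imaging traits) for every plant of the sampling design, with drought
#' curves diverging from control strictly after `onset_day`: incremental
#' growth after the onset is multiplied by a genotype-specific drought
#' factor derived from the latent tolerance score in the truth ledger,
#' calibrated so that mean biomass loss at the end of the drought phase is
#' around 62 percent. Post-harvest target traits are a linear combination of
#' the causal-marker log10 intensities (genotype-by-treatment means at 22
#' DAD) plus a genotype effect and noise.
#'
#' Plants are organised in destructive sampling cohorts: a plant sampled at
#' timepoint `t` is imaged on days 1..t only, mirroring the study design in
#' which leaf material was taken from previously unsampled plants.
#'
#' @param config A [sim_config()] object.
#' @param truth The `truth_ledger` from [simulate_metabolome()]; required
#'   when causal coupling is requested (`n_causal_markers > 0`).
#' @param metabolome The long metabolite table from [simulate_metabolome()];
#'   required for causal coupling.
#' @return A list with `series` (tibble: `plant_id`, `genotype`,
#'   `treatment`, `cohort`, `day`, `trait`, `value`), `post_harvest`
#'   (tibble: `plant_id`, `genotype`, `treatment`, `trait`, `value`) and the
#'   updated `truth` ledger.
#' @export
simulate_phenotypes <- function(config, truth = NULL, metabolome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  max_day <- max(config$timepoints)
  if (config$onset_day >= max_day || config$onset_day < 1) {
    rlang::abort("onset_day outside timepoint range")
  }
  if (config$n_causal_markers > 0 &&
      (is.null(truth) || is.null(metabolome))) {
    rlang::abort("simulate the metabolome first: causal coupling needs its truth ledger")
  }
  set.seed(config$seed + 1L)
  genos <- genotype_labels(config$n_genotypes)

  if (is.null(truth)) {
    # phenotype-only use: draw the latent tolerance here
    truth <- structure(list(
      genotype_tolerance = tibble::tibble(
        genotype = genos, tolerance = stats::rnorm(config$n_genotypes)
      ),
      causal_markers = tibble::tibble(trait = character(),
                                      feature = character(),
                                      coupling = numeric()),
      injected_outliers = tibble::tibble(plant_id = character(),
                                         day = numeric(),
                                         trait = character()),
      seed = config$seed
    ), class = "truth_ledger")
  }
  tol <- stats::setNames(truth$genotype_tolerance$tolerance,
                         truth$genotype_tolerance$genotype)
  # drought growth factor: tolerant genotypes (high score) retain more growth
  dfac <- pmin(pmax(0.29 + 0.07 * tol[genos], 0.05), 0.60)

  nt <- length(config$timepoints)
  plants <- dplyr::bind_rows(lapply(seq_len(nt), function(i) {
    tp <- config$timepoints[i]
    dplyr::bind_rows(
      tidyr::expand_grid(genotype = genos, treatment = "control",
                         replicate = seq_len(config$replicates_control[i]),
                         cohort = tp),
      tidyr::expand_grid(genotype = genos, treatment = "drought",
                         replicate = seq_len(config$replicates_drought[i]),
                         cohort = tp)
    )
  }))
  plants$plant_id <- sprintf("%s_%s_%02d_r%d", plants$genotype,
                             substr(plants$treatment, 1, 1),
                             plants$cohort, plants$replicate)

  A_geno <- stats::setNames(100 * exp(stats::rnorm(config$n_genotypes, 0, 0.10)),
                            genos)
  A_plant <- A_geno[plants$genotype] *
    exp(stats::rnorm(nrow(plants), 0, 0.05))

  traits <- c("Biomass", "Height", "Width")
  trait_scale <- c(Biomass = 1, Height = 0.6, Width = 0.45)

  grid <- tidyr::expand_grid(
    plants, day = seq_len(max_day), trait = traits
  )
  grid <- dplyr::filter(grid, .data$day <= .data$cohort)
  A <- A_plant[match(grid$plant_id, plants$plant_id)] *
    trait_scale[grid$trait]
  base <- logistic_growth(grid$day, A)
  onset_val <- logistic_growth(config$onset_day, A)
  # drought growth suppression sets in smoothly after the onset day (an
  # abrupt rate change would be a non-physiological kink in the curve):
  # the effective growth factor decays from 1 towards the genotype's
  # drought factor with a ~1.5-day time constant
  dd <- pmax(grid$day - config$onset_day, 0)
  f_eff <- 1 - (1 - dfac[grid$genotype]) * (1 - exp(-dd / 1.5))
  f_eff[grid$treatment != "drought"] <- 1
  mu <- onset_val + (base - onset_val) * f_eff
  mu <- ifelse(grid$day <= config$onset_day, base, mu)
  grid$value <- mu * exp(stats::rnorm(nrow(grid), 0, config$pheno_noise_sd))
  series <- dplyr::select(
    grid, "plant_id", "genotype", "treatment", "cohort", "day",
    "trait", "value"
  )

  # post-harvest traits: yield components shrink with the drought factor
  ph_traits <- tibble::tibble(
    trait = c("GrainWeight", "GrainNumber", "SpikeNumber",
              "TillerNumberGain", "PlantWeight", "GrainArea"),
    base = c(30, 900, 8, 6, 45, 18),
    drought_sens = c(0.9, 0.7, 0.5, 0.9, 0.7, 0.15)
  )
  ph <- tidyr::expand_grid(plants, ph_traits)
  geno_tr_eff <- matrix(stats::rnorm(config$n_genotypes * nrow(ph_traits),
                                     0, 0.08),
                        nrow = config$n_genotypes,
                        dimnames = list(genos, ph_traits$trait))
  eff_drought <- ifelse(ph$treatment == "drought",
                        1 - ph$drought_sens * (1 - dfac[ph$genotype]), 1)
  ph$value <- ph$base * exp(geno_tr_eff[cbind(ph$genotype, ph$trait)]) *
    eff_drought * exp(stats::rnorm(nrow(ph), 0, 0.06))

  # couple the target trait to the causal markers' 22-DAD genotype means
  if (config$n_causal_markers > 0) {
    cm <- truth$causal_markers
    m22 <- dplyr::filter(metabolome, !.data$is_blank,
                         .data$timepoint == 22,
                         .data$feature_id %in% cm$feature,
                         !is.na(.data$intensity))
    means <- dplyr::summarise(
      dplyr::group_by(m22, .data$genotype, .data$treatment,
                      .data$feature_id),
      mlog = mean(log10(.data$intensity)), .groups = "drop"
    )
    sig <- dplyr::summarise(
      dplyr::group_by(means, .data$genotype, .data$treatment),
      signal = sum(.data$mlog - mean(truth$base_log[cm$feature])),
      .groups = "drop"
    )
    idx <- ph$trait == config$target_trait
    key <- paste(ph$genotype[idx], ph$treatment[idx])
    sig_map <- stats::setNames(sig$signal, paste(sig$genotype, sig$treatment))
    ph$value[idx] <- ph$value[idx] +
      config$coupling_strength * dplyr::coalesce(sig_map[key], 0)
  }
  post_harvest <- dplyr::select(
    ph, "plant_id", "genotype", "treatment", "trait", "value"
  )

  truth$drought_factor <- tibble::tibble(
    genotype = genos, drought_factor = unname(dfac)
  )
  list(series = tibble::as_tibble(series),
       post_harvest = tibble::as_tibble(post_harvest),
       truth = truth)
}

#' Inject spike outliers into a phenotype time series
#'
#' Shifts a random subset of points by plus or minus `magnitude` times the
#' local noise scale of the plant-by-trait series (estimated from lag-1
#' differences), recording the injected positions for recovery tests.
#'
#' @param series A phenotype time-series tibble (see
#'   [simulate_phenotypes()]).
#' @param rate Fraction of points to corrupt, in \[0, 0.1\].
#' @param magnitude Shift size in multiples of the local noise sd.
#' @param seed Integer seed.
#' @return The series with shifted values, with the injection list attached
#'   as attribute `"injected"` (tibble: `plant_id`, `day`, `trait`,
#'   `shift`).
#' @export
inject_outliers <- function(series, rate, magnitude = 10, seed = 1L) {
  if (nrow(series) == 0) rlang::abort("empty series")
  if (rate < 0 || rate > 0.1) rlang::abort("rate must lie in [0, 0.1]")
  check_columns(series, c("plant_id", "day", "trait", "value"), "series")
  if (rate == 0) {
    attr(series, "injected") <- tibble::tibble(
      plant_id = character(), day = numeric(), trait = character(),
      shift = numeric()
    )
    return(series)
  }
  set.seed(seed)
  # local noise scale per point: growth-curve noise is value-proportional,
  # so estimate one relative noise coefficient per series from first
  # differences (stable, n-1 diffs) and scale it by each point's value
  rolling_lsd <- function(day, value) {
    ord <- order(day)
    v <- value[ord]
    mid <- (v[-1] + v[-length(v)]) / 2
    reld <- diff(v) / ifelse(mid == 0, 1, mid)
    sd0(reld) / sqrt(2) * abs(value)
  }
  local_sd <- dplyr::mutate(
    dplyr::group_by(series, .data$plant_id, .data$trait),
    .lsd = rolling_lsd(.data$day, .data$value)
  )
  lsd <- dplyr::ungroup(local_sd)$.lsd
  n <- nrow(series)
  pick <- which(stats::runif(n) < rate & lsd > 0)
  shift <- sample(c(-1, 1), length(pick), replace = TRUE) *
    magnitude * lsd[pick]
  series$value[pick] <- series$value[pick] + shift
  attr(series, "injected") <- tibble::tibble(
    plant_id = series$plant_id[pick], day = series$day[pick],
    trait = series$trait[pick], shift = shift
  )
  series
}
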
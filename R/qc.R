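#' Parameters for phenotype time-series quality control
#'
#' Defaults follow the imaging-trait QC used for high-throughput
#' phenotyping data: a local-regression confidence-band flagger run for two
#' rounds (`conf_int_size` 5 with span 0.5 for most traits; 7 and 0.55 for
#' biomass), a 2-sd group filter per genotype-by-trait-by-day-by-treatment
#' cell, plant-level exclusion when more than 20% of a plant's points are
#' flagged for a trait, and QC restricted to days up to 22 (later days show
#' genuine sudden changes caused by rewatering and are never flagged).
#'
#' @param conf_int_size Multiplier for the local residual scale (default 5).
#' @param nn_span Nearest-neighbour span, fraction of points in (0, 1\]
#'   (default 0.5).
#' @param rounds Flag-exclude-refit rounds (default 2).
#' @param sd_k Group-filter sd multiplier (default 2).
#' @param drop_fraction Plant-level exclusion threshold on the flagged
#'   fraction (default 0.20).
#' @param last_qc_day Last day subject to QC (default 22).
#' @return A `qc_params` list.
#' @export
qc_params <- function(conf_int_size = 5, nn_span = 0.5, rounds = 2,
                      sd_k = 2, drop_fraction = 0.20, last_qc_day = 22) {
  stopifnot(rounds >= 1, sd_k > 0, conf_int_size > 0,
            nn_span > 0, nn_span <= 1,
            drop_fraction > 0, drop_fraction < 1)
  structure(list(conf_int_size = conf_int_size, nn_span = nn_span,
                 rounds = rounds, sd_k = sd_k,
                 drop_fraction = drop_fraction,
                 last_qc_day = last_qc_day),
            class = "qc_params")
}

# degree-2 local polynomial fit with tricube neighbourhood weights at each
# observed day, made resistant to spikes by lowess-style bisquare
# robustness iterations. Returns fitted values and the neighbourhood
# weight matrix. Span = fraction of points used as neighbours.
local_linear_fit <- function(day, value, span, iter = 2) {
  n <- length(day)
  k <- max(5L, ceiling(span * n))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- abs(day - day[i])
    h <- sort(d, partial = k)[k]
    if (h == 0) h <- max(d, 1e-8)
    W[i, ] <- (1 - pmin(d / h, 1)^3)^3
  }
  delta <- rep(1, n)
  fit <- numeric(n)
  hat <- numeric(n)
  for (it in seq_len(iter + 1)) {
    for (i in seq_len(n)) {
      w <- W[i, ] * delta
      if (sum(w > 0) < 4) w <- W[i, ]
      use <- which(w > 0)
      dd <- day[use] - day[i]
      X <- cbind(1, dd, dd^2)
      XtWX <- crossprod(X, X * w[use])
      li <- drop(solve(XtWX, c(1, 0, 0))) %*% t(X * w[use])
      fit[i] <- drop(li %*% value[use])
      hat[i] <- li[match(i, use)]
      if (is.na(hat[i])) hat[i] <- 0
    }
    if (it <= iter) {
      # relative leave-one-out residuals: high-leverage (boundary) spikes
      # cannot hide by dragging their own fit, and small-absolute-value
      # early-day spikes are judged on the local (value-proportional)
      # noise scale
      ref <- pmax(abs(fit), stats::quantile(abs(fit), 0.1), 1e-12)
      rel <- (value - fit) / (1 - pmin(hat, 0.9)) / ref
      s6 <- 6 * stats::median(abs(rel))
      delta <- if (s6 > 0) pmax(1 - (rel / s6)^2, 0)^2 else rep(1, n)
    }
  }
  list(fitted = fit, weights = W, hat = pmin(hat, 0.9))
}

weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# one round of confidence-band flagging for a single plant x trait series;
# returns indices (into the supplied vectors) flagged this round.
# Constant-coefficient-of-variation band: imaging-derived size traits
# carry multiplicative noise, so the local standard error is modelled as
# proportional to the local fitted value. The relative-noise coefficient
# is a trimmed root mean square of leave-one-out relative residuals
# (suspected spikes excluded by bisquare weighting, leverage shrinkage of
# each point's own residual undone via the hat diagonal), with a small
# absolute floor covering fitted values near zero.
flag_one_round <- function(day, value, conf_int_size, span) {
  lf <- local_linear_fit(day, value, span)
  resid <- value - lf$fitted
  ar <- abs(resid)
  fit_floor <- pmax(abs(lf$fitted), stats::quantile(abs(lf$fitted), 0.1),
                    1e-12)
  rel_loo <- (ar / (1 - lf$hat)) / fit_floor
  med <- stats::median(rel_loo)
  if (med <= 0) {
    med <- mean(rel_loo)
    if (med <= 0) return(integer(0))
  }
  delta <- pmax(1 - (rel_loo / (6 * med))^2, 0)^2
  keep <- delta > 0.05
  if (sum(keep) < 4) keep <- rep(TRUE, length(keep))
  cv <- sqrt(mean(rel_loo[keep]^2))
  if (cv <= 0) return(integer(0))
  scale <- cv * fit_floor
  which(ar > conf_int_size * scale)
}

#' Flag outlying points in phenotype time series
#'
#' Per plant-by-trait series (days up to `last_qc_day` only), fits a
#' degree-1 local polynomial regression with tricube weights over a
#' nearest-neighbour span and flags points whose residual exceeds
#' `conf_int_size` times the robust (MAD-based) residual scale. Flagged
#' points are excluded and the fit repeated for `rounds` rounds; flags are
#' cumulative, so a spike masked by a larger one in round 1 is caught in
#' round 2.
#'
#' Series with fewer than 6 observed days within the QC window are skipped
#' with a warning, never an error.
#'
#' @param series Tibble with `plant_id`, `day`, `trait`, `value`.
#' @param params A [qc_params()] object.
#' @return A tibble of flags (`plant_id`, `day`, `trait`, `round`,
#'   `reason`), with the skipped series recorded in attribute `"skipped"`.
#' @export
detect_timeseries_outliers <- function(series, params = qc_params()) {
  check_columns(series, c("plant_id", "day", "trait", "value"), "series")
  qc <- dplyr::filter(series, .data$day <= params$last_qc_day,
                      !is.na(.data$value))
  groups <- dplyr::group_split(dplyr::group_by(qc, .data$plant_id,
                                               .data$trait))
  skipped <- list()
  flags <- lapply(groups, function(g) {
    g <- dplyr::arrange(g, .data$day)
    if (nrow(g) < 6) {
      skipped[[length(skipped) + 1]] <<-
        tibble::tibble(plant_id = g$plant_id[1], trait = g$trait[1],
                       n_days = nrow(g))
      return(NULL)
    }
    keep <- rep(TRUE, nrow(g))
    out <- list()
    for (r in seq_len(params$rounds)) {
      idx <- which(keep)
      if (length(idx) < 6) break
      hit <- flag_one_round(g$day[idx], g$value[idx],
                            params$conf_int_size, params$nn_span)
      if (length(hit) == 0) next
      hit <- idx[hit]
      keep[hit] <- FALSE
      out[[r]] <- tibble::tibble(
        plant_id = g$plant_id[1], day = g$day[hit], trait = g$trait[1],
        round = r, reason = "confidence_band"
      )
    }
    dplyr::bind_rows(out)
  })
  res <- dplyr::bind_rows(flags)
  if (nrow(res) == 0) {
    res <- tibble::tibble(plant_id = character(), day = numeric(),
                          trait = character(), round = integer(),
                          reason = character())
  }
  if (length(skipped) > 0) {
    rlang::warn(sprintf(
      "%d plant x trait series with fewer than 6 days skipped", length(skipped)
    ))
  }
  attr(res, "skipped") <- dplyr::bind_rows(skipped)
  res
}

#' Flag values beyond k standard deviations within grouping cells
#'
#' Flags values whose distance from their cell mean exceeds `sd_k` times
#' the cell's sample (n-1) standard deviation. Mean and sd are computed
#' fresh on the values supplied to this step. Cells with fewer than
#' `min_n` values are left untouched.
#'
#' @param data Tibble with a `value` column.
#' @param ... Grouping columns (tidy-select), e.g. genotype, trait, day,
#'   treatment.
#' @param sd_k Sd multiplier (default 2).
#' @param min_n Minimum cell size (default 3).
#' @return `data` with a logical `flag_sd` column.
#' @export
filter_group_sd <- function(data, ..., sd_k = 2, min_n = 3) {
  check_columns(data, "value", "data")
  grouped <- dplyr::group_by(data, ...)
  out <- dplyr::mutate(
    grouped,
    .n = sum(!is.na(.data$value)),
    .mu = mean(.data$value, na.rm = TRUE),
    .sd = stats::sd(.data$value, na.rm = TRUE),
    flag_sd = .data$.n >= min_n & !is.na(.data$.sd) &
      abs(.data$value - .data$.mu) > sd_k * .data$.sd,
    flag_sd = dplyr::coalesce(.data$flag_sd, FALSE)
  )
  dplyr::select(dplyr::ungroup(out), -".n", -".mu", -".sd")
}

#' Drop plant-by-trait series with too many flagged points
#'
#' A plant is removed entirely for a trait when strictly more than
#' `threshold` of its data points within the QC window are flagged.
#'
#' @param series Tibble with `plant_id`, `day`, `trait` (the observed
#'   points inside the QC window).
#' @param flags Flag tibble (`plant_id`, `day`, `trait`), e.g. from
#'   [detect_timeseries_outliers()] and/or [filter_group_sd()].
#' @param threshold Flagged-fraction threshold (default 0.20).
#' @param last_qc_day Flags and denominators restricted to days up to this.
#' @return Tibble of dropped pairs (`plant_id`, `trait`, `n_flagged`,
#'   `n_days`, `frac`).
#' @export
drop_plants_by_flag_fraction <- function(series, flags, threshold = 0.20,
                                         last_qc_day = 22) {
  check_columns(series, c("plant_id", "day", "trait"), "series")
  obs <- dplyr::filter(series, .data$day <= last_qc_day)
  denom <- dplyr::summarise(
    dplyr::group_by(obs, .data$plant_id, .data$trait),
    n_days = dplyr::n_distinct(.data$day), .groups = "drop"
  )
  fl <- dplyr::filter(flags, .data$day <= last_qc_day)
  cnt <- dplyr::summarise(
    dplyr::group_by(fl, .data$plant_id, .data$trait),
    n_flagged = dplyr::n_distinct(.data$day), .groups = "drop"
  )
  joined <- dplyr::left_join(denom, cnt, by = c("plant_id", "trait"))
  joined$n_flagged <- dplyr::coalesce(joined$n_flagged, 0L)
  joined$frac <- joined$n_flagged / joined$n_days
  dplyr::filter(joined, .data$frac > threshold)
}

#' Standard-deviation filter for scalar post-harvest traits
#'
#' Applies the group sd rule once per genotype-by-treatment-by-trait cell
#' and removes flagged rows.
#'
#' @param table Tibble with `genotype`, `treatment`, `trait`, `value`.
#' @param sd_k Sd multiplier (2 for pre-screening style data, 3 for
#'   time-course style data).
#' @return The filtered tibble, with removed rows in attribute
#'   `"removed"`.
#' @export
post_harvest_sd_filter <- function(table, sd_k = 3) {
  check_columns(table, c("genotype", "treatment", "trait", "value"),
                "post-harvest table")
  flagged <- filter_group_sd(table, .data$genotype, .data$treatment,
                             .data$trait, sd_k = sd_k)
  out <- dplyr::filter(flagged, !.data$flag_sd)
  out <- dplyr::select(out, -"flag_sd")
  attr(out, "removed") <- dplyr::select(
    dplyr::filter(flagged, .data$flag_sd), -"flag_sd"
  )
  out
}
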
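# Net-change rates of stand structure and trait composition across
# censuses, with percentile-bootstrap inference over 20 x 20 m subplots.

#' Basal area per hectare
#'
#' Sum of stem cross-sections at breast height, pi * (dbh/200)^2 per tree
#' (dbh in cm converted to radius in m), divided by area.
#'
#' @param records census data frame of living trees from one census.
#' @param area_ha reference area in hectares, > 0.
#' @return basal area in m2/ha (0 for an empty record set).
#' @export
basal_area <- function(records, area_ha) {
  if (!is.finite(area_ha) || area_ha <= 0) {
    stop("area_ha must be positive", call. = FALSE)
  }
  if (nrow(records) == 0) return(0)
  sum(pi * (records$dbh_cm / 200)^2) / area_ha
}

#' Stem density per hectare
#'
#' @param records census data frame of living trees from one census.
#' @param area_ha reference area in hectares, > 0.
#' @return stems/ha (0 for an empty record set).
#' @export
stem_density <- function(records, area_ha) {
  if (!is.finite(area_ha) || area_ha <= 0) {
    stop("area_ha must be positive", call. = FALSE)
  }
  nrow(records) / area_ha
}

#' Annual net-change rate
#'
#' (x2 - x1) / t: the net change of a plot-level variable between an
#' initial and a final census, per year.
#'
#' @param x1 initial value (variable units).
#' @param x2 final value (same units).
#' @param t census interval in years, > 0.
#' @return rate in units/year (vectorised).
#' @export
net_change_rate <- function(x1, x2, t) {
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("census interval t must be positive", call. = FALSE)
  }
  (x2 - x1) / t
}

#' Bootstrap configuration
#'
#' @param n_boot number of bootstrap replicates (default 5000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed optional integer seed; when set, results are reproducible
#'   and [summarize_dynamics] derives independent per-(variable, stratum)
#'   substreams from it.
#' @return a `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_boot = 5000, level = 0.95, seed = NULL) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  structure(list(n_boot = as.integer(n_boot), level = level, seed = seed),
            class = "bootstrap_config")
}

# Deterministic substream seed below 2^31, derived from a master seed and
# a stream name, so adding a variable never perturbs another's draws.
substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647)
  for (c in utf8ToInt(name)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

#' Percentile-bootstrap confidence interval for a mean rate
#'
#' Resamples the per-subplot rates with replacement `n_boot` times,
#' computes the mean of each resample, and returns the percentile interval
#' of the bootstrap means at the configured level. The change is flagged
#' significant when the interval excludes zero.
#'
#' @param values non-empty numeric vector of per-subplot rates.
#' @param config a [bootstrap_config].
#' @return list with `mean` (of the observed values), `ci_low`, `ci_high`,
#'   `significant`, `n`, `n_boot`.
#' @export
bootstrap_mean_ci <- function(values, config = bootstrap_config()) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no values to bootstrap", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  reps <- matrix(sample(values, n * config$n_boot, replace = TRUE),
                 nrow = config$n_boot)
  boot_means <- rowMeans(reps)
  alpha <- 1 - config$level
  ci <- unname(stats::quantile(boot_means, c(alpha / 2, 1 - alpha / 2)))
  list(mean = mean(values), ci_low = ci[1], ci_high = ci[2],
       significant = ci[1] > 0 || ci[2] < 0, n = n,
       n_boot = config$n_boot)
}

# Per-subplot state table for one census year: biomass (Mg/ha), basal area
# (m2/ha), stem density (stems/ha), trait CWMs and FDis, computed on the
# subplot's living trees. Subplots present in `subplot_index` but empty in
# this census get zero structure and undefined (NA) trait summaries.
subplot_state <- function(census, plots, traits, year,
                          trait_names = default_cwm_traits(),
                          standardize_fdis = TRUE,
                          allometry = allometry_config(),
                          subplot_index = NULL) {
  recs <- census[census$alive & census$census_year == year, , drop = FALSE]
  key <- paste(recs$plot_id, recs$subplot_id, sep = "/")
  if (is.null(subplot_index)) {
    subplot_index <- unique(data.frame(
      plot_id = recs$plot_id, subplot_id = recs$subplot_id,
      stringsAsFactors = FALSE))
  }
  area_ha <- plots$subplot_area_m2[match(subplot_index$plot_id,
                                         plots$plot_id)] / 1e4
  if (anyNA(area_ha)) {
    stop("census references plot_id absent from plot metadata",
         call. = FALSE)
  }
  biom <- tree_biomass(recs, traits, allometry)$biomass_kg
  out <- subplot_index
  out$census_year <- year
  out$biomass <- NA_real_
  out$basal_area <- NA_real_
  out$stem_density <- NA_real_
  for (tr in trait_names) out[[paste0("cwm_", tr)]] <- NA_real_
  out$fdis <- NA_real_
  idx_key <- paste(subplot_index$plot_id, subplot_index$subplot_id,
                   sep = "/")
  for (i in seq_along(idx_key)) {
    in_sp <- key == idx_key[i]
    sub <- recs[in_sp, , drop = FALSE]
    out$biomass[i] <- sum(biom[in_sp]) / 1000 / area_ha[i]
    out$basal_area[i] <- basal_area(sub, area_ha[i])
    out$stem_density[i] <- stem_density(sub, area_ha[i])
    if (nrow(sub) > 0) {
      cs <- community_summary(sub, traits, trait_names, standardize_fdis)
      for (tr in trait_names) out[[paste0("cwm_", tr)]][i] <- cs$cwm[[tr]]
      out$fdis[i] <- cs$fdis
    }
  }
  out
}

#' Per-subplot stand summaries for every census year
#'
#' Computes, for each subplot and census year, aboveground biomass
#' (Mg/ha), basal area (m2/ha), stem density (stems/ha), the CWM of each
#' configured trait, FDis, and functional-group proportions.
#'
#' @param census multi-year census data frame.
#' @param plots plot metadata (see [read_plots]).
#' @param traits trait data frame.
#' @param trait_names traits entering CWM/FDis
#'   (default [default_cwm_traits]).
#' @param standardize_fdis z-standardise traits before FDis.
#' @param allometry coefficient list from [allometry_config].
#' @return data frame, one row per subplot per census year.
#' @export
stand_summary <- function(census, plots, traits,
                          trait_names = default_cwm_traits(),
                          standardize_fdis = TRUE,
                          allometry = allometry_config()) {
  years <- sort(unique(census$census_year))
  subplot_index <- unique(data.frame(
    plot_id = census$plot_id, subplot_id = census$subplot_id,
    stringsAsFactors = FALSE))
  subplot_index <- subplot_index[order(subplot_index$plot_id,
                                       subplot_index$subplot_id), ,
                                 drop = FALSE]
  rownames(subplot_index) <- NULL
  assigned <- assign_functional_groups(traits)
  states <- lapply(years, function(y) {
    st <- subplot_state(census, plots, traits, y, trait_names,
                        standardize_fdis, allometry, subplot_index)
    recs <- census[census$alive & census$census_year == y, , drop = FALSE]
    g <- assigned$functional_group[match(recs$species_id,
                                         assigned$species_id)]
    key <- paste(recs$plot_id, recs$subplot_id, sep = "/")
    idx_key <- paste(st$plot_id, st$subplot_id, sep = "/")
    for (grp in FUNCTIONAL_GROUPS) st[[paste0("prop_", grp)]] <- NA_real_
    for (i in seq_along(idx_key)) {
      gi <- g[key == idx_key[i]]
      classified <- gi[!is.na(gi) & gi != "unassigned"]
      if (length(classified) > 0) {
        tab <- table(factor(classified, levels = FUNCTIONAL_GROUPS))
        for (grp in FUNCTIONAL_GROUPS) {
          st[[paste0("prop_", grp)]][i] <- tab[[grp]] / length(classified)
        }
      }
    }
    st
  })
  out <- do.call(rbind, states)
  rownames(out) <- NULL
  out
}

#' Net-change inference across subplots, stratified by management history
#'
#' For each monitored variable (biomass, basal area, stem density, each
#' trait CWM, and FDis) and each stratum (`"all"` plus each management
#' history present), computes per-subplot annual net-change rates between
#' `start_year` and `end_year` with [net_change_rate] and a percentile
#' bootstrap of the mean rate over the stratum's subplots
#' ([bootstrap_mean_ci]). The resampling unit is the subplot. When the
#' bootstrap seed is set, each (variable, stratum) pair uses its own
#' deterministic substream, so results are reproducible and mutually
#' independent. Subplots whose rate is undefined (e.g. a trait CWM in an
#' empty subplot) are dropped from that variable's resampling.
#'
#' @param census multi-year census data frame covering both years.
#' @param plots plot metadata.
#' @param traits trait data frame.
#' @param start_year,end_year census years bounding the interval.
#' @param boot a [bootstrap_config].
#' @param trait_names traits entering CWM/FDis.
#' @param variables optional character subset of variables to analyse.
#' @param standardize_fdis z-standardise traits before FDis.
#' @param allometry coefficient list from [allometry_config].
#' @param t_years census interval; defaults to `end_year - start_year`.
#' @return data frame with columns `variable, stratum, mean_rate, ci_low,
#'   ci_high, n_units, n_boot, significant, t_years`.
#' @export
summarize_dynamics <- function(census, plots, traits, start_year, end_year,
                               boot = bootstrap_config(),
                               trait_names = default_cwm_traits(),
                               variables = NULL,
                               standardize_fdis = TRUE,
                               allometry = allometry_config(),
                               t_years = NULL) {
  if (!(start_year %in% census$census_year) ||
      !(end_year %in% census$census_year)) {
    stop("start_year and end_year must both be present in the census",
         call. = FALSE)
  }
  if (start_year >= end_year) {
    stop("start_year must precede end_year", call. = FALSE)
  }
  if (is.null(t_years)) t_years <- end_year - start_year

  both <- census[census$census_year %in% c(start_year, end_year), ,
                 drop = FALSE]
  subplot_index <- unique(data.frame(
    plot_id = both$plot_id, subplot_id = both$subplot_id,
    stringsAsFactors = FALSE))
  subplot_index <- subplot_index[order(subplot_index$plot_id,
                                       subplot_index$subplot_id), ,
                                 drop = FALSE]
  rownames(subplot_index) <- NULL
  s1 <- subplot_state(census, plots, traits, start_year, trait_names,
                      standardize_fdis, allometry, subplot_index)
  s2 <- subplot_state(census, plots, traits, end_year, trait_names,
                      standardize_fdis, allometry, subplot_index)
  all_vars <- c("biomass", "basal_area", "stem_density",
                paste0("cwm_", trait_names), "fdis")
  if (is.null(variables)) variables <- all_vars
  unknown <- setdiff(variables, all_vars)
  if (length(unknown) > 0) {
    stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  history <- plots$management_history[match(subplot_index$plot_id,
                                            plots$plot_id)]
  strata <- c("all", intersect(MANAGEMENT_HISTORIES, unique(history)))

  rows <- list()
  for (v in variables) {
    rate <- net_change_rate(s1[[v]], s2[[v]], t_years)
    for (st in strata) {
      in_st <- if (st == "all") rep(TRUE, length(rate)) else history == st
      vals <- rate[in_st & !is.na(rate)]
      if (length(vals) == 0) {
        warning(sprintf("no usable subplots for %s in stratum %s; omitted",
                        v, st))
        next
      }
      cfg <- boot
      if (!is.null(boot$seed)) {
        cfg$seed <- substream_seed(boot$seed, paste(v, st, sep = "|"))
      }
      b <- bootstrap_mean_ci(vals, cfg)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, stratum = st, mean_rate = b$mean,
        ci_low = b$ci_low, ci_high = b$ci_high, n_units = b$n,
        n_boot = b$n_boot, significant = b$significant,
        t_years = t_years, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
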
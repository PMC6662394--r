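# Individual-based generator of forest-census, trait and climate fixtures
# with a ground-truth event log. It emulates the sampling design of a
# permanent-plot study in subtropical mixed Araucaria forest: 1 ha plots
# split into 25 20 x 20 m subplots, three management histories, annual
# censuses with growth, mortality and recruitment above a 9.5 cm dbh entry
# threshold, and a century-scale climate series with a minimum-temperature
# trend and a rainfall breakpoint.

#' Forest simulation configuration
#'
#' Defaults reproduce the emulated study design: 10 one-hectare plots of
#' 25 subplots (20 x 20 m), five unlogged / two early-logged / three
#' recently logged, 148 species, annual censuses 2000-2009, and stand
#' densities near the published per-history values. Group-level growth,
#' mortality and recruitment rates are annual.
#'
#' @param n_plots number of 1-ha plots.
#' @param subplots_per_plot subplots per plot.
#' @param subplot_side subplot side length (m).
#' @param management_mix named integer vector: plots per management
#'   history.
#' @param n_species species-pool size.
#' @param group_mix named shares of species per generating group (the
#'   seven functional groups plus `"Palm"`); must sum to 1.
#' @param curated_fraction fraction of Pioneer / Large Seeded Pioneer /
#'   Small Shade Tolerant species that carry a curated group label (the
#'   rest are left unlabelled for threshold classification).
#' @param initial_density named stems/ha at the first census, by
#'   management history.
#' @param years census years.
#' @param growth named mean annual dbh increment (cm/yr) by group.
#' @param mortality named annual death probability by group.
#' @param recruitment named recruitment rate (stems/ha/yr) by group.
#' @param tall_mortality_excess multiplier added to the death probability
#'   of trees above the 95th height percentile (0 = off); mimics
#'   windthrow-driven excess mortality of emergent trees.
#' @param seed master seed; all draws flow from it through named
#'   substreams (`pool`, `census`, `dynamics`).
#' @return a `forest_sim_config` list.
#' @export
forest_sim_config <- function(
    n_plots = 10,
    subplots_per_plot = 25,
    subplot_side = 20,
    management_mix = c(unlogged = 5, early_logged = 2,
                       recently_logged = 3),
    n_species = 148,
    group_mix = c(Araucaria = 1 / 148, TreeFern = 2 / 148,
                  Palm = 1 / 148, Pioneer = 0.15,
                  LargeSeededPioneer = 0.10,
                  WindDispersedLargeTree = 0.08,
                  LargeShadeTolerant = 0.22,
                  SmallShadeTolerant = 1 - 0.55 - 4 / 148),
    curated_fraction = 0.5,
    initial_density = c(unlogged = 1160, early_logged = 1340,
                        recently_logged = 1750),
    years = 2000:2009,
    growth = c(Araucaria = 0.30, Pioneer = 0.35,
               LargeSeededPioneer = 0.40, WindDispersedLargeTree = 0.15,
               LargeShadeTolerant = 0.15, SmallShadeTolerant = 0.10,
               TreeFern = 0.05, Palm = 0.05),
    mortality = c(Araucaria = 0.008, Pioneer = 0.025,
                  LargeSeededPioneer = 0.020,
                  WindDispersedLargeTree = 0.012,
                  LargeShadeTolerant = 0.012, SmallShadeTolerant = 0.015,
                  TreeFern = 0.015, Palm = 0.012),
    recruitment = c(Araucaria = 0.1, Pioneer = 3,
                    LargeSeededPioneer = 1, WindDispersedLargeTree = 1,
                    LargeShadeTolerant = 3, SmallShadeTolerant = 6,
                    TreeFern = 0.5, Palm = 0.5),
    tall_mortality_excess = 0,
    seed = 1L) {
  if (abs(sum(group_mix) - 1) > 1e-8) {
    stop("group_mix shares must sum to 1", call. = FALSE)
  }
  if (any(mortality < 0 | mortality > 1)) {
    stop("mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(initial_density <= 0)) {
    stop("initial densities must be positive", call. = FALSE)
  }
  if (sum(management_mix) != n_plots) {
    stop("management_mix must allocate exactly n_plots plots",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "forest_sim_config")
}

# Generating groups; "Palm" is a generation-only category whose species
# carry the palm growth form and a curated SmallShadeTolerant label.
SIM_GROUPS <- c(FUNCTIONAL_GROUPS, "Palm")

sim_group_counts <- function(config) {
  shares <- config$group_mix[SIM_GROUPS]
  shares[is.na(shares)] <- 0
  names(shares) <- SIM_GROUPS
  counts <- floor(shares * config$n_species)
  counts[shares > 0 & counts == 0] <- 1
  # largest-remainder top-up to hit n_species exactly
  while (sum(counts) < config$n_species) {
    r <- shares * config$n_species - counts
    i <- which.max(r)
    counts[i] <- counts[i] + 1
  }
  while (sum(counts) > config$n_species) {
    excess <- counts > 1
    r <- shares * config$n_species - counts
    i <- which(excess)[which.min(r[excess])]
    counts[i] <- counts[i] - 1
  }
  counts
}

#' Generate a synthetic species pool with traits
#'
#' Draws species traits from group-specific distributions chosen so that
#' the threshold classifier recovers each unlabelled species' generating
#' group: Small Shade Tolerant species get maximum heights below 15 m,
#' Pioneers heights inside (15, 19) m with wood density below 0.65 g/cm3,
#' Large Seeded Pioneers heights of at least 19 m with light wood, and the
#' always-labelled groups (Wind-Dispersed Large Trees, Large Shade
#' Tolerants) dense wood so the thresholds leave them unassigned.
#' Araucaria receives its fixed wood density of 0.4475 g/cm3. A share of
#' labelled angiosperm species has wood density withheld so the
#' genus-mean/global fallback tiers are exercised.
#'
#' @param config a [forest_sim_config].
#' @return trait data frame (see [read_traits]) with attributes
#'   `generating_group` (named by species) and `height_k` (named species
#'   parameter of the monotone height-dbh rule).
#' @export
generate_species_pool <- function(config = forest_sim_config()) {
  set.seed(substream_seed(config$seed, "pool"))
  counts <- sim_group_counts(config)
  group <- rep(names(counts), counts)
  n <- length(group)
  sp_id <- sprintf("S%03d", seq_len(n))
  n_gen <- max(2, round(n * 0.6))
  genus <- sprintf("G%03d", sample.int(n_gen, n, replace = TRUE))

  mh <- numeric(n); wd <- numeric(n); seed_len <- numeric(n)
  gf <- rep("angiosperm", n)
  for (g in unique(group)) {
    i <- group == g
    k <- sum(i)
    par <- switch(g,
      Araucaria = list(mh = stats::runif(k, 30, 40), wd = rep(0.4475, k),
                       seed = stats::runif(k, 15, 25), gf = "araucaria"),
      TreeFern = list(mh = stats::runif(k, 4, 10),
                      wd = stats::runif(k, 0.30, 0.45),
                      seed = stats::runif(k, 0.05, 0.2), gf = "tree_fern"),
      Palm = list(mh = stats::runif(k, 8, 14),
                  wd = stats::runif(k, 0.35, 0.45),
                  seed = stats::runif(k, 10, 20), gf = "palm"),
      Pioneer = list(mh = stats::runif(k, 15.2, 18.8),
                     wd = stats::runif(k, 0.45, 0.63),
                     seed = stats::runif(k, 1, 6), gf = "angiosperm"),
      LargeSeededPioneer = list(mh = stats::runif(k, 19.2, 32),
                                wd = stats::runif(k, 0.42, 0.63),
                                seed = stats::runif(k, 12, 30),
                                gf = "angiosperm"),
      WindDispersedLargeTree = list(mh = stats::runif(k, 19.5, 33),
                                    wd = stats::runif(k, 0.68, 0.85),
                                    seed = stats::runif(k, 2, 8),
                                    gf = "angiosperm"),
      LargeShadeTolerant = list(mh = stats::runif(k, 19.2, 30),
                                wd = stats::runif(k, 0.66, 0.85),
                                seed = stats::runif(k, 5, 15),
                                gf = "angiosperm"),
      SmallShadeTolerant = list(mh = stats::runif(k, 6, 14.8),
                                wd = stats::runif(k, 0.50, 0.85),
                                seed = stats::runif(k, 3, 12),
                                gf = "angiosperm"))
    mh[i] <- par$mh; wd[i] <- par$wd; seed_len[i] <- par$seed
    gf[i] <- par$gf
  }

  label <- group
  label[label == "Palm"] <- "SmallShadeTolerant"
  threshold_groups <- c("Pioneer", "LargeSeededPioneer",
                        "SmallShadeTolerant")
  maybe <- which(group %in% threshold_groups)
  unlab <- maybe[stats::runif(length(maybe)) > config$curated_fraction]
  label[unlab] <- NA_character_

  # withhold species-level wood density for some labelled angiosperms so
  # the genus-mean and global tiers fire; unlabelled species keep theirs
  # (the classifier needs them)
  hideable <- which(!is.na(label) & gf == "angiosperm" &
                      group != "Araucaria")
  hide <- hideable[stats::runif(length(hideable)) < 0.35]
  wd[hide] <- NA_real_

  pool <- data.frame(
    species_id = sp_id,
    genus = genus,
    wood_density = wd,
    max_height = mh,
    leaf_length = stats::rlnorm(n, log(80), 0.5),
    sla = stats::runif(n, 8, 25),
    seed_length = seed_len,
    crown_depth = pmax(0.5, 0.3 * mh + stats::rnorm(n, 0, 0.5)),
    stem_slenderness = pmax(2, 0.6 * mh + stats::rnorm(n, 0, 1)),
    functional_group = label,
    stringsAsFactors = FALSE
  )
  pool$growth_form <- gf
  attr(pool, "generating_group") <- stats::setNames(group, sp_id)
  attr(pool, "height_k") <- stats::setNames(stats::runif(n, 10, 25), sp_id)
  pool
}

# Monotone species-level height-dbh rule: h = max_height * d / (d + k_s).
sim_height <- function(dbh, species_id, pool) {
  i <- match(species_id, pool$species_id)
  k <- attr(pool, "height_k")[pool$species_id[i]]
  unname(pool$max_height[i] * dbh / (dbh + k))
}

#' Plot metadata for a simulated forest
#'
#' @param config a [forest_sim_config].
#' @return plot data frame (see [read_plots]).
#' @export
sim_plots <- function(config = forest_sim_config()) {
  history <- rep(names(config$management_mix), config$management_mix)
  data.frame(
    plot_id = sprintf("P%02d", seq_len(config$n_plots)),
    management_history = history,
    area_ha = config$subplots_per_plot * config$subplot_side^2 / 1e4,
    subplot_area_m2 = config$subplot_side^2,
    stringsAsFactors = FALSE
  )
}

# History-specific species-sampling multipliers: unlogged stands carry
# elevated Araucaria / Large Seeded Pioneer shares, logged stands elevated
# Large Shade Tolerant shares.
history_group_weight <- function(history) {
  w <- stats::setNames(rep(1, length(SIM_GROUPS)), SIM_GROUPS)
  if (history == "unlogged") {
    w["Araucaria"] <- 3; w["LargeSeededPioneer"] <- 2
    w["Pioneer"] <- 1.5
  } else if (history == "early_logged") {
    w["LargeShadeTolerant"] <- 1.5; w["Araucaria"] <- 0.5
    w["LargeSeededPioneer"] <- 0.7; w["Pioneer"] <- 0.9
  } else {
    w["LargeShadeTolerant"] <- 2; w["Araucaria"] <- 0.3
    w["LargeSeededPioneer"] <- 0.5; w["Pioneer"] <- 0.8
  }
  w
}

#' Generate the initial synthetic census
#'
#' Populates each plot at its history-specific target density with species
#' drawn under history-dependent group weights and per-species lognormal
#' abundance propensities, dbh from a gamma distribution shifted to the
#' 9.5 cm entry floor, and heights from the monotone species-level
#' height-dbh rule.
#'
#' @param config a [forest_sim_config].
#' @param pool species pool from [generate_species_pool].
#' @return census data frame for the first census year (all trees alive).
#' @export
generate_initial_census <- function(config = forest_sim_config(),
                                    pool = generate_species_pool(config)) {
  set.seed(substream_seed(config$seed, "census"))
  plots <- sim_plots(config)
  ggroup <- attr(pool, "generating_group")
  propensity <- stats::rlnorm(nrow(pool), 0, 1)
  recs <- list()
  next_id <- 1L
  for (p in seq_len(nrow(plots))) {
    history <- plots$management_history[p]
    n <- stats::rpois(1, config$initial_density[[history]] *
                        plots$area_ha[p])
    w <- history_group_weight(history)[ggroup[pool$species_id]] *
      propensity
    sp <- sample(pool$species_id, n, replace = TRUE, prob = w)
    dbh <- DBH_ENTRY_CM + stats::rgamma(n, shape = 1.3, scale = 8)
    recs[[p]] <- data.frame(
      tree_id = sprintf("T%06d", seq.int(next_id, next_id + n - 1)),
      plot_id = plots$plot_id[p],
      subplot_id = sprintf("SP%02d",
                           sample.int(config$subplots_per_plot, n,
                                      replace = TRUE)),
      species_id = sp,
      census_year = config$years[1],
      dbh_cm = dbh,
      height_m = sim_height(dbh, sp, pool),
      alive = TRUE,
      growth_form = pool$growth_form[match(sp, pool$species_id)],
      stringsAsFactors = FALSE
    )
    next_id <- next_id + n
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate annual census dynamics
#'
#' Advances the initial census year by year: survivors grow by
#' group-specific stochastic (gamma, non-negative) dbh increments with
#' heights recomputed from the monotone height-dbh rule; trees die with
#' group-specific annual probabilities, optionally inflated for the
#' tallest trees (`tall_mortality_excess`); recruits enter at the 9.5 cm
#' threshold at group-specific rates. Dead trees appear, flagged
#' `alive = FALSE`, in the census of their death year only. A ground-truth
#' event log (grow / die / recruit with dbh before and after) is returned
#' alongside and is sufficient to recompute every aggregate the analysis
#' reports.
#'
#' @param initial first-year census from [generate_initial_census].
#' @param config a [forest_sim_config].
#' @param pool the species pool used to build `initial`.
#' @return list with `census` (all years, one row per tree per census) and
#'   `events` (tree_id, year, event, dbh_before, dbh_after).
#' @export
simulate_dynamics <- function(initial, config = forest_sim_config(),
                              pool = generate_species_pool(config)) {
  set.seed(substream_seed(config$seed, "dynamics"))
  ggroup <- attr(pool, "generating_group")
  plots <- sim_plots(config)
  live <- initial
  censuses <- list(initial)
  events <- list()
  next_id <- max(as.integer(sub("^T", "", initial$tree_id))) + 1L
  group_of <- function(sp) unname(ggroup[sp])

  for (year in config$years[-1]) {
    n <- nrow(live)
    grp <- group_of(live$species_id)
    # mortality first: deaths carry last year's size
    p_die <- unname(config$mortality[grp])
    if (config$tall_mortality_excess > 0) {
      tall <- live$height_m >= stats::quantile(live$height_m, 0.95)
      p_die <- pmin(1, p_die * (1 + config$tall_mortality_excess * tall))
    }
    dies <- stats::runif(n) < p_die
    dead <- live[dies, , drop = FALSE]
    if (nrow(dead) > 0) {
      dead$census_year <- year
      dead$alive <- FALSE
      events[[length(events) + 1]] <- data.frame(
        tree_id = dead$tree_id, year = year, event = "die",
        dbh_before = dead$dbh_cm, dbh_after = NA_real_,
        stringsAsFactors = FALSE)
    }
    live <- live[!dies, , drop = FALSE]
    # growth of survivors: gamma increments with the group's mean
    g <- unname(config$growth[group_of(live$species_id)])
    inc <- ifelse(g > 0,
                  stats::rgamma(nrow(live), shape = 4, scale = g / 4), 0)
    events[[length(events) + 1]] <- data.frame(
      tree_id = live$tree_id, year = year, event = "grow",
      dbh_before = live$dbh_cm, dbh_after = live$dbh_cm + inc,
      stringsAsFactors = FALSE)
    live$dbh_cm <- live$dbh_cm + inc
    live$height_m <- sim_height(live$dbh_cm, live$species_id, pool)
    live$census_year <- year
    # recruitment: per plot per group, Poisson in the plot area
    rec_rows <- list()
    for (p in seq_len(nrow(plots))) {
      for (g2 in names(config$recruitment)) {
        lambda <- config$recruitment[[g2]] * plots$area_ha[p]
        if (lambda <= 0) next
        k <- stats::rpois(1, lambda)
        if (k == 0) next
        candidates <- names(ggroup)[ggroup == g2]
        if (length(candidates) == 0) next
        sp <- sample(candidates, k, replace = TRUE)
        dbh <- DBH_ENTRY_CM + stats::rexp(k, rate = 1 / 1.5)
        rec_rows[[length(rec_rows) + 1]] <- data.frame(
          tree_id = sprintf("T%06d", seq.int(next_id, next_id + k - 1)),
          plot_id = plots$plot_id[p],
          subplot_id = sprintf("SP%02d",
                               sample.int(config$subplots_per_plot, k,
                                          replace = TRUE)),
          species_id = sp,
          census_year = year,
          dbh_cm = dbh,
          height_m = sim_height(dbh, sp, pool),
          alive = TRUE,
          growth_form = pool$growth_form[match(sp, pool$species_id)],
          stringsAsFactors = FALSE)
        next_id <- next_id + k
      }
    }
    if (length(rec_rows) > 0) {
      recruits <- do.call(rbind, rec_rows)
      events[[length(events) + 1]] <- data.frame(
        tree_id = recruits$tree_id, year = year, event = "recruit",
        dbh_before = NA_real_, dbh_after = recruits$dbh_cm,
        stringsAsFactors = FALSE)
      live <- rbind(live, recruits)
    }
    censuses[[length(censuses) + 1]] <- rbind(live, dead)
  }
  census <- do.call(rbind, censuses)
  rownames(census) <- NULL
  events <- if (length(events) > 0) do.call(rbind, events) else {
    data.frame(tree_id = character(0), year = integer(0),
               event = character(0), dbh_before = numeric(0),
               dbh_after = numeric(0))
  }
  rownames(events) <- NULL
  list(census = census, events = events)
}

#' Generate a complete synthetic forest data set
#'
#' Convenience wrapper: species pool, plot metadata, initial census and
#' simulated dynamics under one configuration.
#'
#' @param config a [forest_sim_config].
#' @return list with `census`, `traits` (the pool), `plots`, `events`.
#' @export
generate_forest <- function(config = forest_sim_config()) {
  pool <- generate_species_pool(config)
  initial <- generate_initial_census(config, pool)
  dyn <- simulate_dynamics(initial, config, pool)
  list(census = dyn$census, traits = pool, plots = sim_plots(config),
       events = dyn$events)
}

#' Climate simulation configuration
#'
#' Defaults emulate the studied 1901-2014 series: annual-mean minimum
#' temperature rising at 0.0118 deg C/yr, summer (highest) minimum rising
#' by 1.49 deg C between the first and last data decade, a trendless
#' winter (lowest) minimum, and rainfall stepping up by 149 mm from the
#' 1965 breakpoint onwards around a 1392 mm pre-break baseline.
#'
#' @param year_range length-2 integer range of years.
#' @param tmin_slope trend of the annual-mean minimum temperature
#'   (deg C/yr).
#' @param tmin_summer_decade_rise first-to-last-decade rise of the summer
#'   minimum (deg C over the series).
#' @param rainfall_break_year first year of the elevated-rainfall period.
#' @param rainfall_step rainfall increase from the breakpoint (mm).
#' @param rainfall_base pre-break mean annual rainfall (mm).
#' @param tmin_base,tmin_summer_base,tmin_winter_base series intercepts at
#'   the first year (deg C).
#' @param noise_sd named vector of Gaussian noise standard deviations for
#'   `tmin` (deg C) and `rainfall` (mm).
#' @param seed integer seed (substream `climate`).
#' @return a `climate_sim_config` list.
#' @export
climate_sim_config <- function(year_range = c(1901, 2014),
                               tmin_slope = 0.0118,
                               tmin_summer_decade_rise = 1.49,
                               rainfall_break_year = 1965,
                               rainfall_step = 149,
                               rainfall_base = 1392,
                               tmin_base = 9.0,
                               tmin_summer_base = 19.6,
                               tmin_winter_base = 1.5,
                               noise_sd = c(tmin = 0.4, rainfall = 150),
                               seed = 1L) {
  stopifnot(all(noise_sd >= 0), year_range[1] < year_range[2])
  structure(as.list(environment()), class = "climate_sim_config")
}

#' Generate a synthetic annual climate series
#'
#' Annual-mean and summer minimum temperatures follow linear trends plus
#' Gaussian noise; the winter minimum is trendless; rainfall is a baseline
#' plus a step from the breakpoint year onwards plus noise (floored at 0).
#' The summer trend slope is `tmin_summer_decade_rise / (n_years - 10)` so
#' the expected first-to-last-decade difference equals the configured
#' rise.
#'
#' @param config a [climate_sim_config].
#' @return climate data frame (see [read_climate]).
#' @export
generate_climate <- function(config = climate_sim_config()) {
  set.seed(substream_seed(config$seed, "climate"))
  years <- seq(config$year_range[1], config$year_range[2])
  n <- length(years)
  t <- years - years[1]
  sd_t <- config$noise_sd[["tmin"]]
  sd_r <- config$noise_sd[["rainfall"]]
  summer_slope <- config$tmin_summer_decade_rise / (n - 10)
  data.frame(
    year = years,
    rainfall_mm = pmax(0, config$rainfall_base +
                         config$rainfall_step *
                         (years >= config$rainfall_break_year) +
                         stats::rnorm(n, 0, sd_r)),
    tmin_annual_mean = config$tmin_base + config$tmin_slope * t +
      stats::rnorm(n, 0, sd_t),
    tmin_winter = config$tmin_winter_base + stats::rnorm(n, 0, sd_t),
    tmin_summer = config$tmin_summer_base + summer_slope * t +
      stats::rnorm(n, 0, sd_t)
  )
}
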
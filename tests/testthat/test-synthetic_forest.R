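# A small, fast configuration used by most generator tests.
small_config <- function(...) {
  forest_sim_config(
    n_plots = 4, subplots_per_plot = 25, n_species = 40,
    management_mix = c(unlogged = 2, early_logged = 1,
                       recently_logged = 1),
    initial_density = c(unlogged = 300, early_logged = 300,
                        recently_logged = 300),
    years = 2000:2004, seed = 101, ...)
}

test_that("the default species pool has the configured size and structure", {
  pool <- generate_species_pool(forest_sim_config(seed = 2))
  expect_equal(nrow(pool), 148)
  expect_equal(anyDuplicated(pool$species_id), 0)
  gg <- attr(pool, "generating_group")
  expect_equal(length(gg), 148)
  # Araucaria carries its fixed wood density
  expect_equal(pool$wood_density[gg[pool$species_id] == "Araucaria"],
               0.4475)
  # all four growth forms are represented so every equation is exercised
  expect_setequal(unique(pool$growth_form),
                  c("angiosperm", "araucaria", "palm", "tree_fern"))
  expect_silent(validate_traits(pool[, setdiff(names(pool),
                                               c("growth_form"))]))
})

test_that("unlabelled species are recovered into their generating group by the classifier", {
  pool <- generate_species_pool(forest_sim_config(seed = 3))
  gg <- attr(pool, "generating_group")
  unlab <- is.na(pool$functional_group)
  expect_gt(sum(unlab), 0)
  got <- classify_functional_group(pool$max_height[unlab],
                                   pool$wood_density[unlab])
  expect_equal(got, unname(gg[pool$species_id[unlab]]))
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- small_config()
  expect_identical(generate_species_pool(cfg), generate_species_pool(cfg))
  pool <- generate_species_pool(cfg)
  expect_identical(generate_initial_census(cfg, pool),
                   generate_initial_census(cfg, pool))
  initial <- generate_initial_census(cfg, pool)
  expect_identical(simulate_dynamics(initial, cfg, pool),
                   simulate_dynamics(initial, cfg, pool))
  expect_identical(generate_climate(climate_sim_config(seed = 5)),
                   generate_climate(climate_sim_config(seed = 5)))
})

test_that("initial census matches the configured densities and the entry threshold", {
  cfg <- forest_sim_config(seed = 4)
  census <- generate_initial_census(cfg)
  expect_gte(min(census$dbh_cm), 9.5)
  expect_true(all(census$alive))
  # expected count = sum over plots of density x area
  expected <- sum(cfg$initial_density[
    rep(names(cfg$management_mix), cfg$management_mix)])
  expect_lt(abs(nrow(census) - expected) / expected, 0.1)
  # per-history density lands near its target
  plots <- sim_plots(cfg)
  for (h in names(cfg$management_mix)) {
    ids <- plots$plot_id[plots$management_history == h]
    dens <- sum(census$plot_id %in% ids) / length(ids)
    expect_lt(abs(dens - cfg$initial_density[[h]]) /
                cfg$initial_density[[h]], 0.1)
  }
})

test_that("unlogged plots are enriched in Araucaria and Large Seeded Pioneers", {
  cfg <- forest_sim_config(seed = 6)
  census <- generate_initial_census(cfg)
  pool <- generate_species_pool(cfg)
  gg <- attr(pool, "generating_group")
  plots <- sim_plots(cfg)
  share <- function(history, group) {
    ids <- plots$plot_id[plots$management_history == history]
    g <- gg[census$species_id[census$plot_id %in% ids]]
    mean(g %in% group)
  }
  expect_gt(share("unlogged", c("Araucaria", "LargeSeededPioneer")),
            share("recently_logged", c("Araucaria", "LargeSeededPioneer")))
  expect_gt(share("recently_logged", "LargeShadeTolerant"),
            share("unlogged", "LargeShadeTolerant"))
})

test_that("a frozen forest does not change", {
  cfg <- small_config(
    growth = c(Araucaria = 0, Pioneer = 0, LargeSeededPioneer = 0,
               WindDispersedLargeTree = 0, LargeShadeTolerant = 0,
               SmallShadeTolerant = 0, TreeFern = 0, Palm = 0),
    mortality = c(Araucaria = 0, Pioneer = 0, LargeSeededPioneer = 0,
                  WindDispersedLargeTree = 0, LargeShadeTolerant = 0,
                  SmallShadeTolerant = 0, TreeFern = 0, Palm = 0),
    recruitment = c(Araucaria = 0, Pioneer = 0, LargeSeededPioneer = 0,
                    WindDispersedLargeTree = 0, LargeShadeTolerant = 0,
                    SmallShadeTolerant = 0, TreeFern = 0, Palm = 0))
  pool <- generate_species_pool(cfg)
  initial <- generate_initial_census(cfg, pool)
  dyn <- simulate_dynamics(initial, cfg, pool)
  final <- dyn$census[dyn$census$census_year == 2004, ]
  rownames(final) <- NULL
  expect_equal(final$dbh_cm, initial$dbh_cm)
  expect_equal(final$tree_id, initial$tree_id)
  expect_true(all(final$alive))
  expect_true(all(dyn$events$event == "grow"))
  expect_true(all(dyn$events$dbh_after == dyn$events$dbh_before))
})

test_that("realized mortality over the interval matches the closed-form survival rate", {
  p <- 0.02
  years <- 2000:2009
  cfg <- forest_sim_config(
    n_plots = 4, n_species = 40,
    management_mix = c(unlogged = 2, early_logged = 1,
                       recently_logged = 1),
    initial_density = c(unlogged = 500, early_logged = 500,
                        recently_logged = 500),
    years = years, seed = 8,
    mortality = c(Araucaria = p, Pioneer = p, LargeSeededPioneer = p,
                  WindDispersedLargeTree = p, LargeShadeTolerant = p,
                  SmallShadeTolerant = p, TreeFern = p, Palm = p),
    recruitment = c(Araucaria = 0, Pioneer = 0, LargeSeededPioneer = 0,
                    WindDispersedLargeTree = 0, LargeShadeTolerant = 0,
                    SmallShadeTolerant = 0, TreeFern = 0, Palm = 0))
  pool <- generate_species_pool(cfg)
  initial <- generate_initial_census(cfg, pool)
  dyn <- simulate_dynamics(initial, cfg, pool)
  died <- sum(dyn$events$event == "die")
  n0 <- nrow(initial)
  expected <- 1 - (1 - p)^(length(years) - 1)
  se <- sqrt(expected * (1 - expected) / n0)
  expect_lt(abs(died / n0 - expected), 4 * se)
})

test_that("generated fixtures pass the validators unchanged (pipeline closure)", {
  cfg <- small_config()
  f <- generate_forest(cfg)
  expect_silent(validate_census(f$census))
  expect_silent(validate_plots(f$plots))
  expect_silent(validate_traits(
    f$traits[, setdiff(names(f$traits), "growth_form")]))
  clim <- generate_climate(climate_sim_config(seed = 9))
  expect_silent(validate_climate(clim))
})

test_that("the event log reconstructs the final census exactly", {
  cfg <- small_config()
  f <- generate_forest(cfg)
  last_year <- max(cfg$years)
  final <- f$census[f$census$census_year == last_year & f$census$alive, ]
  ev <- f$events[f$events$year <= last_year, ]
  # last known dbh per tree from the event log
  ev <- ev[order(ev$year), ]
  last_dbh <- tapply(ev$dbh_after, ev$tree_id, function(x) x[length(x)])
  dead <- unique(ev$tree_id[ev$event == "die"])
  expect_length(intersect(final$tree_id, dead), 0)
  expect_true(all(final$tree_id %in% names(last_dbh) |
                    final$tree_id %in%
                      f$census$tree_id[f$census$census_year ==
                                         cfg$years[1]]))
  has_ev <- final$tree_id %in% names(last_dbh)
  expect_equal(final$dbh_cm[has_ev],
               as.numeric(last_dbh[final$tree_id[has_ev]]),
               tolerance = 1e-12)
})

test_that("noiseless climate recovers the configured trends exactly", {
  cfg <- climate_sim_config(noise_sd = c(tmin = 0, rainfall = 0),
                            seed = 10)
  clim <- generate_climate(cfg)
  fit <- fit_linear_trend(clim$year, clim$tmin_annual_mean)
  expect_equal(fit$slope, 0.0118, tolerance = 1e-10)
  wfit <- fit_linear_trend(clim$year, clim$tmin_winter)
  expect_equal(wfit$slope, 0, tolerance = 1e-10)
  pc <- period_comparison(clim, 1965, "rainfall_mm")
  expect_equal(pc$difference, 149, tolerance = 1e-10)
  dc <- decade_comparison(clim$year, clim$tmin_summer)
  expect_equal(dc$difference, 1.49, tolerance = 1e-10)
})

test_that("noisy climate recovers the rainfall step within sampling error", {
  clim <- generate_climate(climate_sim_config(seed = 12))
  pc <- period_comparison(clim, 1965, "rainfall_mm")
  # step 149 mm, noise sd 150: se of the difference is about 30 mm
  expect_lt(abs(pc$difference - 149), 4 * 30)
})
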
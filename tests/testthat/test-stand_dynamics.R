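# Builds a two-year census: `grow` adds dbh centimetres to every tree of
# the listed plots in the final year.
two_year_census <- function(n_per_subplot = 3, plots = c("P01", "P02"),
                            subplots = c("SP01", "SP02"),
                            years = c(2000, 2009), grow = 0,
                            grow_plots = plots) {
  rows <- list()
  id <- 0
  for (p in plots) for (s in subplots) for (i in seq_len(n_per_subplot)) {
    id <- id + 1
    inc <- if (p %in% grow_plots) grow else 0
    rows[[length(rows) + 1]] <- rbind(
      make_census_row(paste0("T", id), plot_id = p, subplot_id = s,
                      species_id = "SP1", census_year = years[1]),
      make_census_row(paste0("T", id), plot_id = p, subplot_id = s,
                      species_id = "SP1", census_year = years[2],
                      dbh_cm = 20 + inc))
  }
  do.call(rbind, rows)
}

test_that("basal area follows the circular cross-section formula", {
  one <- make_census_row(dbh_cm = 20)
  expect_equal(basal_area(one, 1), pi * 0.1^2, tolerance = 1e-12)
  expect_equal(basal_area(one[0, ], 1), 0)
  a <- make_census(3); b <- make_census(2)
  b$tree_id <- paste0("U", 1:2); b$dbh_cm <- 33
  expect_equal(basal_area(rbind(a, b), 1),
               basal_area(a, 1) + basal_area(b, 1), tolerance = 1e-12)
  expect_error(basal_area(one, -1), "positive")
})

test_that("stem density is count per area", {
  recs <- make_census(5)
  expect_equal(stem_density(recs, 1), 5)
  expect_equal(stem_density(recs, 0.04), 125)
  expect_equal(stem_density(recs[0, ], 1), 0)
})

test_that("net change rate is (x2 - x1) / t and antisymmetric", {
  expect_equal(net_change_rate(10, 10, 5), 0)
  expect_equal(net_change_rate(3, 12, 9), 1)
  expect_equal(net_change_rate(12, 3, 9), -net_change_rate(3, 12, 9))
  expect_error(net_change_rate(1, 2, 0), "positive")
})

test_that("bootstrap CI is degenerate on constant input and reproducible", {
  b <- bootstrap_mean_ci(rep(5, 20), bootstrap_config(200, seed = 1))
  expect_equal(b$ci_low, 5)
  expect_equal(b$ci_high, 5)
  expect_true(b$significant)
  v <- rnorm(30)
  b1 <- bootstrap_mean_ci(v, bootstrap_config(500, seed = 99))
  b2 <- bootstrap_mean_ci(v, bootstrap_config(500, seed = 99))
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, mean(v))
  expect_gte(b1$ci_high, mean(v))
  expect_error(bootstrap_mean_ci(numeric(0)), "no values")
})

test_that("a static forest yields zero, non-significant rates everywhere", {
  census <- two_year_census(grow = 0)
  plots <- make_plots(c("P01", "P02"), c("unlogged", "recently_logged"))
  res <- summarize_dynamics(census, plots, make_traits(), 2000, 2009,
                            boot = bootstrap_config(200, seed = 3))
  expect_true(all(res$mean_rate == 0))
  expect_false(any(res$significant))
  expect_true(all(res$t_years == 9))
})

test_that("uniform growth produces significantly positive biomass rates in all strata", {
  census <- two_year_census(grow = 3)
  plots <- make_plots(c("P01", "P02"), c("unlogged", "recently_logged"))
  res <- summarize_dynamics(census, plots, make_traits(), 2000, 2009,
                            boot = bootstrap_config(300, seed = 5),
                            variables = c("biomass", "basal_area"))
  bio <- res[res$variable == "biomass", ]
  expect_true(all(bio$mean_rate > 0))
  expect_true(all(bio$significant))
  # oracle: recompute the per-subplot rate directly from the equations
  wd <- 0.62
  rate <- (oracle_agb_angiosperm(wd, 23, 15) -
             oracle_agb_angiosperm(wd, 20, 15)) * 3 / 1000 / 0.04 / 9
  expect_equal(unique(bio$mean_rate), rate, tolerance = 1e-10)
})

test_that("growth confined to unlogged plots is flagged only in that stratum", {
  census <- two_year_census(n_per_subplot = 4,
                            subplots = paste0("SP0", 1:4), grow = 3,
                            grow_plots = "P01")
  plots <- make_plots(c("P01", "P02"), c("unlogged", "recently_logged"))
  res <- summarize_dynamics(census, plots, make_traits(), 2000, 2009,
                            boot = bootstrap_config(300, seed = 7),
                            variables = "basal_area")
  expect_true(res$significant[res$stratum == "unlogged"])
  expect_false(res$significant[res$stratum == "recently_logged"])
})

test_that("the all stratum pools the per-stratum subplot rates", {
  census <- two_year_census(grow = 2)
  plots <- make_plots(c("P01", "P02"), c("unlogged", "early_logged"))
  res <- summarize_dynamics(census, plots, make_traits(), 2000, 2009,
                            boot = bootstrap_config(200, seed = 11),
                            variables = "stem_density")
  all_row <- res[res$stratum == "all", ]
  strata <- res[res$stratum != "all", ]
  expect_equal(all_row$n_units, sum(strata$n_units))
  expect_equal(all_row$mean_rate,
               sum(strata$mean_rate * strata$n_units) / sum(strata$n_units),
               tolerance = 1e-12)
})

test_that("per-variable substreams keep results independent of the variable set", {
  census <- two_year_census(grow = 1)
  plots <- make_plots(c("P01", "P02"), c("unlogged", "recently_logged"))
  boot <- bootstrap_config(300, seed = 17)
  solo <- summarize_dynamics(census, plots, make_traits(), 2000, 2009,
                             boot = boot, variables = "biomass")
  multi <- summarize_dynamics(census, plots, make_traits(), 2000, 2009,
                              boot = boot,
                              variables = c("biomass", "basal_area",
                                            "stem_density"))
  expect_equal(solo, multi[multi$variable == "biomass", ],
               ignore_attr = TRUE)
  # and identical across repeated runs under the same seed
  again <- summarize_dynamics(census, plots, make_traits(), 2000, 2009,
                              boot = boot, variables = "biomass")
  expect_identical(solo, again)
})

test_that("stand_summary reports structure, traits and group proportions per subplot-year", {
  census <- two_year_census(grow = 2)
  plots <- make_plots(c("P01", "P02"), c("unlogged", "recently_logged"))
  s <- stand_summary(census, plots, make_traits())
  expect_equal(nrow(s), 2 * 2 * 2)  # 2 plots x 2 subplots x 2 years
  expect_true(all(c("biomass", "basal_area", "stem_density", "fdis",
                    "cwm_wood_density", "prop_Pioneer") %in% names(s)))
  expect_true(all(s$stem_density == 3 / 0.04))
  # single-species subplots: CWM equals that species' trait value
  expect_true(all(s$cwm_max_height == 25))
  expect_true(all(s$fdis == 0))
})
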
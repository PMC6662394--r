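# Small in-code fixtures shared across tests.

make_traits <- function() {
  data.frame(
    species_id = c("SP1", "SP2", "SP3", "SP4", "SP5", "SP6"),
    genus = c("Ga", "Ga", "Ga", "Gb", "Araucaria", "Gc"),
    wood_density = c(0.62, 0.5, 0.7, NA, 0.4475, NA),
    max_height = c(25, 17, 12, 22, 35, 10),
    leaf_length = c(80, 60, 40, 100, 30, 50),
    sla = c(12, 18, 15, 10, 9, 20),
    seed_length = c(8, 3, 5, 15, 20, 4),
    crown_depth = c(8, 5, 3, 7, 10, 2.5),
    stem_slenderness = c(15, 10, 7, 13, 20, 6),
    functional_group = c(NA, NA, NA, "LargeShadeTolerant", "Araucaria",
                         NA),
    stringsAsFactors = FALSE
  )
}

make_census_row <- function(tree_id = "T1", plot_id = "P01",
                            subplot_id = "SP01", species_id = "SP1",
                            census_year = 2000, dbh_cm = 20,
                            height_m = 15, alive = TRUE,
                            growth_form = "angiosperm") {
  data.frame(tree_id = tree_id, plot_id = plot_id,
             subplot_id = subplot_id, species_id = species_id,
             census_year = census_year, dbh_cm = dbh_cm,
             height_m = height_m, alive = alive,
             growth_form = growth_form, stringsAsFactors = FALSE)
}

make_census <- function(n = 3, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_census_row(tree_id = paste0("T", i), ...)
  }))
}

make_plots <- function(plot_ids = "P01", history = "unlogged") {
  data.frame(plot_id = plot_ids,
             management_history = rep_len(history, length(plot_ids)),
             area_ha = 1, subplot_area_m2 = 400,
             stringsAsFactors = FALSE)
}

make_climate <- function(years = 1901:2014, rainfall = 1400,
                         tmin = 10, winter = 2, summer = 20) {
  data.frame(year = years,
             rainfall_mm = rep_len(rainfall, length(years)),
             tmin_annual_mean = rep_len(tmin, length(years)),
             tmin_winter = rep_len(winter, length(years)),
             tmin_summer = rep_len(summer, length(years)))
}

# Independent direct-evaluation oracles for the four biomass equations.
oracle_agb_angiosperm <- function(p, d, h) 0.0673 * (p * d^2 * h)^0.976
oracle_agb_araucaria <- function(d, h) {
  0.4141 * (111.7988 - 15.5317 * d + 0.8544 * d^2 + 0.0180 * d^2 * h) +
    0.3687 * (94.4247 - 12.5807 * d + 0.3381 * d^2 + 0.0091 * d^2 * h)
}
oracle_agb_palm <- function(h) 0.3999 + 7.907 * h
oracle_agb_tree_fern <- function(h) -4266348 / (1 - 2792284 * exp(0.313677 * h))

# Brute-force FDis oracle: explicit centroid and distance loop.
oracle_fdis <- function(a, x, standardize = FALSE) {
  x <- as.matrix(x)
  if (standardize) {
    for (j in seq_len(ncol(x))) {
      s <- sd(x[, j])
      x[, j] <- if (s == 0) 0 else (x[, j] - mean(x[, j])) / s
    }
  }
  keep <- a > 0
  x <- x[keep, , drop = FALSE]; a <- a[keep]
  if (nrow(x) == 1) return(0)
  centroid <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) centroid[j] <- sum(a * x[, j]) / sum(a)
  total <- 0
  for (i in seq_len(nrow(x))) {
    total <- total + a[i] * sqrt(sum((x[i, ] - centroid)^2))
  }
  total / sum(a)
}
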
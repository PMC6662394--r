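#' @keywords internal
"_PACKAGE"

# Column schemas fixed at the file boundary. Units are part of the column
# names (dbh_cm, height_m, area_ha, rainfall_mm) so files are
# self-describing; internal data frames keep the same names.

GROWTH_FORMS <- c("angiosperm", "araucaria", "palm", "tree_fern")

MANAGEMENT_HISTORIES <- c("unlogged", "early_logged", "recently_logged")

FUNCTIONAL_GROUPS <- c("Araucaria", "Pioneer", "LargeSeededPioneer",
                       "WindDispersedLargeTree", "LargeShadeTolerant",
                       "SmallShadeTolerant", "TreeFern")

#' Minimum diameter at breast height for census entry (cm)
#'
#' Trees enter the census when they reach this dbh; living records below it
#' are treated as validation errors.
#' @export
DBH_ENTRY_CM <- 9.5

CENSUS_COLS <- c("tree_id", "plot_id", "subplot_id", "species_id",
                 "census_year", "dbh_cm", "height_m", "alive", "growth_form")
TRAIT_COLS <- c("species_id", "genus", "wood_density", "max_height",
                "leaf_length", "sla", "seed_length", "crown_depth",
                "stem_slenderness", "functional_group")
CLIMATE_COLS <- c("year", "rainfall_mm", "tmin_annual_mean", "tmin_winter",
                  "tmin_summer")
PLOT_COLS <- c("plot_id", "management_history", "area_ha", "subplot_area_m2")

stop_with_diagnostics <- function(header, problems) {
  stop(paste(c(header, paste0("  - ", problems)), collapse = "\n"),
       call. = FALSE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Coerce a character column to numeric, recording row-level diagnostics
# (1-based data rows; header is row 0) instead of silently producing NAs.
parse_numeric <- function(x, col, problems) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & is.na(out))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: column '%s' value '%s' is not numeric", bad, col, raw[bad]))
  }
  list(values = out, problems = problems)
}

parse_logical <- function(x, col, problems) {
  raw <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(raw))
  out[raw %in% c("true", "t", "1", "yes")] <- TRUE
  out[raw %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(raw) & raw != "" & is.na(out))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: column '%s' value '%s' is not logical", bad, col, raw[bad]))
  }
  list(values = out, problems = problems)
}

read_delim_text <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character(0), fileEncoding = "UTF-8")
}

#' Validate a tree-census table
#'
#' Checks every record of a census data frame against the census invariants:
#' numeric dbh and height, positive height, dbh at or above the census entry
#' threshold ([DBH_ENTRY_CM]) for living trees, a known growth form, and
#' uniqueness of (tree_id, census_year). Dead records (`alive = FALSE`) are
#' retained so mortality remains computable, and are exempt from the dbh
#' threshold. Validation is total: every offending row produces a located
#' diagnostic and all diagnostics are reported together.
#'
#' @param census data frame with the census columns (see [read_census]).
#' @param census_window optional length-2 integer vector of acceptable
#'   census years.
#' @return the validated data frame, with typed columns, invisibly classed
#'   as before.
#' @export
validate_census <- function(census, census_window = NULL) {
  check_columns(census, CENSUS_COLS, "census")
  problems <- character(0)
  p <- parse_numeric(census$dbh_cm, "dbh_cm", problems)
  dbh <- p$values; problems <- p$problems
  p <- parse_numeric(census$height_m, "height_m", problems)
  height <- p$values; problems <- p$problems
  p <- parse_numeric(census$census_year, "census_year", problems)
  year <- p$values; problems <- p$problems
  p <- parse_logical(census$alive, "alive", problems)
  alive <- p$values; problems <- p$problems

  gf <- as.character(census$growth_form)
  bad_gf <- which(!gf %in% GROWTH_FORMS)
  if (length(bad_gf) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown growth_form '%s' (expected one of %s)",
      bad_gf, gf[bad_gf], paste(GROWTH_FORMS, collapse = ", ")))
  }

  ok_num <- !is.na(dbh) & !is.na(height) & !is.na(alive)
  thin <- which(ok_num & alive & dbh < DBH_ENTRY_CM)
  if (length(thin) > 0) {
    problems <- c(problems, sprintf(
      "row %d: alive tree with dbh_cm %.2f below the %.1f cm census entry threshold",
      thin, dbh[thin], DBH_ENTRY_CM))
  }
  flat <- which(!is.na(height) & height <= 0)
  if (length(flat) > 0) {
    problems <- c(problems, sprintf(
      "row %d: height_m %.2f is not positive", flat, height[flat]))
  }
  if (!is.null(census_window)) {
    outside <- which(!is.na(year) &
                       (year < census_window[1] | year > census_window[2]))
    if (length(outside) > 0) {
      problems <- c(problems, sprintf(
        "row %d: census_year %d outside window %d-%d", outside,
        as.integer(year[outside]), as.integer(census_window[1]),
        as.integer(census_window[2])))
    }
  }
  key <- paste(census$tree_id, census$census_year, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    problems <- c(problems, sprintf(
      "row %d: duplicate (tree_id, census_year) = (%s, %s)",
      dup, census$tree_id[dup], census$census_year[dup]))
  }
  if (length(problems) > 0) {
    stop_with_diagnostics(
      sprintf("census validation failed (%d problem(s)):", length(problems)),
      problems)
  }
  out <- data.frame(
    tree_id = as.character(census$tree_id),
    plot_id = as.character(census$plot_id),
    subplot_id = as.character(census$subplot_id),
    species_id = as.character(census$species_id),
    census_year = as.integer(year),
    dbh_cm = dbh,
    height_m = height,
    alive = alive,
    growth_form = gf,
    stringsAsFactors = FALSE
  )
  out
}

#' Read a tree-census CSV
#'
#' Reads a comma-separated census file (UTF-8, header row mandatory) with
#' columns `tree_id, plot_id, subplot_id, species_id, census_year, dbh_cm,
#' height_m, alive, growth_form` and validates it with [validate_census].
#'
#' @param path path to the CSV file.
#' @param census_window optional length-2 vector of acceptable census years.
#' @return a validated census data frame, one row per tree per census.
#' @export
read_census <- function(path, census_window = NULL) {
  validate_census(read_delim_text(path), census_window = census_window)
}

#' Write a tree-census CSV
#'
#' @param census a census data frame (see [read_census] for columns).
#' @param path output path.
#' @export
write_census <- function(census, path) {
  check_columns(census, CENSUS_COLS, "census")
  utils::write.csv(census[, CENSUS_COLS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Validate a species-trait table
#'
#' One row per species. Empty cells denote missing values (never sentinel
#' numbers). Requires positive wood density and maximum height where
#' present, finite trait values, unique species ids, and functional-group
#' labels from the recognised set when supplied.
#'
#' @param traits data frame with the trait columns (see [read_traits]).
#' @return typed, validated data frame.
#' @export
validate_traits <- function(traits) {
  check_columns(traits, TRAIT_COLS, "traits")
  problems <- character(0)
  num_cols <- c("wood_density", "max_height", "leaf_length", "sla",
                "seed_length", "crown_depth", "stem_slenderness")
  parsed <- list()
  for (col in num_cols) {
    p <- parse_numeric(traits[[col]], col, problems)
    parsed[[col]] <- p$values; problems <- p$problems
  }
  dup <- which(duplicated(traits$species_id))
  if (length(dup) > 0) {
    problems <- c(problems, sprintf(
      "row %d: duplicate species_id '%s'", dup, traits$species_id[dup]))
  }
  wd <- parsed$wood_density
  bad_wd <- which(!is.na(wd) & wd <= 0)
  if (length(bad_wd) > 0) {
    problems <- c(problems, sprintf(
      "row %d: wood_density %.3f is not positive", bad_wd, wd[bad_wd]))
  }
  mh <- parsed$max_height
  bad_mh <- which(!is.na(mh) & mh <= 0)
  if (length(bad_mh) > 0) {
    problems <- c(problems, sprintf(
      "row %d: max_height %.2f is not positive", bad_mh, mh[bad_mh]))
  }
  fg <- trimws(as.character(traits$functional_group))
  fg[fg == ""] <- NA_character_
  bad_fg <- which(!is.na(fg) & !fg %in% FUNCTIONAL_GROUPS)
  if (length(bad_fg) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown functional_group '%s'", bad_fg, fg[bad_fg]))
  }
  if (length(problems) > 0) {
    stop_with_diagnostics(
      sprintf("traits validation failed (%d problem(s)):", length(problems)),
      problems)
  }
  out <- data.frame(
    species_id = as.character(traits$species_id),
    genus = as.character(traits$genus),
    stringsAsFactors = FALSE
  )
  for (col in num_cols) out[[col]] <- parsed[[col]]
  out$functional_group <- fg
  out
}

#' Read a species-trait CSV
#'
#' Columns: `species_id, genus, wood_density (g/cm3), max_height (m),
#' leaf_length (mm), sla (mm2/mg), seed_length (mm), crown_depth (m),
#' stem_slenderness (m, expected height at dbh 15 cm), functional_group`.
#' Empty cells are read as missing values.
#'
#' @param path path to the CSV file.
#' @return validated trait data frame, one row per species.
#' @export
read_traits <- function(path) {
  validate_traits(read_delim_text(path))
}

#' Write a species-trait CSV
#' @param traits trait data frame.
#' @param path output path.
#' @export
write_traits <- function(traits, path) {
  check_columns(traits, TRAIT_COLS, "traits")
  utils::write.csv(traits[, TRAIT_COLS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Validate an annual climate series
#'
#' Requires unique years and non-negative rainfall; sorts by year and
#' reports (as a message) any gaps in annual coverage.
#'
#' @param climate data frame with columns `year, rainfall_mm,
#'   tmin_annual_mean, tmin_winter, tmin_summer`.
#' @return validated data frame sorted by year.
#' @export
validate_climate <- function(climate) {
  check_columns(climate, CLIMATE_COLS, "climate")
  problems <- character(0)
  parsed <- list()
  for (col in CLIMATE_COLS) {
    p <- parse_numeric(climate[[col]], col, problems)
    parsed[[col]] <- p$values; problems <- p$problems
  }
  dup <- which(duplicated(parsed$year))
  if (length(dup) > 0) {
    problems <- c(problems, sprintf(
      "row %d: duplicate year %s", dup, climate$year[dup]))
  }
  rf <- parsed$rainfall_mm
  wet <- which(!is.na(rf) & rf < 0)
  if (length(wet) > 0) {
    problems <- c(problems, sprintf(
      "row %d: negative rainfall_mm %.1f", wet, rf[wet]))
  }
  if (length(problems) > 0) {
    stop_with_diagnostics(
      sprintf("climate validation failed (%d problem(s)):", length(problems)),
      problems)
  }
  out <- data.frame(year = as.integer(parsed$year),
                    rainfall_mm = rf,
                    tmin_annual_mean = parsed$tmin_annual_mean,
                    tmin_winter = parsed$tmin_winter,
                    tmin_summer = parsed$tmin_summer)
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  gaps <- setdiff(seq(min(out$year), max(out$year)), out$year)
  if (length(gaps) > 0) {
    message(sprintf("climate series has %d missing year(s): %s",
                    length(gaps), paste(gaps, collapse = ", ")))
  }
  out
}

#' Read an annual climate CSV
#'
#' Columns: `year, rainfall_mm, tmin_annual_mean, tmin_winter, tmin_summer`
#' where `tmin_winter`/`tmin_summer` are the lowest and highest minimum
#' temperatures of the year. Output is sorted by year; gaps are reported.
#'
#' @param path path to the CSV file.
#' @return validated climate data frame.
#' @export
read_climate <- function(path) {
  validate_climate(read_delim_text(path))
}

#' Write an annual climate CSV
#' @param climate climate data frame.
#' @param path output path.
#' @export
write_climate <- function(climate, path) {
  check_columns(climate, CLIMATE_COLS, "climate")
  utils::write.csv(climate[, CLIMATE_COLS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Validate plot metadata
#'
#' @param plots data frame with columns `plot_id, management_history,
#'   area_ha, subplot_area_m2`.
#' @return validated data frame.
#' @export
validate_plots <- function(plots) {
  check_columns(plots, PLOT_COLS, "plots")
  problems <- character(0)
  p <- parse_numeric(plots$area_ha, "area_ha", problems)
  area <- p$values; problems <- p$problems
  p <- parse_numeric(plots$subplot_area_m2, "subplot_area_m2", problems)
  sp_area <- p$values; problems <- p$problems
  dup <- which(duplicated(plots$plot_id))
  if (length(dup) > 0) {
    problems <- c(problems, sprintf(
      "row %d: duplicate plot_id '%s'", dup, plots$plot_id[dup]))
  }
  mh <- as.character(plots$management_history)
  bad_mh <- which(!mh %in% MANAGEMENT_HISTORIES)
  if (length(bad_mh) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown management_history '%s'", bad_mh, mh[bad_mh]))
  }
  bad_area <- which(!is.na(area) & area <= 0)
  if (length(bad_area) > 0) {
    problems <- c(problems, sprintf(
      "row %d: area_ha %.3f is not positive", bad_area, area[bad_area]))
  }
  if (length(problems) > 0) {
    stop_with_diagnostics(
      sprintf("plots validation failed (%d problem(s)):", length(problems)),
      problems)
  }
  data.frame(plot_id = as.character(plots$plot_id),
             management_history = mh,
             area_ha = area,
             subplot_area_m2 = sp_area,
             stringsAsFactors = FALSE)
}

#' Read a plot-metadata CSV
#' @param path path to CSV with columns
#'   `plot_id, management_history, area_ha, subplot_area_m2`.
#' @return validated plot data frame.
#' @export
read_plots <- function(path) {
  validate_plots(read_delim_text(path))
}

#' Write a plot-metadata CSV
#' @param plots plot data frame.
#' @param path output path.
#' @export
write_plots <- function(plots, path) {
  check_columns(plots, PLOT_COLS, "plots")
  utils::write.csv(plots[, PLOT_COLS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
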
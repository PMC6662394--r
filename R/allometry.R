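# Growth-form-specific aboveground biomass (AGB) equations for subtropical
# mixed Araucaria forest. Per-tree biomass is kept in kg; conversion to
# Mg/ha happens once, in stand_biomass(), to avoid unit drift.

#' Default allometric coefficients
#'
#' Returns the coefficient set used by the biomass equations, so the module
#' can be re-parameterised (e.g. for sensitivity analysis) without code
#' change. `tree_fern_form` selects between the published hyperbolic form
#' (`"as_printed"`) and a logistic alternative (`"logistic"`); see
#' [agb_tree_fern].
#'
#' @param tree_fern_form `"as_printed"` (default) or `"logistic"`.
#' @param global_wood_density optional global mean wood density (g/cm3)
#'   used as the last-resort tier of [resolve_wood_density]; `NULL` means
#'   "use the mean of species-level values in the supplied trait table".
#' @return a list of coefficient vectors, one entry per equation.
#' @export
allometry_config <- function(tree_fern_form = c("as_printed", "logistic"),
                             global_wood_density = NULL) {
  tree_fern_form <- match.arg(tree_fern_form)
  list(
    angiosperm = c(a = 0.0673, b = 0.976),
    araucaria_trunk = c(scale = 0.4141, c0 = 111.7988, c1 = -15.5317,
                        c2 = 0.8544, c3 = 0.0180),
    araucaria_branch = c(scale = 0.3687, c0 = 94.4247, c1 = -12.5807,
                         c2 = 0.3381, c3 = 0.0091),
    palm = c(intercept = 0.3999, slope = 7.907),
    tree_fern = c(A = 4266348, B = 2792284, k = 0.313677),
    tree_fern_form = tree_fern_form,
    global_wood_density = global_wood_density
  )
}

#' Angiosperm aboveground biomass (pantropical model)
#'
#' AGB (kg) = 0.0673 * (rho * D^2 * H)^0.976, with wood density rho in
#' g/cm3, diameter D in cm and height H in m.
#'
#' @param wood_density wood density (g/cm3), > 0.
#' @param dbh diameter at breast height (cm), > 0.
#' @param height total height (m), > 0.
#' @param config coefficient list from [allometry_config].
#' @return aboveground biomass in kg (vectorised).
#' @export
agb_angiosperm <- function(wood_density, dbh, height,
                           config = allometry_config()) {
  if (any(!is.finite(wood_density)) || any(wood_density <= 0)) {
    stop("wood_density must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("dbh must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("height must be positive and finite", call. = FALSE)
  }
  k <- config$angiosperm
  unname(k["a"] * (wood_density * dbh^2 * height)^k["b"])
}

#' Araucaria aboveground biomass (trunk + live branches)
#'
#' Species-specific model for *Araucaria angustifolia*:
#' trunk = 0.4141 * (111.7988 - 15.5317 D + 0.8544 D^2 + 0.0180 D^2 H),
#' branches = 0.3687 * (94.4247 - 12.5807 D + 0.3381 D^2 + 0.0091 D^2 H).
#' Wood density does not enter this equation. A non-positive result flags
#' inputs outside the model's calibration range and raises an error.
#'
#' @param dbh diameter at breast height (cm), at or above the 9.5 cm census
#'   entry threshold.
#' @param height total height (m), > 0.
#' @param config coefficient list from [allometry_config].
#' @return aboveground biomass in kg (vectorised).
#' @export
agb_araucaria <- function(dbh, height, config = allometry_config()) {
  if (any(!is.finite(dbh)) || any(dbh < DBH_ENTRY_CM)) {
    stop(sprintf("dbh must be >= %.1f cm for the Araucaria model",
                 DBH_ENTRY_CM), call. = FALSE)
  }
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("height must be positive and finite", call. = FALSE)
  }
  poly_dh <- function(k) {
    k["scale"] * (k["c0"] + k["c1"] * dbh + k["c2"] * dbh^2 +
                    k["c3"] * dbh^2 * height)
  }
  agb <- unname(poly_dh(config$araucaria_trunk) +
                  poly_dh(config$araucaria_branch))
  if (any(agb <= 0)) {
    stop("Araucaria model returned non-positive biomass; inputs outside calibration range",
         call. = FALSE)
  }
  agb
}

#' Palm aboveground biomass
#'
#' AGB (kg) = 0.3999 + 7.907 * H for the palm *Syagrus romanzoffiana*;
#' diameter does not enter the equation.
#'
#' @param height total height (m), > 0.
#' @param config coefficient list from [allometry_config].
#' @return aboveground biomass in kg (vectorised).
#' @export
agb_palm <- function(height, config = allometry_config()) {
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("height must be positive and finite", call. = FALSE)
  }
  k <- config$palm
  unname(k["intercept"] + k["slope"] * height)
}

#' Tree-fern aboveground biomass
#'
#' The published equation, implemented verbatim as the default, is
#' AGB (kg) = -4266348 / (1 - 2792284 * exp(0.313677 H)).
#' This form decreases towards zero as H grows and yields sub-kilogram
#' values over realistic heights, which is almost certainly a transcription
#' artefact of the underlying logistic model; it is nevertheless the
#' default for fidelity to the published coefficients. Setting
#' `tree_fern_form = "logistic"` in [allometry_config] selects the
#' saturating alternative AGB = 4266.348 / (1 + 2792.284 exp(-0.313677 H)).
#' The form used is always recorded in [tree_biomass] output.
#'
#' @param height total height (m), > 0.
#' @param config coefficient list from [allometry_config].
#' @return aboveground biomass in kg (vectorised).
#' @export
agb_tree_fern <- function(height, config = allometry_config()) {
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("height must be positive and finite", call. = FALSE)
  }
  k <- config$tree_fern
  if (identical(config$tree_fern_form, "logistic")) {
    return(unname((k["A"] / 1000) /
                    (1 + (k["B"] / 1000) * exp(-k["k"] * height))))
  }
  denom <- 1 - k["B"] * exp(k["k"] * height)
  if (any(denom == 0)) {
    stop("tree-fern equation denominator is zero", call. = FALSE)
  }
  unname(-k["A"] / denom)
}

#' Resolve wood density for one species with tiered fallback
#'
#' Wood density is taken from the species record when present; otherwise
#' the mean over congeneric species with recorded values (genus tier);
#' otherwise a global mean (by default the mean over all species-level
#' values in the trait table). The tier that fired is reported alongside
#' the value.
#'
#' @param species_id species identifier present in `traits`.
#' @param traits trait data frame (see [read_traits]).
#' @param global_mean last-resort wood density (g/cm3); `NULL` means mean
#'   of species-level values in `traits`.
#' @return list with `value` (g/cm3) and `source` (one of `"species"`,
#'   `"genus_mean"`, `"global_mean"`).
#' @export
resolve_wood_density <- function(species_id, traits, global_mean = NULL) {
  i <- match(species_id, traits$species_id)
  if (is.na(i)) {
    stop(sprintf("species '%s' absent from trait table", species_id),
         call. = FALSE)
  }
  wd <- traits$wood_density[i]
  if (!is.na(wd)) {
    return(list(value = wd, source = "species"))
  }
  mates <- traits$wood_density[traits$genus == traits$genus[i] &
                                 traits$species_id != species_id]
  mates <- mates[!is.na(mates)]
  if (length(mates) > 0) {
    return(list(value = mean(mates), source = "genus_mean"))
  }
  if (is.null(global_mean)) {
    pool <- traits$wood_density[!is.na(traits$wood_density)]
    if (length(pool) == 0) {
      stop("no wood density values available for the global-mean tier",
           call. = FALSE)
    }
    global_mean <- mean(pool)
  }
  list(value = global_mean, source = "global_mean")
}

# Vectorised resolution over a species vector; returns value + source per
# element. Genus means and the global mean are precomputed once.
resolve_wood_density_many <- function(species_ids, traits,
                                      global_mean = NULL) {
  i <- match(species_ids, traits$species_id)
  if (anyNA(i)) {
    stop(sprintf("species absent from trait table: %s",
                 paste(unique(species_ids[is.na(i)]), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(global_mean)) {
    pool <- traits$wood_density[!is.na(traits$wood_density)]
    global_mean <- if (length(pool) > 0) mean(pool) else NA_real_
  }
  genus_means <- tapply(traits$wood_density, traits$genus,
                        function(x) mean(x, na.rm = TRUE))
  value <- traits$wood_density[i]
  source <- rep("species", length(i))
  need <- is.na(value)
  if (any(need)) {
    gm <- genus_means[traits$genus[i[need]]]
    use_genus <- !is.na(gm)
    value[need][use_genus] <- gm[use_genus]
    source[need][use_genus] <- "genus_mean"
    left <- need
    left[need] <- !use_genus
    if (any(left)) {
      if (is.na(global_mean)) {
        stop("no wood density values available for the global-mean tier",
             call. = FALSE)
      }
      value[left] <- global_mean
      source[left] <- "global_mean"
    }
  }
  data.frame(value = value, source = source, stringsAsFactors = FALSE)
}

#' Per-tree aboveground biomass with growth-form dispatch
#'
#' Dispatches each living census record to its growth-form equation:
#' angiosperms to [agb_angiosperm] with wood density resolved through
#' [resolve_wood_density], Araucaria to [agb_araucaria] (wood density not
#' used), palms and tree ferns to the height-only equations.
#'
#' @param records census data frame of living trees (see [read_census]).
#' @param traits trait data frame (needed for angiosperm wood density).
#' @param config coefficient list from [allometry_config].
#' @return data frame with `tree_id`, `biomass_kg`, `equation_used`,
#'   `wood_density_source`; one row per input record, same order.
#' @export
tree_biomass <- function(records, traits, config = allometry_config()) {
  if (nrow(records) > 0 && any(!records$alive)) {
    stop("tree_biomass requires living records; filter alive == TRUE first",
         call. = FALSE)
  }
  n <- nrow(records)
  biomass <- numeric(n)
  equation <- character(n)
  wd_source <- rep("not_applicable", n)

  is_ang <- records$growth_form == "angiosperm"
  if (any(is_ang)) {
    wd <- resolve_wood_density_many(records$species_id[is_ang], traits,
                                    global_mean = config$global_wood_density)
    biomass[is_ang] <- agb_angiosperm(wd$value, records$dbh_cm[is_ang],
                                      records$height_m[is_ang], config)
    equation[is_ang] <- "angiosperm"
    wd_source[is_ang] <- wd$source
  }
  is_ara <- records$growth_form == "araucaria"
  if (any(is_ara)) {
    biomass[is_ara] <- agb_araucaria(records$dbh_cm[is_ara],
                                     records$height_m[is_ara], config)
    equation[is_ara] <- "araucaria_trunk_branch"
  }
  is_palm <- records$growth_form == "palm"
  if (any(is_palm)) {
    biomass[is_palm] <- agb_palm(records$height_m[is_palm], config)
    equation[is_palm] <- "palm"
  }
  is_fern <- records$growth_form == "tree_fern"
  if (any(is_fern)) {
    biomass[is_fern] <- agb_tree_fern(records$height_m[is_fern], config)
    equation[is_fern] <- "tree_fern"
  }
  data.frame(tree_id = records$tree_id,
             biomass_kg = biomass,
             equation_used = equation,
             wood_density_source = wd_source,
             stringsAsFactors = FALSE)
}

#' Stand-level aboveground biomass (Mg/ha)
#'
#' Sums per-tree biomass (kg) over living records of one census and
#' converts to Mg/ha.
#'
#' @param records census data frame of living trees from one census.
#' @param area_ha reference area in hectares, > 0.
#' @param traits trait data frame.
#' @param config coefficient list from [allometry_config].
#' @return biomass in Mg/ha (0 for an empty record set).
#' @export
stand_biomass <- function(records, area_ha, traits,
                          config = allometry_config()) {
  if (!is.finite(area_ha) || area_ha <= 0) {
    stop("area_ha must be positive", call. = FALSE)
  }
  if (nrow(records) == 0) return(0)
  sum(tree_biomass(records, traits, config)$biomass_kg) / 1000 / area_ha
}
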
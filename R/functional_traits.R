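# Functional-group classification, community-weighted means (CWM) and
# functional dispersion (FDis). Abundance weights throughout are stem
# counts, not basal area.

#' Default trait set for community-level summaries
#'
#' Ordered trait columns entering CWM and FDis calculations.
#' @return character vector of trait column names.
#' @export
default_cwm_traits <- function() {
  c("max_height", "wood_density", "stem_slenderness", "crown_depth",
    "leaf_length", "seed_length", "sla")
}

#' Threshold classification into functional groups
#'
#' Classifies species from maximum height and wood density:
#' species with maximum height <= 15 m are Small Shade Tolerant; species
#' with maximum height in (15, 19) m and wood density < 0.65 g/cm3 are
#' Pioneer; species with maximum height >= 19 m and wood density
#' < 0.65 g/cm3 are Large Seeded Pioneer; everything else is left
#' unassigned. "Between 15 and 19 m" is read as the open interval
#' (15, 19): exactly 15 m falls to the <= 15 rule and exactly 19 m to the
#' >= 19 rule, so the three height rules partition the axis. The
#' boundaries are configurable.
#'
#' @param max_height species maximum height (m), > 0 (vectorised).
#' @param wood_density species wood density (g/cm3), > 0 (vectorised).
#' @param height_breaks length-2 numeric: the small/pioneer and
#'   pioneer/large height boundaries (default `c(15, 19)`).
#' @param density_break light-wood threshold (default 0.65 g/cm3).
#' @return character vector over `{"SmallShadeTolerant", "Pioneer",
#'   "LargeSeededPioneer", "unassigned"}`.
#' @export
classify_functional_group <- function(max_height, wood_density,
                                      height_breaks = c(15, 19),
                                      density_break = 0.65) {
  if (any(!is.finite(max_height)) || any(max_height <= 0)) {
    stop("max_height must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(wood_density)) || any(wood_density <= 0)) {
    stop("wood_density must be positive and finite", call. = FALSE)
  }
  n <- max(length(max_height), length(wood_density))
  max_height <- rep_len(max_height, n)
  wood_density <- rep_len(wood_density, n)
  out <- rep("unassigned", n)
  out[max_height <= height_breaks[1]] <- "SmallShadeTolerant"
  mid <- max_height > height_breaks[1] & max_height < height_breaks[2]
  out[mid & wood_density < density_break] <- "Pioneer"
  tall <- max_height >= height_breaks[2]
  out[tall & wood_density < density_break] <- "LargeSeededPioneer"
  out
}

#' Assign functional groups to a trait table
#'
#' Curated `functional_group` labels take precedence; the threshold
#' classifier ([classify_functional_group]) fires only for unlabelled
#' species (and only when both max_height and wood_density are known,
#' resolving wood density through the genus/global tiers).
#'
#' @param traits trait data frame (see [read_traits]).
#' @param ... boundary options passed to [classify_functional_group].
#' @return the trait data frame with a filled `functional_group` column
#'   (`"unassigned"` where no rule applies) and a `group_source` column
#'   (`"curated"` or `"threshold"`).
#' @export
assign_functional_groups <- function(traits, ...) {
  source <- ifelse(is.na(traits$functional_group), "threshold", "curated")
  group <- traits$functional_group
  todo <- which(is.na(group))
  if (length(todo) > 0) {
    wd <- resolve_wood_density_many(traits$species_id[todo], traits)
    ok <- !is.na(traits$max_height[todo]) & !is.na(wd$value)
    group[todo][!ok] <- "unassigned"
    if (any(ok)) {
      group[todo][ok] <- classify_functional_group(
        traits$max_height[todo][ok], wd$value[ok], ...)
    }
  }
  traits$functional_group <- group
  traits$group_source <- source
  traits
}

#' Community-weighted mean of a trait
#'
#' CWM = sum(a_j t_j) / sum(a_j) over species with a known trait value;
#' species with missing trait are excluded together with their weight
#' (i.e. the remaining weights renormalise).
#'
#' @param abundances non-negative abundance (stem-count) vector with
#'   positive sum.
#' @param trait_values trait values, same length; may contain `NA`.
#' @return the weighted mean, or `NA` with a warning if no species has a
#'   known trait value.
#' @export
cwm <- function(abundances, trait_values) {
  if (length(abundances) != length(trait_values)) {
    stop("abundances and trait_values must have the same length",
         call. = FALSE)
  }
  if (any(abundances < 0) || sum(abundances) <= 0) {
    stop("abundances must be non-negative with positive sum", call. = FALSE)
  }
  keep <- !is.na(trait_values) & abundances > 0
  if (!any(keep)) {
    warning("all contributing species have missing trait values; CWM undefined")
    return(NA_real_)
  }
  sum(abundances[keep] * trait_values[keep]) / sum(abundances[keep])
}

#' Functional dispersion (FDis)
#'
#' Abundance-weighted mean Euclidean distance of species to the
#' abundance-weighted centroid of the community in multivariate trait
#' space: with weights a_j and trait vectors x_j, the centroid is
#' c = sum(a_j x_j)/sum(a_j) and FDis = sum(a_j ||x_j - c||)/sum(a_j).
#' By default each trait column is z-standardised (zero mean, unit
#' variance over the species pool in `trait_matrix`) before distances,
#' since traits carry incommensurable units; columns with zero variance
#' contribute nothing. A single-species community has dispersion 0.
#'
#' @param abundances non-negative abundance vector with positive sum.
#' @param trait_matrix numeric matrix, species in rows, traits in columns;
#'   must be complete (no `NA`) for species with positive abundance.
#' @param standardize z-standardise trait columns first (default `TRUE`).
#' @return non-negative scalar, invariant to rescaling the abundances.
#' @export
fdis <- function(abundances, trait_matrix, standardize = TRUE) {
  trait_matrix <- as.matrix(trait_matrix)
  if (length(abundances) != nrow(trait_matrix)) {
    stop("abundances must have one entry per trait_matrix row",
         call. = FALSE)
  }
  if (any(abundances < 0) || sum(abundances) <= 0) {
    stop("abundances must be non-negative with positive sum", call. = FALSE)
  }
  keep <- abundances > 0
  if (anyNA(trait_matrix[keep, , drop = FALSE])) {
    stop("trait_matrix must be complete for species with positive abundance",
         call. = FALSE)
  }
  if (standardize) {
    mu <- colMeans(trait_matrix)
    sdv <- apply(trait_matrix, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- Inf  # constant traits drop out
    trait_matrix <- sweep(sweep(trait_matrix, 2, mu, "-"), 2, sdv, "/")
  }
  x <- trait_matrix[keep, , drop = FALSE]
  a <- abundances[keep]
  if (nrow(x) == 1) return(0)
  centroid <- colSums(x * a) / sum(a)
  d <- sqrt(rowSums(sweep(x, 2, centroid, "-")^2))
  sum(a * d) / sum(a)
}

#' Functional-group proportions of a tree community
#'
#' Tallies living trees by the functional group of their species (curated
#' labels first, thresholds for the rest, via [assign_functional_groups])
#' and returns proportions over classified trees; unassigned trees are
#' excluded from the denominator.
#'
#' @param records census data frame of living trees from one census.
#' @param traits trait data frame.
#' @param ... boundary options passed to [classify_functional_group].
#' @return named numeric vector over the functional groups, summing to 1
#'   when any tree is classified; all-`NA` (with a warning) for an empty
#'   community.
#' @export
group_proportions <- function(records, traits, ...) {
  groups <- FUNCTIONAL_GROUPS
  if (nrow(records) == 0) {
    warning("empty community; group proportions undefined")
    return(stats::setNames(rep(NA_real_, length(groups)), groups))
  }
  assigned <- assign_functional_groups(traits, ...)
  g <- assigned$functional_group[match(records$species_id,
                                       assigned$species_id)]
  counts <- table(factor(g, levels = groups))
  total <- sum(counts)
  if (total == 0) {
    warning("no classified trees; group proportions undefined")
    return(stats::setNames(rep(NA_real_, length(groups)), groups))
  }
  stats::setNames(as.numeric(counts) / total, groups)
}

# Species-level community summary used by stand_dynamics: abundance-weighted
# trait means, dispersion and group counts for one set of living records.
community_summary <- function(records, traits,
                              trait_names = default_cwm_traits(),
                              standardize_fdis = TRUE) {
  ab_tab <- table(records$species_id)
  sp <- names(ab_tab)
  a <- as.numeric(ab_tab)
  idx <- match(sp, traits$species_id)
  if (anyNA(idx)) {
    stop(sprintf("species absent from trait table: %s",
                 paste(sp[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  cwms <- vapply(trait_names, function(tr) {
    suppressWarnings(cwm(a, traits[[tr]][idx]))
  }, numeric(1))
  tm <- as.matrix(traits[idx, trait_names, drop = FALSE])
  complete <- stats::complete.cases(tm) & a > 0
  fd <- if (sum(complete) == 0) NA_real_ else {
    fdis(a[complete], tm[complete, , drop = FALSE],
         standardize = standardize_fdis)
  }
  list(cwm = cwms, fdis = fd)
}
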
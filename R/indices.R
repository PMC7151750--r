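# Per-transect functional diversity indices: richness (FRic),
# dispersion (FDis) and originality (FOri), the latter two weighted by
# either density or biomass. All three are normalized against
# pool-level constants so that values are comparable across transects.

space_coords <- function(space, m = NULL) {
  stopifnot(inherits(space, "functional_space"))
  m <- if (is.null(m)) space$chosen_m else m
  if (is.null(m)) stop("functional space has no chosen_m; run select_axes()")
  space$coordinates[, seq_len(m), drop = FALSE]
}

#' Pool-level normalization constants
#'
#' Computed once per functional space over the full species pool in the
#' chosen m axes: the maximum pairwise distance (`d_max`, normalizes
#' FDis), the maximum nearest-neighbor distance (`o_max`, normalizes
#' FOri), and the convex-hull volume of the pool (`volume`, normalizes
#' FRic). Changing the transect set never changes these.
#'
#' @param space a `functional_space` with `chosen_m` set.
#' @return list with `m`, `n_species`, `d_max`, `o_max`, `volume`.
#' @export
pool_constants <- function(space) {
  x <- space_coords(space)
  dm <- as.matrix(stats::dist(x))
  d_max <- max(dm)
  if (d_max <= 0) stop("degenerate pool: all species coincide in the chosen axes")
  diag(dm) <- Inf
  o_max <- max(apply(dm, 1L, min))
  vol <- convhull_volume(unique(x))
  if (is.na(vol))
    stop("species pool does not span ", ncol(x), " dimensions; ",
         "reduce the number of axes")
  list(m = ncol(x), n_species = nrow(x), d_max = d_max, o_max = o_max,
       volume = vol)
}

check_present <- function(space, present) {
  missing <- setdiff(present, rownames(space$coordinates))
  if (length(missing))
    stop("species absent from the functional space: ",
         paste(missing, collapse = ", "))
}

#' Functional richness of a set of species
#'
#' Proportion of the pool's functional space (convex-hull volume in the
#' chosen m axes) covered by the species present. Coordinates
#' duplicated across species (shared functional entities) are
#' deduplicated before hulling. When fewer than m+1 distinct points are
#' present, or the points are affinely degenerate, no m-volume exists:
#' the value is 0 with flag `"insufficient-dimensionality"` rather than
#' a silently incomparable lower-dimensional ratio.
#'
#' @param space a `functional_space` with `chosen_m` set.
#' @param present character vector of species present.
#' @param constants optional precomputed [pool_constants()].
#' @return list with `value` (in `[0, 1]`) and `flag` (`NA` or a label).
#' @export
functional_richness <- function(space, present, constants = NULL) {
  check_present(space, present)
  if (is.null(constants)) constants <- pool_constants(space)
  x <- unique(space_coords(space)[present, , drop = FALSE])
  m <- constants$m
  if (nrow(x) < m + 1L || affine_rank(x) < m)
    return(list(value = 0, flag = "insufficient-dimensionality"))
  vol <- convhull_volume(x)
  if (is.na(vol)) return(list(value = 0, flag = "insufficient-dimensionality"))
  list(value = vol / constants$volume, flag = NA_character_)
}

#' Weighted functional dispersion
#'
#' Weighted mean distance of the species present to their weighted
#' centroid, normalized by half the maximum pairwise distance in the
#' species pool: `FDis = (sum_i w_i ||x_i - c|| / sum_i w_i) / (d_max/2)`
#' with `c = sum_i w_i x_i / sum_i w_i`. Weights are densities or
#' biomasses; the index is invariant to their overall scale. A single
#' species has zero dispersion by convention (flagged).
#'
#' @param space a `functional_space` with `chosen_m` set.
#' @param w named non-negative weights; names are the species present.
#' @param constants optional precomputed [pool_constants()].
#' @return list with `value` and `flag`.
#' @export
functional_dispersion <- function(space, w, constants = NULL) {
  present <- names(w)
  if (is.null(present)) stop("`w` must be named by species")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative with positive sum")
  check_present(space, present)
  if (is.null(constants)) constants <- pool_constants(space)
  if (length(present) == 1L) return(list(value = 0, flag = "singleton"))
  x <- space_coords(space)[present, , drop = FALSE]
  cw <- colSums(x * w) / sum(w)
  dists <- sqrt(rowSums(sweep(x, 2L, cw)^2))
  list(value = (sum(w * dists) / sum(w)) / (constants$d_max / 2),
       flag = NA_character_)
}

#' Weighted functional originality
#'
#' Weighted mean distance of each species present to its nearest
#' neighbor among the species present, normalized by the maximum
#' nearest-neighbor distance in the species pool. High values mean the
#' community is dominated by functionally unique species (low
#' redundancy). Requires at least two species (flagged zero otherwise);
#' species sharing a functional entity have originality zero.
#'
#' @inheritParams functional_dispersion
#' @return list with `value` and `flag`.
#' @export
functional_originality <- function(space, w, constants = NULL) {
  present <- names(w)
  if (is.null(present)) stop("`w` must be named by species")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative with positive sum")
  check_present(space, present)
  if (is.null(constants)) constants <- pool_constants(space)
  if (length(present) == 1L) return(list(value = 0, flag = "singleton"))
  x <- space_coords(space)[present, , drop = FALSE]
  dm <- as.matrix(stats::dist(x))
  diag(dm) <- Inf
  nn <- apply(dm, 1L, min)
  list(value = (sum(w * nn) / sum(w)) / constants$o_max, flag = NA_character_)
}

#' Compute the per-transect index table
#'
#' Assembles the eight monitored quantities for every transect of a
#' survey: species richness, total density, total biomass, FRic, and
#' FDis / FOri each weighted by density and by biomass. Values are on
#' their natural scale; log2 transforms belong to the modeling step.
#'
#' @param survey a `survey_table` (see [aggregate_censuses()]).
#' @param space a `functional_space` with `chosen_m` set, covering all
#'   surveyed species.
#' @return data.frame (one row per transect) with the transect design
#'   columns, the eight indices, and a `flags` column collecting
#'   per-transect computation flags.
#' @export
compute_index_table <- function(survey, space) {
  stopifnot(inherits(survey, "survey_table"))
  dens <- survey$density
  biom <- survey$biomass
  missing <- setdiff(colnames(dens), rownames(space$coordinates))
  if (length(missing))
    stop("surveyed species missing from the functional space: ",
         paste(missing, collapse = ", "))
  constants <- pool_constants(space)
  tr <- survey$transects
  n <- nrow(tr)
  out <- data.frame(
    transect_id = tr$transect_id, site = tr$site, zone = tr$zone,
    year = tr$year, season = tr$season, total_area = tr$total_area,
    species_richness = NA_real_, density_total = NA_real_,
    biomass_total = NA_real_, FRic = NA_real_,
    FDis_density = NA_real_, FDis_biomass = NA_real_,
    FOri_density = NA_real_, FOri_biomass = NA_real_,
    flags = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    di <- dens[i, ]
    present <- colnames(dens)[di > 0]
    if (!length(present)) stop("transect ", tr$transect_id[i], " has no species")
    wd <- di[di > 0]
    names(wd) <- present
    wb <- if (!is.null(biom)) {
      b <- biom[i, present]
      names(b) <- present
      b
    } else NULL
    fr <- functional_richness(space, present, constants)
    fdd <- functional_dispersion(space, wd, constants)
    fod <- functional_originality(space, wd, constants)
    out$species_richness[i] <- length(present)
    out$density_total[i] <- sum(di)
    out$FRic[i] <- fr$value
    out$FDis_density[i] <- fdd$value
    out$FOri_density[i] <- fod$value
    flags <- c(fr$flag, fdd$flag, fod$flag)
    if (!is.null(wb)) {
      fdb <- functional_dispersion(space, wb, constants)
      fob <- functional_originality(space, wb, constants)
      out$biomass_total[i] <- sum(biom[i, ])
      out$FDis_biomass[i] <- fdb$value
      out$FOri_biomass[i] <- fob$value
      flags <- c(flags, fdb$flag, fob$flag)
    }
    flags <- unique(flags[!is.na(flags)])
    out$flags[i] <- if (length(flags)) paste(flags, collapse = ";") else NA_character_
  }
  attr(out, "pool_constants") <- constants
  out
}

#' Names of the eight monitored indices
#' @return character vector in reporting order.
#' @export
index_names <- function() {
  c("species_richness", "density_total", "biomass_total", "FRic",
    "FDis_density", "FDis_biomass", "FOri_density", "FOri_biomass")
}
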
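# Visual-census ingestion: validation, aggregation of nearby censuses
# into transects, biomass estimation from lengths, and the two
# sampling-adequacy checks (species accumulation, transect-area ANOVA).
#
# Census records are long-format: one row per (census, species,
# size class) with the census design columns repeated. Counts within a
# size class are converted to weight with W = a * L^b at the class
# midpoint (modal size for schooling fish); no within-school size
# spread is modeled.

CENSUS_COLUMNS <- c("census_id", "site", "zone", "date", "depth_stratum",
                    "area", "species", "count", "size_class")
ZONE_LEVELS <- c("no_take", "traditional", "sustainable")

#' Season from calendar date
#'
#' Monitoring seasons: cold = January-June, warm = August-November.
#' July and December fall in neither season and are rejected.
#'
#' @param date a `Date` vector.
#' @return character vector, `"cold"` or `"warm"`.
#' @export
season_from_date <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  out <- ifelse(m <= 6, "cold", ifelse(m >= 8 & m <= 11, "warm", NA))
  if (anyNA(out))
    stop("records dated July or December have no defined season: ",
         paste(unique(format(as.Date(date)[is.na(out)], "%Y-%m")), collapse = ", "))
  out
}

#' Validate long-format census records
#'
#' Checks required columns, positive integer counts, positive areas,
#' 5-cm size-class midpoints (2.5, 7.5, 12.5, ...), valid zone labels,
#' and that each census has consistent design columns. Seasons are
#' derived from dates (and July/December rejected).
#'
#' @param records data.frame of census records; optional columns `x`,
#'   `y` (planar coordinates in m) and `group` (pre-assigned
#'   aggregation group).
#' @return the records with `date` coerced to `Date`, invisibly
#'   validated.
#' @export
validate_census_records <- function(records) {
  if (!is.data.frame(records)) stop("`records` must be a data.frame")
  miss <- setdiff(CENSUS_COLUMNS, names(records))
  if (length(miss))
    stop("census records are missing columns: ", paste(miss, collapse = ", "))
  records$date <- as.Date(records$date)
  if (anyNA(records$date)) stop("unparseable dates in census records")
  if (any(records$count <= 0) || any(records$count != round(records$count)))
    stop("counts must be positive integers")
  if (any(records$area <= 0)) stop("census areas must be positive")
  if (any(abs((records$size_class - 2.5) %% 5) > 1e-8))
    stop("size classes must be midpoints of 5-cm bins (2.5, 7.5, 12.5, ...)")
  badz <- !records$zone %in% ZONE_LEVELS
  if (any(badz))
    stop("unknown zone label(s): ", paste(unique(records$zone[badz]), collapse = ", "))
  season_from_date(records$date)
  meta_cols <- intersect(c("site", "zone", "date", "depth_stratum", "area",
                           "x", "y", "group"), names(records))
  for (cl in meta_cols) {
    k <- tapply(records[[cl]], records$census_id, function(v) length(unique(v)))
    if (any(k > 1L))
      stop("census design column '", cl, "' varies within census(es): ",
           paste(names(k)[k > 1L], collapse = ", "))
  }
  records
}

#' Fish weight from length
#'
#' Allometric length-weight relationship `W = a * L^b` with length in
#' cm and weight in g.
#'
#' @param length fish length(s), cm, positive.
#' @param a species scale coefficient, positive.
#' @param b allometric exponent; values outside `[2.5, 3.5]` trigger a
#'   warning (legitimate but unusual for fishes).
#' @return weight(s) in g.
#' @examples
#' estimate_biomass(10, a = 1, b = 3) # 1000 g
#' @export
estimate_biomass <- function(length, a, b) {
  if (any(length <= 0)) stop("length must be positive (cm)")
  if (any(a <= 0)) stop("length-weight coefficient `a` must be positive")
  if (any(b < 2.5 | b > 3.5))
    warning("allometric exponent b outside the typical [2.5, 3.5] range")
  a * length^b
}

# single-linkage connected components under a distance threshold
single_linkage_groups <- function(dmat, threshold) {
  n <- nrow(dmat)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && dmat[i, j] < threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

census_distance_matrix <- function(meta, distances) {
  n <- nrow(meta)
  ids <- meta$census_id
  if (!is.null(meta$group) && !anyNA(meta$group)) {
    dmat <- matrix(Inf, n, n)                      # "far" unless same group
    dmat[outer(meta$group, meta$group, `==`)] <- 0
    dimnames(dmat) <- list(ids, ids)
    attr(dmat, "source") <- "group"
    return(dmat)
  }
  if (!is.null(distances)) {
    sub <- distances[distances$census_a %in% ids & distances$census_b %in% ids, ,
                     drop = FALSE]
    dmat <- matrix(Inf, n, n, dimnames = list(ids, ids))
    diag(dmat) <- 0
    if (nrow(sub)) {
      ia <- match(sub$census_a, ids); ib <- match(sub$census_b, ids)
      dmat[cbind(ia, ib)] <- sub$distance
      dmat[cbind(ib, ia)] <- sub$distance
    }
    attr(dmat, "source") <- "distance_table"
    return(dmat)
  }
  if (!is.null(meta$x) && !is.null(meta$y) && !anyNA(meta$x) && !anyNA(meta$y)) {
    dmat <- as.matrix(stats::dist(cbind(meta$x, meta$y)))
    dimnames(dmat) <- list(ids, ids)
    attr(dmat, "source") <- "coordinates"
    return(dmat)
  }
  stop("cannot locate censuses ", paste(ids, collapse = ", "),
       ": provide a `group` column, a distance table, or x/y coordinates")
}

#' Aggregate visual censuses into transects
#'
#' Censuses performed at the same site on the same day in the same
#' depth stratum are merged into one transect when separated by less
#' than `distance_threshold` (default 200 m). Chained proximity is
#' resolved by single linkage: censuses end up together whenever they
#' are connected through a chain of sub-threshold distances. Location
#' information is taken, in order of precedence, from a pre-assigned
#' `group` column, an explicit pairwise `distances` table
#' (`census_a`, `census_b`, `distance` in m), or planar `x`/`y`
#' coordinates. Merged counts are summed and densities re-expressed per
#' 100 m2 of the combined area.
#'
#' @param records long-format census records (see
#'   [validate_census_records()]).
#' @param distance_threshold aggregation radius in m.
#' @param length_weight optional data.frame (`species`, `a`, `b`) of
#'   length-weight coefficients; required for the biomass matrix. An
#'   error names any observed species without coefficients.
#' @param distances optional pairwise distance table, see above.
#' @return a `survey_table`: list with `transects` (design data.frame:
#'   transect_id, site, zone, date, season, year, depth_stratum,
#'   total_area, n_censuses, species_richness), `density` and `biomass`
#'   matrices (transects x species, per 100 m2; `biomass` `NULL`
#'   without `length_weight`), and `grouping` (census -> transect log).
#' @export
aggregate_censuses <- function(records, distance_threshold = 200,
                               length_weight = NULL, distances = NULL) {
  records <- validate_census_records(records)
  if (!is.null(length_weight)) {
    need <- setdiff(unique(records$species), length_weight$species)
    if (length(need))
      stop("no length-weight coefficients for observed species: ",
           paste(sort(need), collapse = ", "))
    lwa <- stats::setNames(length_weight$a, length_weight$species)
    lwb <- stats::setNames(length_weight$b, length_weight$species)
    records$weight <- estimate_biomass(records$size_class,
                                       lwa[records$species],
                                       lwb[records$species]) * records$count
  }

  meta_cols <- intersect(c("census_id", "site", "zone", "date", "depth_stratum",
                           "area", "x", "y", "group"), names(records))
  meta <- unique(records[, meta_cols, drop = FALSE])
  meta$block <- paste(meta$site, meta$date, meta$depth_stratum, sep = "@")

  meta$transect_id <- NA_character_
  for (blk in unique(meta$block)) {
    sel <- which(meta$block == blk)
    if (length(sel) == 1L) {
      meta$transect_id[sel] <- meta$census_id[sel]
      next
    }
    dmat <- census_distance_matrix(meta[sel, , drop = FALSE], distances)
    grp <- single_linkage_groups(dmat, distance_threshold)
    for (g in unique(grp)) {
      members <- sel[grp == g]
      meta$transect_id[members] <-
        paste(sort(meta$census_id[members]), collapse = "+")
    }
  }

  records$transect_id <- meta$transect_id[match(records$census_id, meta$census_id)]

  area_by_transect <- tapply(meta$area, meta$transect_id, sum)
  first <- meta[!duplicated(meta$transect_id), , drop = FALSE]
  first <- first[order(first$site, first$date, first$transect_id), , drop = FALSE]
  tid <- first$transect_id
  transects <- data.frame(
    transect_id = tid, site = first$site, zone = first$zone,
    date = first$date, season = season_from_date(first$date),
    year = as.integer(format(first$date, "%Y")),
    depth_stratum = first$depth_stratum,
    total_area = as.numeric(area_by_transect[tid]),
    n_censuses = as.integer(table(meta$transect_id)[tid]),
    stringsAsFactors = FALSE)

  species <- sort(unique(records$species))
  counts <- tapply(records$count,
                   list(factor(records$transect_id, levels = tid),
                        factor(records$species, levels = species)),
                   sum, default = 0)
  density <- counts * 100 / transects$total_area
  biomass <- NULL
  if (!is.null(length_weight)) {
    wsum <- tapply(records$weight,
                   list(factor(records$transect_id, levels = tid),
                        factor(records$species, levels = species)),
                   sum, default = 0)
    biomass <- wsum * 100 / transects$total_area
  }
  transects$species_richness <- as.integer(rowSums(density > 0))

  structure(list(transects = transects,
                 density = density, biomass = biomass,
                 grouping = data.frame(census_id = meta$census_id,
                                       transect_id = meta$transect_id,
                                       stringsAsFactors = FALSE),
                 distance_threshold = distance_threshold),
            class = "survey_table")
}

#' Construct a survey table directly
#'
#' For tests and external data already aggregated to transects.
#'
#' @param transects design data.frame with at least `transect_id`,
#'   `site`, `zone`, `year`, `season`, `total_area`.
#' @param density transects x species matrix, individuals per 100 m2.
#' @param biomass optional matching biomass matrix, g per 100 m2.
#' @return a `survey_table`.
#' @export
as_survey_table <- function(transects, density, biomass = NULL) {
  stopifnot(nrow(transects) == nrow(density))
  if (!is.null(biomass)) {
    stopifnot(identical(dim(density), dim(biomass)))
    if (any((density > 0) != (biomass > 0)))
      stop("a species must have biomass > 0 exactly where density > 0")
  }
  rownames(density) <- transects$transect_id
  if (!is.null(biomass)) rownames(biomass) <- transects$transect_id
  transects$species_richness <- as.integer(rowSums(density > 0))
  structure(list(transects = transects, density = density, biomass = biomass,
                 grouping = NULL, distance_threshold = NA_real_),
            class = "survey_table")
}

#' @export
print.survey_table <- function(x, ...) {
  cat("Survey table:", nrow(x$transects), "transects,",
      ncol(x$density), "species\n")
  cat("  sites:", length(unique(x$transects$site)),
      " years:", paste(range(x$transects$year), collapse = "-"),
      " mean area:", round(mean(x$transects$total_area)), "m2\n")
  if (is.null(x$biomass)) cat("  (no biomass matrix: length-weight coefficients not supplied)\n")
  invisible(x)
}

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Species accumulation curve (randomization method)
#'
#' Mean and SD of the cumulative number of distinct species in the
#' first k transects over random orderings of the transects, via
#' [vegan::specaccum()] with `method = "random"`. Used to check that
#' the sampling effort saturates the species pool.
#'
#' @param survey a `survey_table` with at least 2 transects.
#' @param n_permutations number of random orderings.
#' @param seed RNG seed (the curve is reproducible given the seed).
#' @return data.frame with `transects`, `richness_mean`, `richness_sd`.
#' @export
species_accumulation <- function(survey, n_permutations = 100L, seed = 1L) {
  stopifnot(inherits(survey, "survey_table"))
  if (nrow(survey$density) < 2L) stop("need at least 2 transects")
  inc <- (survey$density > 0) * 1
  sa <- with_seed(seed,
    vegan::specaccum(inc, method = "random", permutations = n_permutations))
  data.frame(transects = sa$sites, richness_mean = sa$richness,
             richness_sd = sa$sd)
}

#' Transect-area effect on species richness
#'
#' One-way ANOVA of species richness across transect-area groups, with
#' Tukey HSD post-hoc pairwise comparisons. Used to check whether the
#' aggregation-induced spread of transect areas biases richness.
#'
#' @param survey a `survey_table` whose transects fall into at least
#'   two distinct area groups, each with at least two transects.
#' @return list (`area_effect_test`) with `statistic` (F), `df`
#'   (numerator, denominator), `p_value`, `posthoc` (Tukey table as
#'   data.frame), `method` and `posthoc_method`.
#' @export
area_effect_test <- function(survey) {
  stopifnot(inherits(survey, "survey_table"))
  d <- data.frame(richness = survey$transects$species_richness,
                  area = factor(survey$transects$total_area))
  tab <- table(d$area)
  if (length(tab) < 2L)
    stop("need at least two transect-area groups (found ",
         length(tab), ")")
  if (any(tab < 2L))
    stop("each area group needs at least two transects; too small: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  fit <- stats::aov(richness ~ area, data = d)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$area
  structure(list(statistic = an$`F value`[1L],
                 df = c(an$Df[1L], an$Df[2L]),
                 p_value = an$`Pr(>F)`[1L],
                 posthoc = data.frame(comparison = rownames(tk),
                                      as.data.frame(tk), row.names = NULL),
                 method = "one-way ANOVA",
                 posthoc_method = "Tukey HSD"),
            class = "area_effect_test")
}

#' @export
print.area_effect_test <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.3f, p = %.3g  [post hoc: %s]\n",
              x$method, x$df[1L], x$df[2L], x$statistic, x$p_value,
              x$posthoc_method))
  invisible(x)
}
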
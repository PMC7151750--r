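# Synthetic survey generator.
#
# Emulates the structure of the monitoring program the analysis
# assumes: 11 fixed sites in three management-zone types surveyed
# twice a year (cold and warm season) over 13 years, several visual
# censuses per visit that the 200-m rule aggregates into transects,
# species-level log-scale temporal trends, Gaussian site and season
# random effects, negative-binomial counts, per-species size
# distributions binned to 5-cm classes, and length-weight coefficients.
# Every draw is reproducible from a single seed, and the generator
# returns the ground truth used, so recovery can be tested end to end.

#' Default trait-level probabilities for the survey generator
#'
#' Marginal level frequencies loosely typical of a rocky-reef fish
#' pool: mid-sized, diurnal, mobile-invertebrate feeders dominate.
#'
#' @return named list of per-trait probability vectors.
#' @export
default_trait_probs <- function() {
  list(
    size_class     = c(0.05, 0.20, 0.30, 0.25, 0.15, 0.05),
    mobility       = c(0.35, 0.40, 0.25),
    activity       = c(0.75, 0.25),
    gregariousness = c(0.35, 0.25, 0.25, 0.15),
    water_column   = c(0.45, 0.35, 0.20),
    diet           = c(0.12, 0.10, 0.35, 0.15, 0.13, 0.15)
  )
}

#' Default monitoring sites for the survey generator
#'
#' Eleven fixed sites split across the three management-zone types
#' (4 no-take, 3 traditional-use, 4 sustainable-use).
#'
#' @return data.frame with columns `site` and `zone`.
#' @export
default_sites <- function() {
  data.frame(site = sprintf("S%02d", 1:11),
             zone = c(rep("no_take", 4), rep("traditional", 3),
                      rep("sustainable", 4)),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults describe the monitoring design the pipeline is meant for:
#' 11 sites (4 no-take, 3 traditional, 4 sustainable), 2005-2017, two
#' seasonal visits per year, 4-8 censuses per visit (100 m2 before the
#' 2009 methodology change, 60 m2 after) arranged so the 200-m rule
#' merges them into about 320 transects, a 100-species pool with a
#' lognormal abundance distribution (median 0.1 individuals per 100 m2,
#' log-SD 1.8, so a few dominant species carry most individuals and
#' roughly a quarter of the pool occurs in half the transects), and
#' overdispersed negative-binomial counts.
#'
#' @param seed mandatory RNG seed.
#' @param n_species pool size (at least 2).
#' @param years calendar years surveyed.
#' @param sites data.frame (`site`, `zone`).
#' @param season_months named integer vector: representative survey
#'   month per season (must avoid July and December).
#' @param censuses_per_visit integer range to draw from per visit.
#' @param census_area areas (m2) before/after `area_change_year`.
#' @param area_change_year year the census area changed.
#' @param trait_probs named list of level probabilities per trait
#'   (each summing to 1).
#' @param baseline_mean,baseline_sd log-scale mean and SD of species
#'   baseline densities (individuals per 100 m2).
#' @param year_slope per-year log-scale trend; scalar or one value per
#'   species.
#' @param zone_effects named log-scale offsets per zone type.
#' @param sd_site,sd_season SDs of Gaussian site / season random
#'   effects (log scale).
#' @param nb_size negative-binomial size (dispersion) parameter;
#'   `Inf` switches to Poisson noise (oracle checks).
#' @param length_cv lognormal CV of individual lengths around the
#'   species' typical length (60% of its size-class midpoint).
#' @param lw_a_meanlog,lw_a_sdlog,lw_b_range length-weight coefficient
#'   distributions.
#' @param p_commercial probability a species is commercially targeted.
#' @param cluster_split_prob probability a visit's censuses fall in two
#'   separate clusters (yielding two transects).
#' @param cluster_spacing,cluster_gap within-cluster census spacing and
#'   between-cluster gap, m.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_species = 100L,
                       years = 2005:2017,
                       sites = default_sites(),
                       season_months = c(cold = 3L, warm = 9L),
                       censuses_per_visit = 4:8,
                       census_area = c(before = 100, after = 60),
                       area_change_year = 2009L,
                       trait_probs = default_trait_probs(),
                       baseline_mean = log(0.1),
                       baseline_sd = 1.8,
                       year_slope = 0,
                       zone_effects = c(no_take = 0, traditional = 0,
                                        sustainable = 0),
                       sd_site = 0.4,
                       sd_season = 0.3,
                       nb_size = 0.7,
                       length_cv = 0.25,
                       lw_a_meanlog = log(0.015),
                       lw_a_sdlog = 0.3,
                       lw_b_range = c(2.7, 3.2),
                       p_commercial = 0.28,
                       cluster_split_prob = 0.15,
                       cluster_spacing = 150,
                       cluster_gap = 1000) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (n_species < 2L) stop("n_species must be at least 2 (a single species gives a degenerate trait space)")
  voc <- trait_vocabulary()
  stopifnot(identical(names(trait_probs), names(voc)))
  for (tr in names(voc)) {
    p <- trait_probs[[tr]]
    if (length(p) != length(voc[[tr]]) || abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("trait_probs$", tr, " must be ", length(voc[[tr]]),
           " non-negative probabilities summing to 1")
  }
  stopifnot(sd_site >= 0, sd_season >= 0, nb_size > 0,
            all(sites$zone %in% ZONE_LEVELS),
            !any(season_months %in% c(7L, 12L)))
  slopes <- rep_len(year_slope, n_species)
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              years = years, sites = sites, season_months = season_months,
              censuses_per_visit = censuses_per_visit,
              census_area = census_area,
              area_change_year = area_change_year,
              trait_probs = trait_probs, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, year_slope = slopes,
              zone_effects = zone_effects, sd_site = sd_site,
              sd_season = sd_season, nb_size = nb_size,
              length_cv = length_cv, lw_a_meanlog = lw_a_meanlog,
              lw_a_sdlog = lw_a_sdlog, lw_b_range = lw_b_range,
              p_commercial = p_commercial,
              cluster_split_prob = cluster_split_prob,
              cluster_spacing = cluster_spacing, cluster_gap = cluster_gap)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a species trait table
#'
#' Traits are sampled independently per trait from the configured level
#' probabilities; resampled (bounded retries) if all species collapse
#' into a single functional entity.
#'
#' @param config a `sim_config`.
#' @return trait table (species `sp001`, ... as row names).
#' @export
generate_trait_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  voc <- trait_vocabulary()
  with_seed(config$seed, {
    for (try in 1:100) {
      tab <- as.data.frame(lapply(names(voc), function(tr) {
        sample(voc[[tr]], config$n_species, replace = TRUE,
               prob = config$trait_probs[[tr]])
      }), col.names = names(voc), stringsAsFactors = FALSE)
      rownames(tab) <- sprintf("sp%03d", seq_len(config$n_species))
      if (length(unique(functional_entities(tab)$fe)) >= 2L) return(tab)
    }
    stop("could not generate a trait table with at least 2 functional entities")
  })
}

#' Generate a synthetic census data set with known truth
#'
#' Counts for species s in a census of area A at year t are drawn from
#' a negative binomial with mean
#' `exp(baseline_s + slope_s * (t - t0) + site + season + zone) * A / 100`;
#' individual lengths are drawn per species and binned to 5-cm classes.
#' Census positions are laid out so that the 200-m aggregation rule
#' merges each within-visit cluster into one known transect.
#'
#' @param config a `sim_config`.
#' @param traits trait table from [generate_trait_table()]; regenerated
#'   from the config when omitted.
#' @return list with `records` (long census data.frame ready for
#'   [aggregate_censuses()]), `length_weight`, `commercial`, and
#'   `truth` (per-species slopes and expected directions, random
#'   effects, expected census -> transect grouping, the config).
#' @export
generate_surveys <- function(config, traits = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(traits)) traits <- generate_trait_table(config)
  species <- rownames(traits)
  nsp <- length(species)
  with_seed(config$seed + 1000L, {
    baseline <- stats::rnorm(nsp, config$baseline_mean, config$baseline_sd)
    slopes <- config$year_slope
    typical_len <- size_class_midpoints()[traits$size_class] * 0.6
    lw <- data.frame(species = species,
                     a = stats::rlnorm(nsp, config$lw_a_meanlog,
                                       config$lw_a_sdlog),
                     b = stats::runif(nsp, config$lw_b_range[1],
                                      config$lw_b_range[2]),
                     stringsAsFactors = FALSE)
    commercial <- species[stats::runif(nsp) < config$p_commercial]
    site_eff <- stats::setNames(
      stats::rnorm(nrow(config$sites), 0, config$sd_site), config$sites$site)
    season_eff <- stats::setNames(
      stats::rnorm(length(config$season_months), 0, config$sd_season),
      names(config$season_months))

    ## census-level design
    visits <- expand.grid(site = config$sites$site, year = config$years,
                          season = names(config$season_months),
                          stringsAsFactors = FALSE)
    visits$zone <- config$sites$zone[match(visits$site, config$sites$site)]
    cen <- list()
    for (v in seq_len(nrow(visits))) {
      nc <- if (length(config$censuses_per_visit) > 1L)
        sample(config$censuses_per_visit, 1L) else config$censuses_per_visit
      split2 <- nc >= 4L && stats::runif(1) < config$cluster_split_prob
      cluster <- if (split2) rep(1:2, c(floor(nc / 2), ceiling(nc / 2)))
                 else rep(1L, nc)
      base_x <- 10000 * match(visits$site[v], config$sites$site)
      x <- base_x + (cluster - 1L) * config$cluster_gap +
        stats::ave(seq_len(nc), cluster, FUN = seq_along) * config$cluster_spacing
      yr <- visits$year[v]
      area <- if (yr < config$area_change_year) config$census_area[["before"]]
              else config$census_area[["after"]]
      cen[[v]] <- data.frame(
        census_id = sprintf("%s-%d-%s-c%02d", visits$site[v], yr,
                            visits$season[v], seq_len(nc)),
        site = visits$site[v], zone = visits$zone[v],
        date = as.Date(sprintf("%d-%02d-15", yr,
                               config$season_months[[visits$season[v]]])),
        depth_stratum = "5-15m", area = area, x = x, y = 0,
        year = yr, season = visits$season[v], cluster = cluster,
        stringsAsFactors = FALSE)
    }
    cen <- do.call(rbind, cen)

    ## expected transect grouping from the constructed clusters
    key <- paste(cen$site, cen$date, cen$depth_stratum, cen$cluster)
    expected <- stats::ave(cen$census_id, key,
                           FUN = function(id) paste(sort(id), collapse = "+"))
    expected_transects <- data.frame(census_id = cen$census_id,
                                     expected_transect = expected,
                                     stringsAsFactors = FALSE)

    ## counts: censuses x species
    log_mu <- outer(
      log(cen$area / 100) + site_eff[cen$site] + season_eff[cen$season] +
        config$zone_effects[cen$zone],
      baseline, `+`) +
      outer(cen$year - config$years[1], slopes)
    mu <- exp(log_mu)
    counts <- if (is.infinite(config$nb_size)) {
      matrix(stats::rpois(length(mu), mu), nrow(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_size),
             nrow(mu))
    }

    ## expand positive cells into individuals, bin lengths to 5-cm classes
    pos <- which(counts > 0, arr.ind = TRUE)
    ncell <- nrow(pos)
    if (!ncell) stop("simulation produced no individuals; raise baseline_mean")
    cell_n <- counts[pos]
    cell_of <- rep.int(seq_len(ncell), cell_n)
    sp_of <- pos[cell_of, 2L]
    len <- stats::rlnorm(length(sp_of), log(typical_len[sp_of]),
                         config$length_cv)
    bin <- pmax(0, floor(len / 5)) * 5 + 2.5
    agg_key <- paste(cell_of, bin, sep = "/")
    tab <- table(agg_key)
    parts <- strsplit(names(tab), "/", fixed = TRUE)
    cell_idx <- as.integer(vapply(parts, `[`, "", 1L))
    records <- data.frame(
      cen[pos[cell_idx, 1L],
          c("census_id", "site", "zone", "date", "depth_stratum",
            "area", "x", "y")],
      species = species[pos[cell_idx, 2L]],
      count = as.integer(tab),
      size_class = as.numeric(vapply(parts, `[`, "", 2L)),
      row.names = NULL, stringsAsFactors = FALSE)
    records <- records[order(records$census_id, records$species,
                             records$size_class), ]
    rownames(records) <- NULL

    expected_direction <- ifelse(slopes > 0, "winner",
                                 ifelse(slopes < 0, "loser", "stable"))
    mean_slope <- stats::weighted.mean(slopes, exp(baseline))
    idx_dir <- if (all(slopes == 0)) "stable"
               else if (mean_slope > 0) "increase"
               else if (mean_slope < 0) "decrease" else "mixed"
    truth <- list(baseline = stats::setNames(baseline, species),
                  slopes = stats::setNames(slopes, species),
                  expected_direction = stats::setNames(expected_direction,
                                                       species),
                  site_effects = site_eff, season_effects = season_eff,
                  zone_effects = config$zone_effects,
                  expected_transects = expected_transects,
                  abundance_trend = idx_dir,
                  config = config)
    list(records = records, length_weight = lw, commercial = commercial,
         traits = traits, truth = truth)
  })
}

#' Hand-constructed fixture communities
#'
#' Small coordinate sets with analytically known index behavior,
#' including the two canonical dispersion scenarios: a winner species
#' far from the weighted centroid whose increasing weight must raise
#' FDis (case 1), and a loser species close to the centroid whose
#' decreasing weight must also raise FDis (case 2).
#'
#' @return named list of fixtures; each has a `space`
#'   (`functional_space` built from explicit 2-D coordinates) and one
#'   or more named weight vectors.
#' @export
fixture_communities <- function() {
  sq <- rbind(a = c(0, 0), b = c(1, 0), c = c(1, 1), d = c(0, 1),
              center = c(0.5, 0.5))
  square <- list(space = as_functional_space(sq),
                 weights = stats::setNames(rep(1, 5), rownames(sq)))

  ## case 1: tight central cluster + one outlying species
  c1 <- rbind(core1 = c(-0.05, 0), core2 = c(0.05, 0), core3 = c(0, 0.05),
              core4 = c(0, -0.05), outlier = c(1, 0))
  case1 <- list(space = as_functional_space(c1),
                weights = stats::setNames(rep(1, 5), rownames(c1)),
                focal = "outlier")

  ## case 2: ring of species + one species at their centroid
  th <- 2 * pi * (0:4) / 5
  c2 <- rbind(0.5 * cbind(cos(th), sin(th)), central = c(0, 0))
  rownames(c2) <- c(paste0("ring", 1:5), "central")
  case2 <- list(space = as_functional_space(c2),
                weights = stats::setNames(rep(1, 6), rownames(c2)),
                focal = "central")

  coll <- rbind(p1 = c(0, 0), p2 = c(1, 0), p3 = c(2, 0), off = c(1, 2))
  collinear <- list(space = as_functional_space(coll),
                    weights = stats::setNames(rep(1, 3),
                                              rownames(coll)[1:3]))

  list(square = square, fig_case1 = case1, fig_case2 = case2,
       collinear = collinear)
}
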
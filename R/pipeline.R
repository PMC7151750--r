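# End-to-end orchestration: censuses -> transects -> functional space
# -> index table -> sampling checks -> zone comparisons -> temporal
# trends -> commercial trend -> winners/losers, plus tidy-CSV/JSON
# persistence and a reproducibility manifest.

trend_summary_row <- function(tr) {
  data.frame(response = tr$response, transform = tr$transform,
             estimate = tr$estimate, ci_low = tr$ci[1], ci_high = tr$ci[2],
             p_value = tr$p_value,
             percent_change = tr$percent_change$value,
             pc_ci_low = if (!is.null(tr$percent_change$ci))
               tr$percent_change$ci[1] else NA_real_,
             pc_ci_high = if (!is.null(tr$percent_change$ci))
               tr$percent_change$ci[2] else NA_real_,
             degenerate = isTRUE(tr$degenerate),
             stringsAsFactors = FALSE)
}

zone_summary_row <- function(z) {
  data.frame(response = z$response, transform = z$transform,
             F_value = z$statistic, df_num = z$df[1], df_den = z$df[2],
             p_value = z$p_value, degenerate = isTRUE(z$degenerate),
             stringsAsFactors = FALSE)
}

index_transforms <- function() {
  c(species_richness = "none", density_total = "log2",
    biomass_total = "log2", FRic = "none",
    FDis_density = "none", FDis_biomass = "none",
    FOri_density = "none", FOri_biomass = "none")
}

#' Run the full monitoring analysis
#'
#' From raw census records (or a simulation config) to the full report
#' bundle: transect aggregation, functional space, the eight
#' per-transect indices, species accumulation, per-index zone
#' comparisons and temporal trends with percent changes, commercial
#' biomass trend, and winner/loser classification of the common
#' species. With `out_dir` set, tidy CSV outputs and a JSON manifest
#' (seeds, switches, versions) are written; identical inputs and seed
#' give identical outputs.
#'
#' @param records long-format census records; omit when `config` is a
#'   `sim_config` (the data are then generated).
#' @param traits trait table covering all surveyed species.
#' @param length_weight length-weight coefficient table
#'   (`species`, `a`, `b`).
#' @param commercial character vector of commercial species.
#' @param config optional `sim_config` used to generate all of the
#'   above.
#' @param distance_threshold aggregation radius (m).
#' @param correction PCoA negative-eigenvalue correction.
#' @param axes explicit number of functional axes (default: mSD
#'   choice up to `max_axes`).
#' @param max_axes cap for the mSD axis search.
#' @param common_threshold occurrence proportion defining common
#'   species.
#' @param alpha significance level for trend classification.
#' @param accumulation_permutations permutations for the accumulation
#'   curve.
#' @param seed RNG seed for the accumulation randomization.
#' @param out_dir optional output directory.
#' @return a `reefdiv_report` list: `survey`, `space`, `indices`,
#'   `accumulation`, `area_test`, `zone_comparisons`, `temporal_trends`
#'   (and their summary tables), `commercial_trend`, `common_species`,
#'   `winners_losers`, `wl_counts`, `truth` (simulations only),
#'   `manifest`.
#' @export
run_pipeline <- function(records = NULL, traits = NULL, length_weight = NULL,
                         commercial = NULL, config = NULL,
                         distance_threshold = 200, correction = "sqrt",
                         axes = NULL, max_axes = 6L,
                         common_threshold = 0.5, alpha = 0.05,
                         accumulation_permutations = 100L, seed = 1L,
                         out_dir = NULL) {
  truth <- NULL
  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    sim <- generate_surveys(config)
    records <- sim$records; traits <- sim$traits
    length_weight <- sim$length_weight; commercial <- sim$commercial
    truth <- sim$truth
  }
  if (is.null(records) || is.null(traits))
    stop("need census `records` and `traits` (or a sim `config`)")

  survey <- aggregate_censuses(records, distance_threshold = distance_threshold,
                               length_weight = length_weight)
  space <- build_functional_space(traits, correction = correction,
                                  axes = axes, max_m = max_axes)
  indices <- compute_index_table(survey, space)
  accumulation <- species_accumulation(survey,
                                       n_permutations = accumulation_permutations,
                                       seed = seed)
  area_test <- tryCatch(area_effect_test(survey), error = function(e) e)

  transforms <- index_transforms()
  model_data <- indices
  zone_comparisons <- lapply(index_names(), function(ix)
    fit_zone_comparison(model_data, ix, transform = transforms[[ix]]))
  names(zone_comparisons) <- index_names()
  temporal_trends <- lapply(index_names(), function(ix)
    fit_temporal_trend(model_data, ix, transform = transforms[[ix]]))
  names(temporal_trends) <- index_names()

  commercial_trend <- if (!is.null(commercial) && !is.null(survey$biomass))
    commercial_biomass_trend(survey, commercial)
  common_species <- common_species_filter(survey, common_threshold)
  winners_losers <- if (length(common_species))
    classify_winners_losers(survey, common_species, alpha = alpha)
  wl_counts <- if (!is.null(winners_losers)) winner_loser_counts(winners_losers)

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefdiv")),
    r_version = R.version.string,
    seed = seed,
    distance_threshold = distance_threshold,
    correction_requested = correction,
    correction_applied = space$correction_applied,
    axes = space$chosen_m,
    axes_overridden = !is.null(axes),
    common_threshold = common_threshold, alpha = alpha,
    degenerate_hull_policy = "flag-and-zero",
    nb_rounding = "round-half-to-even",
    simulated = !is.null(config),
    sim_seed = if (!is.null(config)) config$seed)

  report <- structure(list(
    survey = survey, space = space, indices = indices,
    accumulation = accumulation, area_test = area_test,
    zone_comparisons = zone_comparisons,
    zone_summary = do.call(rbind, lapply(zone_comparisons, zone_summary_row)),
    temporal_trends = temporal_trends,
    trend_summary = do.call(rbind, lapply(temporal_trends, trend_summary_row)),
    commercial_trend = commercial_trend,
    common_species = common_species,
    winners_losers = winners_losers, wl_counts = wl_counts,
    truth = truth, manifest = manifest), class = "reefdiv_report")
  rownames(report$zone_summary) <- rownames(report$trend_summary) <- NULL

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Persist a report bundle as tidy CSV + JSON
#'
#' @param report a `reefdiv_report`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(report$survey$transects, "transects.csv")
  wr(data.frame(transect_id = rownames(report$survey$density),
                report$survey$density, check.names = FALSE),
     "density.csv")
  if (!is.null(report$survey$biomass))
    wr(data.frame(transect_id = rownames(report$survey$biomass),
                  report$survey$biomass, check.names = FALSE),
       "biomass.csv")
  if (!is.null(report$survey$grouping)) wr(report$survey$grouping, "grouping.csv")
  wr(data.frame(species = rownames(report$space$coordinates),
                report$space$coordinates), "space_coordinates.csv")
  wr(report$space$msd, "axis_quality_msd.csv")
  wr(report$indices, "index_table.csv")
  wr(report$accumulation, "accumulation_curve.csv")
  wr(report$zone_summary, "zone_comparisons.csv")
  wr(report$trend_summary, "temporal_trends.csv")
  if (!is.null(report$winners_losers)) {
    wr(as.data.frame(report$winners_losers), "winners_losers.csv")
    wr(report$wl_counts, "winner_loser_counts.csv")
  }
  extras <- list(
    manifest = report$manifest,
    pool_constants = attr(report$indices, "pool_constants"),
    eigenvalues = report$space$eigenvalues,
    commercial_trend = if (!is.null(report$commercial_trend))
      trend_summary_row(report$commercial_trend),
    common_species = report$common_species)
  jsonlite::write_json(extras, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.reefdiv_report <- function(x, ...) {
  cat("Monitoring analysis report\n")
  cat("  transects:", nrow(x$survey$transects),
      " species pool:", ncol(x$survey$density),
      " axes:", x$space$chosen_m, "\n")
  cat("  temporal percent changes over", x$temporal_trends[[1]]$span, "years:\n")
  ts <- x$trend_summary
  for (i in seq_len(nrow(ts)))
    cat(sprintf("    %-16s %+6.1f%%  (p = %.3g)\n", ts$response[i],
                ts$percent_change[i], ts$p_value[i]))
  if (!is.null(x$wl_counts)) {
    cat("  common species:", length(x$common_species), "\n")
    for (i in seq_len(nrow(x$wl_counts)))
      cat(sprintf("    %-10s winners %d, losers %d, stable %d, excluded %d\n",
                  x$wl_counts$metric[i], x$wl_counts$winners[i],
                  x$wl_counts$losers[i], x$wl_counts$stable[i],
                  x$wl_counts$excluded[i]))
  }
  invisible(x)
}

#' Read census records from CSV
#'
#' Long format, one row per (census, species, size class); see
#' [validate_census_records()] for the required columns.
#'
#' @param path CSV file.
#' @return validated records data.frame.
#' @export
read_census_csv <- function(path) {
  validate_census_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a species trait table from CSV
#'
#' First column `species`, then the six trait columns.
#'
#' @param path CSV file.
#' @return validated trait table with species row names.
#' @export
read_traits_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(x)) stop("trait CSV needs a `species` column")
  rownames(x) <- x$species
  validate_trait_table(x[setdiff(names(x), "species")])
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_pipeline()] (paths
#' `records`, `traits`, `length_weight`, `commercial_list` plus the
#' scalar switches). Referenced files must exist.
#'
#' @param path YAML file.
#' @return named list of arguments for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (key in c("records", "traits")) {
    if (!is.null(cfg[[key]])) {
      if (!file.exists(cfg[[key]])) stop("missing input file: ", cfg[[key]])
      args[[key]] <- if (key == "records") read_census_csv(cfg[[key]])
                     else read_traits_csv(cfg[[key]])
    }
  }
  if (!is.null(cfg$length_weight)) {
    if (!file.exists(cfg$length_weight)) stop("missing input file: ", cfg$length_weight)
    args$length_weight <- utils::read.csv(cfg$length_weight,
                                          stringsAsFactors = FALSE)
  }
  if (!is.null(cfg$commercial_list)) {
    if (!file.exists(cfg$commercial_list)) stop("missing input file: ", cfg$commercial_list)
    args$commercial <- utils::read.csv(cfg$commercial_list,
                                       stringsAsFactors = FALSE)[[1L]]
  }
  for (key in c("distance_threshold", "correction", "axes", "max_axes",
                "common_threshold", "alpha", "seed", "out_dir"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  args
}
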
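small_sites <- function(n = 3) default_sites()[c(1, 5, 8)[seq_len(n)], ]

test_that("generation is deterministic under a seed", {
  cfg <- sim_config(seed = 7, n_species = 12, years = 2010:2012,
                    sites = small_sites(), censuses_per_visit = 2)
  t1 <- generate_trait_table(cfg)
  t2 <- generate_trait_table(cfg)
  expect_identical(t1, t2)
  s1 <- generate_surveys(cfg)
  s2 <- generate_surveys(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$slopes, s2$truth$slopes)
  # a different seed changes the draws
  cfg2 <- sim_config(seed = 8, n_species = 12, years = 2010:2012,
                     sites = small_sites(), censuses_per_visit = 2)
  expect_false(identical(generate_trait_table(cfg2), t1))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, n_species = 1), "at least 2")
  bad <- default_trait_probs()
  bad$diet <- c(1, 1, 1, 1, 1, 1)
  expect_error(sim_config(seed = 1, trait_probs = bad), "summing to 1")
})

test_that("trait level frequencies respect the configured probabilities", {
  voc <- trait_vocabulary()
  # uniform levels, n = 200: every level count inside exact binomial
  # bounds; 28 level checks run at once, so each uses 99.99% bounds to
  # keep the family-wise false-positive rate ~0.3%
  probs <- lapply(voc, function(l) rep(1 / length(l), length(l)))
  cfg <- sim_config(seed = 11, n_species = 200, trait_probs = probs)
  tab <- generate_trait_table(cfg)
  for (tr in names(voc)) {
    p <- 1 / length(voc[[tr]])
    cnt <- table(factor(tab[[tr]], levels = voc[[tr]]))
    lo <- qbinom(0.00005, 200, p); hi <- qbinom(0.99995, 200, p)
    expect_true(all(cnt >= lo & cnt <= hi),
                label = paste("level frequencies plausible for", tr))
  }
  expect_gte(length(unique(functional_entities(tab)$fe)), 2L)
  # heavily skewed probabilities land on the intended levels (catches
  # any level/probability misalignment that uniform draws cannot)
  skew <- lapply(voc, function(l) {
    p <- rep(0.02, length(l)); p[1] <- 1 - 0.02 * (length(l) - 1); p
  })
  cfg2 <- sim_config(seed = 3, n_species = 500, trait_probs = skew)
  tab2 <- generate_trait_table(cfg2)
  for (tr in names(voc))
    expect_gt(mean(tab2[[tr]] == voc[[tr]][1]), 0.8)
})

test_that("with no effects and Poisson noise, mean counts match the closed form", {
  cfg <- sim_config(seed = 13, n_species = 5, years = 2010:2012,
                    sites = small_sites(1), censuses_per_visit = 8,
                    baseline_mean = log(6), baseline_sd = 0,
                    sd_site = 0, sd_season = 0, nb_size = Inf,
                    cluster_split_prob = 0)
  sim <- generate_surveys(cfg)
  # per-census expected count = exp(baseline) * area / 100
  per_census <- aggregate(count ~ census_id + area, data = sim$records, sum)
  n_censuses <- length(unique(sim$records$census_id))
  expect_equal(nrow(per_census), n_censuses)   # every census has individuals
  mean_by_area <- tapply(per_census$count / 5, per_census$area, mean)
  for (a in names(mean_by_area))
    expect_equal(unname(mean_by_area[[a]]), 6 * as.numeric(a) / 100,
                 tolerance = 0.1)
})

test_that("census layout reproduces the intended transect grouping", {
  cfg <- sim_config(seed = 17, n_species = 10, years = 2008:2010,
                    sites = small_sites(), censuses_per_visit = 4:6,
                    cluster_split_prob = 0.5, baseline_mean = log(4))
  sim <- generate_surveys(cfg)
  sv <- aggregate_censuses(sim$records, length_weight = sim$length_weight)
  got <- sv$grouping
  want <- sim$truth$expected_transects
  m <- merge(got, want, by = "census_id")
  expect_equal(m$transect_id, m$expected_transect)
  # both one- and two-transect visits occur at this split probability
  expect_gt(nrow(sv$transects), length(unique(paste(sv$transects$site,
                                                    sv$transects$date))))
})

test_that("dispersion fixtures behave like the two canonical cases", {
  fx <- fixture_communities()

  # case 1: increasing the weight of a species far from the centroid
  # strictly increases dispersion (while it remains a minority of the
  # total weight; with most of the weight on one point dispersion must
  # eventually fall again)
  c1 <- fx$fig_case1
  kc1 <- pool_constants(c1$space)
  vals <- sapply(c(1, 1.25, 1.5, 2), function(mult) {
    w <- c1$weights
    w[c1$focal] <- w[c1$focal] * mult
    functional_dispersion(c1$space, w, kc1)$value
  })
  expect_true(all(diff(vals) > 0))

  # case 2: decreasing the weight of a species close to the centroid
  # strictly increases dispersion
  c2 <- fx$fig_case2
  kc2 <- pool_constants(c2$space)
  vals2 <- sapply(c(1, 1 / 2, 1 / 4, 1 / 8), function(mult) {
    w <- c2$weights
    w[c2$focal] <- w[c2$focal] * mult
    functional_dispersion(c2$space, w, kc2)$value
  })
  expect_true(all(diff(vals2) > 0))

  # equal weights on a symmetric point set: weighted centroid at the
  # geometric center
  sq <- fx$square
  x <- sq$space$coordinates[c("a", "b", "c", "d"), ]
  w <- rep(1, 4)
  ctr <- colSums(x * w) / sum(w)
  expect_equal(unname(ctr), unname(colMeans(x)))
})

test_that("injected community-wide decline propagates to the index trends", {
  cfg <- sim_config(seed = 19, n_species = 25, years = 2005:2017,
                    sites = default_sites()[c(1, 2, 5, 6, 8, 9), ],
                    censuses_per_visit = 3, baseline_mean = log(3),
                    baseline_sd = 0.8, year_slope = log(0.97),
                    sd_site = 0.2, sd_season = 0.15, nb_size = 2)
  sim <- generate_surveys(cfg)
  expect_equal(sim$truth$abundance_trend, "decrease")
  sv <- aggregate_censuses(sim$records, length_weight = sim$length_weight)
  sp <- build_functional_space(sim$traits, axes = 3)
  idx <- compute_index_table(sv, sp)
  res <- fit_temporal_trend(idx, "density_total", transform = "log2")
  # -3%/year compounds to about -31% over 12 years
  expect_lt(res$estimate, 0)
  expect_lt(res$p_value, 0.05)
  expect_true(res$percent_change$ci[1] < (0.97^12 - 1) * 100 &&
              (0.97^12 - 1) * 100 < res$percent_change$ci[2])
})
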
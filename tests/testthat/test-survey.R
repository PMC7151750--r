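lw1 <- data.frame(species = c("X", "Y"), a = c(0.02, 1), b = c(2.9, 3))

test_that("nearby same-day censuses merge and densities renormalize", {
  rec <- rbind(census_row("c1", "X", 3, x = 0),
               census_row("c2", "X", 5, x = 150))
  sv <- aggregate_censuses(rec, length_weight = lw1)
  expect_equal(nrow(sv$transects), 1L)
  expect_equal(sv$transects$transect_id, "c1+c2")
  expect_equal(sv$transects$total_area, 200)
  expect_equal(unname(sv$density[1, "X"]), 4)      # (3+5) per 200 m2 -> 4/100 m2
  expect_equal(sv$transects$season, "cold")
  # biomass: 8 individuals at 12.5 cm, a=0.02 b=2.9, per 100 m2
  expect_equal(unname(sv$biomass[1, "X"]),
               8 * 0.02 * 12.5^2.9 * 100 / 200)
})

test_that("an isolated census passes through unchanged", {
  rec <- census_row("solo", "Y", 7, area = 60)
  sv <- aggregate_censuses(rec, length_weight = lw1)
  expect_equal(sv$transects$transect_id, "solo")
  expect_equal(sv$transects$total_area, 60)
  expect_equal(unname(sv$density[1, "Y"]), 7 * 100 / 60)
})

test_that("chained proximity merges by single linkage", {
  # A-B 150 m, B-C 150 m, A-C 300 m: one transect of all three
  rec <- rbind(census_row("a", "X", 1, x = 0),
               census_row("b", "X", 1, x = 150),
               census_row("c", "X", 1, x = 300))
  sv <- aggregate_censuses(rec, length_weight = lw1)
  expect_equal(sv$transects$transect_id, "a+b+c")
  # but separate days never merge
  rec2 <- rec
  rec2$date[3] <- as.Date("2010-03-11")
  sv2 <- aggregate_censuses(rec2, length_weight = lw1)
  expect_setequal(sv2$transects$transect_id, c("a+b", "c"))
})

test_that("grouping matches an independent connected-components oracle", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    pos <- matrix(runif(2 * n, 0, 600), ncol = 2)
    rec <- do.call(rbind, lapply(seq_len(n), function(i)
      census_row(sprintf("c%02d", i), "X", i, x = pos[i, 1], y = pos[i, 2])))
    sv <- aggregate_censuses(rec, length_weight = lw1)
    comp <- oracle_components(as.matrix(dist(pos)), 200)
    expect_equal(nrow(sv$transects), length(unique(comp)))
    got <- split(sv$grouping$census_id, sv$grouping$transect_id)
    want <- split(sprintf("c%02d", seq_len(n)), comp)
    expect_setequal(unname(lapply(got, sort)), unname(lapply(want, sort)))
    # aggregation conserves individuals
    expect_equal(sum(sv$density[, "X"] * sv$transects$total_area / 100),
                 sum(rec$count))
  }
})

test_that("location precedence: group column, then distance table, then coords", {
  rec <- rbind(census_row("c1", "X", 2, x = 0),
               census_row("c2", "X", 2, x = 50))
  rec$group <- c("g1", "g2")                      # overrides 50-m proximity
  sv <- aggregate_censuses(rec, length_weight = lw1)
  expect_equal(nrow(sv$transects), 2L)

  rec2 <- rbind(census_row("c1", "X", 2), census_row("c2", "X", 2))
  rec2$x <- NULL; rec2$y <- NULL
  dt <- data.frame(census_a = "c1", census_b = "c2", distance = 120)
  sv2 <- aggregate_censuses(rec2, distances = dt, length_weight = lw1)
  expect_equal(sv2$transects$transect_id, "c1+c2")
  expect_error(aggregate_censuses(rec2, length_weight = lw1), "cannot locate")
})

test_that("record validation catches the contract violations", {
  expect_error(aggregate_censuses(census_row("c", "X", 0)), "positive integers")
  expect_error(aggregate_censuses(census_row("c", "X", 2, size_class = 11)),
               "5-cm")
  expect_error(aggregate_censuses(
    census_row("c", "X", 2, date = as.Date("2010-07-10"))), "season")
  expect_error(aggregate_censuses(census_row("c", "X", 2, zone = "open")),
               "zone")
  expect_error(
    aggregate_censuses(census_row("c", "X", 2), length_weight = lw1[2, ]),
    "X")
  expect_equal(season_from_date(as.Date(c("2011-01-05", "2011-09-20"))),
               c("cold", "warm"))
})

test_that("length-weight relationship and its guards", {
  expect_equal(estimate_biomass(10, a = 1, b = 3), 1000)
  # independent evaluation through logs
  expect_equal(estimate_biomass(25, a = 0.02, b = 2.9),
               exp(log(0.02) + 2.9 * log(25)))
  expect_error(estimate_biomass(0, 1, 3), "positive")
  expect_warning(estimate_biomass(10, 1, 4), "2.5")
})

test_that("accumulation curve: flat, disjoint, and exhaustive small cases", {
  tr <- data.frame(transect_id = paste0("t", 1:3), site = "A",
                   zone = "no_take", year = 2010, season = "cold",
                   total_area = 100)
  shared <- matrix(c(1, 1, 1), 3, 1, dimnames = list(NULL, "X"))
  sv <- as_survey_table(tr, shared)
  acc <- species_accumulation(sv, n_permutations = 50, seed = 1)
  expect_equal(acc$richness_mean, c(1, 1, 1))

  disj <- diag(3); colnames(disj) <- c("X", "Y", "Z")
  acc2 <- species_accumulation(as_survey_table(tr, disj), 50, seed = 1)
  expect_equal(acc2$richness_mean, c(1, 2, 3))

  # 5 transects x 4 species: mean curve equals the exhaustive average
  # over all 5! orderings
  set.seed(52)
  inc <- matrix(rbinom(20, 1, 0.5), 5, 4,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  inc[1, ] <- c(1, 0, 0, 0)  # ensure no empty transect column issues
  tr5 <- data.frame(transect_id = paste0("t", 1:5), site = "A",
                    zone = "no_take", year = 2010, season = "cold",
                    total_area = 100)
  perms <- NULL
  for (p in combinat_perms(5)) {
    cum <- apply(apply(inc[p, , drop = FALSE], 2, cummax), 1, sum)
    perms <- rbind(perms, cum)
  }
  exact <- colMeans(perms)
  acc3 <- species_accumulation(as_survey_table(tr5, inc), 4000, seed = 3)
  expect_equal(acc3$richness_mean, unname(exact), tolerance = 0.02)
  # monotone, ends at the pool richness, for several seeds
  for (s in 1:3) {
    a <- species_accumulation(as_survey_table(tr5, inc), 30, seed = s)
    expect_true(all(diff(a$richness_mean) >= -1e-12))
    expect_equal(a$richness_mean[5], sum(colSums(inc) > 0))
  }
  expect_error(species_accumulation(as_survey_table(tr5[1, , drop = FALSE],
                                                    inc[1, , drop = FALSE])),
               "2 transects")
})

test_that("accumulation is reproducible under a seed", {
  set.seed(53)
  inc <- matrix(rbinom(40, 1, 0.4), 8, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
  tr <- data.frame(transect_id = paste0("t", 1:8), site = "A",
                   zone = "no_take", year = 2010, season = "cold",
                   total_area = 100)
  sv <- as_survey_table(tr, inc)
  a1 <- species_accumulation(sv, 25, seed = 9)
  a2 <- species_accumulation(sv, 25, seed = 9)
  expect_identical(a1, a2)
})

test_that("transect-area ANOVA with post hoc", {
  tr <- data.frame(transect_id = paste0("t", 1:8), site = "A",
                   zone = "no_take", year = 2010, season = "cold",
                   total_area = rep(c(100, 200), each = 4))
  # group means identical (richness 2,4,3,3 in each area group) -> F = 0
  dens <- matrix(0, 8, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  richness <- c(2, 4, 3, 3, 2, 4, 3, 3)
  for (i in 1:8) dens[i, seq_len(richness[i])] <- 1
  sv <- as_survey_table(tr, dens)
  res <- area_effect_test(sv)
  expect_equal(res$statistic, 0)
  expect_equal(res$df, c(1, 6))
  expect_equal(res$posthoc_method, "Tukey HSD")

  tr1 <- tr; tr1$total_area <- 100
  expect_error(area_effect_test(as_survey_table(tr1, dens)), "two")
})
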
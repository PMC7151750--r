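square_space <- function() {
  as_functional_space(rbind(a = c(0, 0), b = c(1, 0), c = c(1, 1),
                            d = c(0, 1), e = c(0.25, 0.25)))
}

test_that("functional richness is a hull-volume proportion", {
  sp <- square_space()
  kc <- pool_constants(sp)
  expect_equal(functional_richness(sp, c("a", "b", "c", "d"), kc)$value, 1)
  expect_equal(functional_richness(sp, rownames(sp$coordinates), kc)$value, 1)
  # triangle over half the square
  expect_equal(functional_richness(sp, c("a", "b", "d"), kc)$value, 0.5)
  # adding a species strictly inside the current hull changes nothing
  expect_equal(functional_richness(sp, c("a", "b", "c", "d", "e"), kc)$value, 1)
  # too few / degenerate points: flagged zero, never NaN
  fr <- functional_richness(sp, c("a", "b"), kc)
  expect_equal(fr$value, 0)
  expect_equal(fr$flag, "insufficient-dimensionality")
  expect_error(functional_richness(sp, "nope"), "absent")
})

test_that("FRic never decreases when a species is added", {
  set.seed(41)
  for (rep in 1:10) {
    coords <- matrix(rnorm(3 * 12), 12, 3)
    rownames(coords) <- sprintf("s%02d", 1:12)
    sp <- as_functional_space(coords)
    kc <- pool_constants(sp)
    present <- sample(rownames(coords), 5)
    v0 <- functional_richness(sp, present, kc)$value
    extra <- sample(setdiff(rownames(coords), present), 1)
    v1 <- functional_richness(sp, c(present, extra), kc)$value
    expect_gte(v1 + 1e-12, v0)
  }
})

test_that("dispersion and originality follow their weighted formulas", {
  sp <- square_space()
  kc <- pool_constants(sp)
  # two species, equal weights: FDis = d / d_max
  w2 <- c(a = 1, b = 1)
  expect_equal(functional_dispersion(sp, w2, kc)$value, 1 / kc$d_max)
  # single species: zero by convention, flagged
  f1 <- functional_dispersion(sp, c(a = 2), kc)
  expect_equal(f1$value, 0)
  expect_equal(f1$flag, "singleton")
  expect_equal(functional_originality(sp, c(a = 2), kc)$value, 0)
  # uniform weight rescaling changes nothing
  w <- c(a = 1, b = 2, c = 3)
  expect_equal(functional_dispersion(sp, w, kc)$value,
               functional_dispersion(sp, w * 7, kc)$value)
  expect_equal(functional_originality(sp, w, kc)$value,
               functional_originality(sp, w * 7, kc)$value)
  expect_error(functional_dispersion(sp, c(a = -1, b = 2), kc), "non-negative")
})

test_that("coincident species (shared FE) have zero originality", {
  coords <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0), d = c(0, 1))
  sp <- as_functional_space(coords)
  kc <- pool_constants(sp)
  expect_equal(functional_originality(sp, c(a = 1, b = 1), kc)$value, 0)
})

test_that("collinear equally spaced trio: weighted mean NN distance = spacing", {
  fx <- fixture_communities()$collinear
  kc <- pool_constants(fx$space)
  got <- functional_originality(fx$space, fx$weights, kc)$value
  coords <- fx$space$coordinates
  expect_equal(got, oracle_fori(coords, fx$weights, kc$o_max), tolerance = 1e-12)
  # each of p1, p2, p3 has nearest neighbor at distance 1
  expect_equal(got, 1 / kc$o_max)
})

test_that("indices match brute-force oracles on random communities", {
  set.seed(42)
  for (rep in 1:12) {
    m <- sample(2:4, 1)
    n <- sample((m + 2):12, 1)
    coords <- matrix(rnorm(n * m), n, m)
    rownames(coords) <- sprintf("s%02d", seq_len(n))
    sp <- as_functional_space(coords)
    kc <- pool_constants(sp)
    k <- sample(2:n, 1)
    present <- sample(rownames(coords), k)
    w <- stats::setNames(runif(k, 0.1, 5), present)

    expect_equal(functional_dispersion(sp, w, kc)$value,
                 oracle_fdis(coords, w, kc$d_max), tolerance = 1e-10)
    expect_equal(functional_originality(sp, w, kc)$value,
                 oracle_fori(coords, w, kc$o_max), tolerance = 1e-10)
    oracle_vol <- if (m == 2) oracle_hull_2d(coords[present, , drop = FALSE])
                  else oracle_hull_nd(coords[present, , drop = FALSE])
    pool_vol <- if (m == 2) oracle_hull_2d(coords) else oracle_hull_nd(coords)
    fr <- functional_richness(sp, present, kc)
    if (is.na(oracle_vol)) {
      expect_equal(fr$value, 0)
    } else {
      expect_equal(fr$value, oracle_vol / pool_vol, tolerance = 1e-10)
    }
    # bounds from the pool-level normalizations (FOri has no such
    # bound: within-transect NN distances can exceed every pool-wide
    # NN distance when most neighbors are absent)
    expect_lte(functional_dispersion(sp, w, kc)$value, 1 + 1e-9)
    expect_gte(functional_originality(sp, w, kc)$value, 0)
    expect_true(fr$value >= 0 && fr$value <= 1 + 1e-12)
  }
})

test_that("index table covers the eight indices and reuses pool constants", {
  set.seed(43)
  coords <- matrix(rnorm(20 * 2), 20, 2)
  rownames(coords) <- sprintf("s%02d", 1:20)
  sp <- as_functional_space(coords)
  tr <- data.frame(transect_id = c("t1", "t2", "t3"), site = "A",
                   zone = "no_take", year = c(2005, 2006, 2007),
                   season = "cold", total_area = 300)
  dens <- matrix(0, 3, 20, dimnames = list(NULL, rownames(coords)))
  dens[1, ] <- 1                       # whole pool at equal weights
  dens[2, 1:6] <- runif(6, 0.5, 4)
  dens[3, 10] <- 2                     # singleton transect
  biom <- dens * 10
  survey <- as_survey_table(tr, dens, biom)
  tab <- compute_index_table(survey, sp)
  expect_equal(tab$FRic[1], 1)
  expect_equal(tab$species_richness, c(20, 6, 1))
  expect_equal(tab$FDis_density[3], 0)
  expect_match(tab$flags[3], "singleton")
  expect_true(all(index_names() %in% names(tab)))
  kc <- attr(tab, "pool_constants")
  # pool constants are a property of the space, not of the transect set
  tab2 <- compute_index_table(as_survey_table(tr[2, , drop = FALSE],
                                              dens[2, , drop = FALSE],
                                              biom[2, , drop = FALSE]), sp)
  expect_identical(kc, attr(tab2, "pool_constants"))
  expect_equal(tab$FDis_density[2], tab2$FDis_density[1])

  # surveyed species missing from the space is an error up front
  dens_bad <- cbind(dens, ghost = c(1, 0, 0))
  expect_error(compute_index_table(as_survey_table(tr, dens_bad), sp),
               "ghost")
})
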
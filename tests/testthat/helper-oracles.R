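# Independent brute-force oracles. These deliberately share no code
# with the package implementations they check: naive loops, exhaustive
# enumeration, and closed forms only.

# Gower dissimilarity by naive per-pair loops over the trait columns
oracle_gower <- function(traits) {
  voc <- trait_vocabulary()
  types <- trait_types()
  n <- nrow(traits)
  d <- matrix(0, n, n, dimnames = list(rownames(traits), rownames(traits)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (tr in names(voc)) {
      vi <- traits[i, tr]; vj <- traits[j, tr]
      if (types[[tr]] == "nominal") {
        acc <- acc + as.numeric(vi != vj)
      } else {
        L <- length(voc[[tr]])
        acc <- acc + abs(match(vi, voc[[tr]]) - match(vj, voc[[tr]])) / (L - 1)
      }
    }
    d[i, j] <- acc / 6
  }
  d
}

# polygon area of the 2-D hull via grDevices::chull + shoelace formula
oracle_hull_2d <- function(xy) {
  xy <- unique(as.matrix(xy))
  h <- grDevices::chull(xy)
  v <- xy[h, , drop = FALSE]
  n <- nrow(v)
  if (n < 3) return(NA_real_)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  unname(abs(s) / 2)
}

# hull volume in d dimensions by exhaustive facet enumeration: a
# d-subset spans a hull hyperplane iff all other points lie (weakly) on
# one side. Hyperplanes are deduplicated by the set of points lying on
# them (a facet may hold more than d coplanar points, e.g. for the
# structured coordinates coming out of a categorical trait space); each
# facet contributes a cone from the centroid whose base volume is
# computed recursively in d-1 dimensions, down to the 2-D shoelace.
oracle_hull_nd <- function(x, tol = 1e-9) {
  x <- unique(as.matrix(x))
  n <- nrow(x); d <- ncol(x)
  if (d == 1) return(max(x) - min(x))
  if (d == 2) return(oracle_hull_2d(x))
  if (n < d + 1) return(NA_real_)
  ctr <- colMeans(x)
  scale <- max(stats::dist(x))
  combs <- utils::combn(n, d)
  seen <- character(0)
  vol <- 0
  any_facet <- FALSE
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    v <- x[idx, , drop = FALSE]
    m <- sweep(v[-1, , drop = FALSE], 2, v[1, ])
    if (qr(m)$rank < d - 1) next                       # degenerate subset
    nr <- qr.Q(qr(t(m)), complete = TRUE)[, d]
    hs <- drop(sweep(x, 2, v[1, ]) %*% nr)
    if (!(all(hs <= tol * scale) || all(hs >= -tol * scale))) next
    on_plane <- which(abs(hs) <= tol * scale)
    key <- paste(on_plane, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    any_facet <- TRUE
    pts <- x[on_plane, , drop = FALSE]
    basis <- svd(t(sweep(pts[-1, , drop = FALSE], 2, pts[1, ])))$u[,
      seq_len(d - 1), drop = FALSE]
    proj <- sweep(pts, 2, pts[1, ]) %*% basis
    base <- oracle_hull_nd(proj, tol)
    if (is.na(base)) next                              # flat facet, no area
    height <- abs(sum((ctr - pts[1, ]) * nr))
    vol <- vol + base * height / d
  }
  if (!any_facet) return(NA_real_)
  vol
}

# weighted dispersion / originality by direct loops
oracle_fdis <- function(coords, w, d_max) {
  if (length(w) == 1) return(0)
  ctr <- rep(0, ncol(coords))
  for (s in names(w)) ctr <- ctr + w[[s]] * coords[s, ]
  ctr <- ctr / sum(w)
  num <- 0
  for (s in names(w)) num <- num + w[[s]] * sqrt(sum((coords[s, ] - ctr)^2))
  (num / sum(w)) / (d_max / 2)
}

oracle_fori <- function(coords, w, o_max) {
  if (length(w) == 1) return(0)
  num <- 0
  for (s in names(w)) {
    nn <- Inf
    for (t in names(w)) if (t != s)
      nn <- min(nn, sqrt(sum((coords[s, ] - coords[t, ])^2)))
    num <- num + w[[s]] * nn
  }
  (num / sum(w)) / o_max
}

# connected components of the sub-threshold proximity graph by
# repeated boolean matrix powering (independent of the union-find in
# the package)
oracle_components <- function(dmat, threshold) {
  adj <- (dmat < threshold) | diag(nrow(dmat)) > 0
  reach <- adj
  for (k in seq_len(nrow(dmat))) reach <- (reach %*% adj) > 0
  comp <- integer(nrow(dmat))
  lab <- 0
  for (i in seq_len(nrow(dmat))) {
    if (comp[i] == 0) {
      lab <- lab + 1
      comp[reach[i, ]] <- lab
    }
  }
  comp
}

# uniformly random valid trait table
rand_traits <- function(n, prefix = "sp") {
  voc <- trait_vocabulary()
  tab <- as.data.frame(lapply(voc, function(l) sample(l, n, replace = TRUE)),
                       stringsAsFactors = FALSE)
  rownames(tab) <- sprintf("%s%03d", prefix, seq_len(n))
  tab
}

# all permutations of 1..n (tiny n only)
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) for (k in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = k)
  out
}

# minimal census record row builder
census_row <- function(census_id, species, count, site = "A",
                       zone = "no_take", date = as.Date("2010-03-10"),
                       depth = "5-15m", area = 100, x = 0, y = 0,
                       size_class = 12.5) {
  data.frame(census_id = census_id, site = site, zone = zone, date = date,
             depth_stratum = depth, area = area, species = species,
             count = count, size_class = size_class, x = x, y = y,
             stringsAsFactors = FALSE)
}
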
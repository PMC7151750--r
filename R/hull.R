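# Convex-hull volume in arbitrary (small) dimension.
#
# Functional richness needs the volume of the convex hull of species
# coordinates in the m retained ordination axes (m is typically 2-6).
# Implemented as an incremental beneath-beyond construction with
# simplicial facets: start from a full-dimensional simplex, insert the
# remaining points one at a time, replace the facets visible from the
# new point by the cone over the horizon ridges.

#' Affine rank of a point configuration
#'
#' Rank of the centered coordinate matrix, i.e. the dimension of the
#' affine subspace spanned by the points. A transect whose species span
#' fewer dimensions than the functional space cannot enclose any volume.
#'
#' @param x numeric matrix, points in rows.
#' @param tol relative tolerance for the rank decision.
#' @return integer affine rank, between 0 and `ncol(x)`.
#' @keywords internal
affine_rank <- function(x, tol = 1e-9) {
  x <- as.matrix(x)
  if (nrow(x) <= 1L) return(0L)
  xc <- sweep(x, 2L, colMeans(x))
  s <- svd(xc, nu = 0L, nv = 0L)$d
  sum(s > tol * max(s[1L], 1e-12))
}

facet_plane <- function(x, vidx, interior) {
  v <- x[vidx, , drop = FALSE]
  d <- ncol(x)
  m <- sweep(v[-1L, , drop = FALSE], 2L, v[1L, ])
  qq <- qr(t(m))
  normal <- qr.Q(qq, complete = TRUE)[, d]
  offset <- sum(normal * v[1L, ])
  # orient outward: the interior point must be on the negative side
  if (sum(normal * interior) > offset) {
    normal <- -normal
    offset <- -offset
  }
  list(v = vidx, normal = normal, offset = offset)
}

#' Volume of the convex hull of a point set
#'
#' Exact (up to floating point) hull volume via incremental
#' beneath-beyond construction. Duplicated rows are removed first.
#'
#' @param x numeric matrix (points in rows). One column gives the range
#'   length; two or more columns give the area / volume / hypervolume.
#' @param tol visibility tolerance, relative to the configuration
#'   diameter.
#' @return the hull volume, or `NA_real_` when the points do not span
#'   the full `ncol(x)` dimensions (affinely degenerate configuration).
#' @examples
#' convhull_volume(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) # unit square
#' @export
convhull_volume <- function(x, tol = 1e-9) {
  x <- unique(as.matrix(x))
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- ncol(x)
  if (d == 0L || n == 0L) return(NA_real_)
  if (d == 1L) {
    if (n < 2L) return(NA_real_)
    return(max(x) - min(x))
  }
  if (n < d + 1L || affine_rank(x, tol) < d) return(NA_real_)

  diam <- max(apply(x, 2L, function(z) max(z) - min(z)))
  eps <- tol * max(diam, 1e-12)

  ## initial simplex: greedily add the point farthest from the affine
  ## hull of the points chosen so far
  simplex <- which.max(x[, 1L])
  for (k in seq_len(d)) {
    base <- x[simplex[1L], ]
    if (length(simplex) == 1L) {
      resid <- sqrt(rowSums(sweep(x, 2L, base)^2))
    } else {
      b <- t(x[simplex[-1L], , drop = FALSE]) - base  # d x (k-1) spanning set
      qb <- qr(b)
      resid <- vapply(seq_len(n), function(i) {
        w <- x[i, ] - base
        sqrt(sum((w - qr.fitted(qb, w))^2))
      }, numeric(1))
    }
    resid[simplex] <- -1
    j <- which.max(resid)
    if (resid[j] <= eps) return(NA_real_)            # degenerate (guarded above)
    simplex <- c(simplex, j)
  }
  interior <- colMeans(x[simplex, , drop = FALSE])

  facets <- lapply(seq_len(d + 1L), function(i)
    facet_plane(x, simplex[-i], interior))

  rest <- setdiff(seq_len(n), simplex)
  if (length(rest)) {
    ## insert far points first: keeps intermediate hulls well conditioned
    ord <- order(-sqrt(rowSums(sweep(x[rest, , drop = FALSE], 2L, interior)^2)))
    rest <- rest[ord]
  }

  for (p in rest) {
    pt <- x[p, ]
    height <- vapply(facets, function(f) sum(f$normal * pt) - f$offset,
                     numeric(1))
    vis <- which(height > eps)
    if (!length(vis)) next                           # inside current hull
    ## horizon ridges: (d-1)-subsets appearing in exactly one visible facet
    ridge_key <- character(0)
    ridge_val <- list()
    for (fi in vis) {
      vv <- facets[[fi]]$v
      for (drop_i in seq_along(vv)) {
        r <- sort(vv[-drop_i])
        key <- paste(r, collapse = ",")
        hit <- match(key, ridge_key)
        if (is.na(hit)) {
          ridge_key <- c(ridge_key, key)
          ridge_val <- c(ridge_val, list(r))
        } else {
          ridge_val[[hit]] <- NULL
          ridge_key <- ridge_key[-hit]
        }
      }
    }
    new_facets <- lapply(ridge_val, function(r)
      facet_plane(x, c(r, p), interior))
    facets <- c(facets[-vis], new_facets)
  }

  ## volume: fan of simplices from the interior point over the facets
  vol <- 0
  for (f in facets) {
    m <- sweep(x[f$v, , drop = FALSE], 2L, interior)
    vol <- vol + abs(det(m)) / factorial(d)
  }
  vol
}
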
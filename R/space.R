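# Functional space: PCoA of the Gower matrix and data-driven choice of
# the number of axes.

new_functional_space <- function(coordinates, eigenvalues, correction,
                                 correction_applied, negative_fraction,
                                 dissimilarity = NULL, chosen_m = NULL,
                                 msd = NULL) {
  structure(
    list(coordinates = coordinates, eigenvalues = eigenvalues,
         correction = correction, correction_applied = correction_applied,
         negative_fraction = negative_fraction,
         dissimilarity = dissimilarity, chosen_m = chosen_m, msd = msd),
    class = "functional_space")
}

#' Construct a functional space directly from coordinates
#'
#' Mainly for fixtures and tests: wraps an already-built coordinate
#' matrix (species in rows) as a `functional_space` using all columns
#' as retained axes. Coordinates are centered column-wise.
#'
#' @param coordinates numeric matrix with species row names.
#' @param chosen_m number of axes to use for indices (default: all).
#' @return a `functional_space` object.
#' @export
as_functional_space <- function(coordinates, chosen_m = ncol(coordinates)) {
  coordinates <- as.matrix(coordinates)
  if (is.null(rownames(coordinates)))
    rownames(coordinates) <- paste0("sp", seq_len(nrow(coordinates)))
  coordinates <- sweep(coordinates, 2L, colMeans(coordinates))
  ev <- colSums(coordinates^2)
  new_functional_space(coordinates, ev, correction = "none",
                       correction_applied = "none", negative_fraction = 0,
                       chosen_m = chosen_m)
}

#' Principal coordinates analysis of a species dissimilarity matrix
#'
#' Metric embedding via eigendecomposition of the double-centered Gram
#' matrix. A Gower matrix on categorical traits is generally
#' non-Euclidean, so negative eigenvalues are expected; when their
#' magnitude exceeds `tol` relative to the leading eigenvalue, the
#' configured correction is applied and recorded: `"sqrt"` (default)
#' embeds the square root of the dissimilarities (Euclidean-embeddable
#' for Gower), `"cailliez"` and `"lingoes"` add the classical constants,
#' `"none"` keeps the raw embedding and simply drops negative axes.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param correction negative-eigenvalue handling, see above.
#' @param tol relative tolerance for declaring negative eigenvalues.
#' @return a `functional_space` with centered coordinates on all
#'   positive axes (ordered by decreasing eigenvalue), the eigenvalues,
#'   and which correction was applied. `chosen_m` is unset; see
#'   [select_axes()].
#' @export
pcoa_traits <- function(d, correction = c("sqrt", "cailliez", "lingoes", "none"),
                        tol = 1e-8) {
  correction <- match.arg(correction)
  dm <- as.matrix(d)
  if (is.null(rownames(dm)))
    dimnames(dm) <- list(paste0("sp", seq_len(nrow(dm))),
                         paste0("sp", seq_len(nrow(dm))))
  if (nrow(dm) < 3L) stop("need at least 3 species for an ordination")
  if (max(dm) < tol)
    stop("degenerate trait space: all dissimilarities are zero (single functional entity)")
  if (max(abs(dm - t(dm))) > tol) stop("dissimilarity matrix is not symmetric")

  n <- nrow(dm)
  # cmdscale warns when it drops non-positive eigenvalues, which is the
  # normal situation for a Gower matrix
  raw <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = n - 1L, eig = TRUE))
  ev <- raw$eig
  negfrac <- sum(abs(ev[ev < 0])) / sum(abs(ev))
  needs_fix <- min(ev) < -tol * max(ev)
  applied <- "none"

  if (!needs_fix || correction == "none") {
    fit <- raw
  } else if (correction == "sqrt") {
    fit <- suppressWarnings(
      stats::cmdscale(sqrt(stats::as.dist(dm)), k = n - 1L, eig = TRUE))
    applied <- "sqrt"
  } else {
    pc <- ape::pcoa(stats::as.dist(dm), correction = correction)
    vec <- if (!is.null(pc$vectors.cor)) pc$vectors.cor else pc$vectors
    evc <- if (!is.null(pc$values$Corr_eig)) pc$values$Corr_eig else pc$values$Eigenvalues
    fit <- list(points = vec, eig = evc)
    applied <- correction
  }

  keep <- which(fit$eig > tol * max(fit$eig))
  coords <- fit$points[, keep, drop = FALSE]
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PC", seq_along(keep))
  new_functional_space(coords, fit$eig[keep], correction = correction,
                       correction_applied = applied,
                       negative_fraction = negfrac, dissimilarity = dm)
}

#' Axis-count quality profile (mean squared deviation)
#'
#' For each candidate dimensionality m, embedded pairwise distances on
#' the first m axes are rescaled so that their maximum matches the
#' maximum input dissimilarity, and the mean squared deviation (mSD)
#' between the rescaled distances and the input dissimilarities is
#' computed over all species pairs. Lower mSD means the m-dimensional
#' space represents the trait dissimilarities more faithfully.
#'
#' Two profiles are reported. `msd` rescales the m-dimensional
#' distances so their maximum matches the maximum input dissimilarity
#' and measures deviation from the input; it typically has an interior
#' minimum and is what drives the axis choice. `msd_corrected` measures
#' the unscaled deviation from the distances over *all* positive axes
#' (the dissimilarities the ordination actually embeds); because
#' distances in nested subspaces grow monotonically toward the full
#' embedding, this profile is non-increasing in m by construction and
#' reaches zero at full rank — it is the guaranteed-monotone quality
#' diagnostic.
#'
#' @param space a `functional_space`.
#' @param d the dissimilarity matrix the space was built from; taken
#'   from the space itself when omitted.
#' @param max_m largest dimensionality to profile (capped at the number
#'   of positive axes).
#' @return data.frame with columns `m`, `msd`, `msd_corrected`, with
#'   attribute `"chosen_m"` = the m minimizing `msd` (smallest m on
#'   ties).
#' @export
axis_quality_msd <- function(space, d = NULL, max_m = 6L) {
  stopifnot(inherits(space, "functional_space"))
  if (is.null(d)) d <- space$dissimilarity
  if (is.null(d)) stop("no dissimilarity matrix available; pass `d`")
  dm <- as.matrix(d)
  low <- lower.tri(dm)
  dv <- dm[low]
  fullv <- as.matrix(stats::dist(space$coordinates))[low]
  kmax <- min(max_m, ncol(space$coordinates))
  prof <- vapply(seq_len(kmax), function(m) {
    sv <- as.matrix(stats::dist(space$coordinates[, seq_len(m), drop = FALSE]))[low]
    c(msd = mean((sv * max(dv) / max(sv) - dv)^2),
      msd_corrected = mean((sv - fullv)^2))
  }, numeric(2))
  out <- data.frame(m = seq_len(kmax), msd = prof["msd", ],
                    msd_corrected = prof["msd_corrected", ])
  attr(out, "chosen_m") <- out$m[which.min(out$msd)]
  out
}

#' Choose the number of functional axes
#'
#' Sets `chosen_m` on a functional space, either to an explicit
#' override (`axes`) or to the mSD-minimizing dimensionality up to
#' `max_m` (see [axis_quality_msd()]). The quality profile is stored on
#' the space either way, so the override is auditable.
#'
#' @param space a `functional_space`.
#' @param axes optional explicit number of axes.
#' @param max_m cap for the mSD search.
#' @return the space with `chosen_m` and `msd` filled in.
#' @export
select_axes <- function(space, axes = NULL, max_m = 6L) {
  prof <- axis_quality_msd(space, max_m = max(max_m, if (is.null(axes)) 0L else axes))
  space$msd <- prof
  space$chosen_m <- if (!is.null(axes)) {
    if (axes > ncol(space$coordinates))
      stop("requested ", axes, " axes but only ", ncol(space$coordinates),
           " positive axes are available")
    as.integer(axes)
  } else {
    attr(prof, "chosen_m")
  }
  space
}

#' Build the functional space from a trait table
#'
#' Convenience wrapper: Gower dissimilarity, PCoA with the configured
#' negative-eigenvalue correction, and axis selection.
#'
#' @inheritParams gower_dissimilarity
#' @inheritParams pcoa_traits
#' @inheritParams select_axes
#' @return a `functional_space` ready for index computation.
#' @export
build_functional_space <- function(traits, correction = "sqrt", axes = NULL,
                                   max_m = 6L, size_scores = "rank") {
  d <- gower_dissimilarity(traits, size_scores = size_scores)
  space <- pcoa_traits(d, correction = correction)
  select_axes(space, axes = axes, max_m = max_m)
}

#' @export
print.functional_space <- function(x, ...) {
  cat("Functional space:", nrow(x$coordinates), "species,",
      ncol(x$coordinates), "positive axes\n")
  cat("  correction requested/applied:", x$correction, "/",
      x$correction_applied,
      sprintf("(negative eigenvalue fraction %.3f)\n", x$negative_fraction))
  if (!is.null(x$chosen_m)) {
    cat("  axes used for indices:", x$chosen_m)
    if (!is.null(x$msd))
      cat(sprintf("  (mSD %.4g)", x$msd$msd[x$chosen_m]))
    cat("\n")
  }
  invisible(x)
}
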
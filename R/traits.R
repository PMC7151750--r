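# Trait coding and functional entities.
#
# Six categorical traits describe each fish species. Three are nominal
# (no level order matters for activity and diet) and four are treated
# as ordinal with a fixed level order. Species sharing all six levels
# form one functional entity (FE) and are functionally indistinguishable
# under this scheme.

#' Trait vocabulary
#'
#' The fixed vocabulary of the six categorical traits used to build the
#' functional space: maximum body size (six ordered length bins),
#' mobility, period of activity, gregariousness, vertical position in
#' the water column, and diet. Diet codes: HD herbivores-detritivores,
#' IS invertivores of sessile invertebrates, IM invertivores of mobile
#' invertebrates, Pk planktivores, FC piscivores/cephalopod feeders
#' (apex predators), O omnivores.
#'
#' @return named list of character vectors, one per trait, levels in
#'   ordinal order where the trait is ordinal.
#' @export
trait_vocabulary <- function() {
  list(
    size_class     = c("0-7", "7-15", "15-30", "30-50", "50-80", ">80"),
    mobility       = c("low", "medium", "high"),
    activity       = c("diurnal", "nocturnal"),
    gregariousness = c("solitary", "pairing", "small_groups", "large_groups"),
    water_column   = c("benthic", "bentho-pelagic", "pelagic"),
    diet           = c("HD", "IS", "IM", "Pk", "FC", "O")
  )
}

#' @rdname trait_vocabulary
#' @export
trait_types <- function() {
  c(size_class = "ordinal", mobility = "ordinal", activity = "nominal",
    gregariousness = "ordinal", water_column = "ordinal", diet = "nominal")
}

# upper bin is open; 100 cm is a pragmatic stand-in for ">80"
size_class_midpoints <- function() {
  c("0-7" = 3.5, "7-15" = 11, "15-30" = 22.5, "30-50" = 40,
    "50-80" = 65, ">80" = 100)
}

#' Validate a species trait table
#'
#' Checks that a trait table has the six expected columns, species as
#' row names, no missing values, and only levels drawn from
#' [trait_vocabulary()].
#'
#' @param traits data.frame with species as row names and the six trait
#'   columns.
#' @return the validated data.frame with character columns, invisibly
#'   unchanged otherwise.
#' @export
validate_trait_table <- function(traits) {
  voc <- trait_vocabulary()
  if (!is.data.frame(traits)) stop("`traits` must be a data.frame")
  missing_cols <- setdiff(names(voc), names(traits))
  if (length(missing_cols))
    stop("trait table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(rownames(traits)) || anyDuplicated(rownames(traits)))
    stop("trait table must have unique species row names")
  traits <- traits[, names(voc), drop = FALSE]
  for (tr in names(voc)) {
    v <- as.character(traits[[tr]])
    if (anyNA(v))
      stop("missing values in trait '", tr, "' for species: ",
           paste(rownames(traits)[is.na(v)], collapse = ", "))
    bad <- !v %in% voc[[tr]]
    if (any(bad))
      stop("unknown level(s) in trait '", tr, "' for species ",
           paste0(rownames(traits)[bad], " ('", v[bad], "')", collapse = ", "))
    traits[[tr]] <- v
  }
  traits
}

#' Functional entities
#'
#' Species sharing the same level for all six traits belong to the same
#' functional entity (FE).
#'
#' @param traits a valid trait table (see [validate_trait_table()]).
#' @return data.frame with columns `species` and `fe` (entity label,
#'   the concatenated 6-tuple).
#' @export
functional_entities <- function(traits) {
  traits <- validate_trait_table(traits)
  fe <- apply(traits, 1L, paste, collapse = "|")
  data.frame(species = rownames(traits), fe = unname(fe),
             stringsAsFactors = FALSE)
}

#' Gower dissimilarity between species from categorical traits
#'
#' Mixed-type Gower dissimilarity with equal weight on the six traits:
#' `d_ij = (1/6) * sum_k delta_k(i, j)`. Nominal traits contribute 0
#' when equal and 1 otherwise; ordinal traits are scored by equally
#' spaced ranks over the full level vocabulary, `0, 1/(L-1), ..., 1`,
#' and contribute the absolute score difference. `d` is 0 exactly when
#' two species share a functional entity, and 1 when they differ
#' maximally in every trait.
#'
#' @param traits trait table (validated internally).
#' @param size_scores `"rank"` (default) scores the body-size bins by
#'   equally spaced ranks; `"midpoint"` scores them by bin midpoints
#'   rescaled to `[0, 1]`.
#' @return symmetric species-by-species matrix with entries in `[0, 1]`
#'   and zero diagonal.
#' @export
gower_dissimilarity <- function(traits, size_scores = c("rank", "midpoint")) {
  size_scores <- match.arg(size_scores)
  traits <- validate_trait_table(traits)
  voc <- trait_vocabulary()
  types <- trait_types()
  n <- nrow(traits)
  acc <- matrix(0, n, n)
  for (tr in names(voc)) {
    v <- traits[[tr]]
    if (types[[tr]] == "nominal") {
      delta <- 1 * outer(v, v, FUN = `!=`)
    } else {
      if (tr == "size_class" && size_scores == "midpoint") {
        mids <- size_class_midpoints()
        r <- (mids[v] - min(mids)) / (max(mids) - min(mids))
      } else {
        r <- (match(v, voc[[tr]]) - 1) / (length(voc[[tr]]) - 1)
      }
      delta <- abs(outer(r, r, `-`))
    }
    acc <- acc + delta
  }
  d <- acc / length(voc)
  dimnames(d) <- list(rownames(traits), rownames(traits))
  d
}
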
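# Mixed-model inference: management-zone comparisons, multi-year
# temporal trends with percent-change derivation, the commercial-
# biomass trend, and per-species winner/loser classification.
#
# Year enters the temporal models as a numeric covariate centered on
# the midpoint of the study span (numerical stability); reported slopes
# are per calendar year. Gaussian LMMs use Satterthwaite degrees of
# freedom (lmerTest). Occurrence GLMMs are binomial; density/biomass
# GLMMs are negative binomial on integer-rounded responses
# (round-half-to-even, after per-100 m2 standardization).

# random-effect terms only for grouping factors with >= 2 levels
random_terms <- function(data, factors) {
  ok <- factors[vapply(factors, function(f) length(unique(data[[f]])) >= 2L,
                       logical(1))]
  list(terms = if (length(ok)) paste0("(1|", ok, ")") else character(0),
       dropped = setdiff(factors, ok))
}

transform_response <- function(y, transform) {
  if (transform == "log2") {
    if (any(y <= 0))
      stop("log2 transform requires strictly positive values")
    log2(y)
  } else y
}

degenerate_trend <- function(response, transform, years, note) {
  structure(list(response = response, transform = transform,
                 estimate = 0, se = NA_real_, ci = c(0, 0), df = NA_real_,
                 p_value = NA_real_, n = NA_integer_,
                 span = diff(range(years)),
                 percent_change = list(value = 0, ci = c(0, 0)),
                 rsd = NULL, singular = NA, dropped_random = character(0),
                 degenerate = TRUE, note = note, model = NULL),
            class = "trend_result")
}

#' Percent change over a study span from a per-year coefficient
#'
#' For a log2-scale response the change over `span` years is
#' `(2^(b * span) - 1) * 100` percent; confidence limits are
#' transformed the same way (Wald on the model scale). For an
#' untransformed response the change is linear relative to the fitted
#' value at the first year: `100 * b * span / baseline`.
#'
#' @param b per-year coefficient on the model scale.
#' @param span study span in years (12 for a 13-year 2005-2017 series).
#' @param transform `"log2"` or `"none"`.
#' @param ci optional length-2 confidence limits of `b`.
#' @param baseline fitted response value at the first year; required
#'   (and must be positive) when `transform = "none"`.
#' @return list with `value` (percent), `ci`, `span`, `transform`.
#' @examples
#' percent_change(log2(1.43) / 12, span = 12, transform = "log2") # +43%
#' @export
percent_change <- function(b, span = 12, transform = c("log2", "none"),
                           ci = NULL, baseline = NULL) {
  transform <- match.arg(transform)
  if (transform == "log2") {
    f <- function(z) (2^(z * span) - 1) * 100
  } else {
    if (is.null(baseline)) stop("`baseline` is required for transform = 'none'")
    if (baseline <= 0) stop("fitted baseline value must be positive")
    f <- function(z) 100 * z * span / baseline
  }
  list(value = f(b), ci = if (!is.null(ci)) f(ci), span = span,
       transform = transform)
}

#' Temporal trend of an index by linear mixed model
#'
#' Fits `y ~ year + (1 | site) + (1 | season)` with Gaussian errors and
#' derives the percent change over the observed span. Density and
#' biomass responses should use `transform = "log2"`.
#'
#' @param data data.frame with the response column plus `year`, `site`,
#'   `season`.
#' @param response name of the response column.
#' @param transform `"none"` or `"log2"`.
#' @param span span in years for the percent change (default: observed
#'   range).
#' @return a `trend_result`: per-year slope `estimate` with Wald 95%
#'   `ci`, Satterthwaite `df` and `p_value`, random-effect SDs (`rsd`),
#'   `percent_change`, and convergence diagnostics. A response with
#'   zero variance yields a flagged degenerate result with slope 0.
#' @export
fit_temporal_trend <- function(data, response, transform = c("none", "log2"),
                               span = NULL) {
  transform <- match.arg(transform)
  if (length(unique(data$year)) < 2L) stop("need at least 2 distinct years")
  y <- transform_response(data[[response]], transform)
  if (is.null(span)) span <- diff(range(data$year))
  if (stats::var(y) == 0)
    return(degenerate_trend(response, transform, data$year,
                            "constant response: zero-variance degenerate fit"))
  d <- data.frame(.y = y, year_c = data$year - mean(range(data$year)),
                  site = factor(data$site), season = factor(data$season))
  rt <- random_terms(d, c("site", "season"))
  msgs <- character(0)
  fit <- withCallingHandlers(
    if (length(rt$terms)) {
      lmerTest::lmer(stats::as.formula(
        paste(".y ~ year_c +", paste(rt$terms, collapse = " + "))), data = d)
    } else stats::lm(.y ~ year_c, data = d),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    }, message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  is_lmm <- inherits(fit, "merMod")
  co <- stats::coef(summary(fit))["year_c", , drop = TRUE]
  b <- co[["Estimate"]]; se <- co[["Std. Error"]]
  dfree <- if (is_lmm) co[["df"]] else stats::df.residual(fit)
  p <- co[[length(co)]]
  ci <- b + c(-1, 1) * stats::qnorm(0.975) * se
  b0 <- if (is_lmm) lme4::fixef(fit)[["(Intercept)"]] else stats::coef(fit)[["(Intercept)"]]
  baseline_model <- b0 + b * (min(data$year) - mean(range(data$year)))
  baseline <- if (transform == "log2") NULL else baseline_model
  rsd <- if (is_lmm) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    stats::setNames(vc$sdcor, sub("^Residual$", "residual", vc$grp))
  } else stats::setNames(summary(fit)$sigma, "residual")
  structure(list(response = response, transform = transform,
                 estimate = b, se = se, ci = ci, df = dfree, p_value = p,
                 n = nrow(d), span = span,
                 percent_change = percent_change(b, span, transform, ci,
                                                 baseline),
                 rsd = rsd,
                 singular = if (is_lmm) lme4::isSingular(fit) else NA,
                 dropped_random = rt$dropped, degenerate = FALSE,
                 note = if (length(msgs)) paste(unique(msgs), collapse = "; "),
                 model = fit),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Trend for %s (%s): b = %.4g per year [%.4g, %.4g], p = %.3g\n",
              x$response, x$transform, x$estimate, x$ci[1], x$ci[2],
              x$p_value))
  cat(sprintf("  change over %d years: %+.1f%%", x$span,
              x$percent_change$value))
  if (!is.null(x$percent_change$ci))
    cat(sprintf(" (CI %+.1f%% to %+.1f%%)", x$percent_change$ci[1],
                x$percent_change$ci[2]))
  cat("\n")
  if (isTRUE(x$degenerate)) cat("  [degenerate fit:", x$note, "]\n")
  invisible(x)
}

#' Compare an index across management-zone types
#'
#' Fits `y ~ zone + (1 | year) + (1 | season) + (1 | site)` and tests
#' the zone factor with a Satterthwaite F test. Year is a random
#' intercept here (the comparison is meant to be independent of
#' temporal trends). Per-zone adjusted means come from
#' [emmeans::emmeans()].
#'
#' @inheritParams fit_temporal_trend
#' @param data data.frame with the response plus `zone`, `year`,
#'   `season`, `site`; all three zone types must be present.
#' @return a `zone_comparison`: `statistic` (F), `df`, `p_value`,
#'   `means` (per-zone adjusted means with CIs), `rsd`, diagnostics.
#' @export
fit_zone_comparison <- function(data, response, transform = c("none", "log2")) {
  transform <- match.arg(transform)
  if (!all(ZONE_LEVELS %in% data$zone))
    stop("all three zones must be represented; missing: ",
         paste(setdiff(ZONE_LEVELS, data$zone), collapse = ", "))
  y <- transform_response(data[[response]], transform)
  if (stats::var(y) == 0)
    return(structure(list(response = response, transform = transform,
                          statistic = NA_real_, df = c(NA, NA),
                          p_value = NA_real_, means = NULL, rsd = NULL,
                          degenerate = TRUE,
                          note = "constant response: zero-variance degenerate fit"),
                     class = "zone_comparison"))
  d <- data.frame(.y = y, zone = factor(data$zone, levels = ZONE_LEVELS),
                  year = factor(data$year), season = factor(data$season),
                  site = factor(data$site))
  rt <- random_terms(d, c("year", "season", "site"))
  if (!length(rt$terms))
    stop("no random-effect factor has two or more levels")
  msgs <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(stats::as.formula(
      paste(".y ~ zone +", paste(rt$terms, collapse = " + "))), data = d),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    }, message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  an <- stats::anova(fit)  # lmerTest: Satterthwaite by default
  emm <- as.data.frame(emmeans::emmeans(fit, "zone"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(response = response, transform = transform,
                 statistic = an$`F value`[1L],
                 df = c(an$NumDF[1L], an$DenDF[1L]),
                 p_value = an$`Pr(>F)`[1L], means = emm,
                 rsd = stats::setNames(vc$sdcor,
                                       sub("^Residual$", "residual", vc$grp)),
                 singular = lme4::isSingular(fit),
                 dropped_random = rt$dropped, degenerate = FALSE,
                 note = if (length(msgs)) paste(unique(msgs), collapse = "; "),
                 model = fit),
            class = "zone_comparison")
}

#' @export
print.zone_comparison <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Zone comparison for", x$response, "- degenerate:", x$note, "\n")
  } else {
    cat(sprintf("Zone comparison for %s: F(%.0f, %.1f) = %.3f, p = %.3g\n",
                x$response, x$df[1], x$df[2], x$statistic, x$p_value))
  }
  invisible(x)
}

#' Common species (occurrence filter)
#'
#' Species present in at least `threshold` of the transects (boundary
#' inclusive).
#'
#' @param survey a `survey_table`.
#' @param threshold occurrence proportion in `(0, 1]`.
#' @return character vector of species names.
#' @export
common_species_filter <- function(survey, threshold = 0.5) {
  stopifnot(inherits(survey, "survey_table"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  occ <- colMeans(survey$density > 0)
  names(occ)[occ >= threshold]
}

# binned-residual heuristic for binomial GLMMs (automated stand-in for
# visual binned-plot inspection): at least 80% of fitted-probability
# bins must have their mean residual inside +/- 2 SE
binned_residual_check <- function(y, p, n_bins = 10L) {
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 3L) return(TRUE)
  bin <- cut(p, br, include.lowest = TRUE)
  ok <- vapply(levels(bin), function(lv) {
    sel <- bin == lv
    if (!sum(sel)) return(TRUE)
    pm <- mean(p[sel])
    abs(mean(y[sel] - p[sel])) <= 2 * sqrt(max(pm * (1 - pm), 1e-12) / sum(sel))
  }, logical(1))
  mean(ok) >= 0.8
}

fit_species_glmm <- function(y, d, family_kind) {
  rt <- random_terms(d, c("site", "season"))
  form <- stats::as.formula(
    paste(".y ~ year_c",
          if (length(rt$terms)) paste("+", paste(rt$terms, collapse = " + "))))
  d$.y <- y
  fam <- switch(family_kind, binomial = stats::binomial(),
                nbinom = glmmTMB::nbinom2())
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(form, data = d, family = fam)),
    error = function(e) e)
  if (inherits(fit, "error")) return(list(ok = FALSE, note = conditionMessage(fit)))
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  co <- tryCatch(summary(fit)$coefficients$cond["year_c", ],
                 error = function(e) rep(NA_real_, 4))
  if (!conv || anyNA(co))
    return(list(ok = FALSE, note = "non-convergence or unstable covariance",
                fit = fit))
  list(ok = TRUE, fit = fit, estimate = co[[1]], se = co[[2]], z = co[[3]],
       p = co[[4]], note = NA_character_)
}

#' Classify common species as winners, losers, or stable
#'
#' For each species and each of three metrics, fits a year-trend GLMM
#' with random intercepts for site and season: occurrence
#' (presence/absence, binomial), and density and biomass (values per
#' 100 m2 rounded to integers, negative binomial). A species is a
#' winner (loser) on a metric when the year effect is significantly
#' positive (negative) at `alpha`; otherwise stable. Species whose
#' model fails to converge (or separates) are marked not classifiable
#' and excluded from winner/loser counts. Binomial fits are validated
#' by an automated binned-residual heuristic; negative-binomial fits
#' report the overdispersion ratio (Pearson chi-square over residual
#' df).
#'
#' @param survey a `survey_table` with a biomass matrix.
#' @param species species to classify; defaults to
#'   [common_species_filter()] at 50% occurrence.
#' @param alpha significance level for the year effect.
#' @param metrics subset of `c("occurrence", "density", "biomass")`.
#' @return a `winner_loser_table` data.frame: one row per species x
#'   metric with `estimate`, `se`, `z`, `p_value`, `direction`,
#'   `overdispersion`, `validated`, `classifiable`, `note`.
#' @export
classify_winners_losers <- function(survey, species = NULL, alpha = 0.05,
                                    metrics = c("occurrence", "density",
                                                "biomass")) {
  stopifnot(inherits(survey, "survey_table"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is.null(species)) species <- common_species_filter(survey, 0.5)
  if (!length(species)) stop("empty species list")
  check <- setdiff(species, colnames(survey$density))
  if (length(check))
    stop("species not in survey: ", paste(check, collapse = ", "))
  if ("biomass" %in% metrics && is.null(survey$biomass))
    stop("survey has no biomass matrix; cannot classify the biomass metric")
  tr <- survey$transects
  d0 <- data.frame(year_c = tr$year - mean(range(tr$year)),
                   site = factor(tr$site), season = factor(tr$season))
  rows <- list()
  for (sp in species) {
    dens <- survey$density[, sp]
    for (metric in metrics) {
      y <- switch(metric,
                  occurrence = as.integer(dens > 0),
                  density = round(dens),
                  biomass = round(survey$biomass[, sp]))
      row <- data.frame(species = sp, metric = metric, estimate = NA_real_,
                        se = NA_real_, z = NA_real_, p_value = NA_real_,
                        direction = "stable", overdispersion = NA_real_,
                        validated = NA, classifiable = FALSE,
                        note = NA_character_, stringsAsFactors = FALSE)
      if (length(unique(y)) == 1L) {
        row$note <- "degenerate: constant response"
        rows[[length(rows) + 1L]] <- row
        next
      }
      res <- fit_species_glmm(y, d0,
                              if (metric == "occurrence") "binomial" else "nbinom")
      if (!res$ok) {
        row$note <- res$note
        rows[[length(rows) + 1L]] <- row
        next
      }
      row$estimate <- res$estimate; row$se <- res$se
      row$z <- res$z; row$p_value <- res$p
      row$classifiable <- TRUE
      if (metric == "occurrence") {
        fitted_p <- stats::predict(res$fit, type = "response")
        row$validated <- binned_residual_check(y, fitted_p)
      } else {
        pr <- stats::residuals(res$fit, type = "pearson")
        row$overdispersion <- sum(pr^2) / stats::df.residual(res$fit)
        row$validated <- TRUE
      }
      if (isTRUE(row$validated) && res$p < alpha)
        row$direction <- if (res$estimate > 0) "winner" else "loser"
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("winner_loser_table", class(out))
  out
}

#' Winner/loser counts by metric
#'
#' @param wl a `winner_loser_table`.
#' @return data.frame with per-metric counts of winners, losers, stable
#'   species, and species excluded as not classifiable or not
#'   validated.
#' @export
winner_loser_counts <- function(wl) {
  split_wl <- split(as.data.frame(wl), wl$metric)
  out <- do.call(rbind, lapply(names(split_wl), function(m) {
    x <- split_wl[[m]]
    usable <- x$classifiable & (is.na(x$validated) | x$validated)
    data.frame(metric = m,
               winners = sum(x$direction == "winner" & usable),
               losers = sum(x$direction == "loser" & usable),
               stable = sum(x$direction == "stable" & usable),
               excluded = sum(!usable))
  }))
  rownames(out) <- NULL
  out
}

#' Temporal trend of summed commercial biomass
#'
#' Sums per-transect biomass over the commercial species, log2
#' transforms, and fits the standard temporal LMM (random intercepts
#' for site and season). Transects where no commercial species was
#' recorded carry no information about the log-scale trend and are
#' dropped (their number is reported).
#'
#' @param survey a `survey_table` with a biomass matrix.
#' @param commercial character vector of commercial species (matched
#'   against the surveyed species; an error reports an empty overlap).
#' @return a `trend_result` with extra fields `n_commercial_species`
#'   and `n_dropped_transects`.
#' @export
commercial_biomass_trend <- function(survey, commercial) {
  stopifnot(inherits(survey, "survey_table"))
  if (is.null(survey$biomass)) stop("survey has no biomass matrix")
  present <- intersect(commercial, colnames(survey$biomass))
  if (!length(present))
    stop("none of the ", length(commercial),
         " commercial species occur in the survey")
  total <- rowSums(survey$biomass[, present, drop = FALSE])
  keep <- total > 0
  d <- data.frame(commercial_biomass = total[keep],
                  year = survey$transects$year[keep],
                  site = survey$transects$site[keep],
                  season = survey$transects$season[keep])
  res <- fit_temporal_trend(d, "commercial_biomass", transform = "log2")
  res$n_commercial_species <- length(present)
  res$n_dropped_transects <- sum(!keep)
  res
}
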
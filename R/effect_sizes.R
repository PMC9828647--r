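#' Standardized effect size of location on a trait within one species
#'
#' Ordinary least squares of the (transformed) trait on the binary location
#' (0 outer, 1 inner). The standardized effect is the slope divided by the
#' residual standard deviation, making effects comparable across traits and
#' species: it is invariant to positive linear rescaling of the trait. With a
#' binary predictor the slope is the inner-minus-outer difference of group
#' means, so the effect reads as that difference in residual-SD units.
#'
#' @param values Numeric trait vector (transformed scale).
#' @param location Binary 0/1 vector of the same length.
#' @return One-row tibble: `slope`, `residual_sd` (using residual df, n - 2),
#'   `effect`, `p_value` (two-sided t-test on the slope), `n`, `converged`.
#' @export
#' @examples
#' species_effect_size(c(1, 3, 4, 6), c(0, 0, 1, 1))  # effect 3/sqrt(2)
species_effect_size <- function(values, location) {
  ok <- !is.na(values) & !is.na(location)
  values <- values[ok]; location <- location[ok]
  n <- length(values)
  if (n < 3) abort(sprintf("need n >= 3 observations, got %d", n))
  if (length(unique(location)) < 2) {
    abort("both location levels must be present (insufficient contrast)")
  }
  fit <- lm(values ~ location)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  rsd <- sigma(fit)
  tibble::tibble(
    slope = slope,
    residual_sd = rsd,
    effect = if (slope == 0) 0 else slope / rsd,
    p_value = sm$coefficients["location", "Pr(>|t|)"],
    n = n,
    converged = TRUE)
}

#' Pooled standardized effect size across species
#'
#' Linear mixed-effects model of the trait on binary location with a random
#' intercept per species (REML), so the location contrast is estimated within
#' species while baseline trait differences among species are absorbed by the
#' random effect. The standardized effect divides the fixed location slope by
#' the sample SD of the conditional residuals. The p-value is a normal (z)
#' approximation on the fixed slope and is flagged as approximate.
#'
#' With a single species (or when the random-intercept fit is degenerate in a
#' way lme4 refuses) the model collapses to OLS on location, equivalent to
#' [species_effect_size()] for the slope.
#'
#' @param values Numeric trait vector (transformed scale).
#' @param location Binary 0/1 vector.
#' @param species_ids Character/factor vector of species identifiers.
#' @return One-row tibble: `slope`, `residual_sd`, `effect`, `p_value`, `n`,
#'   `converged` (FALSE when lme4 reported convergence problems or the fit is
#'   singular), `note`.
#' @export
pooled_effect_size <- function(values, location, species_ids) {
  ok <- !is.na(values) & !is.na(location) & !is.na(species_ids)
  values <- values[ok]; location <- location[ok]
  species_ids <- as.character(species_ids[ok])
  n <- length(values)
  if (length(unique(location)) < 2) {
    abort("both location levels must be present (insufficient contrast)")
  }
  if (length(unique(species_ids)) < 2) {
    est <- species_effect_size(values, location)
    est$note <- "single species: OLS fit"
    return(est)
  }
  dat <- data.frame(y = values, loc = location, sp = species_ids)
  fit <- tryCatch(
    suppressMessages(lme4::lmer(y ~ loc + (1 | sp), data = dat, REML = TRUE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    est <- species_effect_size(values, location)
    est$converged <- FALSE
    est$note <- paste("lmer failed, OLS fallback:",
                      conditionMessage(fit))
    return(est)
  }
  msgs <- fit@optinfo$conv$lme4$messages
  singular <- lme4::isSingular(fit, tol = 1e-5)
  co <- coef(summary(fit))
  slope <- co["loc", "Estimate"]
  zval <- co["loc", "t value"]
  rsd <- sd(residuals(fit))
  tibble::tibble(
    slope = unname(slope),
    residual_sd = rsd,
    effect = if (slope == 0) 0 else unname(slope) / rsd,
    p_value = 2 * pnorm(-abs(unname(zval))),
    n = n,
    converged = is.null(msgs),
    note = if (!is.null(msgs)) paste(msgs, collapse = "; ")
           else if (singular) "singular random-effect fit"
           else NA_character_)
}

#' Effect-size table for all traits and species
#'
#' For each trait: one pooled mixed-model effect size across all species, and
#' one OLS effect size per species with sufficient data (both location levels
#' present and n >= 3). Species observed at a single location are excluded
#' from species-specific models but still contribute to the pooled model.
#' Failures in individual cells are recorded as flagged rows, never fatal.
#'
#' @param tm A `trait_matrix` (transformed values; see [transform_traits()]).
#' @param design A [location_design()].
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05; raw p-values, no multiplicity correction).
#' @return Tibble with columns `trait`, `scope` ("pooled"/"species"),
#'   `species_id`, `slope`, `residual_sd`, `effect`, `p_value`, `n`,
#'   `converged`, `note`, `significant`.
#' @export
effect_size_table <- function(tm, design, alpha = 0.05) {
  long <- trait_long(tm)
  long <- pool_locations(long, design)
  per_trait <- function(df, trait) {
    pooled <- tryCatch(
      pooled_effect_size(df$value, df$location, df$species_id),
      error = function(e) {
        tibble::tibble(slope = NA_real_, residual_sd = NA_real_,
                       effect = NA_real_, p_value = NA_real_,
                       n = sum(!is.na(df$value)), converged = FALSE,
                       note = conditionMessage(e))
      })
    pooled$trait <- trait
    pooled$scope <- "pooled"
    pooled$species_id <- NA_character_
    sp_rows <- lapply(split(df, df$species_id), function(d) {
      d <- d[!is.na(d$value), ]
      if (nrow(d) < 3 || length(unique(d$location)) < 2) return(NULL)
      est <- tryCatch(species_effect_size(d$value, d$location),
                      error = function(e) NULL)
      if (is.null(est)) return(NULL)
      est$trait <- trait
      est$scope <- "species"
      est$species_id <- d$species_id[1]
      est
    })
    dplyr::bind_rows(pooled, dplyr::bind_rows(sp_rows))
  }
  out <- dplyr::bind_rows(lapply(split(long, long$trait), function(df) {
    per_trait(df, df$trait[1])
  }))
  if (!"note" %in% names(out)) out$note <- NA_character_
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out <- out[, c("trait", "scope", "species_id", "slope", "residual_sd",
                 "effect", "p_value", "n", "converged", "note",
                 "significant")]
  out[order(match(out$trait, trait_names()), out$scope, out$species_id), ]
}
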
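#' Species trait means, study-wide (fixed) or per site (local)
#'
#' Fixed means are one study-wide mean per species per trait; local means are
#' per species per site where it was sampled. Fixed CWMs built from the former
#' carry only the species-turnover signal; local CWMs built from the latter
#' add the intraspecific signal. Means are unweighted arithmetic means of the
#' (transformed) colony values; cell sizes are recorded.
#'
#' @param tm A `trait_matrix` (see [transform_traits()]).
#' @param mode `"fixed"` or `"local"`.
#' @return Tibble `species_id` (`site_id` in local mode), `trait`, `mean`,
#'   `n_colonies` (non-missing values contributing to that cell).
#' @export
species_means <- function(tm, mode = c("fixed", "local")) {
  mode <- match.arg(mode)
  long <- trait_long(tm)
  keys <- if (mode == "fixed") c("species_id", "trait")
          else c("species_id", "site_id", "trait")
  out <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(keys))),
    mean = mean(.data$value, na.rm = TRUE),
    n_colonies = sum(!is.na(.data$value)),
    .groups = "drop")
  out$mean[out$n_colonies == 0] <- NA_real_
  out
}

#' Community-weighted means under fixed and local species means
#'
#' Per transect and trait, the CWM is the sum over species of relative
#' abundance times the species trait mean, with abundances renormalized over
#' the trait-sampled taxa. Both variants are computed side by side:
#' `cwm_fixed` uses study-wide species means, `cwm_local` uses the species'
#' mean at that transect's site. A species recorded on a transect but not
#' trait-sampled at that site falls back to its fixed mean in the local CWM
#' (it then contributes zero intraspecific signal rather than losing its
#' cover); the number of such fallbacks is recorded in `attr(, "n_fallback")`.
#'
#' @param abundance An `abundance_table`.
#' @param fixed_means,local_means Output of [species_means()] in the matching
#'   mode.
#' @param design A [location_design()] covering the abundance sites.
#' @return Tibble of class `cwm_table`: `site_id`, `transect_id`, `location`,
#'   `trait`, `cwm_fixed`, `cwm_local`, `coverage` (fraction of transect
#'   intercept from sampled taxa). Transects with zero sampled cover are
#'   dropped with a warning.
#' @export
#' @examples
#' fx <- generate_worked_fixture()
#' tm <- transform_traits(fx$colonies, log = FALSE, standardize = FALSE)
#' cwm <- compute_cwm(fx$abundance, species_means(tm, "fixed"),
#'                    species_means(tm, "local"), location_design(fx$colonies))
compute_cwm <- function(abundance, fixed_means, local_means, design) {
  ab <- tibble::as_tibble(abundance)
  unmapped <- setdiff(unique(ab$site_id), design$site_id)
  if (length(unmapped) > 0) {
    abort(sprintf("abundance site(s) not in location design: %s",
                  paste(unmapped, collapse = ", ")))
  }
  cover <- dplyr::summarise(
    dplyr::group_by(ab, .data$site_id, .data$transect_id),
    coverage = sum(.data$intercept_cm[.data$sampled]) /
      sum(.data$intercept_cm),
    .groups = "drop")
  dead <- cover[cover$coverage == 0, ]
  if (nrow(dead) > 0) {
    warn(sprintf("dropping transect(s) with zero sampled cover: %s",
                 paste(paste(dead$site_id, dead$transect_id, sep = "/"),
                       collapse = ", ")))
    ab <- dplyr::anti_join(ab, dead[, c("site_id", "transect_id")],
                           by = c("site_id", "transect_id"))
  }
  p <- relative_abundance(ab, over_sampled_only = TRUE)
  p <- p[p$p > 0, ]

  known <- unique(fixed_means$species_id)
  unknown_sp <- setdiff(unique(p$taxon_id), known)
  if (length(unknown_sp) > 0) {
    abort(sprintf("sampled taxa with no trait mean: %s",
                  paste(unknown_sp, collapse = ", ")))
  }
  contrib <- dplyr::left_join(
    p, fixed_means[, c("species_id", "trait", "mean")],
    by = c(taxon_id = "species_id"), relationship = "many-to-many")
  names(contrib)[names(contrib) == "mean"] <- "mean_fixed"
  contrib <- dplyr::left_join(
    contrib,
    setNames(local_means[, c("species_id", "site_id", "trait", "mean")],
             c("taxon_id", "site_id", "trait", "mean_local")),
    by = c("taxon_id", "site_id", "trait"))
  n_fallback <- sum(is.na(contrib$mean_local) & !is.na(contrib$mean_fixed))
  contrib$mean_local[is.na(contrib$mean_local)] <-
    contrib$mean_fixed[is.na(contrib$mean_local)]

  out <- dplyr::summarise(
    dplyr::group_by(contrib, .data$site_id, .data$transect_id, .data$trait),
    cwm_fixed = sum(.data$p * .data$mean_fixed),
    cwm_local = sum(.data$p * .data$mean_local),
    .groups = "drop")
  out <- dplyr::left_join(out, cover, by = c("site_id", "transect_id"))
  out <- dplyr::left_join(
    out, tibble::as_tibble(design)[, c("site_id", "location")], by = "site_id")
  out <- out[, c("site_id", "transect_id", "location", "trait",
                 "cwm_fixed", "cwm_local", "coverage")]
  attr(out, "n_fallback") <- n_fallback
  class(out) <- c("cwm_table", class(out))
  out
}

#' Sums-of-squares decomposition of assemblage trait variation
#'
#' Partitions study-wide variation in local CWMs (within and across
#' locations) into a composition-driven part, an intraspecific part and their
#' covariation. Per trait, with transect values \eqn{L} (local CWM),
#' \eqn{F} (fixed CWM) and \eqn{D = L - F}:
#' \deqn{SS_{local} = \sum (L - \bar L)^2, \quad SS_{fixed} = \sum (F - \bar F)^2,
#'       \quad SS_{intra} = \sum (D - \bar D)^2,}
#' \deqn{SS_{cov} = SS_{local} - SS_{fixed} - SS_{intra} = 2\sum(F - \bar F)(D - \bar D).}
#' Each component is expressed as a proportion of \eqn{SS_{local}}; the
#' covariation proportion is negative when intraspecific shifts oppose
#' turnover-driven shifts, so the three proportions sum to 1 but are not all
#' bounded by it.
#'
#' @param cwm A `cwm_table` from [compute_cwm()].
#' @return Tibble per trait: `ss_local`, `ss_fixed`, `ss_intra`, `ss_cov`,
#'   `prop_fixed`, `prop_intra`, `prop_cov`, `n_transects`.
#' @export
ss_decompose <- function(cwm) {
  css <- function(x) sum((x - mean(x))^2)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cwm), .data$trait),
    n_transects = dplyr::n(),
    ss_local = css(.data$cwm_local),
    ss_fixed = css(.data$cwm_fixed),
    ss_intra = css(.data$cwm_local - .data$cwm_fixed),
    .groups = "drop")
  if (any(out$n_transects < 2)) {
    abort("ss_decompose needs at least 2 transects per trait")
  }
  if (any(out$ss_local == 0)) {
    abort(sprintf(
      "constant local CWM (ss_local = 0), proportions undefined for: %s",
      paste(out$trait[out$ss_local == 0], collapse = ", ")))
  }
  out$ss_cov <- out$ss_local - out$ss_fixed - out$ss_intra
  out$prop_fixed <- out$ss_fixed / out$ss_local
  out$prop_intra <- out$ss_intra / out$ss_local
  out$prop_cov <- out$ss_cov / out$ss_local
  out[, c("trait", "ss_local", "ss_fixed", "ss_intra", "ss_cov",
          "prop_fixed", "prop_intra", "prop_cov", "n_transects")]
}

#' Effect-size decomposition of CWM change across locations
#'
#' Mixed-effects models of transect CWMs on binary location (site as random
#' intercept) are fitted separately to the fixed and local CWM series of each
#' trait, and summarized as standardized effects (slope / conditional
#' residual SD). `e_fixed` is the composition-driven shift, `e_local` the
#' realized shift; their difference `e_intra = e_local - e_fixed` is the
#' intraspecific contribution. With fewer than 2 sites per location class the
#' random structure is degenerate and the model falls back to OLS of CWM on
#' location, flagged in `method`.
#'
#' @param cwm A `cwm_table`.
#' @return Tibble per trait: `e_fixed`, `e_local`, `e_intra`, `p_fixed`,
#'   `p_local`, `method` ("lmm" or "ols"), `converged`.
#' @export
effect_decompose <- function(cwm) {
  x <- tibble::as_tibble(cwm)
  if (length(unique(x$location)) < 2) {
    abort("both location classes must be present among transects")
  }
  sites_per_class <- tapply(x$site_id, x$location,
                            function(s) length(unique(s)))
  use_lmm <- all(sites_per_class >= 2)
  one <- function(df) {
    fit1 <- function(y) {
      if (use_lmm) {
        est <- pooled_effect_size(y, df$location, df$site_id)
        est$method <- "lmm"
      } else {
        est <- species_effect_size(y, df$location)
        est$method <- "ols"
        est$note <- "degenerate random structure (<2 sites per class)"
      }
      est
    }
    ef <- fit1(df$cwm_fixed)
    el <- fit1(df$cwm_local)
    tibble::tibble(
      trait = df$trait[1],
      e_fixed = ef$effect, e_local = el$effect,
      e_intra = el$effect - ef$effect,
      p_fixed = ef$p_value, p_local = el$p_value,
      method = ef$method,
      converged = isTRUE(ef$converged) && isTRUE(el$converged))
  }
  out <- dplyr::bind_rows(lapply(split(x, x$trait), one))
  if (!use_lmm) {
    warn("effect_decompose: <2 sites per location class; OLS fallback used")
  }
  out[order(match(out$trait, trait_names())), ]
}

#' Amplification and reduction of compositional trait shifts
#'
#' When intraspecific change aligns with species turnover the realized
#' assemblage shift exceeds the composition-driven one:
#' `amplification = e_local / e_fixed` (> 1 means intraspecific change
#' amplified the compositional shift). When it opposes turnover the realized
#' shift is attenuated: `reduction_percent = 100 (|e_fixed| - |e_local|) /
#' |e_fixed|` (> 0 means intraspecific change countered the compositional
#' shift by that percentage).
#'
#' @param e_fixed,e_local Standardized effects from [effect_decompose()];
#'   vectorized.
#' @return Numeric vector.
#' @export
#' @examples
#' amplification_factor(2, 3)      # 1.5
#' reduction_percent(-2, -1.56)    # 22
amplification_factor <- function(e_fixed, e_local) {
  if (any(e_fixed == 0)) abort("amplification undefined when e_fixed = 0")
  e_local / e_fixed
}

#' @rdname amplification_factor
#' @export
reduction_percent <- function(e_fixed, e_local) {
  if (any(e_fixed == 0)) abort("reduction undefined when e_fixed = 0")
  100 * (abs(e_fixed) - abs(e_local)) / abs(e_fixed)
}

#' Full per-trait decomposition of assemblage trait change
#'
#' Convenience wrapper joining [ss_decompose()], [effect_decompose()] and the
#' amplification/reduction factors into one row per trait.
#'
#' @param cwm A `cwm_table`.
#' @return Tibble, one row per trait, with all SS components, proportions,
#'   standardized effects and `amplification`/`reduction` (NA where
#'   `e_fixed` is 0).
#' @export
decompose_traits <- function(cwm) {
  ss <- ss_decompose(cwm)
  ef <- effect_decompose(cwm)
  out <- dplyr::left_join(ss, ef, by = "trait")
  out$amplification <- ifelse(out$e_fixed == 0, NA_real_,
                              out$e_local / out$e_fixed)
  out$reduction <- ifelse(out$e_fixed == 0, NA_real_,
                          100 * (abs(out$e_fixed) - abs(out$e_local)) /
                            abs(out$e_fixed))
  out[order(match(out$trait, trait_names())), ]
}
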
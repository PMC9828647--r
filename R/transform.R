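#' Log-transform and z-standardize colony traits
#'
#' Traits are measured in incommensurable units (cells/cm2, mg/cm2, mm, ...),
#' so prior to modelling they are log-transformed and standardized to zero
#' mean and unit sample standard deviation per trait. Both steps are optional
#' and the transform metadata is stored so the mapping is invertible.
#'
#' @param colonies A `colony_table` (see [read_colony_table()]).
#' @param log Log-transform (natural log) before standardizing? Default TRUE.
#' @param standardize Center and scale each trait column to mean 0, sample SD
#'   1 (computed over non-missing entries)? Default TRUE.
#' @return A `trait_matrix`: a list with
#'   \describe{
#'     \item{values}{numeric matrix, colonies x traits, rownames = colony_id}
#'     \item{colonies}{tibble of colony metadata aligned to the rows}
#'     \item{transform}{tibble `trait`, `log`, `center`, `scale` recording the
#'       applied transform (center/scale are 0/1 when standardize = FALSE)}
#'   }
#' @seealso [invert_traits()]
#' @export
#' @examples
#' fx <- generate_worked_fixture()
#' tm <- transform_traits(fx$colonies)
#' colMeans(tm$values)  # ~0 per trait
transform_traits <- function(colonies, log = TRUE, standardize = TRUE) {
  traits <- intersect(trait_names(), names(colonies))
  m <- as.matrix(tibble::as_tibble(colonies)[, traits, drop = FALSE])
  rownames(m) <- colonies$colony_id
  if (log) {
    if (any(m <= 0, na.rm = TRUE)) {
      abort("log transform requires strictly positive trait values")
    }
    m <- base::log(m)
  }
  center <- rep(0, length(traits))
  scale <- rep(1, length(traits))
  if (standardize) {
    center <- apply(m, 2, mean, na.rm = TRUE)
    scale <- apply(m, 2, sd, na.rm = TRUE)
    degenerate <- !is.finite(scale) | scale == 0
    if (any(degenerate)) {
      abort(sprintf("zero-variance trait column(s) cannot be standardized: %s",
                    paste(traits[degenerate], collapse = ", ")))
    }
    m <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  }
  structure(
    list(
      values = m,
      colonies = tibble::as_tibble(colonies)[
        , c("colony_id", "species_id", "site_id", "location_class")],
      transform = tibble::tibble(trait = traits, log = log,
                                 center = unname(center),
                                 scale = unname(scale))
    ),
    class = "trait_matrix")
}

#' Invert a trait transform back to raw values
#'
#' @param tm A `trait_matrix` from [transform_traits()].
#' @return A numeric matrix of raw trait values (same shape as `tm$values`).
#' @export
invert_traits <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  m <- sweep(sweep(tm$values, 2, tm$transform$scale, "*"),
             2, tm$transform$center, "+")
  if (isTRUE(tm$transform$log[1])) m <- exp(m)
  m
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d colonies x %d traits (log = %s, standardized = %s)\n",
              nrow(x$values), ncol(x$values),
              x$transform$log[1],
              !all(x$transform$scale == 1 & x$transform$center == 0)))
  invisible(x)
}

# tidy long view of a trait matrix joined to colony metadata
trait_long <- function(tm) {
  vals <- tibble::as_tibble(tm$values)
  vals$colony_id <- rownames(tm$values)
  out <- tidyr::pivot_longer(vals, -"colony_id",
                             names_to = "trait", values_to = "value")
  dplyr::left_join(out, tm$colonies, by = "colony_id")
}
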
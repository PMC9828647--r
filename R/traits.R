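#' Trait vocabulary
#'
#' The nine colony traits handled throughout the package, with their
#' measurement units and type (tissue, morphology or skeleton). Tissue traits
#' are per-area physiological quantities; morphological traits describe colony
#' architecture; skeletal density captures investment in the skeleton.
#'
#' @return `trait_names()` returns a character vector of the nine trait codes.
#'   `trait_dictionary()` returns a tibble with columns `trait`, `type`,
#'   `description` and `unit`.
#'
#' @details Trait codes: ZD zooxanthellae density (cells/cm2), TB total tissue
#'   biomass (mg/cm2), PB protein biomass (mg/cm2), CH chlorophyll
#'   concentration (ug/cm2), SV surface area to volume ratio (1/mm), BD branch
#'   density (count/cm2), BW branch width (mm), CW corallite width (mm), SD
#'   skeletal density (g/cm3).
#'
#' @export
#' @examples
#' trait_names()
#' trait_dictionary()
trait_names <- function() {
  c("ZD", "TB", "PB", "CH", "SV", "BD", "BW", "CW", "SD")
}

#' @rdname trait_names
#' @export
trait_dictionary <- function() {
  tibble::tibble(
    trait = trait_names(),
    type = c(rep("tissue", 4), rep("morphology", 4), "skeleton"),
    description = c(
      "Zooxanthellae (symbiont) density",
      "Total tissue biomass",
      "Protein biomass",
      "Chlorophyll concentration",
      "Surface area to volume ratio",
      "Branch density",
      "Branch width",
      "Corallite width",
      "Skeletal density"
    ),
    unit = c("cells/cm2", "mg/cm2", "mg/cm2", "ug/cm2",
             "1/mm", "count/cm2", "mm", "mm", "g/cm3")
  )
}

#' @rdname trait_names
#' @export
tissue_traits <- function() c("ZD", "TB", "PB", "CH")

#' @rdname trait_names
#' @export
morphology_traits <- function() c("SV", "BD", "BW", "CW")

# location classes in gradient order (offshore -> inshore)
location_classes <- function() c("barrier", "lagoon", "inner")
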
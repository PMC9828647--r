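#' Build the binary location design for the gradient
#'
#' All quantitative comparisons pool sites into inner (1) versus outer (0)
#' sites, the outer pooling both barrier and lagoon reefs. An
#' optional per-species outer scope restricts which outer sites serve as a
#' species' reference (the outer extent of its distribution): records of that
#' species from outer sites outside the scope are excluded from its models.
#'
#' @param colonies A `colony_table`, or any data frame with `site_id` and
#'   `location_class` columns, used to enumerate sites.
#' @param outer_scope Optional named list, `species_id` -> character vector of
#'   outer `site_id`s forming that species' reference.
#' @return A `location_design`: tibble `site_id`, `location_class`,
#'   `location` (0 outer / 1 inner) with the scope stored as an attribute.
#' @export
location_design <- function(colonies, outer_scope = NULL) {
  sites <- dplyr::distinct(tibble::as_tibble(colonies),
                           .data$site_id, .data$location_class)
  dup <- sites$site_id[duplicated(sites$site_id)]
  if (length(dup) > 0) {
    abort(sprintf("site(s) mapped to more than one location class: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  unknown <- setdiff(unique(sites$location_class), location_classes())
  if (length(unknown) > 0) {
    abort(sprintf("unknown location class(es): %s",
                  paste(unknown, collapse = ", ")))
  }
  sites$location <- as.integer(sites$location_class == "inner")
  if (!is.null(outer_scope)) {
    for (sp in names(outer_scope)) {
      bad <- setdiff(outer_scope[[sp]], sites$site_id)
      if (length(bad) > 0) {
        abort(sprintf("outer scope for species '%s' names unknown site(s): %s",
                      sp, paste(bad, collapse = ", ")))
      }
    }
  }
  structure(sites, outer_scope = outer_scope,
            class = c("location_design", class(sites)))
}

#' Attach binary location to colony records
#'
#' Joins the design's 0/1 location onto colony records and applies any
#' per-species outer scope: outer-site records of a scoped species falling
#' outside its scope are dropped (counted in the `n_excluded` attribute).
#'
#' @param colonies A `colony_table`.
#' @param design A [location_design()].
#' @return The colony table with an integer `location` column (0 outer,
#'   1 inner); excluded-row count in `attr(, "n_excluded")`.
#' @export
pool_locations <- function(colonies, design) {
  x <- tibble::as_tibble(colonies)
  unmapped <- setdiff(unique(x$site_id), design$site_id)
  if (length(unmapped) > 0) {
    abort(sprintf("site(s) not covered by the location design: %s",
                  paste(unmapped, collapse = ", ")))
  }
  out <- dplyr::left_join(
    x, tibble::as_tibble(design)[, c("site_id", "location")], by = "site_id")
  scope <- attr(design, "outer_scope")
  n_excluded <- 0L
  if (!is.null(scope)) {
    keep <- rep(TRUE, nrow(out))
    for (sp in names(scope)) {
      drop <- out$species_id == sp & out$location == 0L &
        !(out$site_id %in% scope[[sp]])
      keep <- keep & !drop
    }
    n_excluded <- sum(!keep)
    if (n_excluded > 0) {
      inform(sprintf(
        "pool_locations: excluded %d record(s) outside species' outer scope",
        n_excluded))
    }
    out <- out[keep, ]
  }
  attr(out, "n_excluded") <- n_excluded
  out
}
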
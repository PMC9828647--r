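#' Read and validate a colony-level trait table
#'
#' One row per sampled colony: an identifier, the species, the site, the
#' site's location class along the gradient (`barrier`, `lagoon` or `inner`)
#' and the raw trait values. Raw traits must be strictly positive because the
#' analysis log-transforms them; missing values are allowed and kept as `NA`.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping the canonical column
#'   names (`colony_id`, `species_id`, `site_id`, `location_class`, and trait
#'   codes) to the names used in the file, e.g.
#'   `c(colony_id = "sample", ZD = "zoox_density")`. Columns not mentioned are
#'   expected under their canonical names.
#' @return A tibble of class `colony_table` with columns `colony_id`,
#'   `species_id`, `site_id`, `location_class` and one numeric column per
#'   trait present in the file.
#' @seealso [write_colony_table()], [transform_traits()]
#' @export
read_colony_table <- function(path, schema = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    bad <- setdiff(unname(schema), names(raw))
    if (length(bad) > 0) {
      abort(sprintf("schema maps to columns absent from '%s': %s",
                    path, paste(bad, collapse = ", ")))
    }
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  as_colony_table(raw)
}

#' Validate a data frame as a colony trait table
#'
#' @param x A data frame with the columns described in [read_colony_table()].
#' @return A validated `colony_table` tibble.
#' @export
as_colony_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("colony_id", "species_id", "site_id", "location_class")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("colony table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  traits <- intersect(trait_names(), names(x))
  if (length(traits) == 0) {
    abort("colony table contains none of the nine trait columns")
  }
  unknown_class <- setdiff(unique(x$location_class), location_classes())
  if (length(unknown_class) > 0) {
    abort(sprintf("unknown location_class value(s): %s (expected %s)",
                  paste(unknown_class, collapse = ", "),
                  paste(location_classes(), collapse = "/")))
  }
  for (tr in traits) {
    if (!is.numeric(x[[tr]])) {
      bad_rows <- which(is.na(suppressWarnings(as.numeric(x[[tr]]))) &
                          !is.na(x[[tr]]))
      abort(sprintf("trait column '%s' is not numeric (e.g. row %s)",
                    tr, paste(head(bad_rows, 5), collapse = ", ")))
    }
    nonpos <- which(!is.na(x[[tr]]) & x[[tr]] <= 0)
    if (length(nonpos) > 0) {
      abort(sprintf(
        "trait '%s' has non-positive value(s) in row(s) %s; raw traits must be > 0",
        tr, paste(head(nonpos, 10), collapse = ", ")))
    }
  }
  x$colony_id <- as.character(x$colony_id)
  x$species_id <- as.character(x$species_id)
  x$site_id <- as.character(x$site_id)
  x$location_class <- as.character(x$location_class)
  class(x) <- c("colony_table", class(x))
  x
}

#' @rdname read_colony_table
#' @param x A `colony_table`.
#' @export
write_colony_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Read and validate a line-intercept abundance table
#'
#' Benthic cover from line-intercept transects: for each transect, the length
#' of tape (cm) overlying colonies of each taxon. Taxa absent from
#' `sampled_species` (e.g. massive *Porites*, which is abundant but was not
#' collected for traits) are retained with `sampled = FALSE` so that coverage
#' of the trait-sampled pool can be reported and CWMs renormalized over it.
#'
#' @param path CSV with columns `site_id`, `transect_id`, `taxon_id`,
#'   `intercept_cm` (and optionally `sampled`).
#' @param sampled_species Character vector of trait-sampled taxa; if supplied
#'   it defines the `sampled` flag, overriding any flag in the file.
#' @return A tibble of class `abundance_table`.
#' @export
read_abundance_table <- function(path, sampled_species = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_abundance_table(raw, sampled_species = sampled_species)
}

#' @rdname read_abundance_table
#' @param x A data frame of intercepts.
#' @export
as_abundance_table <- function(x, sampled_species = NULL) {
  x <- tibble::as_tibble(x)
  required <- c("site_id", "transect_id", "taxon_id", "intercept_cm")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("abundance table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(x$intercept_cm)) || !is.numeric(x$intercept_cm)) {
    abort("intercept_cm must be numeric and non-missing")
  }
  neg <- which(x$intercept_cm < 0)
  if (length(neg) > 0) {
    abort(sprintf("negative intercept_cm in row(s) %s",
                  paste(head(neg, 10), collapse = ", ")))
  }
  totals <- dplyr::summarise(
    dplyr::group_by(x, .data$site_id, .data$transect_id),
    total = sum(.data$intercept_cm), .groups = "drop")
  empty <- totals[totals$total <= 0, ]
  if (nrow(empty) > 0) {
    abort(sprintf("transect(s) with zero total intercept: %s",
                  paste(paste(empty$site_id, empty$transect_id, sep = "/"),
                        collapse = ", ")))
  }
  if (!is.null(sampled_species)) {
    x$sampled <- x$taxon_id %in% sampled_species
  } else if (!"sampled" %in% names(x)) {
    x$sampled <- TRUE
  }
  x$sampled <- as.logical(x$sampled)
  x$intercept_cm <- as.numeric(unname(x$intercept_cm))
  x$site_id <- as.character(x$site_id)
  x$transect_id <- as.character(x$transect_id)
  x$taxon_id <- as.character(x$taxon_id)
  class(x) <- c("abundance_table", class(x))
  x
}

#' @rdname read_abundance_table
#' @export
write_abundance_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Relative abundances per transect
#'
#' Converts line-intercept lengths to proportions per transect, either over
#' the trait-sampled taxa only (the default, matching how CWMs are
#' renormalized when part of the cover comes from uncollected taxa) or over
#' all recorded taxa.
#'
#' @param abundance An `abundance_table`.
#' @param transect Optional `site_id`/`transect_id` pair (character vector of
#'   length 2) restricting the result to one transect.
#' @param over_sampled_only If `TRUE` (default), proportions are computed over
#'   taxa with `sampled = TRUE` only.
#' @return A tibble `site_id`, `transect_id`, `taxon_id`, `p`; within each
#'   transect `p` sums to 1 over the chosen taxon set.
#' @export
#' @examples
#' ab <- as_abundance_table(data.frame(
#'   site_id = "s1", transect_id = "t1",
#'   taxon_id = c("A", "B", "unsampled"), intercept_cm = c(300, 100, 100),
#'   sampled = c(TRUE, TRUE, FALSE)))
#' relative_abundance(ab)                            # A 0.75, B 0.25
#' relative_abundance(ab, over_sampled_only = FALSE) # 0.6, 0.2, 0.2
relative_abundance <- function(abundance, transect = NULL,
                               over_sampled_only = TRUE) {
  x <- tibble::as_tibble(abundance)
  if (!is.null(transect)) {
    x <- x[x$site_id == transect[[1]] & x$transect_id == transect[[2]], ]
    if (nrow(x) == 0) {
      abort(sprintf("transect %s/%s not found", transect[[1]], transect[[2]]))
    }
  }
  chosen <- dplyr::summarise(
    dplyr::group_by(x, .data$site_id, .data$transect_id),
    total = sum(.data$intercept_cm[if (over_sampled_only) .data$sampled
                                   else rep(TRUE, dplyr::n())]),
    .groups = "drop")
  if (any(chosen$total <= 0)) {
    bad <- chosen[chosen$total <= 0, ]
    abort(sprintf("transect(s) with zero cover over the chosen taxon set: %s",
                  paste(paste(bad$site_id, bad$transect_id, sep = "/"),
                        collapse = ", ")))
  }
  if (over_sampled_only) x <- x[x$sampled, ]
  out <- dplyr::mutate(
    dplyr::group_by(x, .data$site_id, .data$transect_id),
    p = .data$intercept_cm / sum(.data$intercept_cm))
  out <- dplyr::ungroup(out)
  out[, c("site_id", "transect_id", "taxon_id", "p")]
}
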
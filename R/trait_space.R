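#' Principal component analysis of colonies in trait space
#'
#' PCA of colony-by-trait values via [stats::prcomp()] on complete-case rows
#' (colonies with any missing trait are dropped and counted). Columns are
#' centered; when the input matrix was already z-standardized no further
#' scaling is applied, otherwise `scale` controls correlation- versus
#' covariance-based PCA. Component signs follow a deterministic convention:
#' the largest-magnitude loading of each component is made positive, so
#' results are reproducible across platforms.
#'
#' @param tm A `trait_matrix`.
#' @param scale Scale columns to unit variance before the decomposition?
#'   Default: TRUE unless `tm` is already standardized.
#' @return A `trait_pca`: list with `scores` (colonies x components, rownames
#'   colony_id), `loadings` (traits x components), `explained_variance`
#'   (proportions summing to 1), `rank`, `n_dropped`, `colonies` (metadata of
#'   retained rows).
#' @export
run_pca <- function(tm, scale = NULL) {
  stopifnot(inherits(tm, "trait_matrix"))
  m <- tm$values
  keep <- complete.cases(m)
  n_dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) abort("PCA needs at least 2 complete colony rows")
  already_std <- !all(tm$transform$center == 0 & tm$transform$scale == 1)
  if (is.null(scale)) scale <- !already_std
  if (scale) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("zero-variance trait(s) cannot be scaled: %s",
                    paste(colnames(m)[sds == 0], collapse = ", ")))
    }
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale)
  # deterministic sign convention
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  structure(
    list(
      scores = pc$x,
      loadings = pc$rotation,
      explained_variance = ev / sum(ev),
      rank = sum(ev > max(ev) * 1e-12),
      n_dropped = n_dropped,
      colonies = tm$colonies[keep, ]),
    class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("<trait_pca> %d colonies, %d traits, rank %d (%d dropped)\n",
              nrow(x$scores), nrow(x$loadings), x$rank, x$n_dropped))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance[1:min(3, length(x$explained_variance))]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Mean trait-space shifts of species along the gradient
#'
#' For each species present at two or more location classes, the displacement
#' of its mean PCA score between consecutive classes in gradient order
#' (barrier -> lagoon -> inner). Species seen at a single class are omitted
#' (and counted in `attr(, "n_omitted")`).
#'
#' @param pca A `trait_pca`.
#' @param n_components Number of leading components to report (default 2).
#' @return Tibble `species_id`, `from_location`, `to_location`, one `dPC<k>`
#'   column per component, and `n_from`/`n_to` colony counts.
#' @export
species_shift_vectors <- function(pca, n_components = 2) {
  stopifnot(inherits(pca, "trait_pca"))
  k <- min(n_components, ncol(pca$scores))
  meta <- pca$colonies
  cls <- location_classes()
  centroids <- dplyr::summarise(
    dplyr::group_by(
      cbind(meta, as.data.frame(pca$scores[, seq_len(k), drop = FALSE])),
      .data$species_id, .data$location_class),
    dplyr::across(dplyr::starts_with("PC"), mean),
    n = dplyr::n(), .groups = "drop")
  rows <- list()
  n_omitted <- 0L
  for (sp in unique(centroids$species_id)) {
    cs <- centroids[centroids$species_id == sp, ]
    present <- cls[cls %in% cs$location_class]
    if (length(present) < 2) { n_omitted <- n_omitted + 1L; next }
    for (i in seq_len(length(present) - 1)) {
      a <- cs[cs$location_class == present[i], ]
      b <- cs[cs$location_class == present[i + 1], ]
      d <- as.numeric(b[, paste0("PC", seq_len(k))]) -
        as.numeric(a[, paste0("PC", seq_len(k))])
      rows[[length(rows) + 1]] <- tibble::tibble(
        species_id = sp,
        from_location = present[i], to_location = present[i + 1],
        !!!setNames(as.list(d), paste0("dPC", seq_len(k))),
        n_from = a$n, n_to = b$n)
    }
  }
  if (n_omitted > 0) {
    inform(sprintf(
      "species_shift_vectors: omitted %d single-location species", n_omitted))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_omitted") <- n_omitted
  out
}

#' Abundance-weighted assemblage shift of site-restricted species
#'
#' Species restricted to one side of the gradient mark pure turnover: the
#' displacement between the abundance-weighted mean PCA position of
#' outer-restricted species and that of inner-restricted species is the
#' trait-space shift contributed by species replacement alone. Weights are
#' each restricted species' share of summed intercept cover on its side.
#'
#' @param pca A `trait_pca`.
#' @param abundance An `abundance_table` (used for weights).
#' @param design A [location_design()].
#' @param n_components Number of leading components (default 2).
#' @return A list: `centroids` (tibble per location with weighted mean PC
#'   coordinates), `delta` (named numeric, inner minus outer), `species`
#'   (tibble of restricted species and weights). Empty (with a warning) when
#'   no restricted species exist on either side.
#' @export
assemblage_shift <- function(pca, abundance, design, n_components = 2) {
  stopifnot(inherits(pca, "trait_pca"))
  k <- min(n_components, ncol(pca$scores))
  meta <- pool_locations(pca$colonies, design)
  occ <- dplyr::summarise(dplyr::group_by(meta, .data$species_id),
                          n_loc = length(unique(.data$location)),
                          location = .data$location[1], .groups = "drop")
  restricted <- occ[occ$n_loc == 1, ]
  if (nrow(restricted) == 0 || length(unique(restricted$location)) < 2) {
    warn("assemblage_shift: no site-restricted species on both sides")
    return(list(centroids = tibble::tibble(), delta = NULL,
                species = restricted))
  }
  ab <- pool_locations(
    dplyr::rename(tibble::as_tibble(abundance), species_id = "taxon_id"),
    design)
  cover <- dplyr::summarise(
    dplyr::group_by(ab[ab$species_id %in% restricted$species_id, ],
                    .data$species_id),
    cover = sum(.data$intercept_cm), .groups = "drop")
  sp <- dplyr::left_join(restricted, cover, by = "species_id")
  sp$cover[is.na(sp$cover)] <- 0
  sp <- dplyr::mutate(dplyr::group_by(sp, .data$location),
                      weight = .data$cover / sum(.data$cover))
  sp <- dplyr::ungroup(sp)

  sc <- pca$scores[, seq_len(k), drop = FALSE]
  sp_centroid <- dplyr::summarise(
    dplyr::group_by(cbind(meta, as.data.frame(sc)), .data$species_id),
    dplyr::across(dplyr::starts_with("PC"), mean), .groups = "drop")
  sp <- dplyr::left_join(sp, sp_centroid, by = "species_id")
  pcs <- paste0("PC", seq_len(k))
  centroids <- dplyr::summarise(
    dplyr::group_by(sp, .data$location),
    dplyr::across(dplyr::all_of(pcs),
                  ~ sum(.x * .data$weight)),
    .groups = "drop")
  inner <- centroids[centroids$location == 1, pcs]
  outer <- centroids[centroids$location == 0, pcs]
  delta <- setNames(as.numeric(inner) - as.numeric(outer), pcs)
  list(centroids = centroids, delta = delta,
       species = sp[, c("species_id", "location", "cover", "weight")])
}
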
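# shared in-code fixtures for the test suite

# cwm_table with prescribed fixed/local series for a single trait
manual_cwm <- function(local, fixed, trait = "TB",
                       location = rep(0:1, length.out = length(local))) {
  structure(
    tibble::tibble(
      site_id = paste0("s", seq_along(local)),
      transect_id = "T1",
      location = location,
      trait = trait,
      cwm_fixed = fixed,
      cwm_local = local,
      coverage = 1),
    class = c("cwm_table", "tbl_df", "tbl", "data.frame"))
}

# random multi-trait cwm_table for property tests
random_cwm <- function(n_transects = 8, n_traits = 3) {
  traits <- sample(trait_names(), n_traits)
  dplyr::bind_rows(lapply(traits, function(tr) {
    manual_cwm(local = rnorm(n_transects), fixed = rnorm(n_transects),
               trait = tr)
  }))
}

# minimal colony table: one row per species x site, trait values supplied
# as a named list of vectors aligned with the rows
make_colonies <- function(species, sites, classes, traits) {
  as_colony_table(tibble::tibble(
    colony_id = sprintf("c%02d", seq_along(species)),
    species_id = species, site_id = sites, location_class = classes,
    !!!traits))
}

# a manually built trait_pca for geometric hand-checks
manual_pca <- function(scores, colonies, loadings = NULL) {
  k <- ncol(scores)
  colnames(scores) <- paste0("PC", seq_len(k))
  if (is.null(loadings)) {
    loadings <- diag(k)
    dimnames(loadings) <- list(paste0("t", seq_len(k)), colnames(scores))
  }
  ev <- apply(scores, 2, var)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev / sum(ev),
                 rank = k, n_dropped = 0L, colonies = colonies),
            class = "trait_pca")
}

# full desk-scale analysis of one synthetic community
analyse_community <- function(com) {
  tm <- transform_traits(com$colonies)
  design <- location_design(com$colonies)
  cwm <- compute_cwm(com$abundance, species_means(tm, "fixed"),
                     species_means(tm, "local"), design)
  decompose_traits(cwm)
}
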
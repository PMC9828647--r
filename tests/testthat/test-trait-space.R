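test_that("collinear data load entirely on the first component", {
  col <- make_colonies(
    species = c("a", "a"), sites = c("s1", "s1"), classes = "barrier",
    traits = list(ZD = c(1, 3), TB = c(1, 3)))
  tm <- transform_traits(col, log = FALSE, standardize = FALSE)
  pca <- run_pca(tm, scale = FALSE)
  expect_equal(pca$explained_variance[1], 1)
  expect_equal(pca$rank, 1)
})

test_that("row permutation leaves loadings fixed and permutes scores", {
  com <- generate_community(synthetic_config(seed = 61))
  tm <- transform_traits(com$colonies)
  pca <- run_pca(tm)
  perm <- sample(nrow(tm$values))
  tm2 <- tm
  tm2$values <- tm$values[perm, ]
  tm2$colonies <- tm$colonies[perm, ]
  pca2 <- run_pca(tm2)
  expect_equal(pca2$loadings, pca$loadings, tolerance = 1e-10)
  expect_equal(pca2$scores[rownames(pca$scores), ], pca$scores,
               tolerance = 1e-10)
})

test_that("scores and loadings reconstruct the centered data at full rank", {
  set.seed(123)
  col <- make_colonies(
    species = rep("a", 20), sites = rep("s1", 20), classes = "barrier",
    traits = setNames(lapply(1:5, function(i) exp(rnorm(20))),
                      trait_names()[1:5]))
  tm <- transform_traits(col, log = TRUE, standardize = TRUE)
  pca <- run_pca(tm)
  recon <- pca$scores %*% t(pca$loadings)
  centered <- sweep(tm$values, 2, colMeans(tm$values))
  expect_equal(recon, centered, tolerance = 1e-9)
  # orthogonal scores, unit-norm loadings, variance fractions sum to 1
  g <- crossprod(pca$scores)
  expect_true(all(abs(g[upper.tri(g)]) < 1e-8))
  expect_equal(sum(pca$explained_variance), 1)
  expect_equal(colSums(pca$loadings^2), rep(1, 5), ignore_attr = TRUE)
})

test_that("sign convention makes the largest loading positive and is deterministic", {
  com <- generate_community(synthetic_config(seed = 62))
  tm <- transform_traits(com$colonies)
  pca <- run_pca(tm)
  for (j in seq_len(ncol(pca$loadings))) {
    i_max <- which.max(abs(pca$loadings[, j]))
    expect_gt(pca$loadings[i_max, j], 0)
  }
  expect_identical(pca$loadings, run_pca(tm)$loadings)
})

test_that("species shift vectors are centroid displacements in gradient order", {
  # two colonies per class with known score means
  colonies <- tibble::tibble(
    colony_id = sprintf("c%d", 1:6), species_id = "spA",
    site_id = c("b", "b", "l", "l", "i", "i"),
    location_class = rep(c("barrier", "lagoon", "inner"), each = 2))
  scores <- cbind(c(0, 2, 3, 5, 10, 12), rep(0, 6))
  pca <- manual_pca(scores, colonies)
  sv <- species_shift_vectors(pca)
  expect_equal(nrow(sv), 2)
  expect_equal(sv$from_location, c("barrier", "lagoon"))
  expect_equal(sv$dPC1, c(3, 7))  # 4-1, 11-4
  expect_equal(sv$dPC2, c(0, 0))

  # identical centroids give the zero vector
  pca0 <- manual_pca(cbind(rep(1, 6), rep(2, 6)), colonies)
  sv0 <- species_shift_vectors(pca0)
  expect_true(all(abs(c(sv0$dPC1, sv0$dPC2)) < 1e-12))
})

test_that("single-location species are omitted from shift vectors", {
  com <- generate_community(synthetic_config(seed = 63))
  tm <- transform_traits(com$colonies)
  pca <- run_pca(tm)
  sv <- suppressMessages(species_shift_vectors(pca))
  gens <- com$truth$species$species_id[com$truth$species$role == "generalist"]
  outs <- com$truth$species$species_id[
    com$truth$species$role == "outer_specialist"]
  # generalists span all three classes: two consecutive vectors each;
  # outer specialists span barrier+lagoon: one vector each
  expect_equal(sum(sv$species_id %in% gens), 2 * length(gens))
  expect_equal(sum(sv$species_id %in% outs), length(outs))
  expect_false(any(grepl("^insp", sv$species_id)))
})

test_that("assemblage shift is the abundance-weighted centroid displacement", {
  colonies <- tibble::tibble(
    colony_id = sprintf("c%d", 1:4),
    species_id = c("o1", "o2", "i1", "i2"),
    site_id = c("b", "b", "i", "i"),
    location_class = c("barrier", "barrier", "inner", "inner"))
  design <- location_design(colonies)
  scores <- cbind(c(-1, 1, 0, 4), rep(0, 4))
  pca <- manual_pca(scores, colonies)
  ab_eq <- as_abundance_table(tibble::tibble(
    site_id = c("b", "b", "i", "i"), transect_id = "t1",
    taxon_id = c("o1", "o2", "i1", "i2"), intercept_cm = c(50, 50, 50, 50)))
  sh <- assemblage_shift(pca, ab_eq, design)
  # equal weights: outer centroid (-1+1)/2 = 0, inner (0+4)/2 = 2
  expect_equal(unname(sh$delta["PC1"]), 2)

  ab_w <- as_abundance_table(tibble::tibble(
    site_id = c("b", "b", "i", "i"), transect_id = "t1",
    taxon_id = c("o1", "o2", "i1", "i2"), intercept_cm = c(50, 50, 75, 25)))
  sh_w <- assemblage_shift(pca, ab_w, design)
  # weights (0.75, 0.25) on scores (0, 4): inner centroid at 1
  expect_equal(unname(sh_w$delta["PC1"]), 1)

  # no restricted species on both sides: empty result with a warning
  colonies_gen <- dplyr::mutate(colonies, species_id = "g1")
  pca_gen <- manual_pca(scores, colonies_gen)
  expect_warning(empty <- assemblage_shift(pca_gen, ab_eq, design),
                 "no site-restricted")
  expect_null(empty$delta)
})

test_that("PCA matches a brute-force eigendecomposition up to sign", {
  set.seed(404)
  for (i in 1:10) {
    x <- matrix(rnorm(20 * 9), 20, 9)
    colnames(x) <- trait_names()
    col <- make_colonies(
      species = rep("a", 20), sites = rep("s1", 20), classes = "barrier",
      traits = as.list(as.data.frame(exp(x))))
    tm <- transform_traits(col, log = TRUE, standardize = FALSE)
    pca <- run_pca(tm, scale = FALSE)
    eig <- eigen(cov(x), symmetric = TRUE)
    for (j in 1:9) {
      v <- eig$vectors[, j]
      expect_lt(min(max(abs(pca$loadings[, j] - v)),
                    max(abs(pca$loadings[, j] + v))), 1e-8)
    }
    expect_equal(pca$explained_variance,
                 eig$values / sum(eig$values), tolerance = 1e-10)
  }
})

test_that("intraspecific shift vectors align with tissue loadings at low noise", {
  com <- generate_community(synthetic_config(seed = 77, noise_sd = 0.05))
  tm <- transform_traits(com$colonies)
  pca <- run_pca(tm)
  sv <- suppressMessages(species_shift_vectors(pca))
  # direction of the summed tissue-trait loadings in PC1/PC2 space
  tissue_dir <- colSums(pca$loadings[tissue_traits(), 1:2])
  tissue_dir <- tissue_dir / sqrt(sum(tissue_dir^2))
  gens <- com$truth$species$species_id[com$truth$species$role == "generalist"]
  to_inner <- sv[sv$to_location == "inner" & sv$species_id %in% gens, ]
  cosines <- apply(cbind(to_inner$dPC1, to_inner$dPC2), 1, function(d) {
    sum(d * tissue_dir) / sqrt(sum(d^2))
  })
  # tissue deltas dominate the generating shift, so lagoon->inner moves
  # should point with the tissue loadings
  expect_gt(mean(cosines > 0.7), 0.7)

  sh <- assemblage_shift(pca, com$abundance, location_design(com$colonies))
  expect_gt(sum(sh$delta * tissue_dir), 0)
})
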
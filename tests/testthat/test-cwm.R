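test_that("species means are unweighted arithmetic means per cell", {
  col <- make_colonies(
    species = c("a", "a", "b", "b"),
    sites = c("s1", "s1", "s1", "s2"),
    classes = c("barrier", "barrier", "barrier", "inner"),
    traits = list(ZD = c(1, 3, 5, 7)))
  tm <- transform_traits(col, log = FALSE, standardize = FALSE)
  fx <- species_means(tm, "fixed")
  expect_equal(fx$mean[fx$species_id == "a"], 2)
  # study-wide mean is unweighted across colonies, not abundance-weighted
  expect_equal(fx$mean[fx$species_id == "b"], 6)
  expect_equal(fx$n_colonies[fx$species_id == "a"], 2L)

  lc <- species_means(tm, "local")
  expect_equal(lc$mean[lc$species_id == "b" & lc$site_id == "s1"], 5)
  expect_equal(lc$mean[lc$species_id == "b" & lc$site_id == "s2"], 7)
})

test_that("CWM is the abundance-weighted mean of species means", {
  col <- make_colonies(
    species = c("a", "b"), sites = c("s1", "s1"),
    classes = "barrier", traits = list(TB = c(2, 5)))
  tm <- transform_traits(col, log = FALSE, standardize = FALSE)
  ab <- as_abundance_table(tibble::tibble(
    site_id = "s1", transect_id = "t1", taxon_id = c("a", "b"),
    intercept_cm = c(600, 400)))
  cwm <- compute_cwm(ab, species_means(tm, "fixed"),
                     species_means(tm, "local"), location_design(col))
  expect_equal(cwm$cwm_fixed, 0.6 * 2 + 0.4 * 5)  # 3.2
  expect_equal(cwm$cwm_local, 3.2)
  expect_equal(cwm$coverage, 1)
})

test_that("CWM stays within the convex hull of contributing means", {
  set.seed(99)
  for (i in 1:10) {
    n_sp <- sample(2:6, 1)
    means <- rnorm(n_sp)
    col <- make_colonies(
      species = letters[1:n_sp], sites = "s1", classes = "barrier",
      traits = list(TB = exp(means)))
    tm <- transform_traits(col, log = TRUE, standardize = FALSE)
    ab <- as_abundance_table(tibble::tibble(
      site_id = "s1", transect_id = "t1", taxon_id = letters[1:n_sp],
      intercept_cm = runif(n_sp, 1, 100)))
    cwm <- compute_cwm(ab, species_means(tm, "fixed"),
                       species_means(tm, "local"), location_design(col))
    expect_gte(cwm$cwm_fixed, min(means) - 1e-12)
    expect_lte(cwm$cwm_fixed, max(means) + 1e-12)
  }
  # all species sharing mean m gives CWM m regardless of abundance
  col <- make_colonies(species = c("a", "b"), sites = c("s1", "s1"),
                       classes = "barrier", traits = list(TB = c(4, 4)))
  tm <- transform_traits(col, log = FALSE, standardize = FALSE)
  ab <- as_abundance_table(tibble::tibble(
    site_id = "s1", transect_id = "t1", taxon_id = c("a", "b"),
    intercept_cm = c(999, 1)))
  cwm <- compute_cwm(ab, species_means(tm, "fixed"),
                     species_means(tm, "local"), location_design(col))
  expect_equal(cwm$cwm_fixed, 4)
})

test_that("species unsampled at a site fall back to their fixed mean", {
  col <- make_colonies(
    species = c("a", "a", "b"), sites = c("s1", "s2", "s1"),
    classes = c("barrier", "inner", "barrier"),
    traits = list(TB = c(1, 3, 5)))
  tm <- transform_traits(col, log = FALSE, standardize = FALSE)
  # species b recorded on the s2 transect but never trait-sampled at s2
  ab <- as_abundance_table(tibble::tibble(
    site_id = c("s1", "s1", "s2", "s2"), transect_id = "t1",
    taxon_id = c("a", "b", "a", "b"), intercept_cm = c(50, 50, 50, 50)))
  cwm <- compute_cwm(ab, species_means(tm, "fixed"),
                     species_means(tm, "local"), location_design(col))
  expect_equal(attr(cwm, "n_fallback"), 1L)
  s2 <- cwm[cwm$site_id == "s2", ]
  expect_equal(s2$cwm_local, 0.5 * 3 + 0.5 * 5)  # b contributes its fixed mean
  expect_equal(s2$cwm_fixed, 0.5 * 2 + 0.5 * 5)
})

test_that("SS decomposition reproduces the worked examples", {
  d1 <- ss_decompose(manual_cwm(local = c(1, 3), fixed = c(1.5, 2.5)))
  expect_equal(d1$ss_local, 2)
  expect_equal(d1$ss_fixed, 0.5)
  expect_equal(d1$ss_intra, 0.5)
  expect_equal(d1$ss_cov, 1)
  expect_equal(c(d1$prop_fixed, d1$prop_intra, d1$prop_cov),
               c(0.25, 0.25, 0.5))

  # local = fixed: all variation is compositional
  d2 <- ss_decompose(manual_cwm(local = c(1, 3), fixed = c(1, 3)))
  expect_equal(d2$ss_intra, 0)
  expect_equal(d2$ss_cov, 0)
  expect_equal(d2$prop_fixed, 1)

  # intraspecific differences opposing composition: negative covariation
  d3 <- ss_decompose(manual_cwm(local = c(1.5, 2.5), fixed = c(1, 3)))
  expect_equal(d3$ss_local, 0.5)
  expect_equal(d3$ss_fixed, 2)
  expect_equal(d3$ss_intra, 0.5)
  expect_equal(d3$ss_cov, -2)
  expect_equal(c(d3$prop_fixed, d3$prop_intra, d3$prop_cov), c(4, 1, -4))
  expect_equal(d3$prop_fixed + d3$prop_intra + d3$prop_cov, 1)
})

test_that("SS decomposition errors on degenerate inputs", {
  expect_error(ss_decompose(manual_cwm(local = c(2, 2), fixed = c(1, 3))),
               "ss_local = 0")
  expect_error(ss_decompose(manual_cwm(local = 1, fixed = 1)),
               "at least 2 transects")
})

test_that("SS covariation equals the expanded cross term on random tables", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    cwm <- manual_cwm(local = rnorm(n, sd = runif(1, 0.1, 5)),
                      fixed = rnorm(n, sd = runif(1, 0.1, 5)))
    d <- ss_decompose(cwm)
    f <- cwm$cwm_fixed
    dd <- cwm$cwm_local - cwm$cwm_fixed
    cross <- 2 * sum((f - mean(f)) * (dd - mean(dd)))
    expect_equal(d$ss_cov, cross, tolerance = 1e-9)
  }
})

test_that("effect decomposition is zero when local means equal fixed means", {
  com <- generate_community(synthetic_config(seed = 17))
  tm <- transform_traits(com$colonies)
  design <- location_design(com$colonies)
  fixed <- species_means(tm, "fixed")
  # degenerate local means: copy the fixed mean into every sampled site
  sites <- dplyr::distinct(tibble::as_tibble(com$colonies),
                           species_id, site_id)
  local_eq <- dplyr::inner_join(sites, fixed, by = "species_id",
                                relationship = "many-to-many")
  cwm <- compute_cwm(com$abundance, fixed, local_eq, design)
  expect_equal(cwm$cwm_local, cwm$cwm_fixed, tolerance = 1e-12)
  ef <- effect_decompose(cwm)
  expect_true(all(abs(ef$e_intra) < 1e-8))
})

test_that("effect decomposition falls back to OLS with one site per class", {
  cwm <- dplyr::bind_rows(
    manual_cwm(local = c(1, 1.2, 3, 3.1), fixed = c(1, 1.1, 2.5, 2.6),
               location = c(0, 0, 1, 1)))
  cwm$site_id <- c("s1", "s1", "s2", "s2")
  cwm$transect_id <- c("t1", "t2", "t1", "t2")
  expect_warning(ef <- effect_decompose(cwm), "OLS fallback")
  expect_equal(ef$method, "ols")
  expect_equal(ef$e_intra, ef$e_local - ef$e_fixed)
})

test_that("amplification and reduction follow their definitions", {
  expect_equal(amplification_factor(2, 3), 1.5)
  expect_equal(amplification_factor(1, 1), 1)
  expect_equal(reduction_percent(1, 1), 0)
  expect_equal(reduction_percent(-2, -1.56), 22)
  expect_error(amplification_factor(0, 1), "undefined")
  expect_error(reduction_percent(0, 1), "undefined")
})

test_that("aligned intraspecific and turnover shifts give positive covariation, opposing give attenuation", {
  com <- generate_community(synthetic_config(seed = 53))
  dec <- analyse_community(com)
  # tissue: intraspecific shift aligned with specialist turnover
  for (tr in c("ZD", "CH")) {
    row <- dec[dec$trait == tr, ]
    expect_gt(row$prop_cov, 0)
    expect_equal(sign(row$e_intra), sign(row$e_fixed))
  }
  # morphology: intraspecific shift opposes the compositional shift
  sv <- dec[dec$trait == "SV", ]
  expect_lt(abs(sv$e_local), abs(sv$e_fixed))
  expect_gt(sv$reduction, 0)
})
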
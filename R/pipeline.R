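#' Run the full assemblage-trait pipeline
#'
#' Orchestrates one reproducible run: obtain data (simulate a synthetic
#' community, or read colony and abundance CSVs), transform traits, fit
#' per-species and pooled effect sizes, compute fixed/local CWMs on both the
#' transformed and raw scales, decompose assemblage trait variation, and
#' ordinate colonies in trait space. All stage outputs are written as plain
#' CSV under `out_dir` together with a JSON manifest of config and output
#' checksums; rerunning with the same config and seed reproduces identical
#' files.
#'
#' @param config `NULL` (defaults: simulate), a path to a YAML config file,
#'   or a nested list with elements `simulate` (logical), `synthetic`
#'   (arguments for [synthetic_config()]), `inputs` (`colony_table`,
#'   `abundance_table`, optional `sampled_species`), `transform` (`log`,
#'   `standardize`).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @return Invisibly, a list of class `reef_run` with the in-memory stage
#'   results (`colonies`, `abundance`, `design`, `trait_matrix`, `effects`,
#'   `cwm`, `cwm_raw`, `decomposition`, `pca`, `species_shifts`,
#'   `assemblage_shift`, `report`) and the `manifest`.
#' @export
#' @examples
#' run <- run_pipeline(out_dir = tempfile("reefrun"), seed = 7)
#' run$decomposition
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- resolve_config(config)
  if (!is.null(seed)) cfg$synthetic$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  if (isTRUE(cfg$simulate)) {
    sim <- generate_community(do.call(synthetic_config, cfg$synthetic))
    colonies <- sim$colonies
    abundance <- sim$abundance
  } else {
    if (is.null(cfg$inputs$colony_table) ||
        !file.exists(cfg$inputs$colony_table)) {
      abort("stage input: colony_table file missing and simulate is FALSE")
    }
    if (is.null(cfg$inputs$abundance_table) ||
        !file.exists(cfg$inputs$abundance_table)) {
      abort("stage input: abundance_table file missing and simulate is FALSE")
    }
    colonies <- read_colony_table(cfg$inputs$colony_table,
                                  schema = cfg$inputs$schema)
    abundance <- read_abundance_table(
      cfg$inputs$abundance_table,
      sampled_species = cfg$inputs$sampled_species %||%
        unique(colonies$species_id))
  }

  design <- location_design(colonies)
  tm <- transform_traits(colonies, log = cfg$transform$log,
                         standardize = cfg$transform$standardize)
  effects <- effect_size_table(tm, design)

  cwm <- compute_cwm(abundance, species_means(tm, "fixed"),
                     species_means(tm, "local"), design)
  if (attr(cwm, "n_fallback") > 0) {
    note(sprintf("cwm: %d local-mean fallback(s) to the study-wide mean",
                 attr(cwm, "n_fallback")))
  }
  tm_raw <- transform_traits(colonies, log = FALSE, standardize = FALSE)
  cwm_raw <- compute_cwm(abundance, species_means(tm_raw, "fixed"),
                         species_means(tm_raw, "local"), design)
  decomposition <- decompose_traits(cwm)

  pca <- run_pca(tm)
  if (pca$n_dropped > 0) {
    note(sprintf("pca: dropped %d incomplete colony row(s)", pca$n_dropped))
  }
  species_shifts <- suppressMessages(species_shift_vectors(pca))
  shift <- withCallingHandlers(
    assemblage_shift(pca, abundance, design),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })

  report <- decomposition[, c("trait", "e_fixed", "e_intra", "e_local",
                              "prop_fixed", "prop_intra", "prop_cov")]

  paths <- c(
    colonies = "colonies.csv", abundance = "abundance.csv",
    effects = "effects.csv", cwm = "cwm.csv", cwm_raw = "cwm_raw.csv",
    decomposition = "decomposition.csv", pca_loadings = "pca_loadings.csv",
    pca_scores = "pca_scores.csv", species_shifts = "species_shifts.csv",
    report = "report.csv")
  paths[] <- file.path(out_dir, paths)
  write_colony_table(colonies, paths[["colonies"]])
  write_abundance_table(abundance, paths[["abundance"]])
  readr::write_csv(effects, paths[["effects"]])
  readr::write_csv(tibble::as_tibble(cwm), paths[["cwm"]])
  readr::write_csv(tibble::as_tibble(cwm_raw), paths[["cwm_raw"]])
  readr::write_csv(decomposition, paths[["decomposition"]])
  readr::write_csv(tibble::as_tibble(as.data.frame(pca$loadings),
                                     rownames = "trait"),
                   paths[["pca_loadings"]])
  readr::write_csv(tibble::as_tibble(as.data.frame(pca$scores),
                                     rownames = "colony_id"),
                   paths[["pca_scores"]])
  readr::write_csv(species_shifts, paths[["species_shifts"]])
  readr::write_csv(report, paths[["report"]])

  manifest <- list(
    config = cfg,
    checksums = as.list(tools::md5sum(unname(paths))),
    outputs = as.list(paths),
    warnings = warnings_log)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(structure(
    list(colonies = colonies, abundance = abundance, design = design,
         trait_matrix = tm, effects = effects, cwm = cwm, cwm_raw = cwm_raw,
         decomposition = decomposition, pca = pca,
         species_shifts = species_shifts, assemblage_shift = shift,
         report = report, manifest = manifest,
         manifest_path = manifest_path),
    class = "reef_run"))
}

# merge user config (list or YAML path) over defaults
resolve_config <- function(config) {
  defaults <- list(
    simulate = TRUE,
    synthetic = list(),
    inputs = list(colony_table = NULL, abundance_table = NULL,
                  sampled_species = NULL, schema = NULL),
    transform = list(log = TRUE, standardize = TRUE))
  if (is.null(config)) return(defaults)
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be NULL, a YAML path, or a list")
  merged <- defaults
  for (key in names(config)) {
    if (is.list(defaults[[key]]) && is.list(config[[key]])) {
      merged[[key]][names(config[[key]])] <- config[[key]]
    } else {
      merged[[key]] <- config[[key]]
    }
  }
  if (!is.null(merged$inputs$schema)) {
    merged$inputs$schema <- unlist(merged$inputs$schema)
  }
  if (!is.null(merged$synthetic$delta)) {
    merged$synthetic$delta <- unlist(merged$synthetic$delta)
  }
  if (!is.null(merged$synthetic$colonies_range)) {
    merged$synthetic$colonies_range <- unlist(merged$synthetic$colonies_range)
  }
  merged
}

#' @export
print.reef_run <- function(x, ...) {
  cat(sprintf("<reef_run> %d colonies, %d transects, %d traits\n",
              nrow(x$colonies),
              nrow(dplyr::distinct(tibble::as_tibble(x$abundance),
                                   .data$site_id, .data$transect_id)),
              length(unique(x$cwm$trait))))
  cat("outputs:", dirname(x$manifest_path), "\n")
  invisible(x)
}
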
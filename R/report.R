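#' Analysis run configuration
#'
#' Bundles everything one garden-vs-city run needs. The defaults are the
#' study constants: 1000 permutation replicates, hotspot threshold at the
#' 75th percentile, a 40-observation garden inclusion floor, and the
#' 2000-01-01 to 2022-06-21 community-science date window.
#'
#' @param city_csv Path to the city occurrence CSV.
#' @param garden_box The garden's [bbox()].
#' @param seed Integer seed for the permutation draws.
#' @param garden_csv Optional path to a garden occurrence CSV; when absent
#'   the garden is the city records inside `garden_box`.
#' @param start_date,end_date Date window applied to all records.
#' @param R Permutation replicates.
#' @param threshold Hotspot percentile threshold.
#' @param min_garden_obs Garden inclusion floor (warning below it).
#' @param output_dir Directory for the report bundle.
#' @param log_base Shannon logarithm base: `exp(1)`, 2 or 10.
#' @param garden_name Label used in reports and file content.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(city_csv, garden_box, seed,
                       garden_csv = NULL,
                       start_date = "2000-01-01", end_date = "2022-06-21",
                       R = 1000, threshold = 75, min_garden_obs = 40,
                       output_dir = "gardenspot-output",
                       log_base = exp(1), garden_name = "garden") {
  stopifnot(inherits(garden_box, "bbox"))
  if (R < 1) abort("R must be >= 1.")
  if (threshold < 0 || threshold > 100) abort("threshold must be in [0, 100].")
  if (missing(seed)) abort("seed is required.")
  structure(
    list(city_csv = city_csv, garden_csv = garden_csv,
         garden_box = garden_box,
         start_date = as.Date(start_date), end_date = as.Date(end_date),
         R = as.integer(R), seed = as.integer(seed),
         threshold = threshold, min_garden_obs = as.integer(min_garden_obs),
         output_dir = output_dir, log_base = log_base,
         garden_name = garden_name),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Fields mirror the arguments of [run_config()]; `garden_box` is given as
#' four numbers `[min_lon, min_lat, max_lon, max_lat]`. `overrides` (e.g.
#' parsed command-line flags) win over file values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @param overrides Named list of values that replace file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg[names(overrides)] <- overrides
  if (is.null(cfg$garden_box)) abort("config lacks garden_box.")
  box <- as.numeric(unlist(cfg$garden_box))
  if (length(box) != 4) abort("garden_box must be four numbers: min_lon, min_lat, max_lon, max_lat.")
  args <- cfg[intersect(names(cfg),
                        c("city_csv", "garden_csv", "seed", "start_date",
                          "end_date", "R", "threshold", "min_garden_obs",
                          "output_dir", "log_base", "garden_name"))]
  args$garden_box <- bbox(box[1], box[2], box[3], box[4])
  do.call(run_config, args)
}

#' Run the full garden-vs-city analysis and write a report bundle
#'
#' End-to-end pipeline: read the city CSV, apply the date window,
#' de-duplicate, derive (or read) the garden set, assess the garden against
#' the rectangle-matched permutation null, and write the report bundle to
#' `cfg$output_dir`:
#'
#' * `assessment.json` — the full [assess_garden()] result;
#' * `assessment.csv` — the one-row summary-table form ([tidy()]);
#' * `replicates.csv` + `replicates.csv.meta.json` — the null distribution
#'   and its sampling metadata;
#' * `null_distribution.png` — the distribution-vs-observed figure.
#'
#' Every run logs (via `message()`) the seed, R, threshold, rectangle
#' dimensions and the record count after each filtering stage, so a run can
#' be reproduced from its log alone.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress log messages.
#' @return The `hotspot_assessment`, invisibly, with the written paths in
#'   the `"paths"` attribute.
#' @export
run_analysis <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  city_raw <- read_occurrences(cfg$city_csv, quiet = quiet)
  log("read %d city record(s) from %s (%d dropped in validation)",
      nrow(city_raw), cfg$city_csv, validation_report(city_raw)$n_dropped)
  city <- filter_date_range(city_raw, cfg$start_date, cfg$end_date)
  log("date window %s..%s: %d record(s) remain",
      cfg$start_date, cfg$end_date, nrow(city))
  city <- deduplicate(city)
  log("de-duplication: %d record(s) remain", nrow(city))

  garden <- if (!is.null(cfg$garden_csv)) {
    g <- read_occurrences(cfg$garden_csv, quiet = quiet)
    g <- filter_date_range(g, cfg$start_date, cfg$end_date)
    deduplicate(g)
  } else {
    filter_bbox(city, cfg$garden_box)
  }
  dims <- bbox_dims(cfg$garden_box)
  log("garden '%s': %d record(s) in a %g x %g deg rectangle",
      cfg$garden_name, nrow(garden), dims$width_lon, dims$height_lat)
  log("permutation: R = %d, seed = %d, hotspot threshold = %g",
      cfg$R, cfg$seed, cfg$threshold)

  assessment <- assess_garden(garden, city, cfg$garden_box,
                              R = cfg$R, seed = cfg$seed,
                              threshold = cfg$threshold,
                              min_garden_obs = cfg$min_garden_obs,
                              base = cfg$log_base,
                              garden_name = cfg$garden_name)

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    json = file.path(cfg$output_dir, "assessment.json"),
    csv = file.path(cfg$output_dir, "assessment.csv"),
    replicates = file.path(cfg$output_dir, "replicates.csv"),
    plot = file.path(cfg$output_dir, "null_distribution.png")
  )
  jsonlite::write_json(assessment_as_list(assessment), paths[["json"]],
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(tidy(assessment), paths[["csv"]], progress = FALSE)
  write_null_distribution(assessment$null, paths[["replicates"]])
  ggplot2::ggsave(paths[["plot"]], autoplot(assessment),
                  width = 7, height = 4, dpi = 150)
  log("report bundle written to %s", cfg$output_dir)

  attr(assessment, "paths") <- paths
  invisible(assessment)
}

assessment_as_list <- function(x) {
  list(garden_name = x$garden_name,
       garden_richness = x$garden_richness,
       garden_shannon = x$garden_shannon,
       city_richness = x$city_richness,
       city_shannon = x$city_shannon,
       richness_percentile = x$richness_percentile,
       diversity_percentile = x$diversity_percentile,
       threshold = x$threshold,
       is_richness_hotspot = x$is_richness_hotspot,
       is_diversity_hotspot = x$is_diversity_hotspot,
       n_garden_obs = x$n_garden_obs,
       n_city_obs = x$n_city_obs,
       R = x$R, seed = x$seed,
       dims = list(width_lon = x$null$dims$width_lon,
                   height_lat = x$null$dims$height_lat),
       n_centroids = x$null$n_centroids)
}

#' Sweep assessments over seeds and enrichment strengths
#'
#' Repeats the synthetic-scenario assessment over a grid of garden
#' enrichment values `k` and seeds, returning one tidy row per run — the
#' engine behind calibration (k = 0: percentiles should centre on 50) and
#' power (mean percentile should rise monotonically with k) studies.
#'
#' Each run generates a scenario, de-duplicates, splits the garden by the
#' scenario's garden box, and assesses with `R` replicates. Warnings about
#' small gardens are expected in sparse scenarios and suppressed here.
#'
#' @param k Integer vector of enrichment strengths (0 = null scenario).
#' @param seeds Integer vector of scenario seeds; each (k, seed) pair is one
#'   run.
#' @param R Permutation replicates per run.
#' @param threshold Hotspot percentile threshold.
#' @param ... Scenario overrides passed to [scenario()].
#' @return A tibble with one row per run: `k`, `seed`, the [tidy()]
#'   assessment columns.
#' @export
sweep_scenarios <- function(k = 0L, seeds = 1:20, R = 200, threshold = 75, ...) {
  grid <- tidyr::expand_grid(k = as.integer(k), seed = as.integer(seeds))
  rows <- purrr::pmap(grid, function(k, seed) {
    sc <- scenario(garden_enrichment = k, seed = seed, ...)
    occ <- deduplicate(generate_scenario(sc))
    garden <- filter_bbox(occ, sc$garden_box)
    a <- suppressWarnings(
      assess_garden(garden, occ, sc$garden_box, R = R, seed = seed,
                    threshold = threshold)
    )
    dplyr::bind_cols(tibble(k = k, seed = seed), tidy(a))
  })
  dplyr::bind_rows(rows)
}
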
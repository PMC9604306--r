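#' Define a synthetic occurrence scenario
#'
#' Describes a city-scale cloud of species-labelled observations with the
#' statistical structure the hotspot analysis assumes: a log-normal (skewed)
#' species-abundance distribution, spatial clustering of observation effort,
#' a fraction of records double-reported under two platform tags, and a
#' focal "garden" rectangle whose species pool can optionally be enriched.
#'
#' With `garden_enrichment = 0` (the null scenario) garden-interior records
#' are generated by exactly the same process as the background, so the
#' garden is a hotspot only by chance. With `garden_enrichment = k > 0`,
#' `k` garden-exclusive species are added (each observed
#' `obs_per_exclusive` times inside the garden) together with `2 * k` extra
#' garden-interior records of background species, emulating both a richer
#' species pool and the higher observation effort a garden attracts.
#'
#' @param city_box [bbox()] of the city extent.
#' @param garden_box [bbox()] of the garden, strictly inside `city_box`.
#' @param n_species Number of background species (>= 1).
#' @param abundance_sigma Log-normal shape (sdlog) of the species-abundance
#'   distribution; larger is more skewed.
#' @param n_city_obs Number of background observations (>= 1).
#' @param n_clusters Number of observation-effort clusters.
#' @param cluster_sd Cluster spread in degrees.
#' @param cluster_weight Fraction of background observations drawn from
#'   clusters rather than uniformly.
#' @param garden_enrichment Non-negative `k` as described above; 0 = null.
#' @param obs_per_exclusive Observations per garden-exclusive species.
#' @param duplicate_fraction Fraction in \[0, 1) of records emitted a second
#'   time under the other platform tag.
#' @param seed Integer seed; generation is deterministic given the scenario.
#'
#' @return An object of class `gs_scenario` (a validated parameter list).
#' @seealso [null_scenario()], [hotspot_scenario()], [generate_scenario()]
#' @export
scenario <- function(city_box = bbox(-112.30, 33.25, -111.90, 33.55),
                     garden_box = bbox(-112.11, 33.39, -112.09, 33.41),
                     n_species = 60,
                     abundance_sigma = 1.5,
                     n_city_obs = 2000,
                     n_clusters = 5,
                     cluster_sd = 0.02,
                     cluster_weight = 0.5,
                     garden_enrichment = 0,
                     obs_per_exclusive = 3,
                     duplicate_fraction = 0.15,
                     seed = 1L) {
  stopifnot(inherits(city_box, "bbox"), inherits(garden_box, "bbox"))
  if (!(garden_box$min_lon > city_box$min_lon &&
        garden_box$max_lon < city_box$max_lon &&
        garden_box$min_lat > city_box$min_lat &&
        garden_box$max_lat < city_box$max_lat)) {
    abort("garden_box must lie strictly inside city_box.")
  }
  if (n_species < 1 || n_city_obs < 1) {
    abort("n_species and n_city_obs must be >= 1.")
  }
  if (abundance_sigma <= 0) abort("abundance_sigma must be positive.")
  if (garden_enrichment < 0) abort("garden_enrichment must be >= 0.")
  if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
    abort("duplicate_fraction must be in [0, 1).")
  }
  if (n_clusters < 0 || cluster_sd <= 0 ||
      cluster_weight < 0 || cluster_weight > 1) {
    abort("invalid cluster parameters.")
  }
  structure(
    list(city_box = city_box, garden_box = garden_box,
         n_species = as.integer(n_species),
         abundance_sigma = abundance_sigma,
         n_city_obs = as.integer(n_city_obs),
         n_clusters = as.integer(n_clusters),
         cluster_sd = cluster_sd, cluster_weight = cluster_weight,
         garden_enrichment = as.integer(garden_enrichment),
         obs_per_exclusive = as.integer(obs_per_exclusive),
         duplicate_fraction = duplicate_fraction,
         seed = as.integer(seed)),
    class = "gs_scenario"
  )
}

#' @export
print.gs_scenario <- function(x, ...) {
  cat(sprintf("<gs_scenario> %d obs, %d species (sigma %g), %d clusters (sd %g deg), enrichment %d, dup %.2f, seed %d\n",
              x$n_city_obs, x$n_species, x$abundance_sigma, x$n_clusters,
              x$cluster_sd, x$garden_enrichment, x$duplicate_fraction, x$seed))
  invisible(x)
}

#' Preset scenarios for calibration and recovery studies
#'
#' `null_scenario()` is the calibration setting: no garden enrichment, 60
#' background species, 2000 observations, 5 effort clusters — under it the
#' garden percentile should be uniform on \[0, 100\] over seeds.
#' `hotspot_scenario()` is the recovery setting: a sparse background
#' (400 observations) plus `k` garden-exclusive species and inflated garden
#' effort, so the garden's richness exceeds what any same-size city
#' rectangle can reach.
#'
#' @param seed Integer seed.
#' @param k Number of garden-exclusive species (enrichment strength).
#' @param ... Overrides passed on to [scenario()].
#' @return A `gs_scenario`.
#' @export
null_scenario <- function(seed = 1L, ...) {
  scenario(garden_enrichment = 0, seed = seed, ...)
}

#' @rdname null_scenario
#' @export
hotspot_scenario <- function(k = 10L, seed = 1L, ...) {
  scenario(garden_enrichment = k, n_city_obs = 400, seed = seed, ...)
}

# Draw n points from the background effort process: a mixture of uniform
# noise and truncated Gaussian clusters (a simple Thomas-process stand-in),
# with out-of-box cluster draws redrawn so every point lies in city_box.
draw_locations <- function(n, city_box, centers, cluster_sd, cluster_weight) {
  n_clusters <- nrow(centers)
  comp <- if (n_clusters > 0 && cluster_weight > 0) {
    sample.int(n_clusters + 1L, n, replace = TRUE,
               prob = c(1 - cluster_weight,
                        rep(cluster_weight / n_clusters, n_clusters))) - 1L
  } else {
    integer(n)
  }
  lon <- numeric(n)
  lat <- numeric(n)
  unif <- comp == 0L
  lon[unif] <- runif(sum(unif), city_box$min_lon, city_box$max_lon)
  lat[unif] <- runif(sum(unif), city_box$min_lat, city_box$max_lat)
  todo <- which(!unif)
  while (length(todo) > 0) {
    lon[todo] <- rnorm(length(todo), centers$lon[comp[todo]], cluster_sd)
    lat[todo] <- rnorm(length(todo), centers$lat[comp[todo]], cluster_sd)
    ok <- bbox_contains(city_box, lon[todo], lat[todo])
    todo <- todo[!ok]
  }
  list(lon = lon, lat = lat)
}

#' Generate a synthetic occurrence set
#'
#' Realises a [scenario()] as an occurrence tibble in the same shape that
#' [read_occurrences()] produces, deterministic given the scenario's seed.
#' Generation order: species relative abundances are drawn log-normal and
#' normalised; cluster centres are placed uniformly in the city box;
#' background locations come from the uniform/cluster mixture; each record
#' gets an abundance-weighted species, a uniform date in the 2000-01-01 to
#' 2022-06-21 study window, and a platform tag; enrichment records (if any)
#' are appended uniformly inside the garden box; finally a
#' `duplicate_fraction` of all records is re-emitted verbatim under the
#' other platform tag.
#'
#' Ground truth for tests rides on the `"truth"` attribute: the scenario,
#' the drawn abundance vector, the garden-exclusive species names, and the
#' exact number of injected duplicate rows.
#'
#' @param sc A `gs_scenario`.
#' @return An occurrence tibble (`deduplicated = FALSE`) with a `"truth"`
#'   attribute.
#' @export
generate_scenario <- function(sc) {
  stopifnot(inherits(sc, "gs_scenario"))
  withr::with_seed(sc$seed, {
    species_pool <- sprintf("Species_%03d", seq_len(sc$n_species))
    abundance <- rlnorm(sc$n_species, meanlog = 0, sdlog = sc$abundance_sigma)
    p <- abundance / sum(abundance)

    centers <- tibble(
      lon = runif(sc$n_clusters, sc$city_box$min_lon, sc$city_box$max_lon),
      lat = runif(sc$n_clusters, sc$city_box$min_lat, sc$city_box$max_lat)
    )
    loc <- draw_locations(sc$n_city_obs, sc$city_box, centers,
                          sc$cluster_sd, sc$cluster_weight)

    window <- as.integer(as.Date("2022-06-21") - as.Date("2000-01-01"))
    rand_dates <- function(n) {
      as.Date("2000-01-01") + sample.int(window + 1L, n, replace = TRUE) - 1L
    }
    rand_sources <- function(n) {
      sample(c("eButterfly", "iNaturalist"), n, replace = TRUE)
    }

    occ <- tibble(
      species = sample(species_pool, sc$n_city_obs, replace = TRUE, prob = p),
      lon = loc$lon, lat = loc$lat,
      event_date = rand_dates(sc$n_city_obs),
      source = rand_sources(sc$n_city_obs)
    )

    exclusive <- character(0)
    if (sc$garden_enrichment > 0) {
      k <- sc$garden_enrichment
      exclusive <- sprintf("Exclusive_%03d", seq_len(k))
      n_excl <- k * sc$obs_per_exclusive
      n_extra <- 2L * k
      gb <- sc$garden_box
      enrich <- tibble(
        species = c(rep(exclusive, each = sc$obs_per_exclusive),
                    sample(species_pool, n_extra, replace = TRUE, prob = p)),
        lon = runif(n_excl + n_extra, gb$min_lon, gb$max_lon),
        lat = runif(n_excl + n_extra, gb$min_lat, gb$max_lat),
        event_date = rand_dates(n_excl + n_extra),
        source = rand_sources(n_excl + n_extra)
      )
      occ <- dplyr::bind_rows(occ, enrich)
    }

    n_dup <- floor(sc$duplicate_fraction * nrow(occ))
    if (n_dup > 0) {
      dup_rows <- sample.int(nrow(occ), n_dup)
      dups <- occ[dup_rows, , drop = FALSE]
      dups$source <- ifelse(dups$source == "eButterfly",
                            "iNaturalist", "eButterfly")
      occ <- dplyr::bind_rows(occ, dups)
    }

    occ <- occ[, c("species", "lat", "lon", "event_date", "source")]
    attr(occ, "deduplicated") <- FALSE
    attr(occ, "truth") <- list(
      scenario = sc,
      species_pool = species_pool,
      abundance = p,
      exclusive_species = exclusive,
      n_duplicates = as.integer(n_dup)
    )
    occ
  })
}

#' Write a scenario's data and ground truth to disk
#'
#' Writes `<name>_city.csv` (all records, Darwin-Core columns — the exact
#' dialect [read_occurrences()] reads), `<name>_garden.csv` (the
#' garden-interior subset) and `<name>_truth.json` (the scenario parameters
#' and generation bookkeeping).
#'
#' @param sc A `gs_scenario`.
#' @param dir Output directory (created if needed).
#' @param name File-name stem.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_scenario <- function(sc, dir, name = "scenario") {
  stopifnot(inherits(sc, "gs_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  occ <- generate_scenario(sc)
  truth <- attr(occ, "truth")
  city_path <- file.path(dir, paste0(name, "_city.csv"))
  garden_path <- file.path(dir, paste0(name, "_garden.csv"))
  truth_path <- file.path(dir, paste0(name, "_truth.json"))
  write_occurrences(occ, city_path)
  write_occurrences(filter_bbox(occ, sc$garden_box), garden_path)
  gb <- sc$garden_box
  cb <- sc$city_box
  jsonlite::write_json(list(
    city_box = unclass(cb)[c("min_lon", "min_lat", "max_lon", "max_lat")],
    garden_box = unclass(gb)[c("min_lon", "min_lat", "max_lon", "max_lat")],
    n_species = sc$n_species,
    abundance_sigma = sc$abundance_sigma,
    n_city_obs = sc$n_city_obs,
    n_clusters = sc$n_clusters,
    cluster_sd = sc$cluster_sd,
    cluster_weight = sc$cluster_weight,
    garden_enrichment = sc$garden_enrichment,
    obs_per_exclusive = sc$obs_per_exclusive,
    duplicate_fraction = sc$duplicate_fraction,
    seed = sc$seed,
    n_records_written = nrow(occ),
    n_duplicates = truth$n_duplicates,
    exclusive_species = truth$exclusive_species
  ), truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(city = city_path, garden = garden_path, truth = truth_path))
}
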
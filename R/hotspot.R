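#' Assess a garden against its city's permutation null
#'
#' The central question: are the species richness and Shannon diversity
#' observed in a small focal rectangle (a botanical garden) higher than
#' expected for a same-sized piece of the surrounding city? The garden's
#' metrics are located as percentiles within the rectangle-matched
#' permutation null ([sample_null_distribution()]), and the garden is called
#' a hotspot for a metric when its percentile strictly exceeds `threshold`
#' (a-priori default: the 75th percentile).
#'
#' The city set may physically contain the garden's records: exclusion by
#' `garden_box` happens inside the permutation, so callers need not
#' pre-split. Gardens with fewer than `min_garden_obs` records (default 40,
#' the study-inclusion floor for community-science coverage) are still
#' assessed, with a prominent warning that the sample is below the inclusion
#' criterion.
#'
#' @param garden Occurrence tibble of the garden's records; all must lie
#'   inside `garden_box` (validated) and the set should be deduplicated.
#' @param city Occurrence tibble for the city; should be deduplicated.
#' @param garden_box The garden's [bbox()].
#' @param R Number of permutation replicates (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param threshold Hotspot percentile threshold in \[0, 100\] (default 75);
#'   the comparison is strict (`percentile > threshold`).
#' @param min_garden_obs Minimum garden record count before a
#'   below-inclusion warning is raised (default 40).
#' @param base Logarithm base for the Shannon index.
#' @param garden_name Label carried into reports.
#'
#' @return An object of class `hotspot_assessment`: garden metrics, city
#'   pool metrics, both percentiles, hotspot flags, record counts, and the
#'   full `perm_null` under `$null`. Use [tidy()] for a one-row report
#'   table, [glance()] for a run summary, [autoplot()] for the
#'   distribution-vs-observed figure.
#' @export
assess_garden <- function(garden, city, garden_box, R = 1000, seed,
                          threshold = 75, min_garden_obs = 40,
                          base = exp(1), garden_name = "garden") {
  stopifnot(inherits(garden_box, "bbox"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 100) {
    abort("threshold must be a single percentile in [0, 100].")
  }
  if (missing(seed)) abort("seed is required.")
  outside <- !bbox_contains(garden_box, garden$lon, garden$lat)
  if (any(outside)) {
    abort(sprintf("%d garden record(s) lie outside garden_box.", sum(outside)))
  }
  if (nrow(garden) < min_garden_obs) {
    warn(sprintf(
      "garden '%s' has %d observation(s), below the inclusion criterion of %d community-science observations; assessing anyway, interpret with caution.",
      garden_name, nrow(garden), min_garden_obs))
  }

  gm <- diversity_metrics(garden, base = base)
  null <- sample_null_distribution(city, garden_box, R = R, seed = seed,
                                   base = base)
  city_pool <- occ_subset(city, !bbox_contains(garden_box, city$lon, city$lat))
  cm <- diversity_metrics(city_pool, base = base)

  rp <- percentile_of(gm$richness, null, metric = "richness")
  dp <- percentile_of(gm$shannon, null, metric = "shannon")

  structure(
    list(
      garden_name = garden_name,
      garden_richness = gm$richness,
      garden_shannon = gm$shannon,
      city_richness = cm$richness,
      city_shannon = cm$shannon,
      richness_percentile = rp,
      diversity_percentile = dp,
      threshold = threshold,
      is_richness_hotspot = rp > threshold,
      is_diversity_hotspot = dp > threshold,
      n_garden_obs = nrow(garden),
      n_city_obs = nrow(city),
      R = null$R,
      seed = null$seed,
      null = null
    ),
    class = "hotspot_assessment"
  )
}

#' @export
print.hotspot_assessment <- function(x, ...) {
  flag <- function(hot) if (hot) "HOTSPOT" else "not a hotspot"
  cat(sprintf("<hotspot_assessment> '%s' (%d garden obs vs %d city obs; R = %d, seed = %d)\n",
              x$garden_name, x$n_garden_obs, x$n_city_obs, x$R, x$seed))
  cat(sprintf("  richness  %d (city %d): percentile %.1f -> %s at threshold %g\n",
              x$garden_richness, x$city_richness, x$richness_percentile,
              flag(x$is_richness_hotspot), x$threshold))
  cat(sprintf("  diversity %.3f (city %.3f): percentile %.1f -> %s at threshold %g\n",
              x$garden_shannon, x$city_shannon, x$diversity_percentile,
              flag(x$is_diversity_hotspot), x$threshold))
  invisible(x)
}

#' Garden area as a percentage of city area
#'
#' The headline smallness of a garden relative to its city:
#' `100 * garden_area_km2 / city_area_km2`. Vectorised; returns both the
#' exact value and the value rounded to 4 decimal places, the precision used
#' in reporting.
#'
#' @param city_area_km2,garden_area_km2 Positive areas in square kilometres;
#'   each garden must not exceed its city.
#' @return A tibble with columns `city_area_km2`, `garden_area_km2`,
#'   `percent` and `percent_rounded`.
#' @examples
#' area_percentage(1374.354, 0.367) # 0.0267 percent
#' @export
area_percentage <- function(city_area_km2, garden_area_km2) {
  if (!is.numeric(city_area_km2) || !is.numeric(garden_area_km2) ||
      any(!is.finite(city_area_km2)) || any(!is.finite(garden_area_km2)) ||
      any(city_area_km2 <= 0) || any(garden_area_km2 <= 0)) {
    abort("areas must be positive finite numbers.")
  }
  if (any(garden_area_km2 > city_area_km2)) {
    abort("garden area cannot exceed city area.")
  }
  pct <- 100 * garden_area_km2 / city_area_km2
  tibble(city_area_km2 = city_area_km2,
         garden_area_km2 = garden_area_km2,
         percent = pct,
         percent_rounded = round(pct, 4))
}
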
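#' Tidy a permutation null distribution
#'
#' @param x A `perm_null` from [sample_null_distribution()].
#' @param ... Unused.
#' @return The replicate tibble: `replicate`, `richness`, `shannon`.
#' @exportS3Method generics::tidy
tidy.perm_null <- function(x, ...) {
  x$replicates
}

#' One-row summary of a permutation null distribution
#'
#' @param x A `perm_null`.
#' @param ... Unused.
#' @return A one-row tibble with the sampling metadata and replicate
#'   medians.
#' @exportS3Method generics::glance
glance.perm_null <- function(x, ...) {
  tibble(R = x$R, seed = x$seed,
         width_lon = x$dims$width_lon, height_lat = x$dims$height_lat,
         n_centroids = x$n_centroids, n_records = x$n_records,
         n_excluded = x$n_excluded,
         median_richness = median(x$replicates$richness),
         median_shannon = median(x$replicates$shannon))
}

#' Tidy a hotspot assessment into a report row
#'
#' One row in the shape of the study's summary table: garden metrics, city
#' metrics, and the garden's percentile within the permutation null for
#' each metric.
#'
#' @param x A `hotspot_assessment` from [assess_garden()].
#' @param ... Unused.
#' @return A one-row tibble: `garden`, `richness`, `city_richness`,
#'   `richness_percentile`, `shannon`, `city_shannon`,
#'   `diversity_percentile`, `is_richness_hotspot`, `is_diversity_hotspot`.
#' @exportS3Method generics::tidy
tidy.hotspot_assessment <- function(x, ...) {
  tibble(garden = x$garden_name,
         richness = x$garden_richness,
         city_richness = x$city_richness,
         richness_percentile = x$richness_percentile,
         shannon = x$garden_shannon,
         city_shannon = x$city_shannon,
         diversity_percentile = x$diversity_percentile,
         is_richness_hotspot = x$is_richness_hotspot,
         is_diversity_hotspot = x$is_diversity_hotspot)
}

#' One-row run summary of a hotspot assessment
#'
#' @param x A `hotspot_assessment`.
#' @param ... Unused.
#' @return A one-row tibble with record counts, threshold, R and seed.
#' @exportS3Method generics::glance
glance.hotspot_assessment <- function(x, ...) {
  tibble(garden = x$garden_name,
         n_garden_obs = x$n_garden_obs,
         n_city_obs = x$n_city_obs,
         n_centroids = x$null$n_centroids,
         threshold = x$threshold,
         R = x$R, seed = x$seed)
}
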
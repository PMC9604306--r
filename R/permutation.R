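#' Centroid pool for null sampling
#'
#' Large parts of a city contribute no observations at all, so placing null
#' rectangles uniformly over the map would mostly measure observer absence.
#' Instead the pool of candidate rectangle centres is the set of distinct
#' observed coordinates: every unique (lat, lon) pair in the set, in
#' first-appearance order.
#'
#' @param occ An occurrence tibble; should be deduplicated (warning
#'   otherwise). Must be non-empty.
#' @return A tibble with columns `lat` and `lon`, one row per distinct
#'   coordinate pair.
#' @export
candidate_centroids <- function(occ) {
  if (nrow(occ) == 0) abort("cannot build a centroid pool from an empty occurrence set.")
  if (!is_deduplicated(occ)) {
    warn("candidate_centroids: occurrence set is not flagged as deduplicated.")
  }
  distinct(tibble(lat = occ$lat, lon = occ$lon))
}

#' Rectangle-matched permutation null distribution
#'
#' Builds the null distribution that a focal garden is scored against:
#' what richness and Shannon diversity look like in city rectangles of
#' exactly the garden's dimensions, placed where observations exist.
#'
#' The procedure, in order: (1) every record inside `garden_box` (closed
#' bounds) is removed from `city`, so the garden's own observations can
#' never prop up the city samples; (2) the centroid pool is the distinct
#' coordinates of the remaining records; (3) rectangle dimensions are the
#' degree extents of `garden_box`; (4) for each of `R` replicates, one
#' centroid is drawn uniformly with replacement from the pool, a rectangle
#' of the garden's dimensions is centred on it, and the richness and Shannon
#' index of the records inside (closed bounds) form one replicate. The same
#' seed and inputs give an identical distribution.
#'
#' Replicate rectangles are not clipped to any city boundary: the city is
#' operationally its observation set, and records outside the supplied set
#' simply do not exist.
#'
#' @param city Occurrence tibble for the whole city (may include garden
#'   records; they are excluded here). Should be deduplicated (warning
#'   otherwise).
#' @param garden_box The garden's [bbox()].
#' @param R Number of sampling replicates (default 1000).
#' @param seed Integer seed for the replicate draws; required, and recorded
#'   in the result.
#' @param base Logarithm base for the Shannon index.
#'
#' @return An object of class `perm_null`: a list with `replicates` (tibble
#'   of `replicate`, `richness`, `shannon`), `dims`, `n_centroids`,
#'   `n_records` (post-exclusion pool size), `n_excluded`, `R` and `seed`.
#'   Retrieve the replicate tibble with [tidy()], a one-row summary with
#'   [glance()], and a plot with [autoplot()].
#' @export
sample_null_distribution <- function(city, garden_box, R = 1000, seed, base = exp(1)) {
  stopifnot(inherits(garden_box, "bbox"))
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R < 1) {
    abort("R must be a single integer >= 1.")
  }
  R <- as.integer(R)
  if (missing(seed)) abort("seed is required (and is recorded in the result).")
  if (!is_deduplicated(city)) {
    warn("sample_null_distribution: city set is not flagged as deduplicated.")
  }

  inside <- bbox_contains(garden_box, city$lon, city$lat)
  pool <- occ_subset(city, !inside)
  if (nrow(pool) == 0) {
    abort("no city records remain after excluding the garden rectangle; cannot build a null distribution.")
  }
  cents <- candidate_centroids(pool)
  dims <- bbox_dims(garden_box)

  idx <- withr::with_seed(seed, sample.int(nrow(cents), R, replace = TRUE))

  lon <- pool$lon
  lat <- pool$lat
  species <- pool$species
  half_w <- dims$width_lon / 2
  half_h <- dims$height_lat / 2
  richness <- integer(R)
  shannon <- numeric(R)
  for (r in seq_len(R)) {
    clat <- cents$lat[idx[r]]
    clon <- cents$lon[idx[r]]
    inside_r <- lon >= clon - half_w & lon <= clon + half_w &
      lat >= max(clat - half_h, -90) & lat <= min(clat + half_h, 90)
    sp <- species[inside_r]
    richness[r] <- length(unique(sp))
    shannon[r] <- shannon_from_counts(tabulate(factor(sp)), base = base)
  }

  structure(
    list(
      replicates = tibble(replicate = seq_len(R), richness = richness,
                          shannon = shannon),
      dims = dims,
      n_centroids = nrow(cents),
      n_records = nrow(pool),
      n_excluded = sum(inside),
      R = R,
      seed = as.integer(seed)
    ),
    class = "perm_null"
  )
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "<perm_null> %d replicates of a %g x %g deg rectangle over %d centroids (%d records; %d excluded as garden)\n",
    x$R, x$dims$width_lon, x$dims$height_lat, x$n_centroids, x$n_records,
    x$n_excluded))
  cat(sprintf("  richness: median %g, range [%g, %g]\n",
              median(x$replicates$richness), min(x$replicates$richness),
              max(x$replicates$richness)))
  cat(sprintf("  shannon:  median %.3f, range [%.3f, %.3f]\n",
              median(x$replicates$shannon), min(x$replicates$shannon),
              max(x$replicates$shannon)))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Percentile of a value within a replicate distribution
#'
#' Mid-rank convention: `100 * (#\{replicates < value\} + 0.5 *
#' #\{replicates == value\}) / R`. A value above every replicate scores
#' exactly 100, below every replicate exactly 0, and a value equal to all
#' replicates scores 50, so a garden indistinguishable from the city centres
#' the scale.
#'
#' @param value A single number (the garden's metric).
#' @param replicates Non-empty numeric vector of null replicate values, or a
#'   `perm_null` object together with `metric`.
#' @param metric When `replicates` is a `perm_null`: which column to use,
#'   `"richness"` or `"shannon"`.
#' @return A number in \[0, 100\].
#' @export
percentile_of <- function(value, replicates, metric = c("richness", "shannon")) {
  if (inherits(replicates, "perm_null")) {
    metric <- match.arg(metric)
    replicates <- replicates$replicates[[metric]]
  }
  if (length(replicates) == 0) abort("replicates must be non-empty.")
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    abort("value must be a single number.")
  }
  100 * (sum(replicates < value) + 0.5 * sum(replicates == value)) /
    length(replicates)
}

#' Write a permutation null distribution to disk
#'
#' The replicate table goes to `<path>` as CSV (`replicate`, `richness`,
#' `shannon`) and the sampling metadata (R, seed, rectangle dimensions,
#' centroid-pool size, record counts) to `<path>.meta.json`.
#'
#' @param null A `perm_null` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(null, path) {
  stopifnot(inherits(null, "perm_null"))
  readr::write_csv(null$replicates, path, progress = FALSE)
  meta <- list(R = null$R, seed = null$seed,
               width_lon = null$dims$width_lon,
               height_lat = null$dims$height_lat,
               n_centroids = null$n_centroids,
               n_records = null$n_records,
               n_excluded = null$n_excluded)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
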
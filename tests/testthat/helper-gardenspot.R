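# Shared fixture builders and independent oracles.

# Quick occurrence tibble; scalar arguments recycle.
make_occ <- function(species, lat, lon, date = "2010-06-15",
                     source = "synthetic", deduplicated = FALSE) {
  as_occurrences(
    tibble::tibble(species = species, lat = lat, lon = lon,
                   event_date = as.Date(date), source = source),
    deduplicated = deduplicated
  )
}

# Random occurrence cloud on the unit square, for filter/dedup oracles.
random_occ <- function(n, n_species = 10, seed = 1) {
  withr::with_seed(seed, make_occ(
    species = sample(LETTERS[seq_len(n_species)], n, replace = TRUE),
    lat = runif(n), lon = runif(n),
    date = as.Date("2005-01-01") + sample.int(6000, n, replace = TRUE)
  ))
}

# O(n^2) pairwise duplicate scan: count of rows that match an earlier row on
# the dedup key. Deliberately naive and loop-based.
count_duplicates_bruteforce <- function(occ) {
  n_dup <- 0L
  for (i in seq_len(nrow(occ))) {
    for (j in seq_len(i - 1L)) {
      if (occ$lat[i] == occ$lat[j] && occ$lon[i] == occ$lon[j] &&
          occ$event_date[i] == occ$event_date[j] &&
          occ$species[i] == occ$species[j]) {
        n_dup <- n_dup + 1L
        break
      }
    }
  }
  n_dup
}

# Loop-based point-in-rectangle scan (closed bounds).
bbox_scan_bruteforce <- function(box, lon, lat) {
  keep <- logical(length(lon))
  for (i in seq_along(lon)) {
    keep[i] <- lon[i] >= box$min_lon && lon[i] <= box$max_lon &&
      lat[i] >= box$min_lat && lat[i] <= box$max_lat
  }
  keep
}

# Straight-line reimplementation of the null-distribution procedure,
# independent of the package internals but consuming the RNG identically
# (one sample.int call under the seed).
null_distribution_oracle <- function(city, garden_box, R, seed) {
  inside <- city$lon >= garden_box$min_lon & city$lon <= garden_box$max_lon &
    city$lat >= garden_box$min_lat & city$lat <= garden_box$max_lat
  pool <- city[!inside, , drop = FALSE]
  key <- paste(pool$lat, pool$lon)
  cents <- pool[!duplicated(key), c("lat", "lon")]
  w <- garden_box$max_lon - garden_box$min_lon
  h <- garden_box$max_lat - garden_box$min_lat
  idx <- withr::with_seed(seed, sample.int(nrow(cents), R, replace = TRUE))
  out <- data.frame(replicate = seq_len(R), richness = NA_integer_,
                    shannon = NA_real_)
  for (r in seq_len(R)) {
    clat <- cents$lat[idx[r]]
    clon <- cents$lon[idx[r]]
    keep <- pool$lon >= clon - w / 2 & pool$lon <= clon + w / 2 &
      pool$lat >= max(clat - h / 2, -90) & pool$lat <= min(clat + h / 2, 90)
    counts <- as.integer(table(pool$species[keep]))
    out$richness[r] <- length(counts)
    out$shannon[r] <- if (length(counts) == 0) 0 else {
      p <- counts / sum(counts)
      -sum(p * log(p))
    }
  }
  out
}

# Mid-rank percentile via rank() on the combined vector — an independent
# route to the same convention.
percentile_rank_oracle <- function(value, replicates) {
  r <- rank(c(value, replicates), ties.method = "average")[1]
  100 * (r - 1) / length(replicates)
}

# One null-calibration run: generate a null scenario, centre a pseudo-garden
# of the garden's dimensions on a random observed coordinate, and score its
# richness against the permutation null.
null_run_percentile <- function(seed, R = 200) {
  sc <- null_scenario(seed = seed)
  occ <- deduplicate(generate_scenario(sc))
  cents <- candidate_centroids(occ)
  dims <- bbox_dims(sc$garden_box)
  i <- withr::with_seed(seed + 500000L, sample.int(nrow(cents), 1))
  pseudo_garden <- rectangle_at(cents$lat[i], cents$lon[i], dims)
  garden <- filter_bbox(occ, pseudo_garden)
  null <- sample_null_distribution(occ, pseudo_garden, R = R, seed = seed)
  percentile_of(dplyr::n_distinct(garden$species), null, "richness")
}

write_occ_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
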
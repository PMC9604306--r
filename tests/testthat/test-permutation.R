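test_that("candidate_centroids returns distinct coordinates in first-appearance order", {
  occ <- make_occ(c("A", "B", "C"), lat = c(1, 1, 2), lon = c(5, 5, 6),
                  deduplicated = TRUE)
  cents <- candidate_centroids(occ)
  expect_equal(nrow(cents), 2)
  expect_equal(cents$lat, c(1, 2))

  colocated <- make_occ(c("A", "B", "C"), 1, 5, deduplicated = TRUE)
  expect_equal(nrow(candidate_centroids(colocated)), 1)

  empty <- make_occ(character(0), numeric(0), numeric(0),
                    date = as.Date(character(0)), deduplicated = TRUE)
  expect_error(candidate_centroids(empty), "empty")
})

test_that("centroid pool size matches an independent distinct-pair tally", {
  occ <- withr::with_seed(17, make_occ(
    species = "A",
    lat = sample(seq(0, 1, by = 0.1), 2000, replace = TRUE),
    lon = sample(seq(0, 1, by = 0.1), 2000, replace = TRUE),
    deduplicated = TRUE
  ))
  cents <- candidate_centroids(occ)
  expect_equal(nrow(cents),
               length(unique(paste(occ$lat, occ$lon, sep = "|"))))
})

test_that("rectangle_at centres a box of the requested dimensions", {
  box <- rectangle_at(0, 0, rect_dims(2, 2))
  expect_equal(unclass(box)[c("min_lon", "min_lat", "max_lon", "max_lat")],
               list(min_lon = -1, min_lat = -1, max_lon = 1, max_lat = 1))

  withr::with_seed(23, {
    for (i in 1:25) {
      lat <- runif(1, -60, 60); lon <- runif(1, -150, 150)
      dims <- rect_dims(runif(1, 0.01, 2), runif(1, 0.01, 2))
      b <- rectangle_at(lat, lon, dims)
      expect_equal(b$max_lon - b$min_lon, dims$width_lon, tolerance = 1e-12)
      # centroid is the midpoint of the returned box
      expect_equal((b$min_lon + b$max_lon) / 2, lon, tolerance = 1e-9)
      expect_equal((b$min_lat + b$max_lat) / 2, lat, tolerance = 1e-9)
    }
  })
})

test_that("rectangle_at clamps latitude and rejects antimeridian crossings", {
  b <- rectangle_at(89.9, 0, rect_dims(1, 1))
  expect_equal(b$max_lat, 90)
  expect_error(rectangle_at(0, 179.9, rect_dims(1, 1)), "antimeridian")
})

test_that("a single-record city yields a degenerate null of richness 1, shannon 0", {
  city <- make_occ("A", lat = 10, lon = 10, deduplicated = TRUE)
  garden_box <- bbox(0, 0, 1, 1)
  null <- sample_null_distribution(city, garden_box, R = 25, seed = 4)
  expect_equal(null$replicates$richness, rep(1L, 25))
  expect_equal(null$replicates$shannon, rep(0, 25))
  expect_equal(null$n_centroids, 1)
})

test_that("a garden box covering every record is a fatal exclusion degeneracy", {
  city <- deduplicate(random_occ(50, seed = 9))
  expect_error(sample_null_distribution(city, bbox(-2, -2, 3, 3), R = 10, seed = 1),
               "no city records remain")
  expect_error(sample_null_distribution(city, bbox(0, 0, 1, 1), R = 0, seed = 1),
               "R must be")
})

test_that("the null distribution is bit-identical for identical inputs and seed", {
  city <- deduplicate(random_occ(300, seed = 14))
  garden_box <- bbox(0.4, 0.4, 0.6, 0.6)
  a <- sample_null_distribution(city, garden_box, R = 100, seed = 77)
  b <- sample_null_distribution(city, garden_box, R = 100, seed = 77)
  expect_identical(a, b)
  c_ <- sample_null_distribution(city, garden_box, R = 100, seed = 78)
  expect_false(identical(a$replicates, c_$replicates))
})

test_that("sample_null_distribution matches a straight-line reimplementation", {
  # small city: 20 records over 5 distinct locations, some inside the garden
  withr::with_seed(55, {
    locs <- tibble::tibble(lat = runif(5), lon = runif(5))
    pick <- sample.int(5, 20, replace = TRUE)
    city <- make_occ(
      species = sample(c("A", "B", "C", "D"), 20, replace = TRUE),
      lat = locs$lat[pick], lon = locs$lon[pick], deduplicated = TRUE
    )
  })
  garden_box <- bbox(0.45, 0.45, 0.75, 0.75)
  null <- sample_null_distribution(city, garden_box, R = 200, seed = 31)
  oracle <- null_distribution_oracle(city, garden_box, R = 200, seed = 31)
  expect_equal(null$replicates$richness, oracle$richness)
  expect_equal(null$replicates$shannon, oracle$shannon, tolerance = 1e-12)

  # and on a larger generated city
  occ <- deduplicate(generate_scenario(null_scenario(seed = 6, n_city_obs = 500)))
  sc_box <- bbox(-112.13, 33.38, -112.07, 33.43)
  null2 <- sample_null_distribution(occ, sc_box, R = 50, seed = 8)
  oracle2 <- null_distribution_oracle(occ, sc_box, R = 50, seed = 8)
  expect_equal(null2$replicates$richness, oracle2$richness)
  expect_equal(null2$replicates$shannon, oracle2$shannon, tolerance = 1e-12)
})

test_that("replicate metrics never exceed the post-exclusion city bounds", {
  occ <- deduplicate(generate_scenario(null_scenario(seed = 12, n_city_obs = 800)))
  garden_box <- bbox(-112.11, 33.39, -112.09, 33.41)
  null <- sample_null_distribution(occ, garden_box, R = 150, seed = 3)
  pool_richness <- dplyr::n_distinct(occ$species) # superset of post-exclusion pool
  expect_true(all(null$replicates$richness <= pool_richness))
  expect_true(all(null$replicates$shannon <=
                    log(pmax(null$replicates$richness, 1)) + 1e-9))
  expect_equal(nrow(null$replicates), null$R)
})

test_that("percentile_of follows the mid-rank convention at the extremes and ties", {
  expect_equal(percentile_of(10, c(1, 2, 3)), 100)
  expect_equal(percentile_of(0, c(1, 2, 3)), 0)
  expect_equal(percentile_of(5, rep(5, 400)), 50)
  expect_error(percentile_of(1, numeric(0)), "non-empty")
})

test_that("percentile_of matches a rank-based oracle and is monotone in value", {
  withr::with_seed(19, {
    reps <- sample.int(30, 999, replace = TRUE)  # heavy ties, like richness
    for (v in c(-1, 0, 7, 7.5, 15, 31, sample.int(30, 5))) {
      expect_equal(percentile_of(v, reps), percentile_rank_oracle(v, reps))
    }
    vals <- sort(runif(50, -5, 35))
    p <- vapply(vals, percentile_of, numeric(1), replicates = reps)
    expect_true(all(diff(p) >= 0))
  })
})

test_that("percentile_of reads metrics straight off a perm_null object", {
  city <- deduplicate(random_occ(200, seed = 25))
  null <- sample_null_distribution(city, bbox(0.4, 0.4, 0.6, 0.6), R = 60, seed = 2)
  expect_equal(percentile_of(1e6, null, "richness"), 100)
  expect_equal(percentile_of(3, null, "richness"),
               percentile_of(3, null$replicates$richness))
})

test_that("null distributions serialise to CSV with a JSON metadata sidecar", {
  city <- deduplicate(random_occ(100, seed = 33))
  null <- sample_null_distribution(city, bbox(0.4, 0.4, 0.6, 0.6), R = 20, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_null_distribution(null, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 20)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  expect_equal(meta$R, 20)
  expect_equal(meta$seed, 5)
  expect_equal(meta$n_centroids, null$n_centroids)
})
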
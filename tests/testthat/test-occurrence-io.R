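test_that("read_occurrences parses a Darwin-Core CSV and keeps valid rows", {
  path <- write_occ_csv(c(
    "scientificName,decimalLatitude,decimalLongitude,eventDate,datasetName",
    "Danaus plexippus,33.46,-112.07,2015-08-01,iNaturalist",
    "Vanessa cardui,33.40,-112.10,2010-04-12,eButterfly",
    "Pieris rapae,33.50,-112.00,2021-06-21,iNaturalist"
  ))
  occ <- read_occurrences(path)
  expect_equal(nrow(occ), 3)
  expect_s3_class(occ$event_date, "Date")
  expect_false(is_deduplicated(occ))
  expect_equal(validation_report(occ)$n_dropped, 0)
  expect_equal(occ$species[1], "Danaus plexippus")
  expect_equal(occ$source[2], "eButterfly")
})

test_that("rows violating coordinate/species/date invariants are dropped and reported", {
  path <- write_occ_csv(c(
    "scientificName,decimalLatitude,decimalLongitude,eventDate",
    "Danaus plexippus,95,-112.07,2015-08-01",       # lat out of range
    "  ,33.40,-112.10,2010-04-12",                  # empty species
    "Pieris rapae,33.50,-112.00,2021",              # year-only date
    "Vanessa cardui,33.41,-112.09,2012-03-03"
  ))
  expect_warning(occ <- read_occurrences(path), "dropped 3 of 4")
  expect_equal(nrow(occ), 1)
  rep <- validation_report(occ)
  expect_equal(rep$n_dropped, 3)
  expect_equal(rep$dropped_bad_coordinates, 1)
  expect_equal(rep$dropped_empty_species, 1)
  expect_equal(rep$dropped_unparseable_date, 1)
})

test_that("a missing required column is a fatal configuration error", {
  path <- write_occ_csv(c(
    "species,decimalLatitude,decimalLongitude,eventDate",
    "A,1,1,2010-01-01"
  ))
  expect_error(read_occurrences(path), "scientificName")
  # but a remapped column name works
  occ <- read_occurrences(path, columns = dwc_columns(species = "species"))
  expect_equal(occ$species, "A")
})

test_that("write/read round-trip preserves every field", {
  occ <- random_occ(200, seed = 11)
  path <- tempfile(fileext = ".csv")
  write_occurrences(occ, path)
  back <- read_occurrences(path)
  expect_equal(back$species, occ$species)
  expect_equal(back$lat, occ$lat)
  expect_equal(back$lon, occ$lon)
  expect_equal(back$event_date, occ$event_date)
  expect_equal(back$source, occ$source)
})

test_that("deduplicate keys on (lat, lon, date, species) and keeps first in order", {
  occ <- make_occ(c("A", "A", "B"), lat = c(1, 1, 1), lon = c(2, 2, 2),
                  date = "2010-01-01", source = c("e", "i", "e"))
  out <- deduplicate(occ)
  expect_equal(nrow(out), 2)
  expect_true(is_deduplicated(out))
  expect_equal(out$source, c("e", "e"))  # first record retained

  # same species and coordinates but different dates: distinct observations
  two_dates <- make_occ("A", 1, 2, date = c("2010-01-01", "2010-01-02"))
  expect_equal(nrow(deduplicate(two_dates)), 2)
})

test_that("deduplicate agrees with an all-pairs duplicate scan on injected duplicates", {
  withr::with_seed(42, {
    base <- random_occ(380, n_species = 8, seed = 99)
    dup_rows <- sample.int(nrow(base), 120, replace = TRUE)
  })
  occ <- as_occurrences(rbind(base, base[dup_rows, ]))
  n_dup <- count_duplicates_bruteforce(occ)
  expect_gte(n_dup, 120)  # resampled rows can collide with each other too
  out <- deduplicate(occ)
  expect_equal(nrow(out), nrow(occ) - n_dup)
  # idempotence
  expect_equal(nrow(deduplicate(out)), nrow(out))
})

test_that("optional coordinate rounding merges near-duplicate coordinates", {
  occ <- make_occ("A", lat = c(1.00001, 1.00002), lon = 2, date = "2010-01-01")
  expect_equal(nrow(deduplicate(occ)), 2)
  expect_equal(nrow(deduplicate(occ, round_coords = 3)), 1)
})

test_that("filter_bbox uses closed bounds and matches a linear-scan oracle", {
  box <- bbox(0, 0, 1, 1)
  edge <- make_occ("A", lat = 0.5, lon = 1)  # exactly on max_lon
  expect_equal(nrow(filter_bbox(edge, box)), 1)
  expect_equal(nrow(filter_bbox(edge[0, ], box)), 0)

  occ <- withr::with_seed(7, make_occ("A", lat = runif(1000, -1, 2),
                                      lon = runif(1000, -1, 2)))
  got <- filter_bbox(occ, box)
  keep <- bbox_scan_bruteforce(box, occ$lon, occ$lat)
  expect_equal(nrow(got), sum(keep))
  expect_equal(got$lat, occ$lat[keep])
})

test_that("filter_date_range is inclusive at both ends of the study window", {
  occ <- make_occ("A", 1, 1, date = c("1999-12-31", "2000-01-01",
                                      "2022-06-21", "2022-06-22"))
  out <- filter_date_range(occ)
  expect_equal(format(out$event_date), c("2000-01-01", "2022-06-21"))
  expect_error(filter_date_range(occ, "2020-01-01", "2010-01-01"), "after")

  mixed <- random_occ(500, seed = 3)
  start <- as.Date("2008-01-01"); end <- as.Date("2015-12-31")
  expect_equal(nrow(filter_date_range(mixed, start, end)),
               sum(mixed$event_date >= start & mixed$event_date <= end))
})

test_that("filters commute, never grow the set, and preserve the dedup flag", {
  occ <- deduplicate(random_occ(400, seed = 5))
  box <- bbox(0.2, 0.2, 0.8, 0.8)
  start <- as.Date("2010-01-01"); end <- as.Date("2018-12-31")
  a <- filter_date_range(filter_bbox(occ, box), start, end)
  b <- filter_bbox(filter_date_range(occ, start, end), box)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_lte(nrow(a), nrow(occ))
  expect_true(is_deduplicated(a))
})

test_that("filter_grade keeps requested grades and passes through ungraded sets", {
  occ <- random_occ(10, seed = 2)
  expect_equal(nrow(filter_grade(occ)), 10)  # no grade column
  occ$grade <- rep(c("research", "casual"), 5)
  expect_equal(nrow(filter_grade(occ, "research")), 5)
})
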
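# Readers, writers, config, domain-type validation

test_that("event CSV round-trips exactly and handles the empty case", {
  ev <- ema_events(
    participant_id = c("p1", "p1", "p1"),
    timestamp_utc = c("2016-10-01T08:00:00Z", "2016-10-01T12:30:45Z",
                      "2016-10-02T23:59:59Z"),
    x = c(100.5, -2000, 0), y = c(-50.25, 1e5, 0),
    kind = c("smoking", "nonsmoking", "smoking")
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(as.data.frame(back), as.data.frame(ev))

  # header-only file: empty collection, no error
  writeLines("participant_id,timestamp_utc,x,y,kind", f)
  empty <- read_events(f)
  expect_s3_class(empty, "ema_events")
  expect_equal(nrow(empty), 0L)
})

test_that("malformed event rows are reported with row numbers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,timestamp_utc,x,y,kind",
    "p1,2016-10-01T08:00:00Z,1,2,smoking",
    "p1,2016-10-01T09:00:00Z,1,2,cigarette",
    "p1,not-a-time,1,2,smoking",
    "p1,2016-10-01T10:00:00Z,oops,2,nonsmoking"
  ), f)
  err <- expect_error(read_events(f))
  expect_match(conditionMessage(err), "cigarette")
  expect_match(conditionMessage(err), "row\\(s\\) 2")   # bad kind
  expect_match(conditionMessage(err), "row\\(s\\) 3")   # bad timestamp
  expect_match(conditionMessage(err), "row\\(s\\) 4")   # bad coordinate

  writeLines(c("participant_id,timestamp_utc,x,y", "p1,t,1,2"), f)
  expect_error(read_events(f), "missing column.*kind")
})

test_that("partition GeoJSON round-trips through read_partition", {
  zones <- list(a = square_ring(0, 0, 1), b = square_ring(1, 0, 1))
  part <- zone_partition("custom", zones)
  expect_equal(n_zones <- length(part$zone_ids), 2L)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_partition(part, f)
  back <- read_partition(f)
  expect_equal(back$partition_kind, "custom")
  expect_equal(back$zone_ids, part$zone_ids)
  expect_equal(back$polygons, part$polygons)
})

test_that("partition validation rejects duplicates, overlaps, bad geometry", {
  expect_error(
    zone_partition("custom", stats::setNames(
      list(square_ring(0, 0, 1), square_ring(5, 5, 1)), c("z1", "z1"))),
    "duplicate zone_id: z1")

  # two unit squares overlapping by half: error reports the overlap area
  err <- expect_error(zone_partition("custom", list(
    z1 = square_ring(0, 0, 1), z2 = square_ring(0.5, 0, 1))))
  expect_match(conditionMessage(err), "overlap")
  expect_match(conditionMessage(err), "0\\.5")

  # adjacent squares sharing an edge are fine
  expect_silent(zone_partition("custom", list(
    z1 = square_ring(0, 0, 1), z2 = square_ring(1, 0, 1))))

  # self-intersecting bow-tie is invalid
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(zone_partition("custom", list(z1 = bowtie)), "invalid")

  # non-polygon geometry in a file
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature", properties = list(zone_id = "z1"),
      geometry = list(type = "Point", coordinates = c(0, 0))
    ))
  ), f, auto_unbox = TRUE)
  expect_error(read_partition(f), "not a Polygon")
})

test_that("read_partition accepts every generator-produced partition", {
  extent <- c(xmin = 0, ymin = 0, xmax = 4000, ymax = 3000)
  parts <- list(
    make_fishnet(extent, 1000),
    make_pseudo_blocks(extent, n_seeds = 12, rng_seed = 42,
                       sliver_fraction = 0.25)
  )
  for (p in parts) {
    f <- withr::local_tempfile(fileext = ".geojson")
    write_partition(p, f)
    back <- read_partition(f)
    expect_equal(back$zone_ids, p$zone_ids)
    expect_equal(back$polygons, p$polygons, tolerance = 1e-12)
  }
})

test_that("Esri ASCII rasters round-trip", {
  vals <- matrix(runif(12), nrow = 3)
  r <- density_raster(-300, 150, 150, vals)
  f <- withr::local_tempfile(fileext = ".asc")
  write_asc(r, f)
  back <- read_asc(f)
  expect_equal(back$values, r$values, tolerance = 1e-12)
  expect_equal(back$x_origin, r$x_origin)
  expect_equal(back$cell_size, r$cell_size)
  # header is the standard 6-line block
  expect_match(readLines(f)[1], "^ncols 4$")
})

test_that("configuration validates, round-trips, and rejects unknowns", {
  cfg <- geofence_config()
  expect_equal(cfg$bandwidth_ft, 1320)
  expect_equal(cfg$cell_size_ft, 150)
  expect_equal(cfg$threshold, 0.3)
  expect_equal(cfg$buffer_m, 100)
  expect_equal(cfg$dedup_window_min, 5)
  expect_equal(cfg$normalization_decimals, 6L)

  f <- withr::local_tempfile(fileext = ".json")
  write_config(geofence_config(threshold = 0.5, utc_offset_hours = -7), f)
  back <- read_config(f)
  expect_equal(back$threshold, 0.5)
  expect_equal(back$utc_offset_hours, -7)

  expect_error(geofence_config(threshold = 1.5))
  writeLines('{"bandwidht_ft": 100}', f)
  expect_error(read_config(f), "unknown configuration field")
})
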
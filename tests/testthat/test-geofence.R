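# Zone selection and buffered geofence construction

mk_risk <- function(norms) {
  structure(data.frame(zone_id = names(norms), norm_mean_kde = unname(norms),
                       tercile = NA_character_, stringsAsFactors = FALSE),
            class = c("zone_risk", "data.frame"))
}

test_that("zone selection requires both risk and an event in the bin", {
  part <- zone_partition("custom", list(
    z1 = square_ring(0, 0, 1000),
    z2 = square_ring(1000, 0, 1000),
    z3 = square_ring(2000, 0, 1000)
  ))
  risk <- mk_risk(c(z1 = 0.9, z2 = 0.5, z3 = 0.2))

  # no events in the bin: empty selection
  expect_equal(select_zones(risk, part, mk_spatial_events(numeric(0),
                                                          numeric(0)), 0.3),
               character(0))
  # events present but norm below threshold: not selected
  risk2 <- mk_risk(c(z1 = 0.29, z2 = 0.5, z3 = 0.2))
  ev5 <- mk_spatial_events(rep(500, 5), seq(100, 900, length.out = 5))
  expect_equal(select_zones(risk2, part, ev5, 0.3), character(0))
  # joint condition: events in z1 and z3, only z1 passes the norm test
  ev <- mk_spatial_events(c(500, 2500), c(500, 500))
  expect_equal(select_zones(risk, part, ev, 0.3), "z1")
  # inclusive threshold
  expect_equal(select_zones(risk, part, ev, 0.5), "z1")
  expect_setequal(select_zones(risk, part,
                               mk_spatial_events(c(500, 1500), c(500, 500)),
                               0.5), c("z1", "z2"))
})

test_that("a single square zone buffers to the closed-form rounded square", {
  part <- zone_partition("custom", list(z1 = square_ring(0, 0, 1000)))
  fences <- build_geofences(list(`0` = "z1"), part, buffer_m = 100)
  r <- 100 * 3.28083333
  expected <- 1000^2 + 4 * 1000 * r + pi * r^2
  got <- fences$bins[["0"]]$area_ft2
  expect_equal(got, expected, tolerance = 0.005)
  expect_length(fences$bins[["0"]]$multipolygon, 1L)

  # empty selection gives an empty geofence
  f0 <- build_geofences(list(`0` = character(0)), part, 100)
  expect_equal(f0$bins[["0"]]$area_ft2, 0)
  expect_length(f0$bins[["0"]]$multipolygon, 0L)
})

test_that("adjacent zones merge into a single geofence polygon", {
  part <- zone_partition("custom", list(
    a = square_ring(0, 0, 1000), b = square_ring(1000, 0, 1000)))
  fences <- build_geofences(list(`0` = c("a", "b")), part, 100)
  expect_length(fences$bins[["0"]]$multipolygon, 1L)
  r <- 100 * 3.28083333
  expected <- 2000 * 1000 + 2 * (2000 + 1000) * r + pi * r^2
  expect_equal(fences$bins[["0"]]$area_ft2, expected, tolerance = 0.005)

  # two distant zones stay distinct polygons; zones whose buffers overlap
  # dissolve into one
  part2 <- zone_partition("custom", list(
    a = square_ring(0, 0, 1000), b = square_ring(5000, 0, 1000)))
  f2 <- build_geofences(list(`0` = c("a", "b")), part2, 100)
  expect_length(f2$bins[["0"]]$multipolygon, 2L)
  part3 <- zone_partition("custom", list(
    a = square_ring(0, 0, 1000), b = square_ring(1500, 0, 1000)))
  f3 <- build_geofences(list(`0` = c("a", "b")), part3, 100)  # gap 500 < 2r
  expect_length(f3$bins[["0"]]$multipolygon, 1L)
})

test_that("every contributing zone lies inside its geofence", {
  extent <- c(xmin = 0, ymin = 0, xmax = 6000, ymax = 6000)
  part <- make_pseudo_blocks(extent, n_seeds = 10, rng_seed = 17)
  ids <- part$zone_ids[c(2, 5, 7)]
  fences <- build_geofences(list(`0` = ids), part, 100)
  mp <- fences$bins[["0"]]$multipolygon
  for (id in ids) {
    ring <- part$polygons[[match(id, part$zone_ids)]][[1]]
    inside <- smokefence:::points_in_multipolygon(ring[, 1], ring[, 2], mp)
    expect_true(all(inside))
    # zone vertices sit strictly interior to the buffered outline
    d <- smokefence:::dist_points_polygons(ring[, 1], ring[, 2], mp)
    expect_true(all(d == 0))
  }
})

test_that("geofence construction is deterministic and threshold-monotone", {
  part <- make_fishnet(c(xmin = 0, ymin = 0, xmax = 4000, ymax = 4000), 1000)
  set.seed(41)
  ev <- mk_spatial_events(runif(40, 500, 3500), runif(40, 500, 3500))
  risk <- mk_risk(stats::setNames(round(runif(length(part$zone_ids)), 6),
                                  part$zone_ids))
  f1 <- build_geofences(list(`0` = select_zones(risk, part, ev, 0.3)),
                        part, 100)
  f2 <- build_geofences(list(`0` = select_zones(risk, part, ev, 0.3)),
                        part, 100)
  expect_identical(f1$bins, f2$bins)   # vertex-identical

  prev_area <- Inf
  prev_captured <- NULL
  for (t in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    sel <- select_zones(risk, part, ev, t)
    f <- build_geofences(list(`0` = sel), part, 100)
    expect_lte(f$bins[["0"]]$area_ft2, prev_area + 1e-6)
    prev_area <- f$bins[["0"]]$area_ft2
    cap <- which(points_in_geofence(f, part, ev$x, ev$y, 0))
    if (!is.null(prev_captured)) expect_true(all(cap %in% prev_captured))
    prev_captured <- cap
  }
})

test_that("geofence GeoJSON carries bin, partition and threshold properties", {
  part <- zone_partition("custom", list(z1 = square_ring(0, 0, 1000)))
  fences <- build_geofences(list(`0` = "z1", `1` = character(0)), part, 100,
                            participant_id = "p1", threshold = 0.3)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_geofences(fences, f)
  gj <- jsonlite::read_json(f)
  expect_equal(length(gj$features), 1L)
  props <- gj$features[[1]]$properties
  expect_equal(props$bin_index, 0L)
  expect_equal(props$threshold, 0.3)
  expect_equal(props$zone_ids, "z1")
})
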
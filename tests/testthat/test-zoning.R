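# Fishnets, pseudo-blocks, zonal statistics, normalization, terciles

test_that("fishnet tiles the extent with square interior-disjoint cells", {
  p <- make_fishnet(c(xmin = 0, ymin = 0, xmax = 1000, ymax = 1000), 500)
  expect_equal(length(p$zone_ids), 4L)
  areas <- vapply(p$polygons, function(z) {
    abs(sum(z[[1]][, 1] * c(z[[1]][-1, 2], z[[1]][1, 2]) -
              c(z[[1]][-1, 1], z[[1]][1, 1]) * z[[1]][, 2]) / 2)
  }, numeric(1))
  expect_equal(sum(areas), 1e6)
  expect_equal(p$partition_kind, "fishnet_500")

  # 1200 x 700 at side 500: 3 x 2 = 6 cells covering a 1500 x 1000 superset
  p2 <- make_fishnet(c(xmin = 0, ymin = 0, xmax = 1200, ymax = 700), 500)
  expect_equal(length(p2$zone_ids), 6L)
  expect_equal(sum(vapply(p2$polygons, function(z) 500^2, numeric(1))), 15e5)

  # construction disjointness survives the full overlap check
  expect_silent(zone_partition("custom", stats::setNames(
    lapply(p2$polygons, `[[`, 1), p2$zone_ids)))
})

test_that("pseudo-blocks are deterministic, conservative, and can sliver", {
  extent <- c(xmin = 0, ymin = 0, xmax = 5000, ymax = 5000)
  a <- make_pseudo_blocks(extent, n_seeds = 8, rng_seed = 99)
  b <- make_pseudo_blocks(extent, n_seeds = 8, rng_seed = 99)
  expect_identical(a, b)

  # tessellation conserves the extent area
  areas <- vapply(a$polygons, function(z) {
    ring <- z[[1]]
    abs(sum(ring[, 1] * c(ring[-1, 2], ring[1, 2]) -
              c(ring[-1, 1], ring[1, 1]) * ring[, 2]) / 2)
  }, numeric(1))
  expect_equal(sum(areas), 25e6, tolerance = 1e-9)

  # slivered partition still conserves area and contains a narrow zone
  s <- make_pseudo_blocks(extent, n_seeds = 20, rng_seed = 7,
                          sliver_fraction = 0.2, corridor_width_ft = 20)
  areas_s <- vapply(s$polygons, function(z) {
    ring <- z[[1]]
    abs(sum(ring[, 1] * c(ring[-1, 2], ring[1, 2]) -
              c(ring[-1, 1], ring[1, 1]) * ring[, 2]) / 2)
  }, numeric(1))
  expect_equal(sum(areas_s), 25e6, tolerance = 1e-9)
  widths <- vapply(s$polygons, smokefence:::polygon_min_width, numeric(1))
  expect_true(any(widths < 150))
})

test_that("zonal means average cell centers with half-open edge handling", {
  # constant raster: every zone with a center gets the constant
  vals <- matrix(2.5, nrow = 4, ncol = 4)
  r <- density_raster(0, 0, 100, vals)
  p <- make_fishnet(c(xmin = 0, ymin = 0, xmax = 400, ymax = 400), 200)
  m <- zonal_mean(r, p)
  expect_equal(unname(m[!is.na(m)]), rep(2.5, 4))
  expect_equal(attr(m, "n_missing"), 0L)

  # 2x2 raster {1,2; 3,4}: zone covering the left column's centers -> 2.0
  r2 <- density_raster(0, 0, 100, matrix(c(1, 3, 2, 4), nrow = 2))
  # values[1,] = c(1,2) south row: centers (50,50)=1,(150,50)=2,(50,150)=3...
  left <- zone_partition("custom", list(
    L = rbind(c(0, 0), c(100, 0), c(100, 200), c(0, 200)),
    R = rbind(c(100, 0), c(200, 0), c(200, 200), c(100, 200))
  ))
  m2 <- zonal_mean(r2, left)
  expect_equal(unname(m2["L"]), mean(c(1, 3)))
  expect_equal(unname(m2["R"]), mean(c(2, 4)))

  # a center on the shared edge belongs to the up-and-right zone
  p3 <- zone_partition("custom", list(
    W = rbind(c(0, 0), c(50, 0), c(50, 200), c(0, 200)),
    E = rbind(c(50, 0), c(200, 0), c(200, 200), c(50, 200))
  ))
  m3 <- zonal_mean(r2, p3)
  expect_true(is.na(m3["W"]))        # centers at x=50 go east
  expect_equal(unname(m3["E"]), 2.5)

  # sliver narrower than the cell spacing between centers -> missing
  sliver <- zone_partition("custom", list(
    A = rbind(c(0, 0), c(140, 0), c(140, 200), c(0, 200)),
    S = rbind(c(140, 0), c(148, 0), c(148, 200), c(140, 200)),
    B = rbind(c(148, 0), c(200, 0), c(200, 200), c(148, 200))
  ))
  m4 <- suppressMessages(zonal_mean(r2, sliver))
  expect_true(is.na(m4["S"]))
  expect_equal(attr(m4, "n_missing"), 1L)
})

test_that("convex zones wider than two cells never go missing", {
  set.seed(31)
  r <- density_raster(0, 0, 100, matrix(runif(400), 20, 20))
  p <- make_pseudo_blocks(c(xmin = 200, ymin = 200, xmax = 1800, ymax = 1800),
                          n_seeds = 5, rng_seed = 5)
  big <- vapply(p$polygons, smokefence:::polygon_min_width, numeric(1)) >= 200
  m <- suppressMessages(zonal_mean(r, p))
  expect_true(all(!is.na(m[big])))
})

test_that("min-max normalization maps to [0,1] with the stated conventions", {
  expect_equal(unname(normalize_minmax(c(a = 0, b = 5, c = 10), 6)),
               c(0, 0.5, 1))
  expect_equal(unname(normalize_minmax(c(a = 3, b = 3), 6)), c(1, 1))
  m <- normalize_minmax(c(a = 0, b = NA, c = 2), 6)
  expect_true(is.na(m["b"]))
  expect_error(normalize_minmax(c(a = NA_real_), 6), "missing")

  # 6-decimal rounding: a raw norm of 0.9999984 is stored as 0.999998,
  # below an inclusive threshold of 1.0
  n <- normalize_minmax(c(lo = 0, near = 9999984, top = 1e7), 6)
  expect_equal(unname(n["near"]), 0.999998)
  expect_equal(unname(n["top"]), 1)
  risk <- classify_terciles(n, threshold = 1.0)
  expect_equal(risk$tercile[risk$zone_id == "near"], "not_retained")

  # invariant to positive rescaling of the underlying density
  set.seed(32)
  means <- runif(10)
  expect_equal(normalize_minmax(means * 7.3, 6), normalize_minmax(means, 6))
})

test_that("tercile classification splits retained zones by rank", {
  n <- c(z1 = 0.3, z2 = 0.4, z3 = 0.5, z4 = 0.6, z5 = 0.8, z6 = 1.0)
  r <- classify_terciles(n, 0.3)
  expect_equal(r$tercile, c("low", "low", "medium", "medium", "high", "high"))

  # nothing retained: empty classes, no error
  r0 <- classify_terciles(c(a = 0.1, b = 0.2), 0.5)
  expect_equal(r0$tercile, c("not_retained", "not_retained"))

  # remainder sizes match the enumeration oracle for n = 1..12
  for (n_ret in 1:12) {
    v <- stats::setNames(seq(0.4, 0.9, length.out = n_ret),
                         paste0("z", seq_len(n_ret)))
    r <- classify_terciles(v, 0.3)
    sizes <- as.integer(table(factor(r$tercile,
                                     levels = c("low", "medium", "high"))))
    expect_equal(sizes, tercile_sizes_oracle(n_ret))
  }

  # ties spanning a boundary all take the lower tercile
  v <- c(a = 0.4, b = 0.5, c = 0.5, d = 0.5, e = 0.9, f = 1.0)
  r <- classify_terciles(v, 0.3)
  expect_equal(r$tercile[r$zone_id %in% c("b", "c", "d")],
               rep("low", 3))

  # threshold is inclusive; below-threshold zones are not retained, and a
  # lone retained zone falls in the low group (remainders go to the lower
  # groups: sizes 1/0/0)
  r <- classify_terciles(c(a = 0.29, b = 0.3), 0.3)
  expect_equal(r$tercile, c("not_retained", "low"))

  # missing stays missing
  r <- classify_terciles(c(a = NA, b = 0.5), 0.3)
  expect_equal(r$tercile, c("missing", "low"))
})

test_that("retention is monotone in the threshold", {
  set.seed(33)
  norms <- stats::setNames(round(runif(30), 6), paste0("z", 1:30))
  prev <- NULL
  for (t in seq(0.1, 0.9, by = 0.1)) {
    kept <- classify_terciles(norms, t)
    kept <- kept$zone_id[kept$tercile %in% c("low", "medium", "high")]
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})
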
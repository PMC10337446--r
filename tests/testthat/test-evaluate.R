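# Capture rates, threshold sweep, partition comparison

# a small fitted scenario reused across blocks
eval_fixture <- function(seed = 51) {
  set.seed(seed)
  extent <- c(xmin = 0, ymin = 0, xmax = 6000, ymax = 6000)
  part <- make_fishnet(extent, 1000)
  prof <- participant_profile(
    "p1",
    anchors = list(list(x = 2500, y = 2500, scatter_sd = 300,
                        weights = rep(1, 8))),
    smoking_events_per_day = 1.2, nonsmoking_surveys_per_day = 0.5,
    dispersion = 0.1, extent = extent, rng_seed = seed
  )
  ev <- gen_participant(prof)
  fit <- suppressMessages(fit_geofences(ev, part))
  list(part = part, fit = fit)
}

test_that("capture percentages follow the point-in-polygon counts", {
  # constructed square fence: 4 events in the bin, 3 inside -> 75.0%
  part <- zone_partition("custom", list(z1 = square_ring(0, 0, 1000)))
  fences <- build_geofences(list(`2` = "z1"), part, 100,
                            participant_id = "p1", threshold = 0.3)
  r_ft <- 100 * 3.28083333
  # bin 2 local = 06:00-08:59 PST -> 14:00z at offset -8
  t0 <- as.POSIXct("2016-10-01 14:30:00", tz = "UTC")
  ev <- ema_events(rep("p1", 5),
                   t0 + (0:4) * 600,
                   x = c(500, 900, 10 + 1000 + r_ft, 500, 500),
                   y = c(500, 500, 500, 900, 5000),
                   kind = "smoking")
  binned <- assign_bins(ev, -8)
  expect_equal(unique(binned$bin_index), 2L)
  # events 1,2,4 inside the zone; 3 just beyond the buffer; 5 far away
  rep_ <- capture_rate(fences, part, binned)
  pb <- rep_$per_bin
  expect_equal(pb$n_smoking[pb$bin_index == 2], 5L)
  expect_equal(pb$n_captured[pb$bin_index == 2], 3L)
  expect_equal(pb$pct_captured[pb$bin_index == 2], 60.0)
  expect_true(all(is.na(pb$pct_captured[pb$bin_index != 2])))
  expect_equal(rep_$overall$pct_captured, 60.0)

  # saturation: all events inside their bin's fence
  ev_in <- binned[c(1, 2, 4), ]
  expect_equal(capture_rate(fences, part, ev_in)$overall$pct_captured, 100.0)

  # participant mismatch is an error
  ev_bad <- binned
  ev_bad$participant_id <- "p2"
  expect_error(capture_rate(fences, part, ev_bad), "participant")
})

test_that("events captured by a bin fence are captured time-independently", {
  fx <- eval_fixture()
  fit <- fx$fit
  cap_bin <- predict(fit)
  cap_ti <- points_in_geofence(fit$ti_fences, fx$part,
                               fit$smoking$x, fit$smoking$y,
                               rep("all", nrow(fit$smoking)))
  expect_true(all(!cap_bin | cap_ti))
})

test_that("threshold sweep is non-increasing and saturates at threshold 0", {
  fx <- eval_fixture()
  fit <- fx$fit
  sw <- threshold_sweep(fit$risk, fx$part, fit$smoking,
                        thresholds = c(0, seq(0.1, 0.9, by = 0.1)))
  expect_equal(sw$threshold, c(0, seq(0.1, 0.9, by = 0.1)))
  expect_true(all(diff(sw$pct_captured) <= 0))
  expect_true(all(diff(sw$n_zones_retained) <= 0))
  # no missing zones here, so a 0.0 threshold captures everything
  expect_equal(attr(fit$risk, "n_missing"), 0L)
  expect_equal(sw$pct_captured[1], 100)

  # requesting areas fills the area column and keeps it non-increasing
  sw2 <- threshold_sweep(fit$risk, fx$part, fit$smoking,
                         thresholds = c(0.2, 0.8), compute_area = TRUE)
  expect_true(all(is.finite(sw2$geofence_area_ft2)))
  expect_lte(sw2$geofence_area_ft2[2], sw2$geofence_area_ft2[1])
})

test_that("partition comparison ranks by capture and reports areas", {
  fx <- eval_fixture()
  # identical reports tie at rank 1.5 with equal areas
  r1 <- fx$fit$report
  r2 <- r1
  r2$partition_kind <- "blocks"
  cmp <- compare_partitions(list(r1, r2))
  expect_equal(cmp$overall$rank, c(1.5, 1.5))
  expect_equal(cmp$overall$total_area_ft2[1], cmp$overall$total_area_ft2[2])

  # nested fences: B captures a superset of A -> B ranks strictly higher
  part <- zone_partition("custom", list(
    a = square_ring(0, 0, 1000), b = square_ring(1000, 0, 1000)))
  t0 <- as.POSIXct("2016-10-01 14:30:00", tz = "UTC")
  ev <- assign_bins(ema_events(rep("p1", 3), t0 + (0:2) * 60,
                               x = c(500, 500, 1500), y = rep(500, 3),
                               kind = "smoking"), -8)
  fa <- build_geofences(list(`2` = "a"), part, 100,
                        participant_id = "p1", threshold = 0.3)
  fb <- build_geofences(list(`2` = c("a", "b")), part, 100,
                        participant_id = "p1", threshold = 0.3)
  fa$partition_kind <- "fishnet_500"; fb$partition_kind <- "fishnet_1000"
  ra <- capture_rate(fa, part, ev)
  rb <- capture_rate(fb, part, ev)
  cmp2 <- compare_partitions(list(ra, rb))
  expect_equal(cmp2$overall$rank[cmp2$overall$partition_kind ==
                                   "fishnet_1000"], 1)
  # hand recount: a captures 2 of 3, b captures 3 of 3
  expect_equal(ra$overall$pct_captured, round(100 * 2 / 3, 1))
  expect_equal(rb$overall$pct_captured, 100)

  expect_error(compare_partitions(list(r1)), "at least two")
})

test_that("capture percentages are invariant to a global rescaling", {
  scale <- 0.3048  # report in meters instead of feet: same geometry
  extent <- c(xmin = 0, ymin = 0, xmax = 4000, ymax = 4000)
  part_ft <- make_fishnet(extent, 1000)
  set.seed(52)
  x <- runif(25, 500, 3500); y <- runif(25, 500, 3500)
  ev_ft <- assign_bins(mk_spatial_events(x, y), -8)
  g_ft <- make_grid(ev_ft, 1320, 150)
  risk_ft <- zone_risk_table(kde_surface(ev_ft, g_ft, 1320), part_ft)
  sw_ft <- threshold_sweep(risk_ft, part_ft, ev_ft, buffer_m = 100,
                           ft_per_m = 3.28083333)

  part_m <- zone_partition("custom", stats::setNames(lapply(
    part_ft$polygons, function(p) lapply(p, function(rg) rg * scale)),
    part_ft$zone_ids), check_overlap = FALSE)
  ev_m <- assign_bins(mk_spatial_events(x * scale, y * scale), -8)
  g_m <- make_grid(ev_m, 1320 * scale, 150 * scale)
  risk_m <- zone_risk_table(kde_surface(ev_m, g_m, 1320 * scale), part_m)
  sw_m <- threshold_sweep(risk_m, part_m, ev_m, buffer_m = 100,
                          ft_per_m = 3.28083333 * scale)
  expect_equal(sw_m$pct_captured, sw_ft$pct_captured)
  expect_equal(sw_m$n_zones_retained, sw_ft$n_zones_retained)
})

test_that("case report percentages recompute from raw counts", {
  tab <- case_report_table(c(16, 12, 31, 177), c(8, 47, 67, 61),
                           c("q25", "q50", "q75", "q100"))
  expect_equal(tab$pct_smoking, c(66.7, 20.3, 31.6, 74.4))
  expect_equal(tab$pct_nonsmoking, c(33.3, 79.7, 68.4, 25.6))
  expect_equal(tab$n_total, c(24, 59, 98, 238))
  expect_equal(tab$pct_of_grand_total, c(5.7, 14.1, 23.4, 56.8))
})
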
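# The fitted-model interface ---------------------------------------------

#' Fit person-specific, time-stratified geofences
#'
#' The front door of the package: runs the full construction for one
#' participant and one zone partition. Smoking reports are deduplicated
#' (5-minute window), converted to local time and binned into 3-hour
#' intervals; a quartic kernel density surface of the smoking events is
#' estimated; zonal mean densities are min-max normalized and classified
#' into risk terciles; for each 3-hour bin, zones at or above the risk
#' threshold that contain at least one of the bin's smoking events are
#' unioned and buffered by 100 m into that bin's geofence; and the result
#' is scored in-sample as the percent of smoking events captured.
#'
#' @param events An `"ema_events"` data frame for one participant (raw; the
#'   fit deduplicates and bins internally).
#' @param partition A `"zone_partition"`.
#' @param config A [geofence_config()].
#' @return An object of class `"geofence_model"` with components `events`
#'   (cleaned, binned), `smoking` (cleaned smoking events), `raster`,
#'   `risk`, `fences`, `ti_fences` (time-independent), `report` (a
#'   `"capture_report"`), `partition`, `config`.
#' @examples
#' \donttest{
#' suite <- gen_case_suite(seed = 7)
#' fit <- fit_geofences(suite$participants$q50, suite$partitions$fishnet_1000)
#' summary(fit)
#' }
#' @export
fit_geofences <- function(events, partition, config = geofence_config()) {
  stopifnot(inherits(partition, "zone_partition"),
            inherits(config, "geofence_config"))
  events <- validate_events(as.data.frame(events))
  if (length(unique(events$participant_id)) != 1L) {
    stop("fit_geofences expects events of exactly one participant",
         call. = FALSE)
  }
  pid <- events$participant_id[1L]
  clean <- dedupe_smoking(events, config$dedup_window_min,
                          keep = config$dedup_keep)
  clean <- assign_bins(clean, config$utc_offset_hours)
  smoking <- clean[clean$kind == "smoking", , drop = FALSE]
  if (nrow(smoking) == 0L) {
    stop("participant ", pid, " has no smoking events after deduplication",
         call. = FALSE)
  }
  grid <- make_grid(smoking, config$bandwidth_ft, config$cell_size_ft)
  raster <- kde_surface(smoking, grid, config$bandwidth_ft)
  risk <- zone_risk_table(raster, partition, config$threshold,
                          config$normalization_decimals,
                          mode = config$tercile_mode)
  selected <- lapply(stats::setNames(0:7, as.character(0:7)), function(b) {
    select_zones(risk, partition,
                 smoking[smoking$bin_index == b, , drop = FALSE],
                 config$threshold)
  })
  fences <- build_geofences(selected, partition, config$buffer_m,
                            config$ft_per_m, config$contour_cell_ft,
                            participant_id = pid,
                            threshold = config$threshold)
  ti_selected <- list(all = select_zones(risk, partition, smoking,
                                         config$threshold))
  ti_fences <- build_geofences(ti_selected, partition, config$buffer_m,
                               config$ft_per_m, config$contour_cell_ft,
                               participant_id = pid,
                               threshold = config$threshold)
  report <- capture_rate(fences, partition, smoking, ti_fences)
  structure(list(
    participant_id = pid,
    events = clean,
    smoking = smoking,
    raster = raster,
    risk = risk,
    fences = fences,
    ti_fences = ti_fences,
    report = report,
    partition = partition,
    config = config
  ), class = "geofence_model")
}

#' @export
print.geofence_model <- function(x, ...) {
  cat(sprintf("Geofenced smoking-risk model: participant %s\n",
              x$participant_id))
  cat(sprintf("  %d smoking / %d nonsmoking events after dedup (%d dropped)\n",
              nrow(x$smoking), sum(x$events$kind == "nonsmoking"),
              attr(x$events, "n_dropped") %||% 0L))
  cat(sprintf("  partition %s (%d zones, %d missing), threshold %.2g\n",
              x$partition$partition_kind, n_zones(x$partition),
              attr(x$risk, "n_missing") %||% 0L, x$config$threshold))
  cat(sprintf("  pooled capture %.1f%% (time-independent %.1f%%)\n",
              x$report$overall$pct_captured, x$report$time_independent_pct))
  invisible(x)
}

#' Summarise a fitted geofence model
#'
#' @param object A `"geofence_model"`.
#' @param sweep Also run the 0.1-0.9 threshold sensitivity sweep.
#' @param ... Unused.
#' @return A list of class `"summary.geofence_model"`: the capture report,
#'   zone-risk tercile counts, and optionally the sweep table.
#' @export
summary.geofence_model <- function(object, sweep = FALSE, ...) {
  out <- list(
    participant_id = object$participant_id,
    report = object$report,
    tercile_counts = table(object$risk$tercile),
    n_missing_zones = attr(object$risk, "n_missing") %||% 0L,
    sweep = NULL
  )
  if (sweep) {
    out$sweep <- threshold_sweep(
      object$risk, object$partition, object$smoking,
      buffer_m = object$config$buffer_m,
      ft_per_m = object$config$ft_per_m)
  }
  class(out) <- "summary.geofence_model"
  out
}

#' @export
print.summary.geofence_model <- function(x, ...) {
  print(x$report)
  cat("  zone terciles: ",
      paste(names(x$tercile_counts), as.integer(x$tercile_counts),
            sep = "=", collapse = ", "),
      sprintf(" (%d zone(s) unrasterized)\n", x$n_missing_zones))
  if (!is.null(x$sweep)) {
    cat("  threshold sweep (time-independent):\n")
    print(x$sweep, row.names = FALSE)
  }
  invisible(x)
}

#' Predict capture of events by a fitted geofence model
#'
#' Tests events against the fitted per-bin geofences (closure convention:
#' the perimeter counts as inside, matching trigger-on-entry delivery).
#'
#' @param object A `"geofence_model"`.
#' @param newdata Events to test (`"ema_events"`); defaults to the smoking
#'   events the model was fitted on (in-sample).
#' @param type `"captured"` for a logical vector, `"bin"` for the assigned
#'   bin indices.
#' @param ... Unused.
#' @return Logical or integer vector, one element per event.
#' @export
predict.geofence_model <- function(object, newdata = NULL,
                                   type = c("captured", "bin"), ...) {
  type <- match.arg(type)
  ev <- if (is.null(newdata)) object$smoking else {
    assign_bins(validate_events(as.data.frame(newdata)),
                object$config$utc_offset_hours)
  }
  if (type == "bin") return(ev$bin_index)
  points_in_geofence(object$fences, object$partition, ev$x, ev$y,
                     ev$bin_index)
}

#' Plot a fitted geofence model
#'
#' Draws the kernel density surface, the zone partition, the participant's
#' smoking events and the geofence outlines of one 3-hour bin (or the
#' time-independent fences).
#'
#' @param x A `"geofence_model"`.
#' @param bin Bin index 0-7, or `"all"` for the time-independent geofences.
#' @param ... Passed to [plot.density_raster()].
#' @return `x`, invisibly.
#' @export
plot.geofence_model <- function(x, bin = "all", ...) {
  plot(x$raster,
       main = sprintf("Participant %s - %s fences", x$participant_id,
                      if (identical(bin, "all")) "time-independent"
                      else paste("bin", bin)), ...)
  for (poly in x$partition$polygons) {
    for (ring in poly) {
      graphics::polygon(rbind(ring, ring[1L, ]), border = "grey70")
    }
  }
  graphics::points(x$smoking$x, x$smoking$y, pch = 16, cex = 0.5,
                   col = "grey20")
  fences <- if (identical(bin, "all")) x$ti_fences else x$fences
  key <- if (identical(bin, "all")) "all" else as.character(bin)
  slot <- fences$bins[[key]]
  if (!is.null(slot)) {
    for (poly in slot$multipolygon) {
      for (ring in poly) {
        graphics::polygon(rbind(ring, ring[1L, ]), border = "red3", lwd = 2)
      }
    }
  }
  invisible(x)
}
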
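# Capture-rate evaluation, threshold sweep, partition comparison ---------

#' Score a geofence set by the percent of smoking events captured
#'
#' An event is captured iff it lies inside (closure) the multipolygon of its
#' own 3-hour bin. Evaluation is in-sample by design: the same events that
#' built the fences are scored. Percentages are reported to 1 decimal; bins
#' with no smoking events get `NA` and are excluded from the across-bin
#' average. Both the unweighted across-bin mean and the event-weighted
#' (pooled) percentage are reported, since the two weightings differ on
#' uneven bins.
#'
#' @param fences A `"geofence_set"`.
#' @param partition The matching `"zone_partition"`.
#' @param events Binned smoking events (from [assign_bins()], smoking only).
#' @param ti_fences Optional time-independent `"geofence_set"` (built from
#'   all smoking events pooled, single bin `"all"`); when supplied the
#'   pooled capture against it is reported as `time_independent_pct`.
#' @return An object of class `"capture_report"`: `per_bin` data frame
#'   (`bin_index`, `n_smoking`, `n_captured`, `pct_captured`, `area_ft2`),
#'   `overall` (pooled n / captured / pct), `mean_pct_unweighted`, and
#'   `time_independent_pct`.
#' @export
capture_rate <- function(fences, partition, events, ti_fences = NULL) {
  stopifnot(inherits(fences, "geofence_set"))
  events <- as.data.frame(events)
  if (nrow(events) && any(events$kind != "smoking")) {
    stop("capture_rate expects smoking events only", call. = FALSE)
  }
  if (!"bin_index" %in% names(events)) {
    stop("events must be binned (see assign_bins)", call. = FALSE)
  }
  if (nrow(events) && !is.na(fences$participant_id) &&
      !all(events$participant_id == fences$participant_id)) {
    stop("participant mismatch between events and geofences", call. = FALSE)
  }
  captured <- if (nrow(events)) {
    points_in_geofence(fences, partition, events$x, events$y,
                       events$bin_index)
  } else {
    logical(0)
  }
  per_bin <- data.frame(bin_index = 0:7)
  per_bin$n_smoking <- vapply(0:7, function(b) {
    sum(events$bin_index == b)
  }, integer(1))
  per_bin$n_captured <- vapply(0:7, function(b) {
    sum(captured[events$bin_index == b])
  }, integer(1))
  per_bin$pct_captured <- ifelse(
    per_bin$n_smoking > 0,
    round(100 * per_bin$n_captured / per_bin$n_smoking, 1), NA_real_)
  per_bin$area_ft2 <- vapply(as.character(0:7), function(k) {
    if (k %in% names(fences$bins)) fences$bins[[k]]$area_ft2 else 0
  }, numeric(1))
  n_total <- sum(per_bin$n_smoking)
  n_cap <- sum(per_bin$n_captured)
  ti_pct <- NA_real_
  if (!is.null(ti_fences) && nrow(events)) {
    ti_cap <- points_in_geofence(ti_fences, partition, events$x, events$y,
                                 rep(names(ti_fences$bins)[1L], nrow(events)))
    ti_pct <- round(100 * sum(ti_cap) / nrow(events), 1)
  }
  structure(list(
    participant_id = fences$participant_id,
    partition_kind = fences$partition_kind,
    threshold = fences$threshold,
    per_bin = per_bin,
    overall = list(
      n_smoking = n_total,
      n_captured = n_cap,
      pct_captured = if (n_total > 0) round(100 * n_cap / n_total, 1)
                     else NA_real_
    ),
    mean_pct_unweighted = {
      ok <- !is.na(per_bin$pct_captured)
      if (any(ok)) round(mean(per_bin$pct_captured[ok]), 1) else NA_real_
    },
    time_independent_pct = ti_pct,
    total_area_ft2 = sum(per_bin$area_ft2)
  ), class = "capture_report")
}

#' @export
print.capture_report <- function(x, ...) {
  cat(sprintf(
    "Capture report: participant %s, %s, threshold %s\n",
    x$participant_id, x$partition_kind, format(x$threshold)))
  labs <- bin_labels()
  pb <- x$per_bin
  for (i in seq_len(nrow(pb))) {
    cat(sprintf("  %s  %3d smoking, %3d captured  %s\n",
                labs[i], pb$n_smoking[i], pb$n_captured[i],
                ifelse(is.na(pb$pct_captured[i]), "   -",
                       sprintf("%5.1f%%", pb$pct_captured[i]))))
  }
  cat(sprintf("  pooled: %d/%d = %.1f%%; across-bin mean %.1f%%\n",
              x$overall$n_captured, x$overall$n_smoking,
              x$overall$pct_captured, x$mean_pct_unweighted))
  if (!is.na(x$time_independent_pct)) {
    cat(sprintf("  time-independent: %.1f%%\n", x$time_independent_pct))
  }
  invisible(x)
}

#' Threshold sensitivity sweep
#'
#' Re-runs time-independent geofence construction (zone condition (2)
#' evaluated against all smoking events, irrespective of time of day) over a
#' set of thresholds and reports the percent of smoking events captured at
#' each. Retention is monotone in the threshold, so the capture percentage
#' is non-increasing; a threshold of 0 captures every event lying in a
#' non-missing zone.
#'
#' @param risk A `"zone_risk"` table.
#' @param partition The matching `"zone_partition"`.
#' @param events The participant's smoking events.
#' @param thresholds Numeric thresholds in \[0, 1\] (default 0.1-0.9).
#' @param buffer_m,ft_per_m Buffer distance (meters) and conversion.
#' @param compute_area Also contour the buffer outlines and report geofenced
#'   area (slower; off by default).
#' @param contour_cell_ft Contouring resolution when `compute_area = TRUE`.
#' @return A `data.frame` ordered by threshold with columns `threshold`,
#'   `pct_captured`, `n_zones_retained`, `geofence_area_ft2` (NA unless
#'   `compute_area`).
#' @export
threshold_sweep <- function(risk, partition, events,
                            thresholds = seq(0.1, 0.9, by = 0.1),
                            buffer_m = 100, ft_per_m = 3.28083333,
                            compute_area = FALSE, contour_cell_ft = 20) {
  events <- as.data.frame(events)
  events <- events[events$kind == "smoking", , drop = FALSE]
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  thresholds <- sort(thresholds)
  r_ft <- buffer_m * ft_per_m
  out <- data.frame(threshold = thresholds,
                    pct_captured = NA_real_,
                    n_zones_retained = NA_integer_,
                    geofence_area_ft2 = NA_real_)
  for (k in seq_along(thresholds)) {
    ids <- select_zones(risk, partition, events, thresholds[k])
    out$n_zones_retained[k] <- length(ids)
    if (length(ids) == 0L || nrow(events) == 0L) {
      out$pct_captured[k] <- 0
      if (compute_area) out$geofence_area_ft2[k] <- 0
      next
    }
    polys <- partition$polygons[match(ids, partition$zone_ids)]
    d <- dist_points_polygons(events$x, events$y, polys,
                              cap = r_ft * 1.5 + 1)
    out$pct_captured[k] <- round(100 * mean(d <= r_ft + 1e-9), 1)
    if (compute_area) {
      mp <- buffer_polygons(polys, r_ft, contour_cell_ft)
      out$geofence_area_ft2[k] <- multipolygon_area(mp)
    }
  }
  out
}

#' Compare capture reports across zone partitions
#'
#' Ranks partitions by percent captured, per bin and overall, with ties
#' reported as ties (average ranks), and reports total geofenced area per
#' partition — equal capture can come from very different areas, which
#' matters for intervention burden.
#'
#' @param reports List of `"capture_report"`s for the same participant and
#'   threshold, differing in partition kind.
#' @return A list with `per_bin` (long data frame: bin, partition, pct,
#'   rank) and `overall` (partition, pooled pct, mean pct, total area,
#'   rank), of class `"partition_comparison"`.
#' @export
compare_partitions <- function(reports) {
  if (length(reports) < 2L) {
    stop("need at least two capture reports to compare", call. = FALSE)
  }
  pid <- unique(vapply(reports, function(r) r$participant_id, character(1)))
  thr <- unique(vapply(reports, function(r) r$threshold, numeric(1)))
  if (length(pid) > 1L || length(thr) > 1L) {
    stop("reports must share participant and threshold", call. = FALSE)
  }
  kinds <- unname(vapply(reports, function(r) r$partition_kind, character(1)))
  reports <- unname(reports)
  per_bin <- do.call(rbind, lapply(seq_along(reports), function(i) {
    pb <- reports[[i]]$per_bin
    data.frame(bin_index = pb$bin_index, partition_kind = kinds[i],
               pct_captured = pb$pct_captured, area_ft2 = pb$area_ft2,
               stringsAsFactors = FALSE)
  }))
  # rank within each bin, descending pct; ties share average rank
  per_bin$rank <- NA_real_
  for (b in unique(per_bin$bin_index)) {
    idx <- which(per_bin$bin_index == b & !is.na(per_bin$pct_captured))
    if (length(idx)) {
      per_bin$rank[idx] <- rank(-per_bin$pct_captured[idx],
                                ties.method = "average")
    }
  }
  overall <- data.frame(
    partition_kind = kinds,
    pct_captured = vapply(reports, function(r) r$overall$pct_captured,
                          numeric(1)),
    mean_pct_unweighted = vapply(reports, function(r) r$mean_pct_unweighted,
                                 numeric(1)),
    total_area_ft2 = vapply(reports, function(r) r$total_area_ft2,
                            numeric(1)),
    stringsAsFactors = FALSE
  )
  overall$rank <- rank(-overall$pct_captured, ties.method = "average")
  structure(list(participant_id = pid, threshold = thr,
                 per_bin = per_bin, overall = overall),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf("Partition comparison: participant %s, threshold %s\n",
              x$participant_id, format(x$threshold)))
  print(x$overall, row.names = FALSE)
  invisible(x)
}

#' Recompute event-count summary percentages
#'
#' Builds the per-case report table (smoking n and row %, nonsmoking n and
#' row %, total n and % of the grand total) from raw counts — the format of
#' the study's case summary. Percentages are rounded to 1 decimal.
#'
#' @param n_smoking,n_nonsmoking Integer vectors, one entry per case.
#' @param case_labels Optional case names.
#' @return A `data.frame` with columns `case`, `n_smoking`, `pct_smoking`,
#'   `n_nonsmoking`, `pct_nonsmoking`, `n_total`, `pct_of_grand_total`.
#' @examples
#' case_report_table(c(16, 12, 31, 177), c(8, 47, 67, 61))
#' @export
case_report_table <- function(n_smoking, n_nonsmoking,
                              case_labels = NULL) {
  stopifnot(length(n_smoking) == length(n_nonsmoking),
            all(n_smoking >= 0), all(n_nonsmoking >= 0))
  n_total <- n_smoking + n_nonsmoking
  grand <- sum(n_total)
  data.frame(
    case = case_labels %||% paste0("case_", seq_along(n_smoking)),
    n_smoking = as.integer(n_smoking),
    pct_smoking = round(100 * n_smoking / n_total, 1),
    n_nonsmoking = as.integer(n_nonsmoking),
    pct_nonsmoking = round(100 * n_nonsmoking / n_total, 1),
    n_total = as.integer(n_total),
    pct_of_grand_total = round(100 * n_total / grand, 1),
    stringsAsFactors = FALSE
  )
}
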
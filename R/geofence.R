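# Geofence construction ---------------------------------------------------

#' Select high-risk zones for one 3-hour bin
#'
#' A zone is selected iff (1) its normalized mean KDE is at or above the
#' threshold and (2) at least one of the bin's smoking events falls inside
#' it (boundary points resolved by the same up-and-right half-open rule as
#' the zonal statistics). Normalized means are computed once from all of a
#' participant's smoking events, so risk values are bin-independent; the
#' time stratification enters only through condition (2).
#'
#' @param risk A `"zone_risk"` table (needs `zone_id`, `norm_mean_kde`).
#' @param partition The matching `"zone_partition"`.
#' @param events Smoking events of one bin (any `data.frame` with `x`, `y`).
#' @param threshold Retention threshold in \[0, 1\] (inclusive comparison).
#' @return Character vector of selected zone ids (possibly empty).
#' @export
select_zones <- function(risk, partition, events, threshold = 0.3) {
  stopifnot(inherits(partition, "zone_partition"),
            threshold >= 0, threshold <= 1)
  events <- as.data.frame(events)
  if (nrow(events) == 0L) return(character(0))
  norm <- risk$norm_mean_kde[match(partition$zone_ids, risk$zone_id)]
  zi <- zone_assign(events$x, events$y, partition)
  occupied <- sort(unique(zi[!is.na(zi)]))
  sel <- occupied[!is.na(norm[occupied]) & norm[occupied] >= threshold]
  partition$zone_ids[sel]
}

#' Build buffered geofences from selected zones
#'
#' For each bin, the selected zones are unioned (zones sharing an edge or
#' corner merge into one group) and buffered outward by the configured
#' distance. The buffer is the exact Euclidean offset — the set of points
#' within the buffer distance of the zone union — so joins are round and
#' overlapping buffers of nearby groups dissolve into one polygon. Output
#' outlines are extracted from the distance field by marching-squares
#' contouring at sub-grid accuracy; the capture predicate
#' ([points_in_geofence()]) uses the exact distance test and is independent
#' of the contouring resolution.
#'
#' @param selected Named list: for each bin (names `"0"`..`"7"`, or any
#'   labels) a character vector of selected zone ids. An empty vector gives
#'   an empty geofence for that bin.
#' @param partition The `"zone_partition"` supplying zone polygons.
#' @param buffer_m Buffer distance in meters (converted at `ft_per_m`).
#' @param ft_per_m Feet per meter (default US survey foot).
#' @param contour_cell_ft Distance-field grid step for outline extraction.
#' @param participant_id,threshold Metadata recorded on the result.
#' @return An object of class `"geofence_set"`: per bin a list with
#'   `zone_ids`, `multipolygon` (list of polygons, each a list of rings) and
#'   `area_ft2`, plus metadata fields.
#' @export
build_geofences <- function(selected, partition, buffer_m = 100,
                            ft_per_m = 3.28083333, contour_cell_ft = 20,
                            participant_id = NA_character_,
                            threshold = NA_real_) {
  stopifnot(inherits(partition, "zone_partition"), buffer_m > 0)
  r_ft <- buffer_m * ft_per_m
  bins <- lapply(selected, function(ids) {
    ids <- intersect(ids, partition$zone_ids)
    if (length(ids) == 0L) {
      return(list(zone_ids = character(0), multipolygon = list(),
                  area_ft2 = 0))
    }
    polys <- partition$polygons[match(ids, partition$zone_ids)]
    mp <- buffer_polygons(polys, r_ft, contour_cell_ft)
    list(zone_ids = ids, multipolygon = mp,
         area_ft2 = multipolygon_area(mp))
  })
  structure(list(
    participant_id = participant_id,
    partition_kind = partition$partition_kind,
    threshold = threshold,
    buffer_m = buffer_m,
    buffer_ft = r_ft,
    bins = bins
  ), class = "geofence_set")
}

# Exact-offset buffer of a polygon union, as a multipolygon extracted by
# contouring the Euclidean distance field at level r. The field grid extends
# r plus a margin beyond the zones so every contour closes.
buffer_polygons <- function(polys, r_ft, contour_cell_ft = 20) {
  bb <- vapply(polys, polygon_bbox, numeric(4))
  pad <- r_ft + 3 * contour_cell_ft
  xmin <- min(bb["xmin", ]) - pad; xmax <- max(bb["xmax", ]) + pad
  ymin <- min(bb["ymin", ]) - pad; ymax <- max(bb["ymax", ]) + pad
  xs <- seq(xmin, xmax, by = contour_cell_ft)
  ys <- seq(ymin, ymax, by = contour_cell_ft)
  g <- expand.grid(x = xs, y = ys)
  d <- dist_points_polygons(g$x, g$y, polys, cap = r_ft + 4 * contour_cell_ft)
  z <- matrix(d, nrow = length(xs), ncol = length(ys))  # z[i,j] at xs[i],ys[j]
  contour_multipolygon(xs, ys, z, level = r_ft)
}

#' Test points against a geofence set
#'
#' An event is captured iff it lies inside (closure convention: boundary
#' counts as inside) the multipolygon of its own bin. The test is the exact
#' distance test — within the buffer distance of the bin's selected-zone
#' union — matching the definition of the buffer rather than its contoured
#' outline.
#'
#' @param fences A `"geofence_set"`.
#' @param partition The `"zone_partition"` the fences were built from.
#' @param x,y Event coordinates, feet.
#' @param bin_index Bin key per event: integer 0-7 for time-stratified
#'   fences, or the bin name (e.g. `"all"` for a time-independent set). Use
#'   one value for all events to test against a single bin's fence.
#' @return Logical vector: captured or not.
#' @export
points_in_geofence <- function(fences, partition, x, y, bin_index) {
  stopifnot(inherits(fences, "geofence_set"),
            inherits(partition, "zone_partition"))
  bin_index <- rep_len(as.character(bin_index), length(x))
  out <- logical(length(x))
  keys <- names(fences$bins)
  for (key in unique(bin_index)) {
    idx <- which(bin_index == key)
    slot <- if (key %in% keys) fences$bins[[key]] else NULL
    if (is.null(slot) || length(slot$zone_ids) == 0L) next
    polys <- partition$polygons[match(slot$zone_ids, partition$zone_ids)]
    d <- dist_points_polygons(x[idx], y[idx], polys,
                              cap = fences$buffer_ft * 1.5 + 1)
    out[idx] <- d <= fences$buffer_ft + 1e-9
  }
  out
}

#' Write a geofence set as GeoJSON
#'
#' One feature per (bin, polygon), with properties `bin_index`,
#' `partition_kind`, `threshold` and the contributing `zone_ids`.
#'
#' @param fences A `"geofence_set"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geofences <- function(fences, path) {
  stopifnot(inherits(fences, "geofence_set"))
  features <- list()
  for (key in names(fences$bins)) {
    slot <- fences$bins[[key]]
    for (poly in slot$multipolygon) {
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(
          bin_index = as.integer(key),
          partition_kind = fences$partition_kind,
          threshold = fences$threshold,
          zone_ids = paste(slot$zone_ids, collapse = ";")
        ),
        geometry = list(
          type = "Polygon",
          coordinates = lapply(poly, close_ring_coords)
        )
      )
    }
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.geofence_set <- function(x, ...) {
  cat(sprintf(
    "Geofence set: participant %s, partition %s, threshold %s, buffer %g m\n",
    x$participant_id, x$partition_kind, format(x$threshold), x$buffer_m))
  for (key in names(x$bins)) {
    slot <- x$bins[[key]]
    cat(sprintf("  bin %s: %d zone(s), %d polygon(s), area %.4g ft^2\n",
                key, length(slot$zone_ids), length(slot$multipolygon),
                slot$area_ft2))
  }
  invisible(x)
}
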
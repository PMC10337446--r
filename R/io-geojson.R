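# Zone partitions and GeoJSON I/O ----------------------------------------

PARTITION_KINDS <- c("blocks", "fishnet_500", "fishnet_1000", "custom")

#' Construct a zone partition
#'
#' A partition is a tessellation of (part of) the study extent into
#' identified polygons: irregular blocks or fishnet grid cells. Zone
#' identifiers must be unique; zone interiors must be pairwise disjoint
#' (shared edges are fine). Polygons may carry holes.
#'
#' @param partition_kind One of `"blocks"`, `"fishnet_500"`,
#'   `"fishnet_1000"`, `"custom"`.
#' @param zones Named list: each element a polygon, i.e. a list of rings
#'   (n x 2 coordinate matrices, outer ring first, holes after). A bare ring
#'   matrix is promoted to a single-ring polygon.
#' @param check_overlap Verify pairwise interior disjointness (quadratic in
#'   the number of zones; construction-by-design partitions from
#'   [make_fishnet()] / [make_pseudo_blocks()] skip it).
#' @return An object of class `"zone_partition"`.
#' @export
zone_partition <- function(partition_kind, zones, check_overlap = TRUE) {
  partition_kind <- match.arg(partition_kind, PARTITION_KINDS)
  ids <- names(zones)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every zone needs a zone_id (names of `zones`)", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate zone_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  polys <- lapply(zones, function(z) {
    if (is.matrix(z) || is.data.frame(z)) z <- list(z)
    lapply(z, as_ring)
  })
  for (i in seq_along(polys)) {
    if (!polygon_is_valid(polys[[i]])) {
      stop("zone ", ids[i], " has an invalid polygon ",
           "(self-intersecting, degenerate, or zero-area)", call. = FALSE)
    }
  }
  part <- structure(list(
    partition_kind = partition_kind,
    zone_ids = ids,
    polygons = polys
  ), class = "zone_partition")
  if (check_overlap) check_partition_overlap(part)
  part
}

n_zones <- function(partition) length(partition$zone_ids)

partition_bbox <- function(partition) {
  bb <- vapply(partition$polygons, polygon_bbox, numeric(4))
  c(xmin = min(bb["xmin", ]), ymin = min(bb["ymin", ]),
    xmax = max(bb["xmax", ]), ymax = max(bb["ymax", ]))
}

zone_areas <- function(partition) {
  vapply(partition$polygons, polygon_area, numeric(1))
}

# Pairwise interior-overlap check. For convex zone pairs the intersection
# area is computed exactly by Sutherland-Hodgman clipping (shared edges give
# zero area). Non-convex pairs fall back to a detection heuristic (properly
# crossing edges or a vertex strictly interior to the other zone, with a
# scale-relative clearance so shared Voronoi/fishnet edges never trigger)
# plus a grid estimate of the area.
check_partition_overlap <- function(partition, tol_frac = 1e-6) {
  polys <- partition$polygons
  ids <- partition$zone_ids
  m <- length(polys)
  if (m < 2L) return(invisible(TRUE))
  bb <- vapply(polys, polygon_bbox, numeric(4))
  areas <- zone_areas(partition)
  convex <- vapply(polys, function(p) {
    length(p) == 1L && is_convex_ring(p[[1L]])
  }, logical(1))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (bb["xmin", i] >= bb["xmax", j] || bb["xmin", j] >= bb["xmax", i] ||
          bb["ymin", i] >= bb["ymax", j] || bb["ymin", j] >= bb["ymax", i]) {
        next
      }
      if (convex[i] && convex[j]) {
        area <- convex_intersection_area(polys[[i]][[1L]], polys[[j]][[1L]])
      } else if (zones_overlap(polys[[i]], polys[[j]], areas[i], areas[j])) {
        area <- overlap_area(polys[[i]], polys[[j]])
      } else {
        next
      }
      smaller <- min(areas[i], areas[j])
      if (area > tol_frac * smaller) {
        stop(sprintf(
          "zones %s and %s overlap (area %.6g ft^2, %.3g of the smaller zone)",
          ids[i], ids[j], area, area / smaller), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

zones_overlap <- function(pa, pb, area_a, area_b) {
  clearance_a <- 1e-7 * sqrt(area_a)
  clearance_b <- 1e-7 * sqrt(area_b)
  # vertex of one strictly interior to the other
  va <- do.call(rbind, pa)
  vb <- do.call(rbind, pb)
  ina <- points_in_polygon(vb[, 1L], vb[, 2L], pa)
  if (any(ina)) {
    d <- dist_points_polygon_boundary(vb[ina, 1L], vb[ina, 2L], pa)
    if (any(d > clearance_a)) return(TRUE)
  }
  inb <- points_in_polygon(va[, 1L], va[, 2L], pb)
  if (any(inb)) {
    d <- dist_points_polygon_boundary(va[inb, 1L], va[inb, 2L], pb)
    if (any(d > clearance_b)) return(TRUE)
  }
  # properly crossing edges
  ea <- do.call(rbind, lapply(pa, ring_edges))
  eb <- do.call(rbind, lapply(pb, ring_edges))
  for (k in seq_len(nrow(ea))) {
    for (l in seq_len(nrow(eb))) {
      if (segments_cross(ea[k, 1:2], ea[k, 3:4], eb[l, 1:2], eb[l, 3:4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

overlap_area <- function(pa, pb, n_grid = 120L) {
  ra <- pa[[1L]]; rb <- pb[[1L]]
  if (length(pa) == 1L && length(pb) == 1L &&
      is_convex_ring(ra) && is_convex_ring(rb)) {
    return(convex_intersection_area(ra, rb))
  }
  ba <- polygon_bbox(pa); bb_ <- polygon_bbox(pb)
  xmin <- max(ba["xmin"], bb_["xmin"]); xmax <- min(ba["xmax"], bb_["xmax"])
  ymin <- max(ba["ymin"], bb_["ymin"]); ymax <- min(ba["ymax"], bb_["ymax"])
  if (xmax <= xmin || ymax <= ymin) return(0)
  xs <- seq(xmin, xmax, length.out = n_grid)
  ys <- seq(ymin, ymax, length.out = n_grid)
  g <- expand.grid(x = xs, y = ys)
  both <- points_in_polygon(g$x, g$y, pa) & points_in_polygon(g$x, g$y, pb)
  mean(both) * (xmax - xmin) * (ymax - ymin)
}

#' Read and write zone partitions as GeoJSON
#'
#' Partitions are GeoJSON FeatureCollections of `Polygon` features carrying a
#' `zone_id` property, with coordinates already in the planar US-feet system.
#' `read_partition` validates geometry (rejecting non-polygon features,
#' duplicate ids and self-intersecting rings) and errors when zone interiors
#' overlap by more than a relative area tolerance of the smaller zone.
#'
#' @param path Path to a GeoJSON file.
#' @param partition_kind Partition label used when the file's top-level
#'   `partition_kind` member is absent.
#' @return `read_partition` returns a `"zone_partition"`; `write_partition`
#'   returns `path` invisibly.
#' @export
read_partition <- function(path, partition_kind = NULL) {
  if (!file.exists(path)) {
    stop("partition file not found: ", path, call. = FALSE)
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  kind <- partition_kind %||% gj$partition_kind %||% "custom"
  zones <- list()
  for (k in seq_along(gj$features)) {
    ft <- gj$features[[k]]
    geom <- ft$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      stop("feature ", k, " is not a Polygon (got ",
           geom$type %||% "no geometry", ")", call. = FALSE)
    }
    id <- ft$properties$zone_id
    if (is.null(id)) stop("feature ", k, " lacks a zone_id property",
                          call. = FALSE)
    rings <- lapply(geom$coordinates, function(rg) {
      as_ring(do.call(rbind, lapply(rg, function(p) c(p[[1L]], p[[2L]]))))
    })
    if (!is.null(zones[[as.character(id)]])) {
      stop("duplicate zone_id: ", id, call. = FALSE)
    }
    zones[[as.character(id)]] <- rings
  }
  zone_partition(kind, zones)
}

close_ring_coords <- function(ring) {
  closed <- rbind(ring, ring[1L, , drop = FALSE])
  lapply(seq_len(nrow(closed)), function(i) as.list(unname(closed[i, ])))
}

#' @rdname read_partition
#' @param partition A `"zone_partition"` object.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "zone_partition"))
  features <- lapply(seq_len(n_zones(partition)), function(i) {
    list(
      type = "Feature",
      properties = list(zone_id = partition$zone_ids[i]),
      geometry = list(
        type = "Polygon",
        coordinates = lapply(partition$polygons[[i]], close_ring_coords)
      )
    )
  })
  gj <- list(
    type = "FeatureCollection",
    partition_kind = partition$partition_kind,
    features = features
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("Zone partition (%s): %d zones, total area %.4g ft^2\n",
              x$partition_kind, n_zones(x), sum(zone_areas(x))))
  invisible(x)
}
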
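# Zone partitions, zonal statistics, risk classification -----------------

#' Generate a fishnet grid partition
#'
#' An axis-aligned array of square cells tiling (a superset of) the extent,
#' anchored at the extent's lower-left corner snapped down to a multiple of
#' the cell side. Zone ids encode row and column (`"r003c012"`).
#'
#' @param extent Named numeric `c(xmin=, ymin=, xmax=, ymax=)`, US feet.
#' @param cell_side Cell side length, feet (e.g. 500 or 1000).
#' @param partition_kind Label; defaults to `"fishnet_500"` /
#'   `"fishnet_1000"` when `cell_side` is 500 / 1000, else `"custom"`.
#' @return A `"zone_partition"` of interior-disjoint square cells.
#' @examples
#' make_fishnet(c(xmin = 0, ymin = 0, xmax = 1000, ymax = 1000), 500)
#' @export
make_fishnet <- function(extent, cell_side, partition_kind = NULL) {
  stopifnot(cell_side > 0,
            extent["xmax"] > extent["xmin"], extent["ymax"] > extent["ymin"])
  if (is.null(partition_kind)) {
    partition_kind <- if (cell_side == 500) "fishnet_500"
    else if (cell_side == 1000) "fishnet_1000"
    else "custom"
  }
  x0 <- floor(extent["xmin"] / cell_side) * cell_side
  y0 <- floor(extent["ymin"] / cell_side) * cell_side
  nc <- ceiling((extent["xmax"] - x0) / cell_side)
  nr <- ceiling((extent["ymax"] - y0) / cell_side)
  zones <- list()
  for (r in seq_len(nr)) {
    for (c_ in seq_len(nc)) {
      xa <- x0 + (c_ - 1) * cell_side; ya <- y0 + (r - 1) * cell_side
      zones[[sprintf("r%03dc%03d", r, c_)]] <- as_ring(rbind(
        c(xa, ya), c(xa + cell_side, ya),
        c(xa + cell_side, ya + cell_side), c(xa, ya + cell_side)
      ))
    }
  }
  zone_partition(partition_kind, zones, check_overlap = FALSE)
}

#' Generate an irregular pseudo-block partition
#'
#' A synthetic stand-in for census blocks: a Voronoi tessellation of
#' uniformly sampled seeds clipped to the extent, giving convex zones of
#' highly variable size. Optionally a fraction of zones is split by a narrow
#' corridor (emulating roadway slivers): the corridor itself becomes its own
#' zone, narrower than the density raster's cell size, so it may contain no
#' raster cell center and fail to rasterize — the mechanism behind missing
#' zonal means.
#'
#' @param extent Named numeric `c(xmin=, ymin=, xmax=, ymax=)`, feet.
#' @param n_seeds Number of Voronoi seeds (>= 3).
#' @param rng_seed Integer seed; the partition is deterministic given it.
#' @param sliver_fraction Fraction of zones split by a corridor, in \[0, 1).
#' @param corridor_width_ft Corridor width, feet; keep below the raster cell
#'   size for the sliver effect (default 20).
#' @return A `"zone_partition"` with `partition_kind = "blocks"`.
#' @export
make_pseudo_blocks <- function(extent, n_seeds, rng_seed,
                               sliver_fraction = 0,
                               corridor_width_ft = 20) {
  stopifnot(n_seeds >= 3, sliver_fraction >= 0, sliver_fraction < 1,
            corridor_width_ft > 0)
  with_seed(rng_seed, {
    seeds <- cbind(
      stats::runif(n_seeds, extent["xmin"], extent["xmax"]),
      stats::runif(n_seeds, extent["ymin"], extent["ymax"])
    )
    cells <- voronoi_cells(seeds, extent)
    zones <- list()
    n_split <- floor(sliver_fraction * n_seeds)
    split_idx <- if (n_split > 0) sample(n_seeds, n_split) else integer(0)
    for (i in seq_len(n_seeds)) {
      id <- sprintf("B%03d", i)
      ring <- cells[[i]]
      if (nrow(ring) < 3L) next
      if (i %in% split_idx) {
        pieces <- split_zone_corridor(ring, corridor_width_ft)
        for (k in seq_along(pieces)) {
          suffix <- c("a", "b", "s")[k]
          zones[[paste0(id, suffix)]] <- pieces[[k]]
        }
      } else {
        zones[[id]] <- ring
      }
    }
    zone_partition("blocks", zones, check_overlap = FALSE)
  })
}

# Split a convex ring by a corridor of width w through its centroid at a
# random orientation: returns the two outer pieces and the corridor sliver.
split_zone_corridor <- function(ring, w) {
  cx <- mean(ring[, 1L]); cy <- mean(ring[, 2L])
  theta <- stats::runif(1, 0, pi)
  a <- cos(theta); b <- sin(theta)
  c0 <- a * cx + b * cy
  left <- clip_ring_halfplane(ring, a, b, c0 - w / 2)
  right <- clip_ring_halfplane(ring, -a, -b, -(c0 + w / 2))
  mid <- clip_ring_halfplane(
    clip_ring_halfplane(ring, a, b, c0 + w / 2), -a, -b, -(c0 - w / 2))
  pieces <- list(left, right, mid)
  keep <- vapply(pieces, function(p) nrow(p) >= 3L && ring_area(p) > 0,
                 logical(1))
  if (!all(keep[1:2])) return(list(ring))  # too small to split cleanly
  pieces[keep]
}

# Deterministic zone membership with half-open edge semantics: a query point
# on a shared edge belongs to the zone whose interior lies up-and-right,
# realized by nudging the query point by +eps in x and y before the even-odd
# test. Returns the zone index (first match in partition order) or NA.
zone_assign <- function(px, py, partition, eps = 1e-6) {
  out <- rep(NA_integer_, length(px))
  qx <- px + eps; qy <- py + eps
  bb <- vapply(partition$polygons, polygon_bbox, numeric(4))
  for (i in seq_along(partition$polygons)) {
    todo <- which(is.na(out) &
                    qx >= bb["xmin", i] & qx <= bb["xmax", i] &
                    qy >= bb["ymin", i] & qy <= bb["ymax", i])
    if (!length(todo)) next
    hit <- points_in_polygon(qx[todo], qy[todo], partition$polygons[[i]])
    out[todo[hit]] <- i
  }
  out
}

#' Zonal mean of a density raster
#'
#' For each zone, the arithmetic mean of raster values at the cell centers
#' falling inside the zone. A center on a shared zone edge is assigned to
#' the zone whose interior lies up-and-right (half-open cell semantics), so
#' each center counts exactly once. Zones containing no cell center get `NA`.
#'
#' Two flavours of `NA` are distinguished in the attributes: zones lying
#' fully inside the raster extent that still catch no center — slivers
#' narrower than the cell size, the "did not rasterize" failure mode —
#' are counted in `n_missing` (and logged); zones extending beyond the
#' participant's padded density surface are simply outside the analysis
#' extent and are counted in `n_outside`.
#'
#' @param raster A `"density_raster"`.
#' @param partition A `"zone_partition"` in the same coordinate system.
#' @return Named numeric vector of mean densities (NA for missing zones),
#'   one per zone, with attributes `n_missing` and `n_outside`.
#' @export
zonal_mean <- function(raster, partition) {
  stopifnot(inherits(raster, "density_raster"),
            inherits(partition, "zone_partition"))
  xs <- raster_xs(raster); ys <- raster_ys(raster)
  centers <- expand.grid(x = xs, y = ys)  # x varies fastest
  vals <- as.vector(t(raster$values))     # match expand.grid order
  zi <- zone_assign(centers$x, centers$y, partition,
                    eps = raster$cell_size * 1e-9)
  means <- rep(NA_real_, n_zones(partition))
  names(means) <- partition$zone_ids
  agg <- tapply(vals, zi, mean)
  means[as.integer(names(agg))] <- agg
  bb <- vapply(partition$polygons, polygon_bbox, numeric(4))
  interior <- bb["xmin", ] >= raster$x_origin &
    bb["ymin", ] >= raster$y_origin &
    bb["xmax", ] <= raster$x_origin + raster$n_cols * raster$cell_size &
    bb["ymax", ] <= raster$y_origin + raster$n_rows * raster$cell_size
  unrasterized <- is.na(means) & interior
  attr(means, "n_missing") <- sum(unrasterized)
  attr(means, "n_outside") <- sum(is.na(means) & !interior)
  if (any(unrasterized)) {
    sf_log("%d zone(s) did not rasterize (no cell center inside): %s",
           sum(unrasterized),
           paste(utils::head(names(means)[unrasterized], 10), collapse = ", "))
  }
  means
}

#' Min-max normalize zonal means
#'
#' Rescales non-missing zonal means to \[0, 1\] by
#' `(mean - min) / (max - min)` and rounds to `decimals` places (the study
#' rounds to 6; rounding can exclude the top zone at threshold 1.0, e.g.
#' a raw 0.9999984 rounds to 0.999998 < 1). When all non-missing means are
#' equal the normalized value is 1 for all of them (degenerate convention).
#' `NA` means propagate.
#'
#' @param means Named numeric vector from [zonal_mean()].
#' @param decimals Decimal places kept (default 6).
#' @return Named numeric vector of normalized means in \[0, 1\] (NA
#'   propagated).
#' @export
normalize_minmax <- function(means, decimals = 6L) {
  ok <- !is.na(means)
  if (!any(ok)) stop("all zonal means are missing", call. = FALSE)
  lo <- min(means[ok]); hi <- max(means[ok])
  norm <- rep(NA_real_, length(means))
  names(norm) <- names(means)
  if (hi == lo) {
    norm[ok] <- 1
  } else {
    norm[ok] <- round((means[ok] - lo) / (hi - lo), decimals)
  }
  norm
}

#' Classify retained zones into risk terciles
#'
#' Zones with normalized mean KDE at or above the threshold (inclusive
#' comparison) are retained and split into low/medium/high risk groups.
#' In `"rank"` mode (default) retained zones are sorted ascending and cut
#' into three groups with sizes as equal as possible, remainders going to
#' the lower groups (7 zones split 3/2/2); zones tied on a boundary value
#' all take the lower tercile, keeping the classification deterministic. In
#' `"range"` mode the retained value range is cut into three equal-width
#' intervals. Zones below threshold are `"not_retained"`; missing zones are
#' `"missing"`.
#'
#' @param norms Named normalized means from [normalize_minmax()].
#' @param threshold Retention threshold in \[0, 1\].
#' @param mode `"rank"` or `"range"`.
#' @return A `data.frame` of class `"zone_risk"` with columns `zone_id`,
#'   `norm_mean_kde`, `tercile`.
#' @export
classify_terciles <- function(norms, threshold = 0.3,
                              mode = c("rank", "range")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, threshold <= 1)
  tercile <- rep("not_retained", length(norms))
  tercile[is.na(norms)] <- "missing"
  retained <- which(!is.na(norms) & norms >= threshold)
  if (length(retained)) {
    v <- norms[retained]
    if (mode == "rank") {
      n <- length(v)
      base <- n %/% 3L; rem <- n %% 3L
      sizes <- c(base + (rem >= 1L), base + (rem >= 2L), base)
      ord <- order(v)
      grp <- rep(1:3, times = sizes)[order(ord)]  # group per original index
      # ties spanning a boundary: whole tie group takes the lower tercile
      for (val in unique(v)) grp[v == val] <- min(grp[v == val])
    } else {
      lo <- min(v); hi <- max(v)
      if (hi == lo) {
        grp <- rep(3L, length(v))
      } else {
        grp <- pmin(3L, 1L + floor(3 * (v - lo) / (hi - lo)))
      }
    }
    tercile[retained] <- c("low", "medium", "high")[grp]
  }
  structure(data.frame(
    zone_id = names(norms),
    norm_mean_kde = unname(norms),
    tercile = tercile,
    stringsAsFactors = FALSE
  ), class = c("zone_risk", "data.frame"))
}

#' Per-zone risk table
#'
#' Composes [zonal_mean()], [normalize_minmax()] and [classify_terciles()]
#' into the per-zone risk table: mean KDE, normalized mean KDE and tercile
#' class.
#'
#' @param raster A `"density_raster"` of smoking density.
#' @param partition A `"zone_partition"`.
#' @param threshold Retention threshold (inclusive).
#' @param decimals Rounding of normalized means.
#' @param mode Tercile mode, see [classify_terciles()].
#' @return A `"zone_risk"` data frame with columns `zone_id`, `mean_kde`,
#'   `norm_mean_kde`, `tercile`, and attribute `n_missing`.
#' @export
zone_risk_table <- function(raster, partition, threshold = 0.3,
                            decimals = 6L, mode = c("rank", "range")) {
  means <- zonal_mean(raster, partition)
  norms <- normalize_minmax(means, decimals)
  risk <- classify_terciles(norms, threshold, mode = match.arg(mode))
  risk$mean_kde <- unname(means)
  risk <- risk[, c("zone_id", "mean_kde", "norm_mean_kde", "tercile")]
  attr(risk, "n_missing") <- attr(means, "n_missing")
  attr(risk, "n_outside") <- attr(means, "n_outside")
  class(risk) <- c("zone_risk", "data.frame")
  risk
}

#' Read and write zone risk tables as CSV
#'
#' Columns `zone_id,mean_kde,norm_mean_kde,tercile`.
#'
#' @param risk A `"zone_risk"` data frame.
#' @param path CSV path.
#' @return `read_risk` returns a `"zone_risk"`; `write_risk` returns `path`
#'   invisibly.
#' @export
write_risk <- function(risk, path) {
  utils::write.csv(as.data.frame(risk)[, c("zone_id", "mean_kde",
                                           "norm_mean_kde", "tercile")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_risk
#' @export
read_risk <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("zone_risk", "data.frame"))
}
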
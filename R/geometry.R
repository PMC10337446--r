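# Planar geometry primitives ---------------------------------------------
#
# All geometry is 2-D planar in US feet. A *ring* is an n x 2 numeric matrix
# of vertices, not closed (first vertex is not repeated at the end). A
# *polygon* is a list of rings: the first is the outer boundary, the rest are
# holes. A *multipolygon* is a list of polygons. Point-in-polygon uses the
# even-odd rule, so hole handling falls out of ray casting across all rings.

as_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("a ring needs two coordinate columns", call. = FALSE)
  dimnames(m) <- NULL
  # drop an explicit closing vertex
  n <- nrow(m)
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  # drop consecutive duplicates
  if (nrow(m) >= 2L) {
    dup <- c(FALSE, rowSums(abs(diff(m))) == 0)
    m <- m[!dup, , drop = FALSE]
  }
  m
}

ring_signed_area <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

ring_area <- function(ring) abs(ring_signed_area(ring))

polygon_area <- function(poly) {
  if (length(poly) == 0L) return(0)
  ring_area(poly[[1L]]) - sum(vapply(poly[-1L], ring_area, numeric(1)))
}

multipolygon_area <- function(mp) sum(vapply(mp, polygon_area, numeric(1)))

ring_bbox <- function(ring) {
  c(xmin = min(ring[, 1L]), ymin = min(ring[, 2L]),
    xmax = max(ring[, 1L]), ymax = max(ring[, 2L]))
}

polygon_bbox <- function(poly) ring_bbox(poly[[1L]])

# Even-odd ray casting, vectorized over points; boundary points are resolved
# arbitrarily (callers needing a deterministic edge rule nudge the query
# point; see zone_assign()).
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  if (n < 3L) return(inside)
  x <- ring[, 1L]; y <- ring[, 2L]
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) / (yj - yi) * (xj - xi)
      hit <- px[crosses] < xint
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
    j <- i
  }
  inside
}

points_in_polygon <- function(px, py, poly) {
  inside <- logical(length(px))
  for (ring in poly) inside <- xor(inside, points_in_ring(px, py, ring))
  inside
}

points_in_multipolygon <- function(px, py, mp) {
  inside <- logical(length(px))
  for (poly in mp) inside <- xor(inside, points_in_polygon(px, py, poly))
  inside
}

# Min distance from each point to a polyline segment (x1,y1)-(x2,y2).
dist_points_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / l2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

ring_edges <- function(ring) {
  n <- nrow(ring)
  cbind(ring, ring[c(2:n, 1L), , drop = FALSE])
}

# Distance from each point to the boundary of a polygon (all rings).
dist_points_polygon_boundary <- function(px, py, poly) {
  d <- rep(Inf, length(px))
  for (ring in poly) {
    e <- ring_edges(ring)
    for (k in seq_len(nrow(e))) {
      d <- pmin(d, dist_points_segment(px, py,
                                       e[k, 1L], e[k, 2L], e[k, 3L], e[k, 4L]))
    }
  }
  d
}

# Distance to a union of polygons: 0 inside the union, else Euclidean
# distance to the nearest boundary. This is the exact distance field whose
# sublevel set at r is the r-buffer of the union. With a finite `cap`, the
# exact distance is only computed for points within `cap` of a polygon's
# bounding box; farther points get the bounding-box distance, a lower bound
# on the true distance, so every value <= cap is exact and values > cap are
# guaranteed above the true cap threshold.
dist_points_polygons <- function(px, py, polys, cap = Inf) {
  d <- rep(Inf, length(px))
  inside <- logical(length(px))
  for (poly in polys) {
    bb <- polygon_bbox(poly)
    dxb <- pmax(bb["xmin"] - px, px - bb["xmax"], 0)
    dyb <- pmax(bb["ymin"] - py, py - bb["ymax"], 0)
    bbox_d <- sqrt(dxb * dxb + dyb * dyb)
    near <- which(bbox_d <= cap)
    if (length(near)) {
      inside[near] <- inside[near] |
        points_in_polygon(px[near], py[near], poly)
      d[near] <- pmin(d[near],
                      dist_points_polygon_boundary(px[near], py[near], poly))
    }
    far <- which(bbox_d > cap)
    if (length(far)) d[far] <- pmin(d[far], bbox_d[far])
  }
  d[inside] <- 0
  d
}

# Sutherland-Hodgman step: clip a ring to the half-plane a*x + b*y <= c.
clip_ring_halfplane <- function(ring, a, b, c) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  val <- a * ring[, 1L] + b * ring[, 2L] - c
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- val[i]; vj <- val[j]
    if (vi <= 0) {
      keep_x <- c(keep_x, ring[i, 1L]); keep_y <- c(keep_y, ring[i, 2L])
    }
    if ((vi < 0 && vj > 0) || (vi > 0 && vj < 0)) {
      t <- vi / (vi - vj)
      keep_x <- c(keep_x, ring[i, 1L] + t * (ring[j, 1L] - ring[i, 1L]))
      keep_y <- c(keep_y, ring[i, 2L] + t * (ring[j, 2L] - ring[i, 2L]))
    }
  }
  as_ring(cbind(keep_x, keep_y))
}

clip_ring_rect <- function(ring, xmin, ymin, xmax, ymax) {
  r <- ring
  r <- clip_ring_halfplane(r, -1, 0, -xmin)
  if (nrow(r) < 3L) return(r[0, , drop = FALSE])
  r <- clip_ring_halfplane(r, 1, 0, xmax)
  if (nrow(r) < 3L) return(r[0, , drop = FALSE])
  r <- clip_ring_halfplane(r, 0, -1, -ymin)
  if (nrow(r) < 3L) return(r[0, , drop = FALSE])
  r <- clip_ring_halfplane(r, 0, 1, ymax)
  if (nrow(r) < 3L) return(r[0, , drop = FALSE])
  r
}

is_convex_ring <- function(ring, tol = 1e-9) {
  n <- nrow(ring)
  if (n < 4L) return(TRUE)
  x <- ring[, 1L]; y <- ring[, 2L]
  xp <- c(x[-1L], x[1L]); yp <- c(y[-1L], y[1L])
  xpp <- c(xp[-1L], xp[1L]); ypp <- c(yp[-1L], yp[1L])
  cross <- (xp - x) * (ypp - yp) - (yp - y) * (xpp - xp)
  scale <- max(abs(cross))
  if (scale == 0) return(TRUE)
  signs <- sign(cross[abs(cross) > tol * scale])
  length(unique(signs)) <= 1L
}

# Intersection area of two convex rings via Sutherland-Hodgman.
convex_intersection_area <- function(ring_a, ring_b) {
  r <- ring_a
  if (ring_signed_area(ring_b) < 0) ring_b <- ring_b[rev(seq_len(nrow(ring_b))), ]
  e <- ring_edges(ring_b)
  for (k in seq_len(nrow(e))) {
    # interior of a CCW ring lies to the left of each edge
    dx <- e[k, 3L] - e[k, 1L]; dy <- e[k, 4L] - e[k, 2L]
    # half-plane: -dy*x + dx*y <= -dy*x1 + dx*y1  keeps the left side... sign:
    a <- dy; b <- -dx; c <- dy * e[k, 1L] - dx * e[k, 2L]
    r <- clip_ring_halfplane(r, a, b, c)
    if (nrow(r) < 3L) return(0)
  }
  ring_area(r)
}

# TRUE where segment p1-p2 and q1-q2 cross at interior points of both.
segments_cross <- function(p1, p2, q1, q2, tol = 1e-12) {
  d1 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
  d2 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
  d3 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
  d4 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
  s <- max(abs(c(d1, d2, d3, d4)), 1)
  (d1 / s) * (d2 / s) < -tol && (d3 / s) * (d4 / s) < -tol
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4L) return(FALSE)
  e <- ring_edges(ring)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (shared vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(e[i, 1:2], e[i, 3:4], e[j, 1:2], e[j, 3:4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

polygon_is_valid <- function(poly) {
  for (ring in poly) {
    if (nrow(ring) < 3L) return(FALSE)
    if (ring_area(ring) <= 0) return(FALSE)
    if (ring_self_intersects(ring)) return(FALSE)
  }
  TRUE
}

# Width of a convex-hull region along its narrowest direction (rotating
# calipers over hull edges). Used to detect sliver zones.
polygon_min_width <- function(poly) {
  pts <- do.call(rbind, poly)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  if (n < 3L) return(0)
  w <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    dx <- hull[j, 1L] - hull[i, 1L]; dy <- hull[j, 2L] - hull[i, 2L]
    len <- sqrt(dx * dx + dy * dy)
    if (len == 0) next
    # distance of all hull points from the edge's supporting line
    d <- abs((hull[, 1L] - hull[i, 1L]) * dy -
               (hull[, 2L] - hull[i, 2L]) * dx) / len
    w <- min(w, max(d))
  }
  w
}

# Bounded Voronoi tessellation: each cell is the intersection of the extent
# rectangle with the half-planes nearer its seed than any other seed.
voronoi_cells <- function(seeds, extent) {
  n <- nrow(seeds)
  rect <- as_ring(rbind(
    c(extent["xmin"], extent["ymin"]),
    c(extent["xmax"], extent["ymin"]),
    c(extent["xmax"], extent["ymax"]),
    c(extent["xmin"], extent["ymax"])
  ))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    ring <- rect
    for (j in seq_len(n)) {
      if (i == j) next
      a <- seeds[j, 1L] - seeds[i, 1L]
      b <- seeds[j, 2L] - seeds[i, 2L]
      c_ <- (seeds[j, 1L]^2 + seeds[j, 2L]^2 -
               seeds[i, 1L]^2 - seeds[i, 2L]^2) / 2
      ring <- clip_ring_halfplane(ring, a, b, c_)
      if (nrow(ring) < 3L) break
    }
    cells[[i]] <- ring
  }
  cells
}

# Marching-squares extraction of the multipolygon {field <= level}. `z` is an
# n_x x n_y matrix over ascending grid vectors `xs`, `ys`. The grid must
# extend past the region so every contour closes. Holes are detected by
# even-odd nesting and attached to their smallest enclosing outer ring.
contour_multipolygon <- function(xs, ys, z, level) {
  cl <- grDevices::contourLines(xs, ys, z, levels = level)
  if (length(cl) == 0L) return(list())
  rings <- lapply(cl, function(l) as_ring(cbind(l$x, l$y)))
  rings <- rings[vapply(rings, nrow, integer(1)) >= 3L]
  if (length(rings) == 0L) return(list())
  m <- length(rings)
  depth <- integer(m)
  parent <- rep(NA_integer_, m)
  areas <- vapply(rings, ring_area, numeric(1))
  for (i in seq_len(m)) {
    p <- rings[[i]][1L, ]
    enclosing <- integer(0)
    for (j in seq_len(m)) {
      if (i == j) next
      if (points_in_ring(p[1L], p[2L], rings[[j]])) enclosing <- c(enclosing, j)
    }
    depth[i] <- length(enclosing)
    if (depth[i] %% 2L == 1L) {
      # hole: parent is the smallest enclosing ring
      parent[i] <- enclosing[which.min(areas[enclosing])]
    }
  }
  outers <- which(depth %% 2L == 0L)
  lapply(outers, function(o) {
    holes <- which(!is.na(parent) & parent == o)
    c(rings[o], rings[holes])
  })
}
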
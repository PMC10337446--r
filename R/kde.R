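# Quartic kernel density surface -----------------------------------------

#' Frame the evaluation grid for a participant's density surface
#'
#' The grid covers the events' bounding box padded by one bandwidth on every
#' side (so the kernel support of every event lies inside the grid), with
#' the lower-left origin snapped down to a multiple of the cell size.
#' Density is evaluated at cell centers.
#'
#' @param events An `"ema_events"` data frame with at least one event.
#' @param bandwidth_ft Kernel bandwidth \eqn{\tau}, feet.
#' @param cell_size_ft Cell side length, feet.
#' @return An empty `"density_raster"` (all zeros) spanning the padded
#'   extent.
#' @export
make_grid <- function(events, bandwidth_ft = 1320, cell_size_ft = 150) {
  events <- as.data.frame(events)
  if (nrow(events) == 0L) {
    stop("no events: skip this participant", call. = FALSE)
  }
  stopifnot(bandwidth_ft > 0, cell_size_ft > 0)
  x0 <- floor((min(events$x) - bandwidth_ft) / cell_size_ft) * cell_size_ft
  y0 <- floor((min(events$y) - bandwidth_ft) / cell_size_ft) * cell_size_ft
  n_cols <- ceiling((max(events$x) + bandwidth_ft - x0) / cell_size_ft)
  n_rows <- ceiling((max(events$y) + bandwidth_ft - y0) / cell_size_ft)
  density_raster(x0, y0, cell_size_ft,
                 matrix(0, nrow = n_rows, ncol = n_cols))
}

# Quartic (biweight) kernel: 3/(pi tau^2) (1 - d^2/tau^2)^2 for d < tau,
# zero beyond. Integrates to 1 over the plane, so the surface integrates to
# the number of events.
quartic_weight <- function(d, tau) {
  w <- numeric(length(d))
  inside <- d < tau
  u <- d[inside] / tau
  w[inside] <- 3 / (pi * tau^2) * (1 - u^2)^2
  w
}

#' Kernel density surface of smoking events
#'
#' Evaluates, at every grid-cell center \eqn{g}, the sum over smoking events
#' \eqn{i} within the bandwidth of a compact-support quartic kernel:
#' \deqn{\lambda(g) = \sum_{d_{ig} < \tau} \frac{3}{\pi\tau^2}
#'   \left(1 - \frac{d_{ig}^2}{\tau^2}\right)^2,}
#' where \eqn{d_{ig}} is the Euclidean distance from \eqn{g} to event
#' \eqn{i} and \eqn{\tau} the bandwidth. The weight is exactly zero at
#' distance \eqn{\tau} and beyond. Units are events per square foot; the
#' downstream min-max normalization makes absolute scaling irrelevant.
#'
#' Evaluation is event-by-event over the sub-grid each event can reach
#' (cells within \eqn{\tau}), which is ample for EMA-scale inputs of a few
#' hundred events.
#'
#' @param events Smoking-kind events (`"ema_events"`); nonsmoking rows are an
#'   error, filter first.
#' @param grid A `"density_raster"` from [make_grid()] (values ignored).
#' @param bandwidth_ft Bandwidth \eqn{\tau}, feet.
#' @return The grid with `values` filled in.
#' @examples
#' ev <- ema_events("p1", "2016-10-01T18:00:00Z", 0, 0, "smoking")
#' r <- kde_surface(ev, make_grid(ev, 1320, 150))
#' max(r$values) <= 3 / (pi * 1320^2)
#' @export
kde_surface <- function(events, grid, bandwidth_ft = 1320) {
  events <- as.data.frame(events)
  if (any(events$kind != "smoking")) {
    stop("kde_surface expects smoking events only", call. = FALSE)
  }
  stopifnot(inherits(grid, "density_raster"), bandwidth_ft > 0)
  tau <- bandwidth_ft
  cs <- grid$cell_size
  xs <- raster_xs(grid)
  ys <- raster_ys(grid)
  vals <- matrix(0, nrow = grid$n_rows, ncol = grid$n_cols)
  for (i in seq_len(nrow(events))) {
    ex <- events$x[i]; ey <- events$y[i]
    ci <- which(abs(xs - ex) < tau)
    ri <- which(abs(ys - ey) < tau)
    if (!length(ci) || !length(ri)) next
    dx2 <- (xs[ci] - ex)^2
    dy2 <- (ys[ri] - ey)^2
    d2 <- outer(dy2, dx2, `+`)
    w <- matrix(0, nrow = length(ri), ncol = length(ci))
    inside <- d2 < tau^2
    w[inside] <- 3 / (pi * tau^2) * (1 - d2[inside] / tau^2)^2
    vals[ri, ci] <- vals[ri, ci] + w
  }
  density_raster(grid$x_origin, grid$y_origin, cs, vals)
}
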
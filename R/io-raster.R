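# Density rasters and Esri ASCII grid I/O --------------------------------

#' Construct a density raster
#'
#' A regular square-celled grid of kernel density values. Values are stored
#' as an `n_rows x n_cols` matrix with row 1 the *southernmost* row; the
#' value at `[r, c]` refers to the cell whose center is at
#' `(x_origin + (c - 0.5) * cell_size, y_origin + (r - 0.5) * cell_size)`.
#' Densities are in events per square foot.
#'
#' @param x_origin,y_origin Lower-left corner of the grid, US feet.
#' @param cell_size Cell side length, US feet.
#' @param values Numeric matrix of densities (rows south to north).
#' @return An object of class `"density_raster"`.
#' @export
density_raster <- function(x_origin, y_origin, cell_size, values) {
  stopifnot(is.matrix(values), cell_size > 0,
            all(is.na(values) | is.finite(values)),
            all(values >= 0, na.rm = TRUE))
  structure(list(
    x_origin = as.numeric(x_origin),
    y_origin = as.numeric(y_origin),
    cell_size = as.numeric(cell_size),
    n_rows = nrow(values),
    n_cols = ncol(values),
    values = values
  ), class = "density_raster")
}

# Cell-center coordinate vectors, ascending.
raster_xs <- function(r) r$x_origin + (seq_len(r$n_cols) - 0.5) * r$cell_size
raster_ys <- function(r) r$y_origin + (seq_len(r$n_rows) - 0.5) * r$cell_size

#' Read and write density rasters as Esri ASCII grids
#'
#' The plain-text `.asc` format: a six-line header
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`) followed by rows
#' of values north to south.
#'
#' @param path Path to an `.asc` file.
#' @param raster A `"density_raster"`.
#' @param nodata Value written for missing cells.
#' @return `read_asc` returns a `"density_raster"`; `write_asc` returns
#'   `path` invisibly.
#' @export
write_asc <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "density_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", raster$n_cols),
    sprintf("nrows %d", raster$n_rows),
    sprintf("xllcorner %.10g", raster$x_origin),
    sprintf("yllcorner %.10g", raster$y_origin),
    sprintf("cellsize %.10g", raster$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  # rows written north to south
  for (r in rev(seq_len(raster$n_rows))) {
    row <- raster$values[r, ]
    row[is.na(row)] <- nodata
    writeLines(paste(format(row, digits = 15, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1L))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2L))
  names(vals) <- keys
  ncols <- as.integer(vals["ncols"]); nrows <- as.integer(vals["nrows"])
  body <- lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  m <- do.call(rbind, body)
  if (nrow(m) != nrows || ncol(m) != ncols) {
    stop("raster body does not match header dimensions", call. = FALSE)
  }
  m[m == vals["nodata_value"]] <- NA_real_
  # stored north to south; flip to south-first rows
  density_raster(vals["xllcorner"], vals["yllcorner"], vals["cellsize"],
                 m[rev(seq_len(nrows)), , drop = FALSE])
}

#' @export
print.density_raster <- function(x, ...) {
  cat(sprintf(
    "Density raster: %d x %d cells of %.4g ft, origin (%.6g, %.6g)\n",
    x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin))
  cat(sprintf("  values in [%.4g, %.4g] events/ft^2\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.density_raster <- function(x, ..., main = "Kernel density surface") {
  graphics::image(raster_xs(x), raster_ys(x), t(x$values), asp = 1,
                  xlab = "x (ft)", ylab = "y (ft)", main = main,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}
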
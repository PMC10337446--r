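# Pipeline configuration -------------------------------------------------

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the geofence pipeline. Defaults are the
#' study parameters: a quartic kernel of bandwidth 1320 ft (0.25 mi, a proxy
#' for comfortable walking distance), 150-ft raster cells, a normalized mean
#' KDE retention threshold of 0.3, 100-m buffers around groups of adjacent
#' high-risk zones, a 5-minute smoking-report deduplication window, 6-decimal
#' rounding of normalized values, and a fixed UTC-to-local offset of -8 hours
#' (Pacific Standard Time).
#'
#' @param bandwidth_ft Kernel bandwidth \eqn{\tau} in US feet; density
#'   contributions are exactly zero at distances \eqn{\ge \tau}.
#' @param cell_size_ft Side length of the square density-raster cells, in feet.
#' @param threshold Normalized mean KDE retention threshold in \[0, 1\];
#'   comparison is inclusive (`norm >= threshold`).
#' @param buffer_m Geofence buffer distance around selected zones, in meters.
#' @param dedup_window_min Smoking reports closer than this many minutes to the
#'   most recently retained smoking report are dropped as double reports.
#' @param normalization_decimals Decimal places kept when rounding normalized
#'   mean KDE values.
#' @param utc_offset_hours Signed hours added to UTC to obtain local time.
#'   A fixed offset, not a tz database: daylight-saving handling is the
#'   caller's responsibility.
#' @param ft_per_m Feet per meter used to convert the buffer distance. The
#'   default is the US survey foot (1 m = 3.28083333 ft), matching NAD83 state
#'   plane feet conventions; set to 3.28083990 for the international foot
#'   (the 0.0006% difference is immaterial at these scales).
#' @param dedup_keep Which member of a burst of near-duplicate smoking reports
#'   survives deduplication; `"first"` (the default) or `"last"`.
#' @param tercile_mode `"rank"` (equal-count terciles of retained zones, the
#'   default) or `"range"` (equal-width value terciles, for choropleth-style
#'   maps).
#' @param contour_cell_ft Grid step, in feet, of the distance field from which
#'   geofence outlines are contoured. Smaller is more accurate and slower;
#'   the default resolves buffer areas well below 0.1% error.
#'
#' @return An object of class `"geofence_config"` (a named list).
#' @examples
#' cfg <- geofence_config()
#' cfg$bandwidth_ft
#' @export
geofence_config <- function(bandwidth_ft = 1320,
                            cell_size_ft = 150,
                            threshold = 0.3,
                            buffer_m = 100,
                            dedup_window_min = 5,
                            normalization_decimals = 6L,
                            utc_offset_hours = -8,
                            ft_per_m = 3.28083333,
                            dedup_keep = c("first", "last"),
                            tercile_mode = c("rank", "range"),
                            contour_cell_ft = 20) {
  dedup_keep <- match.arg(dedup_keep)
  tercile_mode <- match.arg(tercile_mode)
  stopifnot(
    is.numeric(bandwidth_ft), length(bandwidth_ft) == 1L, bandwidth_ft > 0,
    is.numeric(cell_size_ft), length(cell_size_ft) == 1L, cell_size_ft > 0,
    is.numeric(threshold), length(threshold) == 1L,
    threshold >= 0, threshold <= 1,
    is.numeric(buffer_m), length(buffer_m) == 1L, buffer_m > 0,
    is.numeric(dedup_window_min), length(dedup_window_min) == 1L,
    dedup_window_min > 0,
    is.numeric(normalization_decimals), length(normalization_decimals) == 1L,
    normalization_decimals >= 0,
    is.numeric(utc_offset_hours), length(utc_offset_hours) == 1L,
    is.numeric(ft_per_m), ft_per_m > 0,
    is.numeric(contour_cell_ft), contour_cell_ft > 0
  )
  structure(list(
    bandwidth_ft = as.numeric(bandwidth_ft),
    cell_size_ft = as.numeric(cell_size_ft),
    threshold = as.numeric(threshold),
    buffer_m = as.numeric(buffer_m),
    dedup_window_min = as.numeric(dedup_window_min),
    normalization_decimals = as.integer(normalization_decimals),
    utc_offset_hours = as.numeric(utc_offset_hours),
    ft_per_m = as.numeric(ft_per_m),
    dedup_keep = dedup_keep,
    tercile_mode = tercile_mode,
    contour_cell_ft = as.numeric(contour_cell_ft)
  ), class = "geofence_config")
}

#' Read or write a pipeline configuration as JSON
#'
#' The JSON file mirrors the field names of [geofence_config()]; missing
#' fields take their defaults, unknown fields are an error.
#'
#' @param path Path to a JSON configuration file.
#' @return `read_config` returns a `"geofence_config"`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(geofence_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(geofence_config, raw)
}

#' @rdname read_config
#' @param config A `"geofence_config"` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "geofence_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.geofence_config <- function(x, ...) {
  cat("Geofence pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# buffer distance in feet
buffer_ft <- function(config) config$buffer_m * config$ft_per_m
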
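# EMA event tables -------------------------------------------------------

EVENT_KINDS <- c("smoking", "nonsmoking")

#' Construct a validated EMA event table
#'
#' An event table is a plain `data.frame` with one row per GPS- and
#' time-stamped self-report and columns `participant_id`, `timestamp_utc`
#' (POSIXct, UTC), `x`, `y` (planar coordinates in US feet) and `kind`
#' (`"smoking"` or `"nonsmoking"`). Coordinates are consumed already
#' projected to a planar feet system (e.g. NAD83 California Zone 3 US feet);
#' the package performs no geographic reprojection.
#'
#' @param participant_id Character vector of participant identifiers.
#' @param timestamp_utc POSIXct timestamps in UTC (or ISO-8601 strings with a
#'   trailing `Z`).
#' @param x,y Numeric planar coordinates in US feet.
#' @param kind `"smoking"` or `"nonsmoking"` per event.
#' @return A `data.frame` of class `c("ema_events", "data.frame")`.
#' @export
ema_events <- function(participant_id, timestamp_utc, x, y, kind) {
  if (is.character(timestamp_utc)) {
    timestamp_utc <- parse_utc(timestamp_utc)
  }
  df <- data.frame(
    participant_id = as.character(participant_id),
    timestamp_utc = timestamp_utc,
    x = as.numeric(x),
    y = as.numeric(y),
    kind = as.character(kind),
    stringsAsFactors = FALSE
  )
  validate_events(df)
}

parse_utc <- function(s) {
  out <- as.POSIXct(strptime(s, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  # fall back to a space separator for hand-written fixtures
  retry <- is.na(out) & !is.na(s)
  if (any(retry)) {
    out[retry] <- as.POSIXct(strptime(s[retry], "%Y-%m-%d %H:%M:%S",
                                      tz = "UTC"))
  }
  out
}

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' @rdname ema_events
#' @param events A candidate event `data.frame`.
#' @export
validate_events <- function(events) {
  required <- c("participant_id", "timestamp_utc", "x", "y", "kind")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    stop("event table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- list(
    timestamp = which(is.na(events$timestamp_utc)),
    coordinate = which(!is.finite(events$x) | !is.finite(events$y)),
    kind = which(!events$kind %in% EVENT_KINDS)
  )
  msgs <- character(0)
  if (length(bad$timestamp)) {
    msgs <- c(msgs, paste0("unparseable timestamp in row(s) ",
                           paste(bad$timestamp, collapse = ", ")))
  }
  if (length(bad$coordinate)) {
    msgs <- c(msgs, paste0("non-finite coordinate in row(s) ",
                           paste(bad$coordinate, collapse = ", ")))
  }
  if (length(bad$kind)) {
    msgs <- c(msgs, paste0(
      "invalid event kind ",
      paste(unique(events$kind[bad$kind]), collapse = ", "),
      " in row(s) ", paste(bad$kind, collapse = ", "),
      " (must be one of: ", paste(EVENT_KINDS, collapse = ", "), ")"
    ))
  }
  if (length(msgs)) stop(paste(msgs, collapse = "; "), call. = FALSE)
  class(events) <- unique(c("ema_events", class(events)))
  events
}

#' Read and write EMA event tables as CSV
#'
#' The CSV has header `participant_id,timestamp_utc,x,y,kind` with ISO-8601
#' UTC timestamps (trailing `Z`). `read_events` validates every row and
#' reports offending row numbers; `write_events` is its inverse, so the two
#' round-trip valid event tables exactly at whole-second resolution.
#'
#' @param path Path to a CSV file.
#' @return `read_events` returns an `"ema_events"` data frame (possibly with
#'   zero rows); `write_events` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' ev <- ema_events("p1", "2016-10-01T18:00:00Z", 100, 200, "smoking")
#' write_events(ev, f)
#' read_events(f)
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    stop("event file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("participant_id", "timestamp_utc", "x", "y", "kind")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("event CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(validate_empty_events())
  }
  df <- data.frame(
    participant_id = raw$participant_id,
    timestamp_utc = parse_utc(raw$timestamp_utc),
    x = suppressWarnings(as.numeric(raw$x)),
    y = suppressWarnings(as.numeric(raw$y)),
    kind = raw$kind,
    stringsAsFactors = FALSE
  )
  validate_events(df)
}

validate_empty_events <- function() {
  df <- data.frame(
    participant_id = character(0),
    timestamp_utc = as.POSIXct(character(0), tz = "UTC"),
    x = numeric(0), y = numeric(0), kind = character(0),
    stringsAsFactors = FALSE
  )
  class(df) <- unique(c("ema_events", class(df)))
  df
}

#' @rdname read_events
#' @param events An `"ema_events"` data frame.
#' @export
write_events <- function(events, path) {
  events <- validate_events(as.data.frame(events))
  out <- data.frame(
    participant_id = events$participant_id,
    timestamp_utc = format_utc(events$timestamp_utc),
    x = events$x,
    y = events$y,
    kind = events$kind,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
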
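# Event-stream cleaning and time binning ---------------------------------

#' Deduplicate near-simultaneous smoking reports
#'
#' Smoking reports closer than `window_min` minutes to the most recently
#' *retained* smoking report are dropped, correcting for double reporting and
#' app glitches. The scan is greedy in chronological order: with reports at
#' 0, 3 and 6 minutes and a 5-minute window, 0 and 6 survive (3 is within 5
#' minutes of retained 0; 6 is not). Nonsmoking reports are never dropped.
#' Timestamp ties are broken by input order.
#'
#' @param events An `"ema_events"` data frame for a single participant.
#' @param window_min Deduplication window in minutes (default 5).
#' @param keep Which member of a duplicate burst survives: `"first"`
#'   (default; the greedy scan runs forward in time) or `"last"` (the scan
#'   runs backward, for sensitivity checks).
#' @return The retained events, chronologically sorted, with attribute
#'   `n_dropped` giving the number of discarded smoking reports.
#' @examples
#' ev <- ema_events("p1",
#'   c("2016-10-01T08:00:00Z", "2016-10-01T08:03:00Z", "2016-10-01T08:06:00Z"),
#'   x = c(0, 0, 0), y = c(0, 0, 0), kind = rep("smoking", 3))
#' dedupe_smoking(ev)  # keeps 08:00 and 08:06
#' @export
dedupe_smoking <- function(events, window_min = 5, keep = c("first", "last")) {
  keep <- match.arg(keep)
  events <- validate_events(as.data.frame(events))
  if (!is.numeric(window_min) || length(window_min) != 1L || window_min <= 0) {
    stop("window_min must be a positive number of minutes", call. = FALSE)
  }
  if (length(unique(events$participant_id)) > 1L) {
    stop("dedupe_smoking expects events of a single participant",
         call. = FALSE)
  }
  ord <- order(events$timestamp_utc)  # stable: ties keep input order
  events <- events[ord, , drop = FALSE]
  smoking <- which(events$kind == "smoking")
  drop <- logical(nrow(events))
  idx <- if (keep == "first") smoking else rev(smoking)
  last_kept <- NA_real_
  for (i in idx) {
    t <- as.numeric(events$timestamp_utc[i])
    if (!is.na(last_kept) && abs(t - last_kept) < window_min * 60) {
      drop[i] <- TRUE
    } else {
      last_kept <- t
    }
  }
  out <- events[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  if (any(drop)) {
    sf_log("dropped %d smoking report(s) within %.3g min of a retained one",
           sum(drop), window_min)
  }
  out
}

#' Convert to local time and assign 3-hour bins
#'
#' Local time is UTC plus a fixed configured offset (no tz database, no
#' daylight-saving logic). The local day is partitioned into eight
#' half-open 3-hour bins `[0,3), [3,6), ..., [21,24)`; bin index
#' `floor(local_hour / 3)` runs 0-7.
#'
#' @param events An `"ema_events"` data frame.
#' @param utc_offset_hours Signed hours added to UTC (e.g. -8 for Pacific
#'   Standard Time).
#' @return The events with added columns `local_timestamp` (POSIXct, still
#'   labelled UTC but shifted by the offset), `bin_index` (0-7) and
#'   `bin_start_hour` (0, 3, ..., 21).
#' @export
assign_bins <- function(events, utc_offset_hours) {
  events <- validate_events(as.data.frame(events))
  stopifnot(is.numeric(utc_offset_hours), length(utc_offset_hours) == 1L)
  local <- events$timestamp_utc + utc_offset_hours * 3600
  hour <- as.numeric(format(local, "%H", tz = "UTC")) +
    as.numeric(format(local, "%M", tz = "UTC")) / 60 +
    as.numeric(format(local, "%S", tz = "UTC")) / 3600
  events$local_timestamp <- local
  events$bin_index <- as.integer(hour %/% 3)
  events$bin_start_hour <- events$bin_index * 3L
  events
}

#' Labels of the eight 3-hour bins
#'
#' @return Character vector of length 8, e.g. `"00:00-02:59"`.
#' @export
bin_labels <- function() {
  sprintf("%02d:00-%02d:59", seq(0, 21, by = 3), seq(2, 23, by = 3))
}
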
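# Shared fixtures and independent oracles --------------------------------

# Events at given minute offsets from a fixed origin instant.
mk_events <- function(min_offsets, kinds = "smoking",
                      x = 0, y = 0, pid = "p1",
                      origin = "2016-10-01T08:00:00Z") {
  t0 <- as.POSIXct(strptime(origin, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  n <- length(min_offsets)
  ema_events(
    participant_id = rep_len(pid, n),
    timestamp_utc = t0 + min_offsets * 60,
    x = rep_len(x, n), y = rep_len(y, n),
    kind = rep_len(kinds, n)
  )
}

# Events at fixed planar positions, all in one bin (18:00 UTC = 10:00 PST).
mk_spatial_events <- function(x, y, kinds = "smoking", pid = "p1") {
  n <- length(x)
  ema_events(
    participant_id = rep_len(pid, n),
    timestamp_utc = as.POSIXct("2016-10-01 18:00:00", tz = "UTC") +
      seq_len(n) * 600,
    x = x, y = y, kind = rep_len(kinds, n)
  )
}

# minutes of each event past the fixture origin instant
event_minutes <- function(ev, origin = "2016-10-01T08:00:00Z") {
  t0 <- as.POSIXct(strptime(origin, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  (as.numeric(ev$timestamp_utc) - as.numeric(t0)) / 60
}

square_ring <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0),
        c(x0 + side, y0 + side), c(x0, y0 + side))
}

# Independent brute-force KDE oracle: plain double loop over cells and
# events with the quartic closed form, no shared code with kde_surface().
kde_brute_force <- function(events, grid, tau) {
  xs <- grid$x_origin + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  ys <- grid$y_origin + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) {
    for (c_ in seq_len(grid$n_cols)) {
      d <- sqrt((events$x - xs[c_])^2 + (events$y - ys[r])^2)
      w <- ifelse(d < tau, 3 / (pi * tau^2) * (1 - (d / tau)^2)^2, 0)
      vals[r, c_] <- sum(w)
    }
  }
  vals
}

# Brute-force deduplication oracle: enumerate all subsets of the smoking
# events and find the (unique) one where retained events are pairwise >=
# window apart and every dropped event follows a retained one within the
# window. Independent of the greedy scan.
dedupe_oracle <- function(times_min, window_min) {
  n <- length(times_min)
  valid <- list()
  for (mask in 0:(2^n - 1)) {
    keep <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    kept <- times_min[keep]
    if (length(kept) >= 2 && any(diff(sort(kept)) < window_min)) next
    dropped <- times_min[!keep]
    ok <- all(vapply(dropped, function(t) {
      any(kept <= t & t - kept < window_min)
    }, logical(1)))
    if (ok) valid[[length(valid) + 1L]] <- sort(kept)
  }
  valid
}

# Equal-count tercile sizes by enumeration: the unique non-increasing
# triple of sizes differing by at most one.
tercile_sizes_oracle <- function(n) {
  for (s1 in 0:n) for (s2 in 0:n) {
    s3 <- n - s1 - s2
    if (s3 < 0) next
    if (s1 >= s2 && s2 >= s3 && s1 - s3 <= 1) return(c(s1, s2, s3))
  }
  stop("no valid split")
}
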
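# Synthetic EMA-stream generator -----------------------------------------
#
# Emulates the statistical structure the pipeline assumes: over an n-day
# study window, a participant self-reports smoking events clustered around a
# few anchor locations (home, workplace, a bar ...) with time-of-day
# profiles, plus a spatially "dispersed" regime where a share of events is
# scattered uniformly over the study extent; nonsmoking reports come from at
# most three daily random surveys. Occasional duplicate smoking reports less
# than five minutes apart are injected to exercise deduplication.

#' Define a synthetic participant profile
#'
#' @param participant_id Identifier string.
#' @param anchors List of anchors, each `list(x =, y =, scatter_sd =,
#'   weights =)`: planar location (feet), isotropic Gaussian scatter SD
#'   (feet), and an 8-vector of relative weights giving P(anchor | bin);
#'   weights are normalized so that, per bin, anchor weights sum to 1.
#' @param bin_weights 8-vector of relative probabilities of the 3-hour bins
#'   (the participant's time-of-day smoking profile); normalized to sum 1.
#'   Default: a waking-hours profile peaking in the evening.
#' @param smoking_events_per_day Mean daily smoking reports (Poisson).
#' @param nonsmoking_surveys_per_day Mean daily nonsmoking reports; realized
#'   counts are capped at 3 per day (the survey burden cap).
#' @param dispersion Probability in \[0, 1\] that an event is drawn uniformly
#'   over the extent instead of from an anchor.
#' @param duplicate_rate Probability a smoking report spawns a duplicate
#'   under 5 minutes later (double-report artifact).
#' @param n_days Study length in days (default 30).
#' @param extent Named `c(xmin=, ymin=, xmax=, ymax=)` study extent, feet.
#' @param utc_offset_hours Local-time offset used to emit UTC timestamps.
#' @param start_date Local calendar date of day 1 (`"YYYY-MM-DD"`).
#' @param rng_seed Integer seed; generation is deterministic given it.
#' @return A `"participant_profile"` list.
#' @export
participant_profile <- function(participant_id,
                                anchors,
                                bin_weights = c(2, 1, 2, 4, 5, 6, 8, 5),
                                smoking_events_per_day = 1,
                                nonsmoking_surveys_per_day = 1,
                                dispersion = 0,
                                duplicate_rate = 0.04,
                                n_days = 30L,
                                extent = c(xmin = 0, ymin = 0,
                                           xmax = 20000, ymax = 20000),
                                utc_offset_hours = -8,
                                start_date = "2016-10-01",
                                rng_seed = 1L) {
  stopifnot(length(anchors) >= 1L,
            smoking_events_per_day >= 0, nonsmoking_surveys_per_day >= 0,
            dispersion >= 0, dispersion <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            n_days >= 1, length(bin_weights) == 8L, all(bin_weights >= 0),
            sum(bin_weights) > 0)
  anchors <- lapply(anchors, function(a) {
    stopifnot(is.numeric(a$x), is.numeric(a$y), a$scatter_sd > 0,
              length(a$weights) == 8L, all(a$weights >= 0))
    a
  })
  # normalize anchor weights per bin: columns over anchors sum to 1
  w <- do.call(rbind, lapply(anchors, function(a) a$weights))
  colsum <- colSums(w)
  colsum[colsum == 0] <- 1
  w <- sweep(w, 2L, colsum, "/")
  for (i in seq_along(anchors)) anchors[[i]]$weights <- w[i, ]
  structure(list(
    participant_id = as.character(participant_id),
    anchors = anchors,
    bin_weights = bin_weights / sum(bin_weights),
    smoking_events_per_day = smoking_events_per_day,
    nonsmoking_surveys_per_day = nonsmoking_surveys_per_day,
    dispersion = dispersion,
    duplicate_rate = duplicate_rate,
    n_days = as.integer(n_days),
    extent = extent,
    utc_offset_hours = utc_offset_hours,
    start_date = start_date,
    rng_seed = as.integer(rng_seed)
  ), class = "participant_profile")
}

# Draw one location: anchor Gaussian (redrawn into the extent) or uniform
# background.
draw_location <- function(profile, bin) {
  if (stats::runif(1) < profile$dispersion) {
    return(c(stats::runif(1, profile$extent["xmin"], profile$extent["xmax"]),
             stats::runif(1, profile$extent["ymin"], profile$extent["ymax"])))
  }
  p_anchor <- vapply(profile$anchors, function(a) a$weights[bin + 1L],
                     numeric(1))
  if (sum(p_anchor) == 0) p_anchor <- rep(1, length(p_anchor))
  a <- profile$anchors[[sample.int(length(p_anchor), 1L, prob = p_anchor)]]
  for (k in 1:100) {
    pt <- c(stats::rnorm(1, a$x, a$scatter_sd),
            stats::rnorm(1, a$y, a$scatter_sd))
    if (pt[1] >= profile$extent["xmin"] && pt[1] <= profile$extent["xmax"] &&
        pt[2] >= profile$extent["ymin"] && pt[2] <= profile$extent["ymax"]) {
      return(pt)
    }
  }
  c(min(max(pt[1], profile$extent["xmin"]), profile$extent["xmax"]),
    min(max(pt[2], profile$extent["ymin"]), profile$extent["ymax"]))
}

#' Generate a synthetic participant's EMA event stream
#'
#' Per day, the smoking-report count is Poisson at the profile rate and the
#' nonsmoking count is Poisson capped at 3; each event samples a 3-hour bin
#' from the time-of-day profile, a uniform second within the bin, and a
#' location (anchor scatter or uniform background, see
#' [participant_profile()]). With probability `duplicate_rate` a smoking
#' report spawns a duplicate under 5 minutes later to exercise
#' deduplication. Deterministic given `rng_seed`.
#'
#' @param profile A `"participant_profile"`.
#' @return An `"ema_events"` data frame, chronologically sorted, with
#'   attribute `n_base_smoking` (smoking events before duplicate injection).
#' @export
gen_participant <- function(profile) {
  stopifnot(inherits(profile, "participant_profile"))
  with_seed(profile$rng_seed, {
    day0 <- as.POSIXct(paste0(profile$start_date, " 00:00:00"), tz = "UTC")
    rows <- list()
    n_base <- 0L
    for (day in seq_len(profile$n_days)) {
      n_smoke <- stats::rpois(1, profile$smoking_events_per_day)
      n_non <- min(stats::rpois(1, profile$nonsmoking_surveys_per_day), 3L)
      for (kind in c("smoking", "nonsmoking")) {
        n <- if (kind == "smoking") n_smoke else n_non
        for (e in seq_len(n)) {
          bin <- sample.int(8L, 1L, prob = profile$bin_weights) - 1L
          sec <- floor(stats::runif(1, 0, 3 * 3600))
          local <- day0 + (day - 1) * 86400 + bin * 10800 + sec
          utc <- local - profile$utc_offset_hours * 3600
          pt <- draw_location(profile, bin)
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = profile$participant_id,
            timestamp_utc = utc, x = pt[1], y = pt[2], kind = kind,
            stringsAsFactors = FALSE)
          if (kind == "smoking") {
            n_base <- n_base + 1L
            if (stats::runif(1) < profile$duplicate_rate) {
              # double report: same place, under 5 minutes later
              rows[[length(rows) + 1L]] <- data.frame(
                participant_id = profile$participant_id,
                timestamp_utc = utc + floor(stats::runif(1, 10, 290)),
                x = pt[1], y = pt[2], kind = "smoking",
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    if (length(rows) == 0L) return(validate_empty_events())
    ev <- do.call(rbind, rows)
    ev <- ev[order(ev$timestamp_utc), , drop = FALSE]
    rownames(ev) <- NULL
    ev <- validate_events(ev)
    attr(ev, "n_base_smoking") <- n_base
    ev
  })
}

#' Generate the four-case synthetic study suite
#'
#' Builds four synthetic participants spanning EMA-compliance quartiles,
#' calibrated to the study's case summary: daily rates are the per-case
#' 30-day totals (16/8, 12/47, 31/67, 177/61 smoking/nonsmoking) divided by
#' 30, and a stream is redrawn (deterministic sub-seed sequence) until its
#' realized totals fall in the case range of 12-177 smoking and 8-67
#' nonsmoking events. Three cases are anchor-concentrated; the fourth
#' ("q100", the heaviest smoker) is spatially dispersed, with most events
#' scattered uniformly so that roughly two zones hold ~42% of its events.
#' Also emits the three zone partitions covering the common extent: a
#' 500-ft fishnet, a 1000-ft fishnet and a Voronoi pseudo-block partition
#' (with sliver corridors to exercise the rasterization-failure path).
#'
#' @param seed Integer master seed.
#' @param n_blocks Number of Voronoi seeds for the pseudo-block partition.
#' @param sliver_fraction Fraction of pseudo-blocks split by a sliver
#'   corridor.
#' @return A list with `participants` (named list of `"ema_events"`),
#'   `profiles`, `partitions` (named list: `blocks`, `fishnet_500`,
#'   `fishnet_1000`) and `extent`.
#' @examples
#' \donttest{
#' suite <- gen_case_suite(seed = 7)
#' sapply(suite$participants, nrow)
#' }
#' @export
gen_case_suite <- function(seed = 7L, n_blocks = 40L, sliver_fraction = 0.2) {
  extent <- c(xmin = 0, ymin = 0, xmax = 20000, ymax = 20000)
  mk_anchor <- function(x, y, sd, w) list(x = x, y = y, scatter_sd = sd,
                                          weights = w)
  day <- c(0, 0, 1, 2, 2, 1, 0.5, 0.2)   # daytime anchor (work)
  eve <- c(2, 1, 0.5, 0.5, 1, 2, 4, 3)   # evening anchor (home/bar)
  specs <- list(
    q25 = list(rate_s = 16 / 30, rate_n = 8 / 30, dispersion = 0.05,
               anchors = list(mk_anchor(4000, 5000, 200, eve),
                              mk_anchor(7000, 9000, 250, day))),
    q50 = list(rate_s = 12 / 30, rate_n = 47 / 30, dispersion = 0,
               anchors = list(mk_anchor(12000, 13000, 150, eve + day))),
    q75 = list(rate_s = 31 / 30, rate_n = 67 / 30, dispersion = 0.1,
               anchors = list(mk_anchor(15000, 4000, 250, eve),
                              mk_anchor(11000, 6000, 200, day),
                              mk_anchor(16500, 7500, 300, eve))),
    q100 = list(rate_s = 177 / 30, rate_n = 61 / 30, dispersion = 0.58,
                anchors = list(mk_anchor(6000, 15000, 200, eve),
                               mk_anchor(9000, 16500, 200, day)))
  )
  participants <- list()
  profiles <- list()
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    sp <- specs[[i]]
    for (try in 1:50) {
      prof <- participant_profile(
        participant_id = nm,
        anchors = sp$anchors,
        smoking_events_per_day = sp$rate_s,
        nonsmoking_surveys_per_day = sp$rate_n,
        dispersion = sp$dispersion,
        extent = extent,
        rng_seed = child_seed(seed, i * 100 + try)
      )
      ev <- gen_participant(prof)
      n_s <- attr(ev, "n_base_smoking")
      n_n <- sum(ev$kind == "nonsmoking")
      if (n_s >= 12 && n_s <= 177 && n_n >= 8 && n_n <= 67) break
    }
    participants[[nm]] <- ev
    profiles[[nm]] <- prof
  }
  partitions <- list(
    blocks = make_pseudo_blocks(extent, n_seeds = n_blocks,
                                rng_seed = child_seed(seed, 9001),
                                sliver_fraction = sliver_fraction),
    fishnet_500 = make_fishnet(extent, 500),
    fishnet_1000 = make_fishnet(extent, 1000)
  )
  list(participants = participants, profiles = profiles,
       partitions = partitions, extent = extent)
}
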
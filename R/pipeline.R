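# End-to-end pipeline with file interfaces -------------------------------

#' Run the full geofence pipeline from files
#'
#' Chains the stages end to end for one participant's event CSV against one
#' or more partition GeoJSONs: preprocess (dedup + binning), kernel density
#' surface, zonal risk tables, per-bin geofences, capture reports, the
#' 0.1-0.9 threshold sweep, and (given several partitions) the partition
#' comparison. Every stage output is written to `out_dir` in the documented
#' plain-text formats, plus a JSON run manifest with file digests and
#' counts; stages communicate only through these files, so any stage can be
#' inspected or swapped.
#'
#' @param config A [geofence_config()].
#' @param events_path CSV of EMA events for one participant.
#' @param partition_paths Named character vector of partition GeoJSON paths
#'   (names label the partitions in outputs).
#' @param out_dir Output directory, created if needed.
#' @return The run manifest (a list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, events_path, partition_paths, out_dir) {
  stopifnot(inherits(config, "geofence_config"), length(partition_paths) >= 1)
  if (is.null(names(partition_paths)) || any(!nzchar(names(partition_paths)))) {
    names(partition_paths) <- paste0("partition_", seq_along(partition_paths))
  }
  for (p in c(events_path, partition_paths)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  events <- read_events(events_path)
  pid <- unique(events$participant_id)
  if (length(pid) != 1L) {
    stop("pipeline expects a single-participant event file", call. = FALSE)
  }
  outputs <- character(0)
  stage_counts <- list(n_events_in = nrow(events))

  fits <- list()
  reports <- list()
  for (nm in names(partition_paths)) {
    partition <- read_partition(partition_paths[[nm]])
    fit <- fit_geofences(events, partition, config)
    fits[[nm]] <- fit
    reports[[nm]] <- fit$report

    risk_path <- file.path(out_dir, paste0("risk_", nm, ".csv"))
    write_risk(fit$risk, risk_path)
    fence_path <- file.path(out_dir, paste0("fences_", nm, ".geojson"))
    write_geofences(fit$fences, fence_path)
    sweep <- threshold_sweep(fit$risk, partition, fit$smoking,
                             buffer_m = config$buffer_m,
                             ft_per_m = config$ft_per_m)
    sweep_path <- file.path(out_dir, paste0("sweep_", nm, ".csv"))
    utils::write.csv(sweep, sweep_path, row.names = FALSE, quote = FALSE)
    report_path <- file.path(out_dir, paste0("capture_", nm, ".csv"))
    utils::write.csv(fit$report$per_bin, report_path, row.names = FALSE,
                     quote = FALSE)
    outputs <- c(outputs, risk_path, fence_path, sweep_path, report_path)
    stage_counts[[paste0("n_zones_", nm)]] <- n_zones(partition)
    stage_counts[[paste0("n_missing_zones_", nm)]] <-
      attr(fit$risk, "n_missing") %||% 0L
  }

  # shared preprocessing outputs (identical across partitions)
  clean_path <- file.path(out_dir, "events_clean.csv")
  write_events(fits[[1L]]$events, clean_path)
  asc_path <- file.path(out_dir, "kde_surface.asc")
  write_asc(fits[[1L]]$raster, asc_path)
  outputs <- c(clean_path, asc_path, outputs)
  stage_counts$n_events_clean <- nrow(fits[[1L]]$events)
  stage_counts$n_smoking_clean <- nrow(fits[[1L]]$smoking)

  if (length(reports) >= 2L) {
    cmp <- compare_partitions(reports)
    cmp_path <- file.path(out_dir, "partition_comparison.csv")
    utils::write.csv(cmp$overall, cmp_path, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, cmp_path)
  }

  manifest <- list(
    participant_id = pid,
    config = unclass(config),
    inputs = lapply(stats::setNames(
      c(events_path, as.list(partition_paths)),
      c("events", names(partition_paths))
    ), function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))),
    counts = stage_counts,
    package_version = as.character(utils::packageVersion("smokefence")),
    started = format_utc(t0),
    finished = format_utc(Sys.time())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write the synthetic case-study suite to disk
#'
#' Materializes [gen_case_suite()] as files: one events CSV per participant,
#' the three partition GeoJSONs, and a manifest of profile parameters —
#' a one-command reproduction of the synthetic case study.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Paths of written files (named list), invisibly.
#' @export
write_case_suite <- function(seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  suite <- gen_case_suite(seed)
  paths <- list()
  for (nm in names(suite$participants)) {
    p <- file.path(out_dir, paste0("events_", nm, ".csv"))
    write_events(suite$participants[[nm]], p)
    paths[[paste0("events_", nm)]] <- p
  }
  for (nm in names(suite$partitions)) {
    p <- file.path(out_dir, paste0(nm, ".geojson"))
    write_partition(suite$partitions[[nm]], p)
    paths[[nm]] <- p
  }
  profile_meta <- lapply(suite$profiles, function(pr) {
    pr$anchors <- lapply(pr$anchors, function(a) {
      list(x = a$x, y = a$y, scatter_sd = a$scatter_sd,
           weights = as.numeric(a$weights))
    })
    unclass(pr)
  })
  mp <- file.path(out_dir, "suite_manifest.json")
  jsonlite::write_json(list(seed = seed, profiles = profile_meta),
                       mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$manifest <- mp
  invisible(paths)
}
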
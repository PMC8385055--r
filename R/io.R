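#' Write a synthetic experiment to disk
#'
#' One multi-page TIFF per tile (pages time-major, channel-minor in the
#' order brightfield, effector_tracker, target_tracker, viability; 16-bit
#' samples), the ground-truth droplet and cell tables as CSV, and the
#' generator configuration echoed to `config.yaml`.
#'
#' @param experiment A `droplet_experiment` ([generate_experiment()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tile in seq_along(experiment$images)) {
    pages <- list()
    for (ti in seq_along(experiment$images[[tile]])) {
      for (ch in channel_names()) {
        pages[[length(pages) + 1L]] <- experiment$images[[tile]][[ti]][[ch]]
      }
    }
    tiff::writeTIFF(pages, file.path(dir, sprintf("tile_%03d.tif", tile)),
                    bits.per.sample = 16, compression = "LZW")
  }
  readr::write_csv(experiment$droplets, file.path(dir, "ground_truth_droplets.csv"))
  readr::write_csv(experiment$cells, file.path(dir, "ground_truth_cells.csv"))
  cfg <- unclass(experiment$config)
  cfg$encapsulation <- unclass(cfg$encapsulation)
  cfg$droplet_radius_px <- NULL; cfg$cell_radius_px <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read an experiment directory written by [write_experiment()]
#'
#' Validates up front that every (tile, timepoint, channel) page is present
#' and that all pages share one shape, with errors naming the offending
#' tile/timepoint/channel.
#'
#' @param dir Directory path.
#' @return A `droplet_experiment` (ground-truth tables included when the
#'   CSVs are present).
#' @export
read_experiment <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path)) stop("no config.yaml in ", dir)
  raw <- yaml::read_yaml(cfg_path)
  enc <- do.call(encapsulation_params, raw$encapsulation[
    c("conc_effector", "conc_target", "droplet_volume_pl", "dilution_factor")])
  raw$encapsulation <- enc
  config <- do.call(generator_config, raw[intersect(names(raw),
    names(formals(generator_config)))])
  n_t <- config$n_timepoints
  chans <- channel_names()
  shape <- NULL
  images <- vector("list", config$n_tiles)
  for (tile in seq_len(config$n_tiles)) {
    path <- file.path(dir, sprintf("tile_%03d.tif", tile))
    if (!file.exists(path)) stop("missing image file for tile ", tile, ": ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != n_t * length(chans)) {
      # name the first missing (timepoint, channel) slot
      miss <- length(pages)  # pages are time-major, channel-minor
      t_miss <- miss %/% length(chans)
      ch_miss <- chans[miss %% length(chans) + 1]
      stop(sprintf("tile %d: expected %d pages, found %d (first missing: timepoint %d, channel %s)",
                   tile, n_t * length(chans), length(pages), t_miss, ch_miss))
    }
    per_t <- vector("list", n_t)
    k <- 1L
    for (ti in seq_len(n_t)) {
      frames <- list()
      for (ch in chans) {
        m <- pages[[k]]; k <- k + 1L
        if (is.null(shape)) shape <- dim(m)
        if (!identical(dim(m), shape)) {
          stop(sprintf("tile %d, timepoint %d, channel %s: shape %s differs from %s",
                       tile, ti - 1, ch, paste(dim(m), collapse = "x"),
                       paste(shape, collapse = "x")))
        }
        frames[[ch]] <- m
      }
      per_t[[ti]] <- frames
    }
    images[[tile]] <- per_t
  }
  droplets <- cells <- NULL
  dp <- file.path(dir, "ground_truth_droplets.csv")
  cp <- file.path(dir, "ground_truth_cells.csv")
  if (file.exists(dp)) droplets <- readr::read_csv(dp, show_col_types = FALSE)
  if (file.exists(cp)) cells <- readr::read_csv(cp, show_col_types = FALSE)
  structure(list(images = images, droplets = droplets, cells = cells,
                 config = config),
            class = "droplet_experiment")
}

#' @export
print.droplet_experiment <- function(x, ...) {
  cat(sprintf("Droplet experiment: %d tiles x %d timepoints x %d channels (%d x %d px)\n",
              length(x$images), length(x$images[[1]]), length(x$images[[1]][[1]]),
              nrow(x$images[[1]][[1]][[1]]), ncol(x$images[[1]][[1]][[1]])))
  if (!is.null(x$droplets)) {
    cat(sprintf("  ground truth: %d droplets, %d cells\n",
                dplyr::n_distinct(x$droplets$droplet_id),
                if (nrow(x$cells)) dplyr::n_distinct(x$cells$cell_id) else 0L))
  }
  invisible(x)
}

#' Run the full droplet cytotoxicity pipeline
#'
#' Detection (brightfield, per tile and timepoint), tracking with mover
#' removal, per-droplet cell counting and viability attribution, death
#' calling and kinetics — deterministic for a fixed input.
#'
#' @param experiment A `droplet_experiment`, or a directory path readable
#'   by [read_experiment()].
#' @param analysis An [analysis_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `droplets.csv`, `tracks.csv`, `census.csv`, `events.csv` and
#'   `summary.json`.
#' @return A `droplet_pipeline` list: `detections`, `tracks`, `census`,
#'   `traces`, `kinetics` (a `droplet_kinetics`), `n_timepoints`,
#'   `analysis`.
#' @export
run_pipeline <- function(experiment, analysis = analysis_config(),
                         out_dir = NULL) {
  if (is.character(experiment)) experiment <- read_experiment(experiment)
  n_t <- length(experiment$images[[1]])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  detections <- stage("detect", detect_experiment(experiment, analysis))
  tracks <- stage("track", build_tracks(
    detections,
    tracking_config(analysis$allowed_movement, analysis$droplet_radius_px),
    n_t))
  cells <- stage("census", analyze_cells(experiment, tracks, analysis))
  kin <- stage("kinetics", if (nrow(cells$census)) {
    summarise_kinetics(cells$census, cells$traces, analysis, n_t)
  } else NULL)
  out <- structure(list(detections = detections, tracks = tracks,
                        census = cells$census, traces = cells$traces,
                        kinetics = kin, n_timepoints = n_t,
                        analysis = analysis),
                   class = "droplet_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.droplet_pipeline <- function(x, ...) {
  cat(sprintf("Droplet pipeline: %d detections, %d tracks (%d complete), %d timepoints\n",
              nrow(x$detections), nrow(x$tracks$tracks),
              sum(x$tracks$tracks$status == "complete"), x$n_timepoints))
  if (!is.null(x$kinetics)) print(x$kinetics)
  invisible(x)
}

#' Write pipeline output tables
#'
#' @param pipeline A `droplet_pipeline`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(pipeline$detections, file.path(out_dir, "droplets.csv"))
  tracks_flat <- dplyr::left_join(pipeline$tracks$positions,
                                  pipeline$tracks$tracks, by = "track_id")
  readr::write_csv(tracks_flat, file.path(out_dir, "tracks.csv"))
  readr::write_csv(pipeline$census, file.path(out_dir, "census.csv"))
  kin <- pipeline$kinetics
  if (!is.null(kin)) {
    readr::write_csv(kin$events, file.path(out_dir, "events.csv"))
    jsonlite::write_json(summary_list(pipeline), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}

summary_list <- function(pipeline) {
  kin <- pipeline$kinetics
  status <- table(pipeline$tracks$tracks$status)
  list(
    n_tracks = nrow(pipeline$tracks$tracks),
    n_complete = unname(status["complete"] %||% 0L),
    n_removed_mover = unname(status["removed_mover"] %||% 0L),
    n_removed_gap = unname(status["removed_gap"] %||% 0L),
    n_droplets_total = kin$n_droplets_total,
    n_droplets_with_cells = kin$n_droplets_with_cells,
    n_pairs_1_1 = kin$n_pairs_1_1,
    n_eligible = nrow(kin$eligible),
    n_excluded_dead_at_t0 = nrow(kin$excluded),
    killer_fraction = kin$killer$fraction,
    fast_killer_fraction = kin$kinetics$fast_killer_fraction,
    slow_killer_fraction = kin$kinetics$slow_killer_fraction,
    t_fast = kin$kinetics$t_fast,
    lytic_hit_histogram = as.list(setNames(kin$kinetics$histogram$n,
                                           kin$kinetics$histogram$hour)),
    control_viability = if (is.null(kin$control)) NULL else
      as.list(setNames(kin$control$cum_dead_fraction, kin$control$hour))
  )
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Validate pipeline outputs against generator ground truth
#'
#' The synthetic ground truth plays the role of manual counting: pipeline
#' tracks are matched to truth droplets by t = 0 centre proximity, and at
#' the chosen timepoints the per-metric percent deviation is computed for
#' droplet count, the per-droplet cell distribution (droplets binned by
#' total cell count 0, 1, 2, 3, 4+), the 1:1 pairing count, and the
#' cumulative dead-cell count. Percent deviation is
#' `100 * |observed - truth| / max(truth, 1)` (the denominator guard keeps
#' empty classes finite).
#'
#' @param pipeline A `droplet_pipeline` ([run_pipeline()]).
#' @param experiment The `droplet_experiment` the pipeline was run on
#'   (must carry ground-truth tables).
#' @param timepoints Hours at which to compare.
#' @return A `validation_report` list: `metrics` (tibble `metric`,
#'   `timepoint`, `stratum`, `observed`, `truth`, `deviation_pct`),
#'   `max_deviation_pct`, `n_matched`, `n_unmatched_tracks`.
#' @export
validate_against_truth <- function(pipeline, experiment,
                                   timepoints = c(3, 4, 10)) {
  if (is.null(experiment$droplets)) stop("experiment carries no ground truth")
  n_t <- pipeline$n_timepoints
  if (n_t != experiment$config$n_timepoints) {
    stop("pipeline and experiment disagree on the number of timepoints; ",
         "outputs and truth must come from the same run")
  }
  timepoints <- timepoints[timepoints <= n_t - 1]
  truth_d <- experiment$droplets
  truth_c <- experiment$cells

  # match complete tracks to truth droplets at t = 0 by nearest centre
  t0_truth <- truth_d[truth_d$timepoint == 0, ]
  complete <- pipeline$tracks$tracks[pipeline$tracks$tracks$status == "complete", ]
  pos0 <- pipeline$tracks$positions[pipeline$tracks$positions$timepoint == 0 &
    pipeline$tracks$positions$track_id %in% complete$track_id, ]
  pos0 <- dplyr::left_join(pos0, complete[, c("track_id", "tile_id")], by = "track_id")
  match_rows <- purrr::pmap(pos0, function(track_id, timepoint, droplet_index,
                                           x, y, radius, tile_id, ...) {
    cand <- t0_truth[t0_truth$tile_id == tile_id, ]
    d2 <- (cand$x - x)^2 + (cand$y - y)^2
    i <- which.min(d2)
    if (length(i) && sqrt(d2[i]) <= radius) {
      tibble::tibble(track_id = track_id, droplet_id = cand$droplet_id[i],
                     match_dist = sqrt(d2[i]))
    } else {
      tibble::tibble(track_id = track_id, droplet_id = NA_integer_,
                     match_dist = NA_real_)
    }
  })
  matches <- dplyr::bind_rows(match_rows)
  n_unmatched <- sum(is.na(matches$droplet_id))
  matches <- matches[!is.na(matches$droplet_id), ]

  # truth per matched droplet: cell counts and death times
  truth_counts <- truth_c[truth_c$timepoint == 0 &
                          truth_c$droplet_id %in% matches$droplet_id, ] |>
    dplyr::group_by(.data$droplet_id) |>
    dplyr::summarise(
      k_eff = sum(.data$cell_type == "effector"),
      k_tgt = sum(.data$cell_type == "target"),
      deaths = list(.data$death_time[!is.na(.data$death_time)]),
      .groups = "drop")
  truth_counts <- dplyr::left_join(matches, truth_counts, by = "droplet_id") |>
    dplyr::mutate(k_eff = dplyr::coalesce(.data$k_eff, 0L),
                  k_tgt = dplyr::coalesce(.data$k_tgt, 0L))
  census <- pipeline$census[pipeline$census$track_id %in% matches$track_id, ]

  bin_label <- function(n) ifelse(n >= 4, "4+", as.character(n))
  rows <- list()
  for (t in timepoints) {
    # droplet count: all droplets are present at every timepoint
    obs_n <- sum(pipeline$detections$timepoint == t)
    truth_n <- sum(truth_d$timepoint == t)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      metric = "droplet_count", timepoint = t, stratum = "all",
      observed = obs_n, truth = truth_n)
    ct <- census[census$timepoint == t, ]
    ct <- dplyr::left_join(ct, truth_counts, by = "track_id")
    # cell distribution: droplets per total-cell-count bin
    obs_bin <- table(bin_label(ct$n_effector + ct$n_target))
    tru_bin <- table(bin_label(ct$k_eff + ct$k_tgt))
    for (b in union(names(obs_bin), names(tru_bin))) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = "cell_distribution", timepoint = t, stratum = b,
        observed = unname(obs_bin[b] %||% 0L), truth = unname(tru_bin[b] %||% 0L))
    }
    # 1:1 pairing count
    rows[[length(rows) + 1L]] <- tibble::tibble(
      metric = "pairing_1_1", timepoint = t, stratum = "all",
      observed = sum(ct$n_effector == 1 & ct$n_target == 1),
      truth = sum(ct$k_eff == 1 & ct$k_tgt == 1))
    # cumulative dead cells
    rows[[length(rows) + 1L]] <- tibble::tibble(
      metric = "dead_cells", timepoint = t, stratum = "all",
      observed = sum(ct$dead_effector + ct$dead_target + ct$dead_unknown),
      truth = sum(vapply(ct$deaths, function(d) sum(unlist(d) <= t), numeric(1))))
  }
  metrics <- dplyr::bind_rows(rows) |>
    dplyr::mutate(deviation_pct = 100 * abs(.data$observed - .data$truth) /
                    pmax(.data$truth, 1))
  structure(list(metrics = metrics,
                 max_deviation_pct = max(metrics$deviation_pct),
                 n_matched = nrow(matches),
                 n_unmatched_tracks = n_unmatched),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation against ground truth: %d droplets matched (%d unmatched tracks)\n",
              x$n_matched, x$n_unmatched_tracks))
  worst <- x$metrics[which.max(x$metrics$deviation_pct), ]
  cat(sprintf("  max deviation: %.3f%% (%s, t = %d h, stratum %s)\n",
              x$max_deviation_pct, worst$metric, worst$timepoint, worst$stratum))
  invisible(x)
}
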
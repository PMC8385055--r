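#' Preprocess one fluorescence channel for one droplet
#'
#' Follows the fixed order: square crop around the droplet, white top-hat
#' (disk structuring element) to remove background, zeroing of non-droplet
#' pixels, then threshold to a binary image. Thresholding uses Otsu on the
#' in-disk top-hat intensities, guarded by a contrast floor: when the
#' droplet contains no signal above the floor the binary is empty rather
#' than letting Otsu split background noise.
#'
#' @param fluor_image Numeric matrix (one tile, one timepoint, one channel).
#' @param droplet One-row data frame (or list) with `x`, `y`, `radius` in
#'   pixel units (0-based coordinates).
#' @param tophat_radius Structuring-element radius, px.
#' @param contrast_floor Minimum in-disk top-hat maximum for any foreground.
#' @param margin Extra crop margin beyond the radius, px.
#' @return A list: `binary` (logical matrix), `crop` (raw intensities),
#'   `tophat` (masked top-hat intensities), `mask` (in-disk logical),
#'   `x0`, `y0` (0-based tile coordinates of the crop's top-left pixel),
#'   `threshold` (the value used, NA when the crop is empty).
#' @export
preprocess_channel <- function(fluor_image, droplet, tophat_radius,
                               contrast_floor = 0.1, margin = 2) {
  stopifnot(tophat_radius > 0)
  x <- droplet$x[1]; y <- droplet$y[1]; r <- droplet$radius[1]
  h <- nrow(fluor_image); w <- ncol(fluor_image)
  half <- ceiling(r) + margin
  cx <- round(x); cy <- round(y)
  xs <- max(0, cx - half):min(w - 1, cx + half)
  ys <- max(0, cy - half):min(h - 1, cy + half)
  crop <- fluor_image[ys + 1, xs + 1, drop = FALSE]
  mask <- outer((ys - y)^2, (xs - x)^2, "+") <= r^2
  brush_size <- 2 * ceiling(tophat_radius) + 1
  th <- EBImage::whiteTopHat(crop, EBImage::makeBrush(brush_size, "disc"))
  th[!mask] <- 0
  in_disk <- th[mask]
  if (!length(in_disk) || max(in_disk) < contrast_floor) {
    binary <- matrix(FALSE, nrow(crop), ncol(crop))
    thr <- NA_real_
  } else {
    thr <- max(EBImage::otsu(matrix(in_disk, nrow = 1), range = c(0, 1)),
               contrast_floor / 2)
    binary <- th > thr
  }
  list(binary = binary, crop = crop, tophat = th, mask = mask,
       x0 = xs[1], y0 = ys[1], threshold = thr)
}

#' Count cells in a binary droplet crop
#'
#' 8-connected component labelling; components with area outside
#' `[min_area, max_area]` are discarded. Gaussian-rendered cells binarise
#' to blobs where diagonal adjacency is routine, hence 8- rather than
#' 4-connectivity.
#'
#' @param binary Logical matrix (from [preprocess_channel()]).
#' @param min_area,max_area Area bounds, px^2.
#' @param intensity Optional matrix of the same shape; per-object mean
#'   intensity is computed from it (e.g. the raw crop).
#' @param offset `c(x0, y0)` added to centroids to express them in tile
#'   coordinates.
#' @return A list: `count`, and `objects` — a tibble with `x`, `y`
#'   (centroid), `area`, `mean_intensity`.
#' @export
count_cells <- function(binary, min_area, max_area, intensity = NULL,
                        offset = c(0, 0)) {
  lab <- label8(binary)
  n_raw <- max(lab)
  empty <- tibble::tibble(x = numeric(), y = numeric(), area = integer(),
                          mean_intensity = numeric())
  if (n_raw == 0) return(list(count = 0L, objects = empty))
  areas <- tabulate(lab, nbins = n_raw)
  keep <- which(areas >= min_area & areas <= max_area)
  if (!length(keep)) return(list(count = 0L, objects = empty))
  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[lab > 0]
  sel <- labv %in% keep
  idx <- idx[sel, , drop = FALSE]; labv <- labv[sel]
  f <- factor(labv, levels = keep)
  cx <- tapply(idx[, 2] - 1, f, mean) + offset[1]
  cy <- tapply(idx[, 1] - 1, f, mean) + offset[2]
  mi <- if (!is.null(intensity)) {
    as.numeric(tapply(intensity[idx], f, mean))
  } else NA_real_
  list(count = length(keep),
       objects = tibble::tibble(x = as.numeric(cx), y = as.numeric(cy),
                                area = areas[keep], mean_intensity = mi))
}

#' Attribute viability objects to a cell type
#'
#' Each viability-channel object is assigned to the cell type whose nearest
#' tracker-channel object centroid is closest, provided that distance is at
#' most `max_dist` (one cell diameter); otherwise it is counted as unknown.
#' Callers should pass t = 0 tracker centroids as a fallback when the
#' current-frame tracker signal has decayed away.
#'
#' @param viability_objects Tibble of viability objects (`x`, `y`, ...).
#' @param effector_objects,target_objects Tracker-object tibbles for the
#'   same droplet and timepoint (possibly 0-row).
#' @param max_dist Maximum centroid distance for attribution, px.
#' @return `viability_objects` with an `attributed` column
#'   ("effector"/"target"/"unknown") and `attr_dist`.
#' @export
attribute_dead_cells <- function(viability_objects, effector_objects,
                                 target_objects, max_dist) {
  n <- nrow(viability_objects)
  if (n == 0) {
    return(dplyr::mutate(viability_objects, attributed = character(0),
                         attr_dist = numeric(0)))
  }
  near <- function(objs) {
    if (is.null(objs) || nrow(objs) == 0) return(rep(Inf, n))
    d <- sqrt(outer(viability_objects$x, objs$x, "-")^2 +
              outer(viability_objects$y, objs$y, "-")^2)
    apply(d, 1, min)
  }
  de <- near(effector_objects)
  dt <- near(target_objects)
  best <- pmin(de, dt)
  type <- ifelse(best > max_dist, "unknown",
                 ifelse(de <= dt, "effector", "target"))
  dplyr::mutate(viability_objects, attributed = type,
                attr_dist = ifelse(is.finite(best), best, NA_real_))
}

#' Occupancy classification of a droplet census
#'
#' Freezes each track's occupancy class at the first timepoint (cell
#' division is not modelled over the assay window) and derives the
#' eligibility strata: 1:1 pairs for the killing analysis, effector-only
#' and target-only droplets as internal controls, multi-cell droplets for
#' the serial-killing analysis.
#'
#' @param census Census tibble with `track_id`, `timepoint`, `n_effector`,
#'   `n_target` columns.
#' @return `census` with `k_effector`, `k_target` (t = 0 counts),
#'   `occupancy` label and logical flags `pair_1_1`, `effector_only`,
#'   `target_only`, `multi`, `empty`.
#' @export
census_droplet <- function(census) {
  t0 <- census
  if (nrow(census) > 0) {
    t0 <- dplyr::filter(census, .data$timepoint == min(.data$timepoint))
  }
  t0 <- dplyr::transmute(t0, track_id = .data$track_id,
                         k_effector = .data$n_effector,
                         k_target = .data$n_target)
  census |>
    dplyr::select(-dplyr::any_of(c("k_effector", "k_target"))) |>
    dplyr::left_join(t0, by = "track_id") |>
    dplyr::mutate(
      occupancy = occupancy_label(.data$k_effector, .data$k_target),
      pair_1_1 = .data$k_effector == 1 & .data$k_target == 1,
      effector_only = .data$k_effector > 0 & .data$k_target == 0,
      target_only = .data$k_effector == 0 & .data$k_target > 0,
      multi = .data$k_effector + .data$k_target > 2,
      empty = .data$k_effector + .data$k_target == 0
    )
}

#' Per-droplet cell counting and viability attribution over an experiment
#'
#' For every complete track, every timepoint and every fluorescence
#' channel: crop, top-hat, mask, threshold, count. Viability objects are
#' attributed to effector or target by nearest tracker centroid (falling
#' back to t = 0 centroids when the tracker signal has decayed), and a
#' background-corrected viability trace is built per track and cell type
#' (baseline: median in-disk viability intensity at t = 0).
#'
#' @param experiment A `droplet_experiment`.
#' @param tracks A `droplet_tracks` ([build_tracks()]).
#' @param analysis An [analysis_config()].
#' @return A list: `census` (per track x timepoint counts with occupancy
#'   flags, see [census_droplet()]) and `traces` (per track x cell type x
#'   timepoint background-corrected viability intensity).
#' @export
analyze_cells <- function(experiment, tracks, analysis = analysis_config()) {
  complete <- tracks$tracks$track_id[tracks$tracks$status == "complete"]
  if (length(complete) == 0) {
    empty_census <- census_droplet(tibble::tibble(
      track_id = integer(), tile_id = integer(), timepoint = integer(),
      n_effector = integer(), n_target = integer(), n_viability = integer(),
      dead_effector = integer(), dead_target = integer(),
      dead_unknown = integer()))
    return(list(census = empty_census,
                traces = tibble::tibble(track_id = integer(),
                                        cell_type = character(),
                                        timepoint = integer(),
                                        intensity = numeric())))
  }
  pos <- tracks$positions[tracks$positions$track_id %in% complete, ]
  tile_of <- setNames(tracks$tracks$tile_id, tracks$tracks$track_id)
  n_t <- length(experiment$images[[1]])
  max_dist <- analysis$cell_diameter_px

  census_rows <- vector("list", length(complete) * n_t)
  trace_rows <- vector("list", length(complete) * n_t)
  row_i <- 0L

  for (tr in complete) {
    p <- pos[pos$track_id == tr, ]
    p <- p[order(p$timepoint), ]
    tile <- tile_of[[as.character(tr)]]
    base_via <- NA_real_
    eff0 <- NULL; tgt0 <- NULL
    for (t in 0:(n_t - 1)) {
      d <- p[p$timepoint == t, ]
      frames <- experiment$images[[tile]][[t + 1]]
      counts <- list()
      objs <- list()
      for (ch in c("effector_tracker", "target_tracker", "viability")) {
        pre <- preprocess_channel(frames[[ch]], d, analysis$tophat_radius,
                                  analysis$contrast_floor, analysis$crop_margin_px)
        cc <- count_cells(pre$binary, analysis$min_area, analysis$max_area,
                          intensity = pre$crop, offset = c(pre$x0, pre$y0))
        counts[[ch]] <- cc$count
        objs[[ch]] <- cc$objects
        if (ch == "viability" && t == 0) {
          base_via <- median(pre$crop[pre$mask])
        }
      }
      if (t == 0) { eff0 <- objs$effector_tracker; tgt0 <- objs$target_tracker }
      eff_ref <- if (nrow(objs$effector_tracker)) objs$effector_tracker else eff0
      tgt_ref <- if (nrow(objs$target_tracker)) objs$target_tracker else tgt0
      via <- attribute_dead_cells(objs$viability, eff_ref, tgt_ref, max_dist)
      corrected <- function(type) {
        v <- via[via$attributed == type, ]
        if (nrow(v) == 0) 0 else max(pmax(v$mean_intensity - base_via, 0))
      }
      row_i <- row_i + 1L
      census_rows[[row_i]] <- tibble::tibble(
        track_id = tr, tile_id = tile, timepoint = t,
        n_effector = counts$effector_tracker,
        n_target = counts$target_tracker,
        n_viability = counts$viability,
        dead_effector = sum(via$attributed == "effector"),
        dead_target = sum(via$attributed == "target"),
        dead_unknown = sum(via$attributed == "unknown")
      )
      trace_rows[[row_i]] <- tibble::tibble(
        track_id = tr, cell_type = c("effector", "target"), timepoint = t,
        intensity = c(corrected("effector"), corrected("target"))
      )
    }
  }
  census <- census_droplet(dplyr::bind_rows(census_rows))
  traces <- dplyr::bind_rows(trace_rows) |>
    dplyr::arrange(.data$track_id, .data$cell_type, .data$timepoint)
  list(census = census, traces = traces)
}
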
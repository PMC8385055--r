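#' Tracking configuration
#'
#' @param allowed_movement Maximum centre displacement (px) between
#'   consecutive timepoints for two detections to be linked. Keep this well
#'   below the droplet radius: if the allowed movement exceeds the radius, a
#'   neighbouring droplet can be mistaken for the same droplet at the next
#'   timepoint. A warning is issued when `allowed_movement >= droplet_radius`.
#' @param droplet_radius Nominal droplet radius (px), used only for the
#'   sanity warning.
#' @param require_full_length If `TRUE` (default), only tracks spanning
#'   every timepoint are `complete`; all others are flagged and excluded
#'   from downstream analysis (but retained in the output for audit).
#' @return A `tracking_config` list.
#' @export
tracking_config <- function(allowed_movement, droplet_radius = NULL,
                            require_full_length = TRUE) {
  stopifnot(allowed_movement > 0)
  if (!is.null(droplet_radius) && allowed_movement >= droplet_radius) {
    warning("allowed_movement >= droplet radius: risk of linking to a different droplet")
  }
  structure(list(allowed_movement = allowed_movement,
                 require_full_length = require_full_length),
            class = "tracking_config")
}

#' Link droplet detections between two consecutive timepoints
#'
#' Greedy globally-nearest matching: the pair with the smallest centre
#' distance is matched first (provided the distance is within the allowed
#' movement), both detections are removed, and the process repeats.
#' Distance ties are broken in favour of the lower `droplet_index`. Greedy
#' global matching prevents two droplets from claiming the same partner and
#' coincides with the optimal assignment when droplet spacing is large
#' compared to the jitter.
#'
#' @param dets_t,dets_t1 Detection tibbles (columns `droplet_index`, `x`,
#'   `y`) from consecutive timepoints of one tile.
#' @param allowed_movement Maximum link distance, px.
#' @return A list: `matches` (tibble `index_t`, `index_t1`, `dist`),
#'   `unmatched_t`, `unmatched_t1` (integer vectors of `droplet_index`).
#' @export
link_timepoints <- function(dets_t, dets_t1, allowed_movement) {
  n1 <- nrow(dets_t); n2 <- nrow(dets_t1)
  empty <- tibble::tibble(index_t = integer(), index_t1 = integer(), dist = numeric())
  if (n1 == 0 || n2 == 0) {
    return(list(matches = empty,
                unmatched_t = dets_t$droplet_index,
                unmatched_t1 = dets_t1$droplet_index))
  }
  d <- sqrt(outer(dets_t$y, dets_t1$y, "-")^2 + outer(dets_t$x, dets_t1$x, "-")^2)
  cand <- which(d <= allowed_movement, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(list(matches = empty,
                unmatched_t = dets_t$droplet_index,
                unmatched_t1 = dets_t1$droplet_index))
  }
  dist <- d[cand]
  i_idx <- dets_t$droplet_index[cand[, 1]]
  j_idx <- dets_t1$droplet_index[cand[, 2]]
  ord <- order(dist, i_idx, j_idx)
  used_i <- logical(n1); used_j <- logical(n2)
  mi <- integer(0); mj <- integer(0); md <- numeric(0)
  for (k in ord) {
    a <- cand[k, 1]; b <- cand[k, 2]
    if (used_i[a] || used_j[b]) next
    used_i[a] <- TRUE; used_j[b] <- TRUE
    mi <- c(mi, dets_t$droplet_index[a])
    mj <- c(mj, dets_t1$droplet_index[b])
    md <- c(md, d[a, b])
  }
  list(matches = tibble::tibble(index_t = mi, index_t1 = mj, dist = md),
       unmatched_t = dets_t$droplet_index[!used_i],
       unmatched_t1 = dets_t1$droplet_index[!used_j])
}

#' Build droplet tracks across all timepoints
#'
#' Chains pairwise links into tracks, one tile at a time. A droplet whose
#' displacement between two frames exceeds the allowed movement never links
#' across that step, so a planted "mover" appears as two broken chains;
#' broken chains are flagged `removed_mover` when unmatched detections
#' exist on the far side of the break (the droplet re-appeared elsewhere)
#' and `removed_gap` otherwise (the droplet vanished or was missed). Only
#' `complete` tracks — spanning every timepoint — enter downstream
#' analysis; removed tracks are retained with their status for audit.
#'
#' @param detections Detection tibble with `tile_id`, `timepoint`,
#'   `droplet_index`, `x`, `y`, `radius` columns ([detect_experiment()]).
#' @param config A [tracking_config()].
#' @param n_timepoints Total number of timepoints in the experiment.
#' @return A list of class `droplet_tracks`: `tracks` (tibble `track_id`,
#'   `tile_id`, `status`, `max_step`, `start_t`, `end_t`) and `positions`
#'   (tibble `track_id`, `timepoint`, `droplet_index`, `x`, `y`, `radius`).
#' @export
build_tracks <- function(detections, config, n_timepoints) {
  stopifnot(inherits(config, "tracking_config"), n_timepoints >= 2)
  m <- config$allowed_movement
  all_tracks <- list(); all_pos <- list(); next_track <- 1L

  for (tile in sort(unique(detections$tile_id))) {
    dt <- detections[detections$tile_id == tile, ]
    per_t <- lapply(0:(n_timepoints - 1), function(t) dt[dt$timepoint == t, ])
    # chain id per (timepoint, droplet_index)
    links <- vector("list", n_timepoints - 1)
    for (t in seq_len(n_timepoints - 1)) {
      links[[t]] <- link_timepoints(per_t[[t]], per_t[[t + 1]], m)
    }
    # start a chain at every detection not matched from the previous frame
    chains <- list()
    carry <- list()  # droplet_index (at current t) -> chain id
    for (t in 0:(n_timepoints - 1)) {
      dets <- per_t[[t + 1]]
      matched_from_prev <- if (t == 0) integer(0) else links[[t]]$matches$index_t1
      new_idx <- setdiff(dets$droplet_index, matched_from_prev)
      carry_new <- list()
      # continue chains
      if (t > 0) {
        mt <- links[[t]]$matches
        for (k in seq_len(nrow(mt))) {
          cid <- carry[[as.character(mt$index_t[k])]]
          chains[[cid]]$timepoint <- c(chains[[cid]]$timepoint, t)
          chains[[cid]]$droplet_index <- c(chains[[cid]]$droplet_index, mt$index_t1[k])
          chains[[cid]]$step <- c(chains[[cid]]$step, mt$dist[k])
          carry_new[[as.character(mt$index_t1[k])]] <- cid
        }
      }
      for (idx in new_idx) {
        cid <- length(chains) + 1L
        chains[[cid]] <- list(timepoint = t, droplet_index = idx, step = numeric(0))
        carry_new[[as.character(idx)]] <- cid
      }
      carry <- carry_new
    }
    # unmatched detections per boundary (for mover vs gap disambiguation)
    unmatched_next <- vapply(seq_len(n_timepoints - 1),
                             function(t) length(links[[t]]$unmatched_t1) > 0, logical(1))
    unmatched_prev <- vapply(seq_len(n_timepoints - 1),
                             function(t) length(links[[t]]$unmatched_t) > 0, logical(1))
    for (cid in seq_along(chains)) {
      ch <- chains[[cid]]
      t0 <- ch$timepoint[1]; t1 <- ch$timepoint[length(ch$timepoint)]
      status <- if (t0 == 0 && t1 == n_timepoints - 1) {
        "complete"
      } else {
        # broken: did the droplet re-appear on the far side of the break?
        mover <- (t1 < n_timepoints - 1 && unmatched_next[t1 + 1]) ||
                 (t0 > 0 && unmatched_prev[t0])
        if (mover) "removed_mover" else "removed_gap"
      }
      if (!config$require_full_length && status == "removed_gap") status <- "complete"
      pos <- per_t[[1]][0, ]
      for (k in seq_along(ch$timepoint)) {
        dets <- per_t[[ch$timepoint[k] + 1]]
        pos <- dplyr::bind_rows(pos, dets[dets$droplet_index == ch$droplet_index[k], ])
      }
      all_tracks[[length(all_tracks) + 1L]] <- tibble::tibble(
        track_id = next_track, tile_id = tile, status = status,
        max_step = if (length(ch$step)) max(ch$step) else NA_real_,
        start_t = t0, end_t = t1
      )
      all_pos[[length(all_pos) + 1L]] <- tibble::tibble(
        track_id = next_track,
        timepoint = pos$timepoint,
        droplet_index = pos$droplet_index,
        x = pos$x, y = pos$y, radius = pos$radius
      )
      next_track <- next_track + 1L
    }
  }
  empty_tracks <- tibble::tibble(track_id = integer(), tile_id = integer(),
                                 status = character(), max_step = numeric(),
                                 start_t = integer(), end_t = integer())
  empty_pos <- tibble::tibble(track_id = integer(), timepoint = integer(),
                              droplet_index = integer(), x = numeric(),
                              y = numeric(), radius = numeric())
  structure(list(tracks = dplyr::bind_rows(empty_tracks, all_tracks),
                 positions = dplyr::bind_rows(empty_pos, all_pos)),
            class = "droplet_tracks")
}

#' @export
print.droplet_tracks <- function(x, ...) {
  tab <- table(x$tracks$status)
  cat("Droplet tracks:", nrow(x$tracks), "total —",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
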
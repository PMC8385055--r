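#' Call a death time from a viability trace
#'
#' A cell is called dead at the first timepoint where its
#' background-corrected viability intensity exceeds `theta` and stays above
#' `theta` for `persistence` consecutive frames (the run may be truncated
#' by the end of the series). An alive cell's corrected intensity is ~0;
#' the dye signal after death is bright and stable.
#'
#' @param intensity Numeric vector, one value per timepoint (hour 0, 1, ...).
#' @param theta Intensity threshold (>= 0).
#' @param persistence Required consecutive frames above threshold (>= 1).
#' @return Integer hour index of death, or `NA` if never called.
#' @export
call_death_time <- function(intensity, theta, persistence = 1) {
  stopifnot(theta >= 0, persistence >= 1)
  above <- intensity > theta
  n <- length(above)
  for (t in seq_len(n)) {
    if (above[t]) {
      run_end <- min(n, t + persistence - 1)
      if (all(above[t:run_end])) return(t - 1L)
    }
  }
  NA_integer_
}

#' Call death events for all traces
#'
#' @param traces Tibble with `track_id`, `cell_type`, `timepoint`,
#'   `intensity` ([analyze_cells()] or [simulate_cohort()]).
#' @param theta,persistence See [call_death_time()].
#' @return A tibble of death events: `track_id`, `cell_type`, `death_time`.
#'   Cells that never cross the threshold are omitted.
#' @export
call_deaths <- function(traces, theta = 0.1, persistence = 1) {
  traces |>
    dplyr::group_by(.data$track_id, .data$cell_type) |>
    dplyr::arrange(.data$timepoint, .by_group = TRUE) |>
    dplyr::summarise(death_time = call_death_time(.data$intensity, theta, persistence),
                     .groups = "drop") |>
    dplyr::filter(!is.na(.data$death_time))
}

#' Select the eligible 1:1 droplets for the killing analysis
#'
#' Keeps complete tracks whose occupancy is exactly one effector and one
#' target with no cell called dead at t = 0. Every exclusion is returned
#' with its reason, and eligible + excluded add up exactly to the number of
#' complete 1:1 tracks.
#'
#' @param census Census tibble with occupancy flags ([census_droplet()]).
#' @return A list: `eligible` (tibble of `track_id`), `excluded` (tibble of
#'   `track_id`, `reason` — `dead_at_t0` for 1:1 droplets dead at t = 0;
#'   droplets that are not 1:1 are not part of this stratum).
#' @export
select_eligible <- function(census) {
  t0 <- census[census$timepoint == 0, ]
  pairs <- t0[t0$pair_1_1, ]
  dead0 <- pairs$dead_effector + pairs$dead_target + pairs$dead_unknown > 0
  list(
    eligible = tibble::tibble(track_id = pairs$track_id[!dead0]),
    excluded = tibble::tibble(track_id = pairs$track_id[dead0],
                              reason = rep("dead_at_t0", sum(dead0)))
  )
}

#' Killer fraction among eligible 1:1 droplets
#'
#' Fraction of eligible 1:1 droplets whose target cell dies within the
#' observation window. Effector deaths in 1:1 droplets are not counted
#' here (the killer fraction concerns target death).
#'
#' @param eligible Tibble of eligible `track_id`s ([select_eligible()]).
#' @param events Death events ([call_deaths()]).
#' @return A list: `fraction`, `n_killers`, `n_eligible`.
#' @export
killer_fraction <- function(eligible, events) {
  if (nrow(eligible) == 0) stop("no eligible 1:1 droplets")
  killers <- events |>
    dplyr::filter(.data$cell_type == "target",
                  .data$track_id %in% eligible$track_id) |>
    dplyr::distinct(.data$track_id)
  list(fraction = nrow(killers) / nrow(eligible),
       n_killers = nrow(killers), n_eligible = nrow(eligible))
}

#' Per-hour lytic-hit kinetics and fast/slow killer split
#'
#' Builds the per-hour histogram of target death times among eligible 1:1
#' droplets and splits killers at `t_fast` hours: effectors whose target
#' dies within `t_fast` hours are fast killers, the rest slow killers.
#'
#' @param events Death events restricted to eligible 1:1 droplets (target
#'   rows are used).
#' @param n_timepoints Number of hourly frames (histogram support 0..n-1).
#' @param t_fast Fast/slow boundary in hours (default 4).
#' @return A `kinetics_summary` list: `histogram` (tibble `hour`, `n`),
#'   `n_events`, `fast_killer_fraction`, `slow_killer_fraction` (both `NA`
#'   when there are no events), `t_fast`.
#' @export
kinetics_histogram <- function(events, n_timepoints, t_fast = 4) {
  times <- events$death_time[events$cell_type == "target"]
  hours <- 0:(n_timepoints - 1)
  hist <- tibble::tibble(hour = hours,
                         n = vapply(hours, function(h) sum(times == h), integer(1)))
  n_ev <- length(times)
  fast <- if (n_ev == 0) NA_real_ else sum(times <= t_fast) / n_ev
  structure(list(histogram = hist, n_events = n_ev,
                 fast_killer_fraction = fast,
                 slow_killer_fraction = if (is.na(fast)) NA_real_ else 1 - fast,
                 t_fast = t_fast),
            class = "kinetics_summary")
}

#' Detect serial killers
#'
#' A serial killer is a single effector co-encapsulated with two or more
#' targets of which at least two die during the window.
#'
#' @param census Census tibble with occupancy flags ([census_droplet()]).
#' @param events Death events ([call_deaths()]); for multi-target droplets
#'   kill times are read from the census `dead_target` step function.
#' @return A tibble: `track_id`, `n_targets`, `n_kills`, `kill_times`
#'   (list-column of hours).
#' @export
detect_serial_killers <- function(census, events) {
  t0 <- census[census$timepoint == 0, ]
  candidates <- t0$track_id[t0$k_effector == 1 & t0$k_target >= 2]
  if (!length(candidates)) {
    return(tibble::tibble(track_id = integer(), n_targets = integer(),
                          n_kills = integer(), kill_times = list()))
  }
  census[census$track_id %in% candidates, ] |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$timepoint, .by_group = TRUE) |>
    dplyr::summarise(
      n_targets = .data$k_target[1],
      n_kills = max(cummax(.data$dead_target)),
      kill_times = list({
        cm <- cummax(.data$dead_target)
        .data$timepoint[which(diff(c(0, cm)) > 0)]
      }),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_kills >= 2)
}

#' Spontaneous target death in effector-free droplets
#'
#' The cumulative fraction of targets dying over time in droplets with no
#' effector — the assay's internal negative control for target viability.
#'
#' @param census Census tibble with occupancy flags.
#' @param events Death events.
#' @param n_timepoints Number of hourly frames.
#' @return A tibble `hour`, `cum_dead_fraction`, or `NULL` when the
#'   target-only stratum is empty.
#' @export
control_viability <- function(census, events, n_timepoints) {
  t0 <- census[census$timepoint == 0, ]
  stratum <- t0$track_id[t0$target_only]
  if (!length(stratum)) return(NULL)
  n_targets <- sum(t0$k_target[t0$target_only])
  times <- events$death_time[events$cell_type == "target" &
                             events$track_id %in% stratum]
  hours <- 0:(n_timepoints - 1)
  tibble::tibble(
    hour = hours,
    cum_dead_fraction = vapply(hours, function(h) sum(times <= h), numeric(1)) /
      max(n_targets, 1)
  )
}

#' Full kinetics summary of a censused experiment
#'
#' Runs eligibility selection, death calling, killer fraction, per-hour
#' kinetics, serial-killer detection and the negative-control viability
#' curve in one step.
#'
#' @param census Census tibble with occupancy flags.
#' @param traces Viability traces.
#' @param analysis An [analysis_config()] (uses `theta`, `persistence`,
#'   `t_fast`).
#' @param n_timepoints Number of hourly frames.
#' @return A `droplet_kinetics` list: `events`, `eligible`, `excluded`,
#'   `killer` (see [killer_fraction()]), `kinetics`
#'   ([kinetics_histogram()]), `serial_killers`, `control`, and totals
#'   `n_droplets_total`, `n_droplets_with_cells`, `n_pairs_1_1`.
#' @export
summarise_kinetics <- function(census, traces, analysis = analysis_config(),
                               n_timepoints = max(census$timepoint) + 1) {
  events <- call_deaths(traces, analysis$theta, analysis$persistence)
  sel <- select_eligible(census)
  elig_events <- events[events$track_id %in% sel$eligible$track_id, ]
  killer <- if (nrow(sel$eligible)) killer_fraction(sel$eligible, elig_events) else
    list(fraction = NA_real_, n_killers = 0L, n_eligible = 0L)
  t0 <- census[census$timepoint == 0, ]
  structure(list(
    events = events,
    eligible = sel$eligible,
    excluded = sel$excluded,
    killer = killer,
    kinetics = kinetics_histogram(elig_events, n_timepoints, analysis$t_fast),
    serial_killers = detect_serial_killers(census, events),
    control = control_viability(census, events, n_timepoints),
    n_droplets_total = nrow(t0),
    n_droplets_with_cells = sum(!t0$empty),
    n_pairs_1_1 = sum(t0$pair_1_1)
  ), class = "droplet_kinetics")
}

#' @export
print.droplet_kinetics <- function(x, ...) {
  cat("Droplet cytotoxicity kinetics\n")
  cat(sprintf("  droplets analysed: %d (%d with cells, %d 1:1 pairs, %d eligible)\n",
              x$n_droplets_total, x$n_droplets_with_cells, x$n_pairs_1_1,
              nrow(x$eligible)))
  if (!is.na(x$killer$fraction)) {
    cat(sprintf("  killer fraction: %.3f (%d/%d)\n", x$killer$fraction,
                x$killer$n_killers, x$killer$n_eligible))
  }
  if (!is.na(x$kinetics$fast_killer_fraction)) {
    cat(sprintf("  fast killers (<= %g h): %.1f%%\n", x$kinetics$t_fast,
                100 * x$kinetics$fast_killer_fraction))
  }
  if (nrow(x$serial_killers)) {
    cat(sprintf("  serial killers: %d\n", nrow(x$serial_killers)))
  }
  invisible(x)
}
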
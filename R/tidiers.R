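#' Tidy the per-hour lytic-hit histogram of a kinetics summary
#'
#' @param x A `droplet_kinetics` object ([summarise_kinetics()]).
#' @param ... Unused.
#' @return A tibble with one row per hour: `hour`, `n_events`, `fraction`
#'   (of all killer events).
#' @export
tidy.droplet_kinetics <- function(x, ...) {
  h <- x$kinetics$histogram
  tibble::tibble(hour = h$hour, n_events = h$n,
                 fraction = if (x$kinetics$n_events > 0) h$n / x$kinetics$n_events
                            else NA_real_)
}

#' One-row summary of a kinetics analysis
#'
#' @param x A `droplet_kinetics` object.
#' @param ... Unused.
#' @return A one-row tibble: droplet totals, eligibility, killer fraction
#'   and the fast/slow killer split.
#' @export
glance.droplet_kinetics <- function(x, ...) {
  tibble::tibble(
    n_droplets_total = x$n_droplets_total,
    n_droplets_with_cells = x$n_droplets_with_cells,
    n_pairs_1_1 = x$n_pairs_1_1,
    n_eligible = nrow(x$eligible),
    n_excluded_dead_at_t0 = nrow(x$excluded),
    n_killers = x$killer$n_killers,
    killer_fraction = x$killer$fraction,
    fast_killer_fraction = x$kinetics$fast_killer_fraction,
    slow_killer_fraction = x$kinetics$slow_killer_fraction,
    t_fast = x$kinetics$t_fast,
    n_serial_killers = nrow(x$serial_killers)
  )
}

#' Tidy a validation report
#'
#' @param x A `validation_report` ([validate_against_truth()]).
#' @param ... Unused.
#' @return The per-metric comparison tibble.
#' @export
tidy.validation_report <- function(x, ...) x$metrics

#' One-row summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A one-row tibble with `max_deviation_pct`, `n_matched`,
#'   `n_unmatched_tracks`.
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(max_deviation_pct = x$max_deviation_pct,
                 n_matched = x$n_matched,
                 n_unmatched_tracks = x$n_unmatched_tracks)
}
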
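#' Encapsulation parameters for two-species Poisson cell loading
#'
#' Describes the co-flow encapsulation of effector and target cells into
#' picolitre droplets. Cells arrive at the flow-focusing junction at random,
#' so the number of cells of each species in a droplet is Poisson-distributed
#' with mean \eqn{\lambda = c \cdot d \cdot V} where \eqn{c} is the cell
#' concentration in the feed (cells/mL), \eqn{d} the dilution factor (the
#' fraction of the droplet volume contributed by that cell stream; 0.5 for
#' two aqueous inlets at equal flow) and \eqn{V} the droplet volume in pL
#' (1 mL = 1e9 pL). The two species are loaded independently.
#'
#' @param conc_effector,conc_target Cell concentrations in cells/mL.
#' @param droplet_volume_pl Droplet volume in pL.
#' @param dilution_factor Fraction of droplet volume contributed by each
#'   cell stream, in (0, 1].
#'
#' @return An object of class `encapsulation_params`: a list with the inputs
#'   plus derived Poisson means `lambda_effector` and `lambda_target`.
#' @examples
#' p <- encapsulation_params(7e6, 10e6)
#' p$lambda_effector  # 0.245 expected effector cells per droplet
#' @export
encapsulation_params <- function(conc_effector = 7e6,
                                 conc_target = 10e6,
                                 droplet_volume_pl = 70,
                                 dilution_factor = 0.5) {
  stopifnot(
    conc_effector > 0, conc_target > 0,
    droplet_volume_pl > 0,
    dilution_factor > 0, dilution_factor <= 1
  )
  p <- list(
    conc_effector = conc_effector,
    conc_target = conc_target,
    droplet_volume_pl = droplet_volume_pl,
    dilution_factor = dilution_factor,
    lambda_effector = lambda_from_concentration(conc_effector, droplet_volume_pl, dilution_factor),
    lambda_target = lambda_from_concentration(conc_target, droplet_volume_pl, dilution_factor)
  )
  structure(p, class = "encapsulation_params")
}

#' @export
print.encapsulation_params <- function(x, ...) {
  cat("Two-species Poisson encapsulation\n")
  cat(sprintf("  effector: %.3g cells/mL -> lambda = %.4g cells/droplet\n",
              x$conc_effector, x$lambda_effector))
  cat(sprintf("  target:   %.3g cells/mL -> lambda = %.4g cells/droplet\n",
              x$conc_target, x$lambda_target))
  cat(sprintf("  droplet volume %.3g pL, dilution factor %.3g\n",
              x$droplet_volume_pl, x$dilution_factor))
  invisible(x)
}

#' Expected cells per droplet from a feed concentration
#'
#' @param conc Cell concentration in cells/mL; must be positive.
#' @param droplet_volume_pl Droplet volume in pL; must be positive.
#' @param dilution_factor Fraction of droplet volume contributed by the cell
#'   stream, in (0, 1].
#' @return The Poisson mean, cells per droplet.
#' @examples
#' lambda_from_concentration(7e6, 70, 0.5)   # 0.245
#' @export
lambda_from_concentration <- function(conc, droplet_volume_pl, dilution_factor = 0.5) {
  if (any(conc <= 0) || any(droplet_volume_pl <= 0) ||
      any(dilution_factor <= 0) || any(dilution_factor > 1)) {
    stop("conc and droplet_volume_pl must be positive; dilution_factor in (0, 1]")
  }
  conc / 1e9 * dilution_factor * droplet_volume_pl
}

#' Joint occupancy probability of a droplet
#'
#' Probability that a droplet contains exactly `k_effector` effector cells
#' and `k_target` target cells, under independent Poisson loading of the two
#' species.
#'
#' @param params An [encapsulation_params()] object.
#' @param k_effector,k_target Non-negative integer counts (vectorised).
#' @return Probabilities, same length as the recycled `k` vectors.
#' @examples
#' p <- encapsulation_params(7e6, 10e6)
#' occupancy_pmf(p, 1, 1)  # ~ 0.047, the 1:1 pairing probability
#' @export
occupancy_pmf <- function(params, k_effector, k_target) {
  stopifnot(inherits(params, "encapsulation_params"))
  if (any(k_effector < 0) || any(k_target < 0) ||
      any(k_effector != floor(k_effector)) || any(k_target != floor(k_target))) {
    stop("occupancy counts must be non-negative integers")
  }
  dpois(k_effector, params$lambda_effector) * dpois(k_target, params$lambda_target)
}

#' Full occupancy table up to a truncation bound
#'
#' @param params An [encapsulation_params()] object.
#' @param k_max Truncation of the support (per species). At the assay's
#'   loading densities the mass beyond the default is negligible (< 1e-50).
#' @return A tibble with columns `k_effector`, `k_target`, `class`
#'   (an "E:T k:k" label) and `prob`.
#' @export
occupancy_table <- function(params, k_max = 50) {
  grid <- tidyr::expand_grid(k_effector = 0:k_max, k_target = 0:k_max)
  dplyr::mutate(grid,
    class = occupancy_label(.data$k_effector, .data$k_target),
    prob = occupancy_pmf(params, .data$k_effector, .data$k_target)
  )
}

#' Label an occupancy class
#'
#' @param k_effector,k_target Non-negative integer counts.
#' @return Character vector of "E:T k:k" labels.
#' @export
occupancy_label <- function(k_effector, k_target) {
  sprintf("E:T %d:%d", as.integer(k_effector), as.integer(k_target))
}

#' Monte-Carlo simulation of droplet occupancy
#'
#' Draws independent Poisson counts per species for each droplet — the
#' stochastic twin of [occupancy_pmf()].
#'
#' @param params An [encapsulation_params()] object.
#' @param n_droplets Number of droplets to simulate (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with one row per occupancy class: `k_effector`,
#'   `k_target`, `class`, `n`, `frac`.
#' @export
simulate_encapsulation <- function(params, n_droplets, seed = NULL) {
  stopifnot(inherits(params, "encapsulation_params"), n_droplets >= 1)
  if (!is.null(seed)) set.seed(seed)
  ke <- rpois(n_droplets, params$lambda_effector)
  kt <- rpois(n_droplets, params$lambda_target)
  tibble::tibble(k_effector = ke, k_target = kt) |>
    dplyr::count(.data$k_effector, .data$k_target, name = "n") |>
    dplyr::mutate(
      class = occupancy_label(.data$k_effector, .data$k_target),
      frac = .data$n / n_droplets
    ) |>
    dplyr::relocate("class", .after = "k_target")
}

#' Compare an observed occupancy table with the Poisson prediction
#'
#' For each observed occupancy class, reports the observed fraction, the
#' predicted probability under independent Poisson loading, and the absolute
#' and relative deviation. The function reports disagreement as-is: with the
#' assay's stated loading densities the observed 1:1 pairing fraction falls
#' below the naive Poisson prediction, and that gap is part of the output.
#'
#' @param observed A data frame with columns `k_effector`, `k_target`, `n`
#'   (non-negative counts, total > 0) — e.g. the output of
#'   [simulate_encapsulation()] or a census-derived count table.
#' @param params An [encapsulation_params()] object.
#' @return A tibble with columns `k_effector`, `k_target`, `class`,
#'   `observed_n`, `observed_frac`, `predicted_frac`, `abs_dev`, `rel_dev`.
#' @export
compare_observed_predicted <- function(observed, params) {
  stopifnot(is.data.frame(observed),
            all(c("k_effector", "k_target", "n") %in% names(observed)))
  if (nrow(observed) == 0) stop("observed occupancy table is empty")
  if (any(observed$n < 0)) stop("observed counts must be non-negative")
  total <- sum(observed$n)
  if (total <= 0) stop("observed occupancy table has zero total count")
  observed |>
    dplyr::transmute(
      k_effector = .data$k_effector,
      k_target = .data$k_target,
      class = occupancy_label(.data$k_effector, .data$k_target),
      observed_n = .data$n,
      observed_frac = .data$n / total,
      predicted_frac = occupancy_pmf(params, .data$k_effector, .data$k_target),
      abs_dev = abs(.data$observed_frac - .data$predicted_frac),
      rel_dev = .data$abs_dev / .data$predicted_frac
    ) |>
    tibble::as_tibble()
}
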
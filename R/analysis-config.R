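#' Analysis configuration for the droplet pipeline
#'
#' Collects every tunable parameter of the detection, tracking, counting
#' and kinetics stages. Pixel-unit defaults are derived from the nominal
#' droplet and cell sizes in micrometres.
#'
#' @param pixel_size_um Pixel size, um/px.
#' @param droplet_radius_um Nominal droplet radius, um.
#' @param cell_diameter_um Nominal cell diameter, um.
#' @param radius_factor Hough radius search range as multiples of the
#'   nominal radius (default 0.8–1.2x).
#' @param radius_step Hough radius grid step, px.
#' @param sensitivity Ring-contrast score threshold for [find_droplets()].
#' @param stretch_pct Contrast-stretch percentiles for the brightfield.
#' @param allowed_movement_factor Allowed inter-frame movement as a fraction
#'   of the nominal droplet radius (kept below 1: beyond the radius a
#'   different droplet can be picked up at the next timepoint).
#' @param crop_margin_px Extra margin around the droplet disk when cropping.
#' @param tophat_factor Top-hat structuring-element radius as a multiple of
#'   the nominal cell radius.
#' @param area_factor Component area bounds as multiples of the nominal
#'   cell area (pi r^2).
#' @param contrast_floor Minimum top-hat foreground level inside the disk
#'   for a droplet crop to be considered non-empty; below it the binary is
#'   empty (guards Otsu against splitting pure background noise).
#' @param theta Viability intensity threshold for death calling (on
#'   background-corrected intensities).
#' @param persistence Number of consecutive frames the viability signal
#'   must stay above `theta` (1 is appropriate for hourly sampling, since
#'   the dye signal is stable after death).
#' @param t_fast Fast/slow killer boundary, hours.
#' @param validation_timepoints Hours at which [validate_against_truth()]
#'   compares pipeline outputs with ground truth.
#' @return An `analysis_config` list with derived pixel-unit fields:
#'   `radius_range`, `allowed_movement`, `tophat_radius`, `min_area`,
#'   `max_area`, `cell_diameter_px`.
#' @export
analysis_config <- function(pixel_size_um = 2,
                            droplet_radius_um = 25,
                            cell_diameter_um = 10,
                            radius_factor = c(0.8, 1.2),
                            radius_step = 0.5,
                            sensitivity = 0.45,
                            stretch_pct = c(1, 99),
                            allowed_movement_factor = 0.5,
                            crop_margin_px = 2,
                            tophat_factor = 1.5,
                            area_factor = c(0.25, 4),
                            contrast_floor = 0.1,
                            theta = 0.1,
                            persistence = 1,
                            t_fast = 4,
                            validation_timepoints = c(3, 4, 10)) {
  cfg <- as.list(environment())
  stopifnot(cfg$pixel_size_um > 0, cfg$droplet_radius_um > 0,
            cfg$cell_diameter_um > 0, length(cfg$radius_factor) == 2,
            cfg$persistence >= 1, cfg$theta >= 0)
  r_px <- cfg$droplet_radius_um / cfg$pixel_size_um
  cell_px <- cfg$cell_diameter_um / cfg$pixel_size_um
  cell_area <- pi * (cell_px / 2)^2
  cfg$droplet_radius_px <- r_px
  cfg$cell_diameter_px <- cell_px
  cfg$radius_range <- cfg$radius_factor * r_px
  cfg$allowed_movement <- cfg$allowed_movement_factor * r_px
  cfg$tophat_radius <- cfg$tophat_factor * cell_px / 2
  cfg$min_area <- cfg$area_factor[1] * cell_area
  cfg$max_area <- cfg$area_factor[2] * cell_area
  structure(cfg, class = "analysis_config")
}
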
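#' Configuration for the synthetic time-lapse generator
#'
#' Defines a simulated droplet cytotoxicity experiment: immobilised ~50 um
#' water-in-oil droplets hex-packed in square tiles, two-species Poisson
#' cell loading, hourly imaging over four channels (brightfield plus
#' effector-tracker, target-tracker and viability fluorescence), small
#' per-frame droplet jitter and an occasional large displacement ("mover").
#'
#' Dye behaviour emulated: the target tracker is stable over the experiment;
#' the effector tracker decays exponentially (calcein-like) with a
#' configurable half-life; the viability channel sits at background for a
#' live cell and switches to a bright, stable signal from the cell's death
#' hour onward.
#'
#' @param tile_px Side of a square tile in pixels.
#' @param n_tiles Number of independent tiles (fields of view).
#' @param pixel_size_um Pixel size, um/px.
#' @param droplet_diameter_um,droplet_diameter_sd_um Droplet diameter mean
#'   and standard deviation, um. Radii are constant over time per droplet.
#' @param lattice_fill Fraction of hex-lattice sites occupied by a droplet;
#'   vacant sites are the landing spots for movers.
#' @param encapsulation An [encapsulation_params()] object (cell loading).
#' @param n_timepoints Number of hourly frames (t = 0 .. n-1 h); >= 2.
#' @param jitter_sd_px Per-frame droplet centre jitter, px.
#' @param mover_fraction Fraction of droplets given one displacement far
#'   beyond the tracker's allowed movement, at a random frame.
#' @param cell_diameter_um Cell diameter, um (rendered spot FWHM).
#' @param cell_jitter_sd_px Per-frame jitter of a cell within its droplet.
#' @param bf_background,bf_ring_depth,bf_ring_width_px Brightfield level,
#'   rim darkness and rim radial width.
#' @param fluor_background Fluorescence background level (all channels).
#' @param target_amp Target-tracker spot amplitude (stable).
#' @param effector_amp,effector_half_life_h Effector-tracker amplitude at
#'   t = 0 and its decay half-life in hours.
#' @param viability_amp Viability spot amplitude after death (stable).
#' @param noise_sd Additive Gaussian noise sd on every frame.
#' @param killer_prob Probability that a target co-encapsulated with at
#'   least one effector is killed during the window.
#' @param death_rate_per_h Rate of the exponential lytic-hit time model;
#'   death hours are the discretised exponential over 1..(n_timepoints-1).
#' @param spontaneous_death_prob Probability that a target in an
#'   effector-free droplet dies spontaneously during the window (late
#'   hours); the effector-free stratum is the assay's negative control.
#' @param effector_death_prob Spontaneous effector death probability
#'   (default off).
#' @param seed Integer seed; the whole experiment is reproducible from it.
#'
#' @return A `generator_config` list.
#' @export
generator_config <- function(tile_px = 512,
                             n_tiles = 6,
                             pixel_size_um = 2,
                             droplet_diameter_um = 50,
                             droplet_diameter_sd_um = 2,
                             lattice_fill = 0.92,
                             encapsulation = encapsulation_params(),
                             n_timepoints = 11,
                             jitter_sd_px = 0.5,
                             mover_fraction = 0.02,
                             cell_diameter_um = 10,
                             cell_jitter_sd_px = 0.3,
                             bf_background = 0.85,
                             bf_ring_depth = 0.7,
                             bf_ring_width_px = 1.0,
                             fluor_background = 0.02,
                             target_amp = 0.7,
                             effector_amp = 0.7,
                             effector_half_life_h = 10,
                             viability_amp = 0.7,
                             noise_sd = 0.01,
                             killer_prob = 0.2,
                             death_rate_per_h = 0.5,
                             spontaneous_death_prob = 0.05,
                             effector_death_prob = 0,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_timepoints >= 2,
    cfg$droplet_diameter_um > cfg$cell_diameter_um, cfg$cell_diameter_um > 0,
    cfg$killer_prob >= 0, cfg$killer_prob <= 1,
    cfg$mover_fraction >= 0, cfg$mover_fraction < 1,
    cfg$lattice_fill > 0, cfg$lattice_fill <= 1,
    inherits(cfg$encapsulation, "encapsulation_params")
  )
  cfg$droplet_radius_px <- cfg$droplet_diameter_um / 2 / cfg$pixel_size_um
  cfg$cell_radius_px <- cfg$cell_diameter_um / 2 / cfg$pixel_size_um
  structure(cfg, class = "generator_config")
}

channel_names <- function() c("brightfield", "effector_tracker", "target_tracker", "viability")

# Discretised exponential lytic-hit time model over hours 1..(T-1):
# P(h) proportional to F(h) - F(h-1) with F the Exp(rate) cdf.
death_time_probs <- function(n_timepoints, rate) {
  hours <- seq_len(n_timepoints - 1)
  p <- stats::pexp(hours, rate) - stats::pexp(hours - 1, rate)
  p / sum(p)
}

#' Assign death fates to encapsulated cells
#'
#' Each target cell sharing its droplet with at least one effector dies with
#' probability `killer_prob`, at an hour drawn from `death_probs` (index =
#' hour). Targets in effector-free droplets (the negative-control stratum)
#' die with probability `spontaneous_death_prob`, in the late half of the
#' window. Effector cells die with probability `effector_death_prob`
#' (default never).
#'
#' @param cells A tibble with one row per cell: `cell_id`, `droplet_id`,
#'   `cell_type` ("effector"/"target").
#' @param killer_prob Kill probability for co-encapsulated targets.
#' @param death_probs Probability vector over death hours 1..length.
#' @param n_timepoints Number of hourly frames.
#' @param spontaneous_death_prob,effector_death_prob See above.
#' @return `cells` with a `death_time` column (hour index, NA = survives).
#' @export
sample_fates <- function(cells, killer_prob, death_probs,
                         n_timepoints,
                         spontaneous_death_prob = 0,
                         effector_death_prob = 0) {
  stopifnot(killer_prob >= 0, killer_prob <= 1)
  if (nrow(cells) == 0) return(dplyr::mutate(cells, death_time = integer(0)))
  has_eff <- cells |>
    dplyr::group_by(.data$droplet_id) |>
    dplyr::summarise(n_eff = sum(.data$cell_type == "effector"), .groups = "drop")
  cells <- dplyr::left_join(cells, has_eff, by = "droplet_id")
  hours <- seq_along(death_probs)
  late_hours <- hours[hours > (n_timepoints - 1) / 2]
  n <- nrow(cells)
  death <- rep(NA_integer_, n)
  is_target <- cells$cell_type == "target"
  exposed <- is_target & cells$n_eff > 0
  killed <- exposed & runif(n) < killer_prob
  death[killed] <- sample(hours, sum(killed), replace = TRUE, prob = death_probs)
  spont <- is_target & cells$n_eff == 0 & runif(n) < spontaneous_death_prob
  death[spont] <- if (length(late_hours)) {
    sample(late_hours, sum(spont), replace = TRUE)
  } else {
    sample(hours, sum(spont), replace = TRUE, prob = death_probs)
  }
  eff_dead <- !is_target & runif(n) < effector_death_prob
  death[eff_dead] <- sample(hours, sum(eff_dead), replace = TRUE, prob = death_probs)
  cells$death_time <- death
  dplyr::select(cells, -"n_eff")
}

# Hex-lattice site centres for one tile, leaving a margin so droplets never
# touch the tile border (border droplets are a detection test case, not a
# default condition).
hex_sites <- function(tile_px, pitch_px, margin_px) {
  row_pitch <- pitch_px * sqrt(3) / 2
  ys <- seq(margin_px, tile_px - 1 - margin_px, by = row_pitch)
  sites <- purrr::map_dfr(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) pitch_px / 2 else 0
    xs <- seq(margin_px + off, tile_px - 1 - margin_px, by = pitch_px)
    tibble::tibble(x = xs, y = ys[i])
  })
  sites
}

# Rejection-sample n cell offsets inside a droplet with pairwise separation.
# Cells sediment side by side rather than stacking, so overlapping spots are
# rare in practice; separation keeps rendered spots resolvable.
place_cells <- function(n, r_inner, min_sep, max_try = 200) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  for (attempt in seq_len(max_try)) {
    th <- runif(n, 0, 2 * pi)
    rr <- r_inner * sqrt(runif(n))
    xy <- cbind(rr * cos(th), rr * sin(th))
    if (n == 1 || min(stats::dist(xy)) >= min_sep) return(xy)
  }
  # crowded droplet: rejection sampling rarely hits a valid configuration,
  # so fall back to a randomly rotated ring of maximal mutual separation
  th <- 2 * pi * (0:(n - 1)) / n + runif(1, 0, 2 * pi)
  R <- max(r_inner - 0.5, 1)
  cbind(R * cos(th), R * sin(th)) + matrix(rnorm(2 * n, 0, 0.3), n, 2)
}

add_spot <- function(img, x, y, sigma, amp, extent) {
  # x, y are 0-based scene coordinates; img is [row, col] = [y+1, x+1]
  n <- nrow(img)
  cx <- round(x); cy <- round(y)
  xs <- max(0, cx - extent):min(n - 1, cx + extent)
  ys <- max(0, cy - extent):min(n - 1, cy + extent)
  if (!length(xs) || !length(ys)) return(img)
  dx2 <- (xs - x)^2; dy2 <- (ys - y)^2
  patch <- amp * exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + patch
  img
}

add_ring <- function(img, x, y, r, depth, width) {
  n <- nrow(img)
  extent <- ceiling(r + 3 * width)
  cx <- round(x); cy <- round(y)
  xs <- max(0, cx - extent):min(n - 1, cx + extent)
  ys <- max(0, cy - extent):min(n - 1, cy + extent)
  if (!length(xs) || !length(ys)) return(img)
  d <- sqrt(outer((ys - y)^2, (xs - x)^2, "+"))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] - depth * exp(-((d - r) / width)^2)
  img
}

#' Generate a ground-truthed synthetic droplet time-lapse experiment
#'
#' Produces the full image stack (tile x timepoint x channel matrices with
#' intensities in \[0, 1\]) together with the per-droplet and per-cell ground
#' truth used as the oracle by the validation harness. Deterministic for a
#' fixed `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A `droplet_experiment` list:
#'   \describe{
#'     \item{images}{`images[[tile]][[timepoint + 1]][[channel]]`, matrices.}
#'     \item{droplets}{Per-droplet, per-timepoint truth: `droplet_id`,
#'       `tile_id`, `timepoint`, `x`, `y`, `radius_px`, `is_mover`.}
#'     \item{cells}{Per-cell, per-timepoint truth: `cell_id`, `droplet_id`,
#'       `tile_id`, `timepoint`, `x`, `y`, `cell_type`, `death_time`.}
#'     \item{config}{The configuration used.}
#'   }
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  r_nom <- config$droplet_radius_px
  r_max <- r_nom + 2.5 * config$droplet_diameter_sd_um / 2 / config$pixel_size_um
  pitch <- 2 * r_max + 8
  margin <- r_max + 5
  if (2 * margin >= config$tile_px) stop("tile too small for the droplet layout")

  n_t <- config$n_timepoints
  sigma_cell <- config$cell_diameter_um / config$pixel_size_um / 2.355  # FWHM = diameter

  all_droplets <- list(); all_cells <- list()
  vacancies <- list(); next_id <- 1L; next_cell <- 1L

  # --- sample ground truth per tile ---
  for (tile in seq_len(config$n_tiles)) {
    sites <- hex_sites(config$tile_px, pitch, margin)
    if (nrow(sites) < 2) stop("tile too small for the droplet layout")
    occ <- runif(nrow(sites)) < config$lattice_fill
    n_d <- sum(occ)
    if (n_d == 0) next
    vac <- sites[!occ, , drop = FALSE]
    dro <- sites[occ, , drop = FALSE]
    radius <- pmin(pmax(rnorm(n_d, r_nom, config$droplet_diameter_sd_um / 2 / config$pixel_size_um),
                        r_nom * 0.85), r_max)
    is_mover <- runif(n_d) < config$mover_fraction
    # movers land on vacant sites; cap at availability
    if (sum(is_mover) > nrow(vac)) {
      is_mover[sample(which(is_mover), sum(is_mover) - nrow(vac))] <- FALSE
    }
    jump_site <- rep(NA_integer_, n_d)
    if (any(is_mover)) {
      jump_site[is_mover] <- sample(nrow(vac), sum(is_mover))
    }
    jump_frame <- ifelse(is_mover, sample(seq_len(n_t - 1), n_d, replace = TRUE), NA_integer_)

    ids <- next_id:(next_id + n_d - 1L); next_id <- next_id + n_d
    # per-timepoint centres: base + independent jitter per frame
    for (i in seq_len(n_d)) {
      base_x <- rep(dro$x[i], n_t); base_y <- rep(dro$y[i], n_t)
      if (is_mover[i]) {
        tt <- (jump_frame[i] + 1):n_t
        base_x[tt] <- vac$x[jump_site[i]]
        base_y[tt] <- vac$y[jump_site[i]]
      }
      all_droplets[[length(all_droplets) + 1L]] <- tibble::tibble(
        droplet_id = ids[i], tile_id = tile, timepoint = 0:(n_t - 1),
        x = base_x + rnorm(n_t, 0, config$jitter_sd_px),
        y = base_y + rnorm(n_t, 0, config$jitter_sd_px),
        radius_px = radius[i], is_mover = is_mover[i]
      )
    }
    # cells
    ke <- rpois(n_d, config$encapsulation$lambda_effector)
    kt <- rpois(n_d, config$encapsulation$lambda_target)
    for (i in seq_len(n_d)) {
      n_c <- ke[i] + kt[i]
      if (n_c == 0) next
      off <- place_cells(n_c, radius[i] - config$cell_radius_px - 1,
                         min_sep = 2.1 * config$cell_diameter_um / config$pixel_size_um)
      types <- c(rep("effector", ke[i]), rep("target", kt[i]))
      all_cells[[length(all_cells) + 1L]] <- tibble::tibble(
        cell_id = next_cell:(next_cell + n_c - 1L),
        droplet_id = ids[i], tile_id = tile,
        cell_type = types, off_x = off[, 1], off_y = off[, 2]
      )
      next_cell <- next_cell + n_c
    }
  }

  droplets <- dplyr::bind_rows(all_droplets)
  cells0 <- dplyr::bind_rows(all_cells)
  if (nrow(cells0) == 0) {
    cells0 <- tibble::tibble(cell_id = integer(), droplet_id = integer(),
                             tile_id = integer(), cell_type = character(),
                             off_x = numeric(), off_y = numeric())
  }

  fates <- sample_fates(
    dplyr::select(cells0, "cell_id", "droplet_id", "cell_type"),
    killer_prob = config$killer_prob,
    death_probs = death_time_probs(n_t, config$death_rate_per_h),
    n_timepoints = n_t,
    spontaneous_death_prob = config$spontaneous_death_prob,
    effector_death_prob = config$effector_death_prob
  )
  cells0 <- dplyr::left_join(cells0, dplyr::select(fates, "cell_id", "death_time"),
                             by = "cell_id")

  # per-timepoint cell positions: droplet centre + fixed offset + small
  # jitter. For multi-cell droplets the jitter is redrawn (a few tries)
  # when it would push two cells closer than the rendering separation, so
  # that distinct cells stay resolvable over time; on failure the cells
  # fall back to their base offsets.
  keep_sep <- 1.9 * config$cell_diameter_um / config$pixel_size_um
  cells <- if (nrow(cells0)) {
    long <- tidyr::expand_grid(cells0, timepoint = 0:(n_t - 1)) |>
      dplyr::left_join(dplyr::select(droplets, "droplet_id", "timepoint",
                                     drop_x = "x", drop_y = "y"),
                       by = c("droplet_id", "timepoint")) |>
      dplyr::arrange(.data$droplet_id, .data$timepoint, .data$cell_id)
    n_long <- nrow(long)
    jit_x <- rnorm(n_long, 0, config$cell_jitter_sd_px)
    jit_y <- rnorm(n_long, 0, config$cell_jitter_sd_px)
    grp <- interaction(long$droplet_id, long$timepoint, drop = TRUE)
    for (ix in split(seq_len(n_long), grp)) {
      if (length(ix) < 2) next
      for (try in 1:20) {
        xy <- cbind(long$off_x[ix] + jit_x[ix], long$off_y[ix] + jit_y[ix])
        if (min(stats::dist(xy)) >= keep_sep) break
        jit_x[ix] <- rnorm(length(ix), 0, config$cell_jitter_sd_px)
        jit_y[ix] <- rnorm(length(ix), 0, config$cell_jitter_sd_px)
        if (try == 20) { jit_x[ix] <- 0; jit_y[ix] <- 0 }
      }
    }
    long |>
      dplyr::mutate(x = .data$drop_x + .data$off_x + jit_x,
                    y = .data$drop_y + .data$off_y + jit_y) |>
      dplyr::select("cell_id", "droplet_id", "tile_id", "timepoint",
                    "x", "y", "cell_type", "death_time")
  } else {
    tibble::tibble(cell_id = integer(), droplet_id = integer(), tile_id = integer(),
                   timepoint = integer(), x = numeric(), y = numeric(),
                   cell_type = character(), death_time = integer())
  }

  images <- render_experiment(droplets, cells, config, sigma_cell)

  structure(list(images = images, droplets = droplets, cells = cells,
                 config = config),
            class = "droplet_experiment")
}

render_experiment <- function(droplets, cells, config, sigma_cell) {
  n_t <- config$n_timepoints
  L <- config$tile_px
  spot_extent <- ceiling(4 * sigma_cell)
  tiles <- seq_len(config$n_tiles)
  images <- vector("list", config$n_tiles)
  for (tile in tiles) {
    dt <- droplets[droplets$tile_id == tile, ]
    ct <- cells[cells$tile_id == tile, ]
    per_t <- vector("list", n_t)
    for (t in 0:(n_t - 1)) {
      dtt <- dt[dt$timepoint == t, ]
      ctt <- ct[ct$timepoint == t, ]
      chans <- list()
      # brightfield: light field with dark droplet rims
      bf <- matrix(config$bf_background, L, L)
      for (i in seq_len(nrow(dtt))) {
        bf <- add_ring(bf, dtt$x[i], dtt$y[i], dtt$radius_px[i],
                       config$bf_ring_depth, config$bf_ring_width_px)
      }
      chans$brightfield <- bf
      # fluorescence channels
      eff_amp_t <- config$effector_amp * 2^(-t / config$effector_half_life_h)
      for (ch in c("effector_tracker", "target_tracker", "viability")) {
        img <- matrix(config$fluor_background, L, L)
        vis <- switch(ch,
          effector_tracker = ctt[ctt$cell_type == "effector", ],
          target_tracker = ctt[ctt$cell_type == "target", ],
          viability = ctt[!is.na(ctt$death_time) & ctt$death_time <= t, ]
        )
        amp <- switch(ch,
          effector_tracker = eff_amp_t,
          target_tracker = config$target_amp,
          viability = config$viability_amp
        )
        for (i in seq_len(nrow(vis))) {
          img <- add_spot(img, vis$x[i], vis$y[i], sigma_cell, amp, spot_extent)
        }
        chans[[ch]] <- img
      }
      per_t[[t + 1]] <- lapply(chans, function(m) {
        m <- m + matrix(rnorm(L * L, 0, config$noise_sd), L, L)
        m[m < 0] <- 0; m[m > 1] <- 1
        m
      })
    }
    images[[tile]] <- per_t
  }
  images
}

#' Table-level simulation of a cytotoxicity cohort
#'
#' Generates per-droplet occupancy, fates and idealised background-corrected
#' viability traces directly at the table level — the same statistical model
#' the image generator uses, without rendering pixels. Intended for studying
#' the kinetics estimators (eligibility, death calling, killer fraction) at
#' cohort sizes where rendering whole image stacks is unnecessary.
#'
#' @param n_droplets Number of droplets.
#' @param params An [encapsulation_params()] object.
#' @param killer_prob,death_rate_per_h,spontaneous_death_prob As in
#'   [generator_config()].
#' @param n_timepoints Hourly frames.
#' @param viability_amp,noise_sd Trace level after death and Gaussian noise
#'   on every trace sample.
#' @param seed Integer seed.
#' @return A list with `census` (one row per droplet x timepoint, same
#'   columns as the image pipeline census) and `traces` (per droplet x
#'   cell type x timepoint viability intensity), plus the `cells` truth.
#' @export
simulate_cohort <- function(n_droplets, params = encapsulation_params(),
                            killer_prob = 0.2, death_rate_per_h = 0.5,
                            spontaneous_death_prob = 0.05,
                            n_timepoints = 11,
                            viability_amp = 0.7, noise_sd = 0.01,
                            seed = 1L) {
  set.seed(seed)
  ke <- rpois(n_droplets, params$lambda_effector)
  kt <- rpois(n_droplets, params$lambda_target)
  cells <- tibble::tibble(
    droplet_id = rep(seq_len(n_droplets), ke + kt),
    cell_type = unlist(purrr::map2(ke, kt, ~ c(rep("effector", .x), rep("target", .y))),
                       use.names = FALSE)
  )
  cells$cell_id <- seq_len(nrow(cells))
  cells <- sample_fates(cells, killer_prob,
                        death_time_probs(n_timepoints, death_rate_per_h),
                        n_timepoints,
                        spontaneous_death_prob = spontaneous_death_prob)
  # idealised traces: one per droplet x cell type (channel-level signal)
  per_type <- cells |>
    dplyr::group_by(.data$droplet_id, .data$cell_type) |>
    dplyr::summarise(first_death = suppressWarnings(min(.data$death_time, na.rm = TRUE)),
                     n_dead = sum(!is.na(.data$death_time)), .groups = "drop")
  traces <- tidyr::expand_grid(per_type, timepoint = 0:(n_timepoints - 1)) |>
    dplyr::mutate(
      intensity = pmax(0, ifelse(is.finite(.data$first_death) & .data$timepoint >= .data$first_death,
                                 viability_amp, 0) +
                          rnorm(dplyr::n(), 0, noise_sd))
    ) |>
    dplyr::transmute(track_id = .data$droplet_id, cell_type = .data$cell_type,
                     timepoint = .data$timepoint, intensity = .data$intensity)

  census <- tidyr::expand_grid(
    tibble::tibble(track_id = seq_len(n_droplets), k_effector = ke, k_target = kt),
    timepoint = 0:(n_timepoints - 1)
  )
  dead_tbl <- cells |>
    dplyr::filter(!is.na(.data$death_time)) |>
    dplyr::select("droplet_id", "cell_type", "death_time")
  census <- census |>
    dplyr::left_join(
      dead_tbl |>
        dplyr::group_by(.data$droplet_id, .data$cell_type) |>
        dplyr::summarise(times = list(.data$death_time), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "cell_type", values_from = "times",
                           names_prefix = "deaths_"),
      by = c(track_id = "droplet_id")
    )
  if (!"deaths_target" %in% names(census)) census$deaths_target <- list(NULL)
  if (!"deaths_effector" %in% names(census)) census$deaths_effector <- list(NULL)
  census <- census |>
    dplyr::mutate(
      dead_target = purrr::map2_int(.data$deaths_target, .data$timepoint,
                                    ~ sum(unlist(.x) <= .y)),
      dead_effector = purrr::map2_int(.data$deaths_effector, .data$timepoint,
                                      ~ sum(unlist(.x) <= .y)),
      dead_unknown = 0L,
      n_effector = .data$k_effector, n_target = .data$k_target,
      n_viability = .data$dead_target + .data$dead_effector,
      occupancy = occupancy_label(.data$k_effector, .data$k_target),
      status = "complete", tile_id = 1L
    ) |>
    dplyr::select("track_id", "tile_id", "timepoint", "n_effector", "n_target",
                  "n_viability", "dead_effector", "dead_target", "dead_unknown",
                  "status") |>
    census_droplet()
  list(census = census, traces = traces, cells = cells)
}
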
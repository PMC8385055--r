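#' Percentile contrast stretching
#'
#' Linearly rescales the intensity window between the `low_pct` and
#' `high_pct` percentiles to \[0, 1\], clipping outside. Used on brightfield
#' frames so the droplet rims dominate the dynamic range before circle
#' detection.
#'
#' @param image Numeric matrix.
#' @param low_pct,high_pct Percentiles in \[0, 100\], `low_pct < high_pct`.
#' @return The stretched matrix. A constant image is returned unchanged
#'   with attribute `constant = TRUE`.
#' @export
stretch_contrast <- function(image, low_pct = 1, high_pct = 99) {
  stopifnot(is.matrix(image), low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  qs <- quantile(image, c(low_pct, high_pct) / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    attr(image, "constant") <- TRUE
    return(image)
  }
  out <- (image - qs[1]) / (qs[2] - qs[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Ring-minus-interior template for one radius: positive weights (mean) on an
# annulus of the given radius, negative weights (mean) on an interior disk.
# Convolving the inverted brightfield with it scores "dark rim around a
# light interior" and is ~0 on structureless background.
ring_kernel <- function(radius, extent, ring_width = 1) {
  sz <- 2 * extent + 1
  d <- sqrt(outer((-extent:extent)^2, (-extent:extent)^2, "+"))
  ring <- abs(d - radius) <= ring_width
  inner <- d <= 0.6 * radius
  k <- matrix(0, sz, sz)
  k[ring] <- 1 / sum(ring)
  k[inner] <- k[inner] - 1 / sum(inner)
  k
}

#' Detect droplets in a brightfield frame
#'
#' Circular Hough-style detection: the contrast-stretched, inverted
#' brightfield is convolved (FFT) with ring templates over a radius grid;
#' the per-pixel best ring-contrast score is thresholded, candidate centres
#' are kept greedily in descending score order with a minimum centre
#' separation, and detections whose disk touches the tile border are
#' dropped. Deterministic.
#'
#' @param brightfield Numeric matrix (one tile, one timepoint).
#' @param radius_range `c(r_min, r_max)` in px.
#' @param sensitivity Ring-contrast score threshold in (0, 1); lower accepts
#'   fainter rims.
#' @param radius_step Radius grid step, px.
#' @param low_pct,high_pct Contrast-stretch percentiles.
#' @return A tibble: `droplet_index` (1..n in descending score order), `x`,
#'   `y` (0-based pixel coordinates, origin top-left), `radius`, `score`.
#' @export
find_droplets <- function(brightfield, radius_range, sensitivity = 0.45,
                          radius_step = 0.5, low_pct = 1, high_pct = 99) {
  stopifnot(length(radius_range) == 2, all(radius_range > 0),
            radius_range[1] <= radius_range[2])
  inv <- 1 - stretch_contrast(brightfield, low_pct, high_pct)
  radii <- seq(radius_range[1], radius_range[2], by = radius_step)
  extent <- ceiling(max(radii) + 2)
  best <- matrix(-Inf, nrow(inv), ncol(inv))
  best_r <- matrix(radii[1], nrow(inv), ncol(inv))
  for (r in radii) {
    resp <- EBImage::filter2(inv, ring_kernel(r, extent), boundary = "replicate")
    upd <- resp > best
    best[upd] <- resp[upd]
    best_r[upd] <- r
  }
  cand <- which(best > sensitivity, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(droplet_index = integer(), x = numeric(), y = numeric(),
                          radius = numeric(), score = numeric()))
  }
  sc <- best[cand]
  ord <- order(-sc)
  cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]
  min_sep <- radius_range[1]
  acc_x <- numeric(0); acc_y <- numeric(0); acc_r <- numeric(0); acc_s <- numeric(0)
  for (i in seq_along(sc)) {
    px <- unname(cand[i, 2]) - 1; py <- unname(cand[i, 1]) - 1  # 0-based x (col), y (row)
    if (length(acc_x) == 0 || min((acc_x - px)^2 + (acc_y - py)^2) >= min_sep^2) {
      acc_x <- c(acc_x, px); acc_y <- c(acc_y, py)
      acc_r <- c(acc_r, best_r[cand[i, 1], cand[i, 2]]); acc_s <- c(acc_s, sc[i])
    }
  }
  det <- tibble::tibble(x = acc_x, y = acc_y, radius = acc_r, score = acc_s)
  # border rule: the whole disk must lie inside the tile
  w <- ncol(brightfield); h <- nrow(brightfield)
  det <- dplyr::filter(det,
    .data$x - .data$radius >= 0, .data$x + .data$radius <= w - 1,
    .data$y - .data$radius >= 0, .data$y + .data$radius <= h - 1)
  det$droplet_index <- seq_len(nrow(det))
  dplyr::relocate(det, "droplet_index")
}

#' Label image of detected droplets
#'
#' Paints each detection's disk (pixel centre within the radius) with its
#' `droplet_index`. Where disks overlap, the higher-score detection wins
#' (detections are painted in descending score order and never overwritten);
#' overlaps are reported in attribute `n_overlap_px`.
#'
#' @param detections Tibble from [find_droplets()].
#' @param image_shape `c(n_rows, n_cols)`.
#' @return Integer matrix of droplet indices (0 = background).
#' @export
make_droplet_mask <- function(detections, image_shape) {
  mask <- matrix(0L, image_shape[1], image_shape[2])
  n_overlap <- 0L
  ord <- order(-detections$score)
  for (i in ord) {
    x <- detections$x[i]; y <- detections$y[i]; r <- detections$radius[i]
    xs <- max(0, floor(x - r)):min(image_shape[2] - 1, ceiling(x + r))
    ys <- max(0, floor(y - r)):min(image_shape[1] - 1, ceiling(y + r))
    inside <- outer((ys - y)^2, (xs - x)^2, "+") <= r^2
    sub <- mask[ys + 1, xs + 1, drop = FALSE]
    n_overlap <- n_overlap + sum(inside & sub != 0L)
    sub[inside & sub == 0L] <- detections$droplet_index[i]
    mask[ys + 1, xs + 1] <- sub
  }
  attr(mask, "n_overlap_px") <- n_overlap
  mask
}

#' Run droplet detection over a whole experiment
#'
#' Applies [find_droplets()] to the brightfield channel of every tile and
#' timepoint.
#'
#' @param experiment A `droplet_experiment` (from [generate_experiment()] or
#'   [read_experiment()]).
#' @param analysis An [analysis_config()].
#' @return A tibble of detections with `tile_id` and `timepoint` columns.
#' @export
detect_experiment <- function(experiment, analysis = analysis_config()) {
  purrr::map_dfr(seq_along(experiment$images), function(tile) {
    purrr::map_dfr(seq_along(experiment$images[[tile]]), function(ti) {
      bf <- experiment$images[[tile]][[ti]]$brightfield
      det <- find_droplets(bf, analysis$radius_range, analysis$sensitivity,
                           analysis$radius_step, analysis$stretch_pct[1],
                           analysis$stretch_pct[2])
      det$tile_id <- tile
      det$timepoint <- ti - 1L
      det
    })
  })
}
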
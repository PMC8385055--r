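# a synthetic fluorescence frame: background + Gaussian spots
spot_frame <- function(n = 64, spots = list(), bg = 0.02, sigma = 2.1,
                      amp = 0.7) {
  img <- matrix(bg, n, n)
  for (s in spots) {
    d2 <- outer((0:(n - 1) - s[2])^2, (0:(n - 1) - s[1])^2, "+")
    img <- img + amp * exp(-d2 / (2 * sigma^2))
  }
  img
}

droplet_at <- function(x, y, r = 12.5) {
  tibble::tibble(droplet_index = 1L, x = x, y = y, radius = r, score = 1)
}

test_that("a signal-free droplet crop binarises to all-false", {
  img <- spot_frame(64)
  pre <- preprocess_channel(img, droplet_at(32, 32), tophat_radius = 3.75)
  expect_false(any(pre$binary))
  expect_true(is.na(pre$threshold))
})

test_that("a bright spot at the droplet centre yields one component containing the peak", {
  img <- spot_frame(64, list(c(32, 32)))
  pre <- preprocess_channel(img, droplet_at(32, 32), tophat_radius = 3.75)
  cc <- count_cells(pre$binary, 5, 79)
  expect_equal(cc$count, 1)
  # the component contains the spot peak (= droplet centre here)
  peak_rc <- c(32 - pre$y0 + 1, 32 - pre$x0 + 1)
  expect_true(pre$binary[peak_rc[1], peak_rc[2]])
})

test_that("signal outside the droplet disk is masked away", {
  # spot centred 2 px outside the disk edge
  img <- spot_frame(64, list(c(32 + 12.5 + 2, 32)), sigma = 1.2)
  pre <- preprocess_channel(img, droplet_at(32, 32), tophat_radius = 3.75)
  cc <- count_cells(pre$binary, 5, 79)
  expect_equal(cc$count, 0)
})

test_that("components are counted with 8-connectivity and area bounds", {
  bin <- matrix(FALSE, 32, 32)
  bin[5:10, 5:9] <- TRUE     # 30 px
  bin[20:25, 20:24] <- TRUE  # 30 px
  cc <- count_cells(bin, 10, 500)
  expect_equal(cc$count, 2)
  # a 4-px speck is filtered out by min_area
  bin2 <- bin; bin2[15, 15] <- TRUE; bin2[15, 16] <- TRUE
  bin2[16, 15] <- TRUE; bin2[16, 16] <- TRUE
  expect_equal(count_cells(bin2, 10, 500)$count, 2)
  expect_equal(count_cells(bin2, 1, 500)$count, 3)
  # diagonal adjacency joins a component (8-connectivity)
  diag_bin <- matrix(FALSE, 8, 8)
  diag_bin[cbind(1:4, 1:4)] <- TRUE
  expect_equal(count_cells(diag_bin, 1, 99)$count, 1)
})

test_that("raising min_area never increases the count", {
  set.seed(5)
  bin <- matrix(runif(64 * 64) < 0.2, 64)
  counts <- vapply(c(1, 2, 4, 8, 16), function(a) count_cells(bin, a, 1e4)$count,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("counting is translation-invariant", {
  img <- spot_frame(96, list(c(40, 40), c(52, 44)))
  pre1 <- preprocess_channel(img, droplet_at(45, 42), tophat_radius = 3.75)
  cc1 <- count_cells(pre1$binary, 5, 79)
  # same scene shifted by (+13, +9)
  img2 <- spot_frame(96, list(c(53, 49), c(65, 53)))
  pre2 <- preprocess_channel(img2, droplet_at(58, 51), tophat_radius = 3.75)
  cc2 <- count_cells(pre2$binary, 5, 79)
  expect_equal(cc1$count, cc2$count)
  expect_equal(cc1$objects$area, cc2$objects$area)
})

test_that("dead cells are attributed to the nearest tracker object within reach", {
  via <- tibble::tibble(x = c(10, 50), y = c(10, 50),
                        area = 20, mean_intensity = 0.5)
  eff <- tibble::tibble(x = 40, y = 10)
  tgt <- tibble::tibble(x = 11, y = 10)
  out <- attribute_dead_cells(via, eff, tgt, max_dist = 5)
  expect_equal(out$attributed, c("target", "unknown"))
  # no tracker objects at all -> unknown
  none <- attribute_dead_cells(via, eff[0, ], tgt[0, ], max_dist = 5)
  expect_true(all(none$attributed == "unknown"))
})

test_that("occupancy is frozen at the first timepoint and strata are flagged", {
  census <- tidyr::expand_grid(track_id = 1:4, timepoint = 0:2) |>
    dplyr::mutate(
      n_effector = c(1, 1, 1,  0, 0, 0,  2, 2, 2,  1, 2, 2),
      n_target   = c(1, 1, 1,  2, 2, 2,  0, 0, 0,  2, 2, 2))
  out <- census_droplet(census)
  t0 <- out[out$timepoint == 0, ]
  expect_equal(t0$pair_1_1, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(t0$target_only, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(t0$effector_only, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(t0$multi, c(FALSE, FALSE, FALSE, TRUE))
  # occupancy fixed per track even when later counts drift
  expect_true(all(out$k_effector[out$track_id == 4] == 1))
  expect_equal(unique(out$occupancy[out$track_id == 4]), "E:T 1:2")
})

test_that("per-droplet counts match ground truth on clean images", {
  exp <- small_experiment()
  pl <- small_pipeline()
  # map tracks to truth droplets via t = 0 proximity
  tr <- pl$tracks
  complete <- tr$tracks[tr$tracks$status == "complete", ]
  pos0 <- tr$positions[tr$positions$timepoint == 0 &
                       tr$positions$track_id %in% complete$track_id, ]
  pos0 <- dplyr::left_join(pos0, complete[, c("track_id", "tile_id")],
                           by = "track_id")
  truth0 <- exp$droplets[exp$droplets$timepoint == 0, ]
  truth_k <- exp$cells[exp$cells$timepoint == 0, ] |>
    dplyr::count(droplet_id, cell_type) |>
    tidyr::pivot_wider(names_from = cell_type, values_from = n, values_fill = 0L)
  mism <- 0; total <- 0
  for (i in seq_len(nrow(pos0))) {
    cand <- truth0[truth0$tile_id == pos0$tile_id[i], ]
    j <- which.min((cand$x - pos0$x[i])^2 + (cand$y - pos0$y[i])^2)
    kt <- truth_k[truth_k$droplet_id == cand$droplet_id[j], ]
    k_eff <- if (nrow(kt) && "effector" %in% names(kt)) kt$effector else 0L
    k_tgt <- if (nrow(kt) && "target" %in% names(kt)) kt$target else 0L
    cen <- pl$census[pl$census$track_id == pos0$track_id[i], ]
    total <- total + nrow(cen)
    mism <- mism + sum(cen$n_effector != k_eff | cen$n_target != k_tgt)
  }
  expect_lte(mism / total, 0.02)
})
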
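test_that("generation is bit-identical under a fixed seed", {
  cfg <- generator_config(tile_px = 128, n_tiles = 1, n_timepoints = 3, seed = 11)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$droplets, b$droplets)
  expect_identical(a$cells, b$cells)
  expect_identical(a$images, b$images)
})

test_that("zero loading yields droplets but no cells", {
  cfg <- generator_config(tile_px = 128, n_tiles = 1, n_timepoints = 2,
                          encapsulation = encapsulation_params(1e-3, 1e-3),
                          seed = 2)
  exp <- generate_experiment(cfg)
  expect_gt(nrow(exp$droplets), 0)
  expect_equal(nrow(exp$cells), 0)
  # fluorescence channels are pure background
  expect_lt(max(exp$images[[1]][[1]]$target_tracker),
            cfg$fluor_background + 6 * cfg$noise_sd)
})

test_that("droplet interiors never overlap and cells stay inside their droplet", {
  exp <- small_experiment()
  for (t in unique(exp$droplets$timepoint)) {
    for (tile in unique(exp$droplets$tile_id)) {
      d <- exp$droplets[exp$droplets$timepoint == t & exp$droplets$tile_id == tile, ]
      if (nrow(d) < 2) next
      dm <- as.matrix(dist(cbind(d$x, d$y)))
      diag(dm) <- Inf
      rsum <- outer(d$radius_px, d$radius_px, "+")
      expect_true(all(dm > rsum - 1e-9))
    }
  }
  joined <- dplyr::inner_join(
    exp$cells, exp$droplets,
    by = c("droplet_id", "tile_id", "timepoint"), suffix = c("_c", "_d"))
  inside <- sqrt((joined$x_c - joined$x_d)^2 + (joined$y_c - joined$y_d)^2) <=
    joined$radius_px
  expect_true(all(inside))
})

test_that("radius is constant over time and non-movers move less than movers", {
  exp <- small_experiment()
  by_drop <- exp$droplets |>
    dplyr::group_by(droplet_id, is_mover) |>
    dplyr::summarise(
      r_sd = sd(radius_px),
      max_step = max(sqrt(diff(x)^2 + diff(y)^2)),
      .groups = "drop")
  expect_true(all(by_drop$r_sd == 0))
  cfg <- exp$config
  m <- 0.5 * cfg$droplet_radius_px  # default allowed movement downstream
  expect_true(all(by_drop$max_step[!by_drop$is_mover] < m))
  if (any(by_drop$is_mover)) {
    expect_true(all(by_drop$max_step[by_drop$is_mover] > m))
  }
})

test_that("viability switches from background to bright at the death hour and stays on", {
  cfg <- generator_config(tile_px = 192, n_tiles = 1, n_timepoints = 4,
                          encapsulation = encapsulation_params(4e7, 4e7),
                          killer_prob = 1, death_rate_per_h = 100,  # all deaths at hour 1
                          spontaneous_death_prob = 0,
                          mover_fraction = 0, noise_sd = 0.002, seed = 13)
  exp <- generate_experiment(cfg)
  dead <- exp$cells[!is.na(exp$cells$death_time), ]
  expect_gt(nrow(dead), 0)
  expect_true(all(dead$death_time == 1))
  probe <- function(cell_row) {
    img <- exp$images[[1]][[cell_row$timepoint + 1]]$viability
    img[round(cell_row$y) + 1, round(cell_row$x) + 1]
  }
  for (cid in unique(dead$cell_id)) {
    tr <- dead[dead$cell_id == cid, ]
    v0 <- probe(tr[tr$timepoint == 0, ])
    v_after <- vapply(1:3, function(t) probe(tr[tr$timepoint == t, ]), numeric(1))
    expect_lt(v0, 0.1)              # background before death
    expect_true(all(v_after > 0.4)) # bright from death onward, stable
  }
})

test_that("a cell appears in exactly one tracker channel, by type", {
  exp <- small_experiment()
  img_e <- exp$images[[1]][[1]]$effector_tracker
  img_t <- exp$images[[1]][[1]]$target_tracker
  c0 <- exp$cells[exp$cells$timepoint == 0 & exp$cells$tile_id == 1, ]
  for (i in seq_len(nrow(c0))) {
    own <- if (c0$cell_type[i] == "effector") img_e else img_t
    other <- if (c0$cell_type[i] == "effector") img_t else img_e
    expect_gt(own[round(c0$y[i]) + 1, round(c0$x[i]) + 1], 0.3)
    expect_lt(other[round(c0$y[i]) + 1, round(c0$x[i]) + 1], 0.25)
  }
})

test_that("fate sampling follows the kill probability and death-time model", {
  pairs <- tibble::tibble(
    cell_id = 1:4000,
    droplet_id = rep(1:2000, each = 2),
    cell_type = rep(c("effector", "target"), 2000)
  )
  probs <- dropcyto:::death_time_probs(11, 0.5)
  # killer_prob = 0 -> no events
  f0 <- sample_fates(pairs, 0, probs, 11)
  expect_true(all(is.na(f0$death_time)))
  # killer_prob = 1, point mass at hour 2 -> every target dies at hour 2
  point <- c(0, 1, rep(0, 8))
  set.seed(1)
  f1 <- sample_fates(pairs, 1, point, 11)
  expect_true(all(f1$death_time[f1$cell_type == "target"] == 2))
  expect_true(all(is.na(f1$death_time[f1$cell_type == "effector"])))
  # killer_prob = 0.2 -> binomial count within 3 SE of 400
  set.seed(2)
  f2 <- sample_fates(pairs, 0.2, probs, 11)
  n_events <- sum(!is.na(f2$death_time))
  expect_lt(abs(n_events - 400), 3 * sqrt(2000 * 0.2 * 0.8))
})

test_that("targets without effectors only die spontaneously, late", {
  solo <- tibble::tibble(cell_id = 1:1000, droplet_id = 1:1000,
                         cell_type = "target")
  set.seed(3)
  f <- sample_fates(solo, killer_prob = 1,
                    dropcyto:::death_time_probs(11, 0.5), 11,
                    spontaneous_death_prob = 0.1)
  n_dead <- sum(!is.na(f$death_time))
  expect_lt(abs(n_dead - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  expect_true(all(f$death_time[!is.na(f$death_time)] > 5))
})

test_that("ground-truth occupancy matches the Poisson model", {
  exp <- validation_experiment()
  k <- exp$cells[exp$cells$timepoint == 0, ] |>
    dplyr::count(droplet_id, cell_type) |>
    tidyr::pivot_wider(names_from = cell_type, values_from = n, values_fill = 0L)
  n_droplets <- dplyr::n_distinct(exp$droplets$droplet_id)
  n11 <- sum(k$effector == 1 & k$target == 1)
  p11 <- occupancy_pmf(exp$config$encapsulation, 1, 1)
  se <- sqrt(p11 * (1 - p11) * n_droplets)
  expect_lt(abs(n11 - n_droplets * p11), 3 * se)
})
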
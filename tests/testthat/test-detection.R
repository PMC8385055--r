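test_that("contrast stretching maps the percentile window to full range", {
  # image already spanning [0, 1]: identity at (0, 100)
  img <- matrix(seq(0, 1, length.out = 100), 10)
  expect_equal(stretch_contrast(img, 0, 100), img)
  # two-valued image maps to {0, 1}
  two <- matrix(c(10, 20), 4, 4)
  out <- stretch_contrast(two, 0, 100)
  expect_equal(sort(unique(as.numeric(out))), c(0, 1))
  # ramp: everything below the low percentile clips to 0 (oracle: quantile)
  ramp <- matrix(1:1000, 20)
  qs <- quantile(ramp, c(0.01, 0.99), names = FALSE)
  st <- stretch_contrast(ramp, 1, 99)
  expect_true(all(st[ramp <= qs[1]] == 0))
  expect_true(all(st[ramp >= qs[2]] == 1))
  mid <- ramp > qs[1] & ramp < qs[2]
  expect_equal(st[mid], (ramp[mid] - qs[1]) / (qs[2] - qs[1]))
  # constant image: unchanged, flagged
  flat <- matrix(5, 8, 8)
  out <- stretch_contrast(flat)
  expect_true(attr(out, "constant"))
  expect_equal(as.numeric(out), rep(5, 64))
})

test_that("droplets in a noise-free render are found with sub-pixel accuracy", {
  exp <- clean_tile_experiment()
  ana <- analysis_config()
  det <- find_droplets(exp$images[[1]][[1]]$brightfield, ana$radius_range,
                       ana$sensitivity)
  tru <- exp$droplets[exp$droplets$timepoint == 0, ]
  expect_equal(nrow(det), nrow(tru))
  d <- sqrt(outer(det$x, tru$x, "-")^2 + outer(det$y, tru$y, "-")^2)
  nearest <- apply(d, 2, min)
  expect_true(all(nearest <= 1))                       # centres within 1 px
  hit <- apply(d, 2, which.min)
  rel_err <- abs(det$radius[hit] - tru$radius_px) / tru$radius_px
  expect_true(all(rel_err <= 0.05))                    # radii within 5%
  # determinism: no randomised accumulator
  expect_identical(det, find_droplets(exp$images[[1]][[1]]$brightfield,
                                      ana$radius_range, ana$sensitivity))
})

test_that("a blank tile yields no detections", {
  set.seed(4)
  blank <- matrix(0.85 + rnorm(256^2, 0, 0.01), 256)
  det <- find_droplets(blank, c(10, 15))
  expect_equal(nrow(det), 0)
})

test_that("droplets touching the tile border are excluded", {
  img <- matrix(0.85, 256, 256)
  ring <- function(img, x, y, r) {
    d <- sqrt(outer((0:255 - y)^2, (0:255 - x)^2, "+"))
    img - 0.7 * exp(-((d - r) / 1)^2)
  }
  img <- ring(img, 128, 128, 12.5)  # interior
  img <- ring(img, 250, 128, 12.5)  # half outside the right edge
  det <- find_droplets(img, c(10, 15))
  expect_equal(nrow(det), 1)
  expect_equal(det$x, 128, tolerance = 1)
  expect_equal(det$y, 128, tolerance = 1)
})

test_that("recall degrades gracefully as noise increases", {
  cfg0 <- generator_config(tile_px = 256, n_tiles = 1, n_timepoints = 2,
                           mover_fraction = 0, seed = 21)
  ana <- analysis_config()
  recall <- vapply(c(0, 0.05, 0.25), function(ns) {
    cfg <- generator_config(tile_px = 256, n_tiles = 1, n_timepoints = 2,
                            mover_fraction = 0, noise_sd = ns, seed = 21)
    exp <- generate_experiment(cfg)
    det <- find_droplets(exp$images[[1]][[1]]$brightfield, ana$radius_range,
                         ana$sensitivity)
    tru <- exp$droplets[exp$droplets$timepoint == 0, ]
    if (nrow(det) == 0) return(0)
    d <- sqrt(outer(det$x, tru$x, "-")^2 + outer(det$y, tru$y, "-")^2)
    mean(apply(d, 2, min) <= 2)
  }, numeric(1))
  expect_true(all(diff(recall) <= 0))
  expect_equal(recall[1], 1)
})

test_that("droplet masks follow the discrete-disk containment rule", {
  # r = 10 disk at the centre of a 64x64 tile: 317 lattice points satisfy
  # dx^2 + dy^2 <= r^2 (brute-force count)
  brute <- sum(outer((-32:31)^2, (-32:31)^2, "+") <= 100)
  expect_equal(brute, 317)
  det <- tibble::tibble(droplet_index = 1L, x = 32, y = 32, radius = 10, score = 1)
  mask <- make_droplet_mask(det, c(64, 64))
  expect_equal(sum(mask == 1L), 317)
  # zero detections -> all-zero mask
  none <- make_droplet_mask(det[0, ], c(32, 32))
  expect_true(all(none == 0L))
  # two disjoint disks: areas add up
  det2 <- tibble::tibble(droplet_index = 1:2, x = c(20, 44), y = c(20, 44),
                         radius = 8, score = c(2, 1))
  m2 <- make_droplet_mask(det2, c(64, 64))
  one <- make_droplet_mask(det2[1, ], c(64, 64))
  expect_equal(sum(m2 == 1L), sum(one == 1L))
  expect_equal(sum(m2 == 2L), sum(one == 1L))
  # mask area within 5% of pi r^2
  expect_lt(abs(sum(m2 > 0) - 2 * pi * 64) / (2 * pi * 64), 0.05)
})

test_that("overlapping disks are resolved in favour of the higher score", {
  det <- tibble::tibble(droplet_index = 1:2, x = c(30, 40), y = c(32, 32),
                        radius = 8, score = c(1, 5))
  mask <- make_droplet_mask(det, c(64, 64))
  # the overlap column x = 35 belongs to droplet 2 (higher score)
  expect_equal(mask[33, 36], 2L)
  expect_gt(attr(mask, "n_overlap_px"), 0)
})
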
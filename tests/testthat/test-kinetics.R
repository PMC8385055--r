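test_that("death time is the first persistent threshold crossing", {
  expect_equal(call_death_time(c(0, 0, 0, 8, 9, 9), theta = 1), 3L)
  expect_true(is.na(call_death_time(rep(0, 6), theta = 1)))
  # persistence: a one-frame blip is not a death
  expect_true(is.na(call_death_time(c(0, 5, 0, 0, 0), theta = 1, persistence = 2)))
  expect_equal(call_death_time(c(0, 5, 6, 0, 0), theta = 1, persistence = 2), 1L)
  # the persistence run may be truncated by the end of the series
  expect_equal(call_death_time(c(0, 0, 0, 0, 5), theta = 1, persistence = 3), 4L)
  # death at t = 0 is callable
  expect_equal(call_death_time(c(7, 7, 7), theta = 1), 0L)
})

test_that("eligibility keeps 1:1 droplets alive at t = 0 and logs exclusions", {
  census <- tidyr::expand_grid(track_id = 1:4, timepoint = 0:2) |>
    dplyr::mutate(
      n_effector = rep(c(1, 1, 2, 0), each = 3),
      n_target = rep(c(1, 1, 1, 2), each = 3),
      dead_effector = 0L,
      dead_target = c(0, 0, 0, 1, 1, 1, 0, 0, 0, 0, 0, 0),
      dead_unknown = 0L) |>
    census_droplet()
  sel <- select_eligible(census)
  expect_equal(sel$eligible$track_id, 1)
  expect_equal(sel$excluded$track_id, 2)
  expect_equal(sel$excluded$reason, "dead_at_t0")
  # bookkeeping: eligible + excluded = complete 1:1 tracks, exactly
  n11 <- sum(census$pair_1_1[census$timepoint == 0])
  expect_identical(nrow(sel$eligible) + nrow(sel$excluded), n11)
})

test_that("killer fraction counts target deaths among eligible pairs", {
  eligible <- tibble::tibble(track_id = 1:10)
  events <- tibble::tibble(track_id = c(1, 2, 11),
                           cell_type = c("target", "target", "target"),
                           death_time = c(2L, 3L, 1L))
  kf <- killer_fraction(eligible, events)
  expect_equal(kf$fraction, 0.2)
  expect_equal(kf$n_killers, 2)
  # effector deaths are not killer events
  ev2 <- tibble::tibble(track_id = 3, cell_type = "effector", death_time = 1L)
  expect_equal(killer_fraction(eligible, ev2)$fraction, 0)
  expect_error(killer_fraction(eligible[0, ], events), "eligible")
})

test_that("kinetics histogram splits fast and slow killers at t_fast", {
  ev <- tibble::tibble(track_id = 1:4, cell_type = "target",
                       death_time = c(1L, 1L, 2L, 5L))
  ks <- kinetics_histogram(ev, n_timepoints = 11, t_fast = 4)
  expect_equal(ks$fast_killer_fraction, 0.75)
  expect_equal(ks$slow_killer_fraction, 0.25)
  expect_equal(ks$histogram$n[ks$histogram$hour == 1], 2)
  expect_equal(sum(ks$histogram$n), ks$n_events)
  # all events within t_fast
  ev2 <- dplyr::mutate(ev, death_time = c(1L, 2L, 3L, 4L))
  expect_equal(kinetics_histogram(ev2, 11, 4)$fast_killer_fraction, 1)
  # zero events: histogram of zeros, fractions reported missing
  ks0 <- kinetics_histogram(ev[0, ], 11, 4)
  expect_true(all(ks0$histogram$n == 0))
  expect_true(is.na(ks0$fast_killer_fraction))
  expect_true(is.na(ks0$slow_killer_fraction))
})

test_that("the fast-killer fraction is monotone in t_fast", {
  set.seed(8)
  ev <- tibble::tibble(track_id = 1:50, cell_type = "target",
                       death_time = sample(1:10, 50, replace = TRUE))
  fracs <- vapply(1:10, function(tf)
    kinetics_histogram(ev, 11, tf)$fast_killer_fraction, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("serial killers need one effector, two targets and two kills", {
  base <- tidyr::expand_grid(track_id = 1:3, timepoint = 0:3)
  census <- base |>
    dplyr::mutate(
      n_effector = rep(c(1, 1, 1), each = 4),
      n_target = rep(c(2, 2, 1), each = 4),
      dead_effector = 0L,
      dead_target = c(0, 1, 1, 2,   0, 0, 1, 1,   0, 1, 1, 1),
      dead_unknown = 0L) |>
    census_droplet()
  sk <- detect_serial_killers(census, events = NULL)
  expect_equal(sk$track_id, 1)
  expect_equal(sk$n_kills, 2)
  expect_equal(sk$kill_times[[1]], c(1, 3))
})

test_that("control viability accumulates spontaneous target deaths", {
  census <- tidyr::expand_grid(track_id = 1:2, timepoint = 0:9) |>
    dplyr::mutate(n_effector = 0L, n_target = 1L,
                  dead_effector = 0L, dead_target = 0L, dead_unknown = 0L) |>
    census_droplet()
  # no deaths -> flat zero
  cv <- control_viability(census, tibble::tibble(track_id = integer(),
                                                 cell_type = character(),
                                                 death_time = integer()), 10)
  expect_true(all(cv$cum_dead_fraction == 0))
  # a single droplet dying at hour 9 steps from 0 to 1/2 at hour 9
  ev <- tibble::tibble(track_id = 1, cell_type = "target", death_time = 9L)
  cv2 <- control_viability(census, ev, 10)
  expect_equal(cv2$cum_dead_fraction, c(rep(0, 9), 0.5))
  # empty stratum -> missing
  census_pairs <- dplyr::mutate(census, n_effector = 1L) |> census_droplet()
  expect_null(control_viability(census_pairs, ev, 10))
})

test_that("death calling on cohort traces recovers the generator's fates", {
  co <- simulate_cohort(4000, killer_prob = 0.3, seed = 17)
  events <- call_deaths(co$traces, theta = 0.1)
  truth <- co$cells |>
    dplyr::filter(!is.na(death_time)) |>
    dplyr::group_by(droplet_id, cell_type) |>
    dplyr::summarise(death_time = min(death_time), .groups = "drop")
  joined <- dplyr::inner_join(events, truth,
                              by = c(track_id = "droplet_id", "cell_type"),
                              suffix = c("_called", "_true"))
  expect_equal(nrow(joined), nrow(truth))
  expect_true(all(joined$death_time_called == joined$death_time_true))
})

test_that("killer fraction estimates are unbiased across seeds", {
  ests <- vapply(1:4, function(s) {
    co <- simulate_cohort(8000, killer_prob = 0.2, seed = 100 + s)
    events <- call_deaths(co$traces, theta = 0.1)
    sel <- select_eligible(co$census)
    killer_fraction(sel$eligible,
                    events[events$track_id %in% sel$eligible$track_id, ])$fraction
  }, numeric(1))
  n_pairs <- 8000 * occupancy_pmf(encapsulation_params(), 1, 1)
  se <- sqrt(0.2 * 0.8 / n_pairs)
  expect_lt(abs(mean(ests) - 0.2), se)
})

test_that("full kinetics summary reconciles its own bookkeeping", {
  co <- simulate_cohort(3000, killer_prob = 0.25, seed = 23)
  kin <- summarise_kinetics(co$census, co$traces, analysis_config(), 11)
  expect_identical(nrow(kin$eligible) + nrow(kin$excluded), kin$n_pairs_1_1)
  expect_equal(sum(kin$kinetics$histogram$n), kin$kinetics$n_events)
  g <- glance(kin)
  expect_equal(g$killer_fraction, kin$killer$fraction)
  td <- tidy(kin)
  expect_equal(sum(td$n_events), kin$kinetics$n_events)
})
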
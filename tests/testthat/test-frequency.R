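test_that("frequency maps count cloudy fractions of valid slots", {
  time <- jja_times(2006, cadence = 15)[1:48]   # one day, 48 slots
  flags <- array(0L, c(3, 3, 48))
  flags[1, 1, ] <- 1L                    # always cloudy
  flags[2, 2, 1:24] <- 1L                # half cloudy
  flags[3, 3, ] <- NA_integer_           # never observed
  flags[1, 2, 1:24] <- NA_integer_       # half missing, rest cloudy
  flags[1, 2, 25:48] <- 1L
  fm <- frequency_map(make_mask(flags, time))
  expect_identical(fm$values[1, 1], 1)
  expect_identical(fm$values[2, 2], 0.5)
  expect_true(is.na(fm$values[3, 3]))
  expect_identical(fm$values[1, 2], 1)   # missing excluded from denominator
  expect_identical(fm$n_slots[1, 2], 24L)
  expect_error(frequency_map(make_mask(flags, time), months = 1), "empty window")
})

test_that("outputs are invariant to timestamp reordering", {
  set.seed(51)
  time <- jja_times(2006, cadence = 60)
  flags <- array(rbinom(4 * 4 * length(time), 1, 0.3), c(4, 4, length(time)))
  perm <- sample(seq_along(time))
  m1 <- make_mask(flags, time)
  m2 <- make_mask(flags[, , perm], time[perm])
  expect_identical(frequency_map(m1)$values, frequency_map(m2)$values)
  b <- rect(0, 2, 0, 2)
  expect_identical(box_daily_series(m1, b), box_daily_series(m2, b))
  expect_identical(diurnal_cycle(m1, b), diurnal_cycle(m2, b))
})

test_that("window frequency equals the slot-weighted mean of daily maps", {
  set.seed(52)
  time <- jja_times(2006, cadence = 60)
  flags <- array(rbinom(2 * 2 * length(time), 1, 0.4), c(2, 2, length(time)))
  flags[sample(length(flags), 200)] <- NA_integer_
  mk <- make_mask(flags, time)
  fm <- frequency_map(mk)
  meta <- forestcloud:::slot_meta(mk$time)
  num <- den <- matrix(0, 2, 2)
  for (d in unique(meta$date)) {
    sel <- which(meta$date == d)
    day <- forestcloud:::freq_from_slots(flags, sel)
    ok <- day$n_slots > 0
    num[ok] <- num[ok] + day$values[ok] * day$n_slots[ok]
    den <- den + day$n_slots
  }
  expect_equal(fm$values, num / den, tolerance = 1e-12)
})

test_that("daily box series reduce correctly in degenerate cases", {
  time <- jja_times(2006, cadence = 60)
  nt <- length(time)
  flags <- array(1L, c(4, 4, nt))
  mk <- make_mask(flags, time)
  d <- box_daily_series(mk, rect(0, 4, 0, 4))
  expect_identical(nrow(d), 92L)
  expect_true(all(d$value == 1))
  # a one-pixel box reproduces that pixel's own daily frequency
  set.seed(53)
  flags2 <- array(rbinom(4 * 4 * nt, 1, 0.5), c(4, 4, nt))
  mk2 <- make_mask(flags2, time)
  d1 <- box_daily_series(mk2, rect(2, 3, 2, 3))
  meta <- forestcloud:::slot_meta(time)
  manual <- vapply(split(seq_len(nt), meta$date),
                   function(s) mean(flags2[3, 3, s]), numeric(1))
  expect_equal(d1$value, unname(manual), tolerance = 1e-12)
})

test_that("dekadal differences recover the seasonal enhancement pattern", {
  lc <- small_landcover(30, c(6, 24, 6, 24))
  cfg <- sim_config("2006-01-01", "2006-12-31", cadence_minutes = 60,
                    p_cloud_base = 0.3, delta_forest_jja = 0.15,
                    wind_displacement_km_per_ms = 0, seed = 54)
  mk <- truth_mask_stack(simulate_truth(lc, cfg))
  dd <- dekadal_difference_series(mk, get_box(lc, "forest"),
                                  list(get_box(lc, "nonforest_1"),
                                       get_box(lc, "nonforest_2")))
  expect_identical(nrow(dd), 36L)
  jja <- dd$dekad >= 16 & dd$dekad <= 24   # fully inside Jun-Aug
  winter <- dd$dekad <= 12 | dd$dekad >= 28
  expect_gt(mean(dd$value[jja]), 0.10)
  expect_lt(abs(mean(dd$value[winter])), 0.02)
})

test_that("a null landscape's dekadal differences are centred on zero", {
  lc <- small_landcover(30, c(6, 24, 6, 24))
  cfg <- sim_config("2005-01-01", "2005-12-31", cadence_minutes = 60,
                    delta_forest_jja = 0, wind_displacement_km_per_ms = 0,
                    seed = 55)
  mk <- truth_mask_stack(simulate_truth(lc, cfg))
  dd <- dekadal_difference_series(mk, get_box(lc, "forest"),
                                  list(get_box(lc, "nonforest_1"),
                                       get_box(lc, "nonforest_2")))
  expect_gte(nrow(dd), 30L)
  se <- stats::sd(dd$value) / sqrt(nrow(dd))
  expect_lt(abs(mean(dd$value)), 3 * se)
})

test_that("a single dekad of input yields a length-1 difference series", {
  time <- jja_times(2006, cadence = 60)[1:(9 * 12)]  # Jun 1-9, all dekad 16
  flags <- array(1L, c(6, 6, length(time)))
  mk <- make_mask(flags, time)
  dd <- dekadal_difference_series(mk, rect(0, 3, 0, 3), list(rect(3, 6, 3, 6)))
  expect_identical(nrow(dd), 1L)
  expect_identical(dd$value, 0)
})

test_that("diurnal cycles are flat for a time-homogeneous process and led
          by forest when the onset lead is on", {
  set.seed(56)
  time <- jja_times(2006, cadence = 60)
  flags <- array(rbinom(4 * 4 * length(time), 1, 0.3), c(4, 4, length(time)))
  dc <- diurnal_cycle(make_mask(flags, time), rect(0, 4, 0, 4))
  expect_identical(dc$hour, 6:17)
  expect_lt(diff(range(dc$value)), 0.1)   # sampling noise only

  lc <- small_landcover(24, c(4, 20, 4, 20))
  cfg <- sim_config("2006-06-01", "2006-08-31", cadence_minutes = 60,
                    diurnal_lead_hours = 2, delta_forest_jja = 0.05,
                    wind_displacement_km_per_ms = 0, seed = 56)
  mk <- truth_mask_stack(simulate_truth(lc, cfg))
  f <- diurnal_cycle(mk, get_box(lc, "forest"))
  nf <- diurnal_cycle(mk, get_box(lc, "nonforest_1"))
  early <- f$hour <= 9
  expect_true(all((f$value - nf$value)[early] > 0))
  # the lead shrinks once both onsets saturate
  expect_gt(mean((f$value - nf$value)[early]),
            mean((f$value - nf$value)[f$hour >= 14]))
})
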
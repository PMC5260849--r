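test_that("ecdf_steepest picks the densest dark mode", {
  expect_identical(ecdf_steepest(c(7L, 7L, 7L), window_w = 1), 7L)
  # brute-force value: counts at 5 (x2) beat 6 and 9 (x1 each)
  expect_identical(ecdf_steepest(c(5L, 5L, 6L, 9L), window_w = 1), 5L)
  # tie between two equally dense values goes to the smaller (darker)
  expect_identical(ecdf_steepest(c(10L, 10L, 40L, 40L), window_w = 1), 10L)
  expect_error(ecdf_steepest(integer(0)), "insufficient")
  expect_error(ecdf_steepest(c(1.5, 2.5)), "integer")
  expect_error(ecdf_steepest(c(5L, 2000L)), "10-bit")
})

test_that("ecdf_steepest matches the exhaustive slope search", {
  set.seed(401)
  for (i in 1:60) {
    n <- sample(c(5, 50, 500, 5000), 1)
    base <- sample(0:900, 1)
    spread <- sample(c(1, 3, 10, 40), 1)
    x <- pmin(pmax(round(stats::rnorm(n, base, spread)), 0L), 1023L)
    if (runif(1) < 0.5)  # add a bright contaminating mode
      x <- c(x, pmin(round(stats::rnorm(n %/% 3, base + 50, 2)), 1023L))
    x <- as.integer(x)
    w <- sample(1:5, 1)
    expect_identical(ecdf_steepest(x, w), oracle_steepest(x, w),
                     info = sprintf("case %d (n=%d, w=%d)", i, length(x), w))
  }
})

test_that("a clear+cloud count mixture yields the clear level", {
  set.seed(402)
  x <- as.integer(c(round(rnorm(100, 80, 1.5)), round(rnorm(30, 200, 3))))
  v <- ecdf_steepest(x, window_w = 3)
  expect_lte(abs(v - 80L), 3L)
})

test_that("climatology equals truth exactly on a noiseless cloud-free stack", {
  lc <- small_landcover(20, c(4, 16, 4, 16))
  cfg <- sim_config("2005-06-01", "2005-08-31", cadence_minutes = 60,
                    p_cloud_base = 0, delta_forest_jja = 0, noise_sd = 0,
                    seed = 21)
  tr <- simulate_truth(lc, cfg)
  cs <- render_counts(tr)
  clim <- build_clearsky_climatology(cs, min_samples = 1)
  populated <- clim$n > 0
  expect_identical(clim$values[populated], tr$clearsky[populated])
})

test_that("climatology matches the scalar estimator pixel by pixel", {
  lc <- small_landcover(8, c(2, 6, 2, 6))
  cfg <- sim_config("2005-06-01", "2005-06-30", cadence_minutes = 30,
                    p_cloud_base = 0.4, delta_forest_jja = 0, noise_sd = 3,
                    seed = 22)
  cs <- render_counts(simulate_truth(lc, cfg))
  clim <- build_clearsky_climatology(cs, window_w = 3, min_samples = 1)
  bins <- time_bin(cs$time, cs$scheme)$bin
  for (b in unique(bins)) {
    slots <- which(bins == b)
    for (p in seq_len(8 * 4)) {   # a subsample of pixels
      i <- ((p - 1) %% 8) + 1; j <- ((p - 1) %/% 8) * 2 + 1
      samples <- cs$counts[i, j, slots]
      expect_identical(clim$values[i, j, b],
                       ecdf_steepest(samples, window_w = 3))
    }
  }
})

test_that("undersampled bins are invalid, not extrapolated", {
  lc <- build_landcover(6, 6, rect(1, 5, 1, 5),
                        boxes = list(forest = rect(2, 4, 2, 4)))
  cfg <- sim_config("2005-07-01", "2005-07-02", cadence_minutes = 60,
                    noise_sd = 0, seed = 23)
  cs <- render_counts(simulate_truth(lc, cfg))
  clim <- build_clearsky_climatology(cs, min_samples = 20)  # only 2 samples/bin
  expect_true(all(is.na(clim$values)))
  expect_true(all(clim$n %in% c(0L, 2L)))
  # all-missing bins stay invalid even with min_samples = 1
  cs$counts[] <- NA_integer_
  clim2 <- build_clearsky_climatology(cs, min_samples = 1)
  expect_true(all(is.na(clim2$values)))
})

test_that("detection uses strict exceedance of climatology + threshold", {
  time <- as.POSIXct("2006-07-05 12:00:00", tz = "UTC")
  sc <- bin_scheme()
  b <- time_bin(time, sc)$bin
  clim_vals <- array(NA_integer_, c(1, 1, sc$n_bins))
  clim_vals[1, 1, b] <- 80L
  clim <- structure(list(values = clim_vals,
                         n = array(100L, c(1, 1, sc$n_bins)), scheme = sc,
                         window_w = 3L, min_samples = 20L),
                    class = "clearsky_clim")
  mk_counts <- function(v) structure(list(
    counts = array(v, c(1, 1, 1)), time = time, scheme = sc),
    class = "count_stack")
  expect_identical(detect_clouds(mk_counts(91L), clim)$flags[1, 1, 1], 1L)
  expect_identical(detect_clouds(mk_counts(90L), clim)$flags[1, 1, 1], 0L)
  expect_identical(detect_clouds(mk_counts(NA_integer_), clim)$flags[1, 1, 1],
                   NA_integer_)
  # invalid climatology bin propagates to a missing flag
  time2 <- as.POSIXct("2006-07-05 13:00:00", tz = "UTC")
  cs2 <- structure(list(counts = array(500L, c(1, 1, 1)), time = time2,
                        scheme = sc), class = "count_stack")
  expect_identical(detect_clouds(cs2, clim)$flags[1, 1, 1], NA_integer_)
})

test_that("cloud frequency is non-increasing in the detection threshold", {
  lc <- small_landcover(16, c(3, 13, 3, 13))
  cfg <- sim_config("2005-06-01", "2005-08-31", cadence_minutes = 60,
                    p_cloud_base = 0.35, noise_sd = 2, seed = 24)
  cs <- render_counts(simulate_truth(lc, cfg))
  clim <- build_clearsky_climatology(cs, min_samples = 5)
  prev <- NULL
  for (tau in c(5, 10, 20, 45, 60)) {
    f <- frequency_map(detect_clouds(cs, clim, threshold = tau))$values
    if (!is.null(prev)) expect_true(all(f <= prev + 1e-12, na.rm = TRUE))
    prev <- f
  }
})

test_that("detection separates clouds cleanly when boost >> threshold + noise", {
  lc <- small_landcover(16, c(3, 13, 3, 13))
  cfg <- sim_config("2004-06-01", "2005-08-31", months = 6:8,
                    cadence_minutes = 15, p_cloud_base = 0.3,
                    delta_forest_jja = 0, cloud_boost_counts = 50,
                    noise_sd = 2, seed = 25)
  tr <- simulate_truth(lc, cfg)
  cs <- render_counts(tr)
  clim <- build_clearsky_climatology(cs)
  conf <- mask_confusion(detect_clouds(cs, clim), tr)
  expect_gt(conf$hit_rate, 0.99)
  expect_lt(conf$false_alarm_rate, 0.01)
})
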
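test_that("the generator is bit-reproducible under a fixed seed", {
  lc <- small_landcover(12, c(2, 10, 2, 10))
  cfg <- sim_config("2006-06-01", "2006-06-20", cadence_minutes = 60,
                    seed = 99)
  t1 <- simulate_truth(lc, cfg)
  t2 <- simulate_truth(lc, cfg)
  expect_identical(t1$true_cloud, t2$true_cloud)
  expect_identical(t1$clearsky, t2$clearsky)
  expect_identical(t1$wind, t2$wind)
  expect_identical(render_counts(t1)$counts, render_counts(t2)$counts)
  # a different seed changes the draw
  t3 <- simulate_truth(lc, sim_config("2006-06-01", "2006-06-20",
                                      cadence_minutes = 60, seed = 100))
  expect_false(identical(t1$true_cloud, t3$true_cloud))
})

test_that("a null landscape is exchangeable between forest and non-forest", {
  lc <- small_landcover()
  cfg <- sim_config("2006-06-01", "2006-08-31", cadence_minutes = 60,
                    delta_forest_jja = 0, wind_displacement_km_per_ms = 0,
                    seed = 31)
  tr <- simulate_truth(lc, cfg)
  fm <- frequency_map(truth_mask_stack(tr))
  box_mean <- function(b) mean(fm$values[(b$r0 + 1):b$r1, (b$c0 + 1):b$c1])
  boxes <- lapply(c("forest", "nonforest_1", "nonforest_2"),
                  function(nm) get_box(lc, nm))
  freqs <- vapply(boxes, box_mean, numeric(1))
  npx <- vapply(boxes, forestcloud:::rect_ncell, numeric(1))
  nslots <- npx * sum(fm$n_slots[1, 1, drop = TRUE])
  se <- sqrt(0.3 * 0.7 * (1 / nslots[1] + 1 / nslots[2]))
  expect_lt(abs(freqs[1] - freqs[2]), 3 * se)
  expect_lt(abs(freqs[1] - freqs[3]), 3 * se)
})

test_that("the JJA forest enhancement is recovered within binomial error", {
  lc <- small_landcover()
  cfg <- sim_config("2006-06-01", "2006-08-31", cadence_minutes = 60,
                    p_cloud_base = 0.3, delta_forest_jja = 0.10,
                    wind_displacement_km_per_ms = 0, seed = 32)
  tr <- simulate_truth(lc, cfg)
  fm <- frequency_map(truth_mask_stack(tr), months = 6:8)
  box_stats <- function(b) {
    v <- fm$values[(b$r0 + 1):b$r1, (b$c0 + 1):b$c1]
    n <- fm$n_slots[(b$r0 + 1):b$r1, (b$c0 + 1):b$c1]
    c(mean(v), sum(n))
  }
  f <- box_stats(get_box(lc, "forest"))
  n1 <- box_stats(get_box(lc, "nonforest_1"))
  n2 <- box_stats(get_box(lc, "nonforest_2"))
  d <- f[1] - (n1[1] + n2[1]) / 2
  se <- sqrt(0.4 * 0.6 / f[2] + 0.3 * 0.7 / (n1[2] + n2[2]))
  expect_lt(abs(d - 0.10), 3 * se)
})

test_that("enhancement is absent outside JJA and reduced after the storm", {
  lc <- build_landcover(30, 30, rect(5, 25, 5, 25),
                        damage_rect = rect(5, 25, 5, 25))
  cfg <- sim_config("2008-06-01", "2009-08-31", cadence_minutes = 60,
                    p_cloud_base = 0.2, delta_forest_jja = 0.3,
                    klaus_date = "2009-01-24", klaus_residual_delta = 0.05,
                    wind_displacement_km_per_ms = 0, seed = 33)
  tr <- simulate_truth(lc, cfg)
  mk <- truth_mask_stack(tr)
  meta <- forestcloud:::slot_meta(mk$time)
  forest_freq <- function(sel) mean(tr$true_cloud[6:25, 6:25, sel])
  jja08 <- which(meta$year == 2008 & meta$month %in% 6:8)
  oct08 <- which(meta$month %in% c(9:12, 1:5))
  jja09 <- which(meta$year == 2009 & meta$month %in% 6:8)
  expect_gt(forest_freq(jja08), 0.45)          # ~0.5 with enhancement
  expect_lt(abs(forest_freq(oct08) - 0.2), 0.02)  # base rate off-season
  expect_lt(forest_freq(jja09), 0.30)          # residual 0.05 post-storm
})

test_that("wind displaces the enhancement field by whole pixels", {
  enh <- matrix(0, 5, 5); enh[3, 3] <- 1
  sh <- forestcloud:::shift_matrix(enh, -2, 1)
  expect_identical(which(sh == 1), which(matrix(seq_len(25), 5, 5) ==
                                          (3 + 1) * 5 - 4))  # row 1, col 4
  expect_identical(sum(forestcloud:::shift_matrix(enh, 10, 0)), 0)  # shifted out
})

test_that("rendered counts follow the additive count model exactly", {
  lc <- small_landcover(10, c(2, 8, 2, 8))
  # no clouds, no noise: counts equal the clear-sky table exactly
  cfg0 <- sim_config("2006-07-01", "2006-07-10", cadence_minutes = 60,
                     p_cloud_base = 0, delta_forest_jja = 0, noise_sd = 0,
                     seed = 41)
  tr0 <- simulate_truth(lc, cfg0)
  cs0 <- render_counts(tr0)
  bins <- time_bin(cs0$time, cs0$scheme)$bin
  for (s in seq_along(cs0$time))
    expect_identical(cs0$counts[, , s], tr0$clearsky[, , bins[s]])

  # all clouds: counts equal clearsky + boost
  cfg1 <- sim_config("2006-07-01", "2006-07-10", cadence_minutes = 60,
                     p_cloud_base = 1, delta_forest_jja = 0,
                     cloud_boost_counts = 50, noise_sd = 0, seed = 42)
  tr1 <- simulate_truth(lc, cfg1)
  cs1 <- render_counts(tr1)
  expect_identical(cs1$counts[, , 1], tr1$clearsky[, , bins[1]] + 50L)

  # clipping keeps counts in the 10-bit range
  cfg2 <- sim_config("2006-07-01", "2006-07-05", cadence_minutes = 60,
                     clear_base_counts = 1000, p_cloud_base = 1,
                     delta_forest_jja = 0, cloud_boost_counts = 900,
                     noise_sd = 30, seed = 43)
  cs2 <- render_counts(simulate_truth(lc, cfg2), threshold_hint = 0)
  expect_true(all(cs2$counts <= 1023L & cs2$counts >= 0L))
})

test_that("rendering warns when clouds cannot exceed the threshold", {
  lc <- small_landcover(8, c(2, 6, 2, 6))
  cfg <- sim_config("2006-07-01", "2006-07-03", cadence_minutes = 60,
                    cloud_boost_counts = 8, seed = 44)
  tr <- simulate_truth(lc, cfg)
  expect_warning(render_counts(tr, threshold_hint = 10), "undetectable")
})

test_that("missing observations are injected at the configured rate", {
  lc <- small_landcover(20, c(4, 16, 4, 16))
  cfg <- sim_config("2006-06-01", "2006-07-31", cadence_minutes = 60,
                    missing_rate = 0.1, seed = 45)
  cs <- render_counts(simulate_truth(lc, cfg))
  p <- mean(is.na(cs$counts))
  expect_lt(abs(p - 0.1), 3 * sqrt(0.1 * 0.9 / length(cs$counts)))
})

test_that("degenerate generator inputs error out", {
  lc <- small_landcover(8, c(2, 6, 2, 6))
  expect_error(sim_config("2006-07-01", "2006-07-03", p_cloud_base = 1.4,
                          seed = 1), "\\[0, 1\\]")
  expect_error(sim_config("2006-07-01", "2006-07-03", seed = NULL), "seed")
  cfg <- sim_config("2006-02-01", "2006-02-10", months = 6:8, seed = 1)
  expect_error(simulate_truth(lc, cfg), "empty record")
})
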
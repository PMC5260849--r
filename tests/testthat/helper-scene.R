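# Shared fixtures: tiny scenes, hand-built mask stacks, and the independent
# brute-force oracle for the ECDF steepest-section estimator.

# Exhaustive slope search over all integer candidates in the sample range:
# score(v) = ECDF(v + w/2) - ECDF(v - w/2), the ECDF evaluated by counting
# sorted samples (the counts are compared exactly, before the common 1/n
# scaling, so ties break toward the smallest candidate). Independent of the
# histogram/running-sum path used by the package.
oracle_steepest <- function(samples, w) {
  samples <- sort(samples[!is.na(samples)])
  n_below <- function(x) findInterval(x, samples)  # samples <= x
  cand <- min(samples):max(samples)
  score <- vapply(cand, function(v) n_below(v + w / 2) - n_below(v - w / 2),
                  numeric(1))
  cand[which.max(score)]
}

# cloud_mask built directly from a flag array (0 clear, 1 cloud, NA missing)
make_mask <- function(flags, time, daylight = c(6, 18)) {
  structure(list(flags = flags, time = time,
                 scheme = forestcloud::bin_scheme(daylight),
                 threshold = NA_real_),
            class = "cloud_mask")
}

# JJA daylight timestamps for one or more summers
jja_times <- function(years = 2006, cadence = 60) {
  cals <- lapply(years, function(y)
    forestcloud::slot_calendar(sprintf("%d-06-01", y), sprintf("%d-08-31", y),
                               cadence_minutes = cadence))
  do.call(c, lapply(cals, forestcloud::slot_times))
}

# small landcover with well-separated boxes
small_landcover <- function(n = 40, forest = c(8, 32, 8, 32)) {
  forestcloud::build_landcover(n, n, forestcloud::rect(forest[1], forest[2],
                                                       forest[3], forest[4]))
}
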
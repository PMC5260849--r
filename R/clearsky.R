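#' Clear-sky count level from the steepest section of the sample ECDF
#'
#' The clear-sky level of a pixel within a (dekad, hour) bin is the integer
#' count value `v` maximizing the ECDF rise over the window
#' `(v - w/2, v + w/2]`, i.e. the densest mode of the count distribution.
#' Because clouds only brighten the scene, ties are broken toward the
#' smallest (darkest) candidate. Candidates are all integers spanning the
#' sample range.
#'
#' @param samples Integer counts (0..1023); `NA`s are dropped.
#' @param window_w Window width in counts (default 3).
#' @return The clear-sky count (integer scalar).
#' @examples
#' ecdf_steepest(c(5L, 5L, 6L, 9L), window_w = 1)  # 5
#' @export
ecdf_steepest <- function(samples, window_w = 3) {
  samples <- samples[!is.na(samples)]
  if (length(samples) == 0L) stop("insufficient data: no samples")
  if (any(samples != round(samples))) stop("samples must be integer counts")
  window_w <- as.integer(window_w)
  if (window_w < 1L) stop("window_w must be >= 1")
  samples <- as.integer(samples)
  minv <- min(samples); maxv <- max(samples)
  if (minv < 0L || maxv > 1023L) stop("counts must be 10-bit (0..1023)")
  h <- tabulate(samples - minv + 1L, nbins = maxv - minv + 1L)
  cs <- c(0L, cumsum(h))
  len <- length(h)
  v <- minv:maxv
  hi <- clamp(v + window_w %/% 2L - minv + 1L, 0L, len)
  lo <- clamp(v + window_w %/% 2L - window_w - minv + 1L, 0L, len)
  score <- cs[hi + 1L] - cs[lo + 1L]
  v[which.max(score)]  # which.max takes the first (smallest) maximizer
}

#' Build the per-pixel clear-sky climatology
#'
#' Applies [ecdf_steepest()] to every pixel and every (dekad, hour) bin of a
#' count stack, pooling all years. Bins with fewer than `min_samples` valid
#' counts are marked invalid rather than extrapolated.
#'
#' @param stack A `count_stack` (see [render_counts()]).
#' @param scheme A [bin_scheme()]; defaults to the stack's own.
#' @param window_w ECDF window width in counts (default 3).
#' @param min_samples Minimum valid samples per bin (default 20).
#' @return An object of class `clearsky_clim`: `values` (ny x nx x n_bins
#'   integer array, `NA` = invalid bin), `n` (sample counts), `scheme`,
#'   `window_w`, `min_samples`.
#' @export
build_clearsky_climatology <- function(stack, scheme = stack$scheme,
                                       window_w = 3, min_samples = 20) {
  stopifnot(inherits(stack, "count_stack"), inherits(scheme, "bin_scheme"))
  dims <- dim(stack$counts)
  npix <- dims[1] * dims[2]
  bins <- time_bin(stack$time, scheme)$bin
  cm <- stack$counts
  dim(cm) <- c(npix, dims[3])
  res <- clim_steepest_cpp(cm, bins, scheme$n_bins,
                           as.integer(window_w), as.integer(min_samples))
  values <- res$values; dim(values) <- c(dims[1], dims[2], scheme$n_bins)
  n <- res$n; dim(n) <- c(dims[1], dims[2], scheme$n_bins)
  structure(list(values = values, n = n, scheme = scheme,
                 window_w = as.integer(window_w),
                 min_samples = as.integer(min_samples)),
            class = "clearsky_clim")
}

#' @export
print.clearsky_clim <- function(x, ...) {
  nb <- sum(colSums(!is.na(x$values), dims = 2) > 0)
  cat(sprintf("<clearsky_clim %d x %d px, %d bins (%d populated), w=%d>\n",
              dim(x$values)[1], dim(x$values)[2], x$scheme$n_bins, nb,
              x$window_w))
  invisible(x)
}

#' Threshold-exceedance cloud detection
#'
#' A slot is flagged cloudy when its count strictly exceeds the pixel's
#' clear-sky climatology for that (dekad, hour) bin by more than `threshold`
#' counts (`count > clim + threshold`); otherwise clear. Missing counts and
#' invalid climatology bins propagate to missing flags.
#'
#' @param stack A `count_stack`.
#' @param clim A [build_clearsky_climatology()] result on a compatible
#'   bin scheme.
#' @param threshold Constant threshold in counts (default 10).
#' @return A `cloud_mask` object: `flags` (ny x nx x nt integer array,
#'   0 = clear, 1 = cloud, `NA` = missing), `time`, `scheme`, `threshold`.
#' @export
detect_clouds <- function(stack, clim, threshold = 10) {
  stopifnot(inherits(stack, "count_stack"), inherits(clim, "clearsky_clim"))
  dims <- dim(stack$counts)
  if (!all(dims[1:2] == dim(clim$values)[1:2]))
    stop("count stack and climatology grids differ")
  bins <- time_bin(stack$time, clim$scheme)$bin
  flags <- array(NA_integer_, dims)
  for (b in unique(bins)) {
    slots <- which(bins == b)
    ref <- clim$values[, , b] + threshold
    f <- as.integer(stack$counts[, , slots] > as.vector(ref))
    flags[, , slots] <- f
  }
  structure(list(flags = flags, time = stack$time, scheme = clim$scheme,
                 threshold = threshold),
            class = "cloud_mask")
}

#' @export
print.cloud_mask <- function(x, ...) {
  cat(sprintf("<cloud_mask %d x %d px, %d slots, cloud %.1f%%, missing %.1f%%>\n",
              dim(x$flags)[1], dim(x$flags)[2], length(x$time),
              100 * mean(x$flags == 1L, na.rm = TRUE),
              100 * mean(is.na(x$flags))))
  invisible(x)
}

#' Confusion summary of a detected mask against the simulation truth
#'
#' @param mask A detected `cloud_mask`.
#' @param truth A [simulate_truth()] result on the same grid and times.
#' @return List with `hit_rate` (detected cloud | true cloud), `false_alarm_rate`
#'   (detected cloud | true clear), and the confusion counts.
#' @export
mask_confusion <- function(mask, truth) {
  stopifnot(inherits(mask, "cloud_mask"), inherits(truth, "truth_stack"))
  f <- mask$flags
  tr <- truth$true_cloud
  # counted expression by expression to keep peak memory at one temporary
  hits <- sum(f == 1L & tr, na.rm = TRUE)
  misses <- sum(f == 0L & tr, na.rm = TRUE)
  fa <- sum(f == 1L & !tr, na.rm = TRUE)
  cr <- sum(f == 0L & !tr, na.rm = TRUE)
  list(hit_rate = hits / (hits + misses),
       false_alarm_rate = fa / (fa + cr),
       n = c(hit = hits, miss = misses, false_alarm = fa, correct_rejection = cr))
}
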
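#' Welch two-sample t-test between two daily box series
#'
#' Compares the daily cloud-frequency values of two boxes with Welch's
#' unequal-variance two-sample t-test (two-sided).
#'
#' @param a,b Daily series (`data.frame` with a `value` column, or numeric
#'   vectors). `NA`s are dropped.
#' @return An object of class `fc_ttest`: `t`, `df`, `p`, `n` (per sample),
#'   `mean_diff`.
#' @export
ttest_two_boxes <- function(a, b) {
  x <- if (is.data.frame(a)) a$value else a
  y <- if (is.data.frame(b)) b$value else b
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("insufficient data: need >= 2 non-missing values per series")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate: both series constant
    if (mean(x) == mean(y)) {
      res <- list(t = 0, df = length(x) + length(y) - 2L, p = 1)
    } else {
      res <- list(t = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2L, p = 0)
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(c(res, list(n = c(length(x), length(y)),
                        mean_diff = mean(x) - mean(y))),
            class = "fc_ttest")
}

#' @export
print.fc_ttest <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.3f, df = %.1f, p = %.3g (n = %d, %d)\n",
              x$t, x$df, x$p, x$n[1], x$n[2]))
  invisible(x)
}

boot_means <- function(v, n_boot) {
  if (length(v) == 1L) return(rep(v, n_boot))
  colMeans(matrix(sample(v, length(v) * n_boot, replace = TRUE),
                  nrow = length(v)))
}

#' Bootstrap 50/95 percentile intervals per bin
#'
#' For every bin (e.g. dekad of year, or hour of day), resamples the
#' contributing daily values with replacement `n_boot` times and reports the
#' 2.5/25/75/97.5 percentiles of the bootstrap bin mean. Deterministic under
#' a fixed seed.
#'
#' @param daily `data.frame` with columns `bin` and `value` (one row per
#'   contributing day; `NA` values dropped).
#' @param n_boot Bootstrap replicates (default 1000; < 100 warns).
#' @param seed Integer seed (mandatory).
#' @return `data.frame` with columns `bin`, `estimate`, `q2.5`, `q25`,
#'   `q75`, `q97.5`, `n`; attribute `n_boot`. Empty bins give `NA` rows.
#' @export
bootstrap_percentile_intervals <- function(daily, n_boot = 1000, seed) {
  stopifnot(is.data.frame(daily), all(c("bin", "value") %in% names(daily)))
  if (n_boot < 100) warning("n_boot < 100: intervals will be unstable")
  bins <- sort(unique(daily$bin))
  out <- with_seed(seed, {
    rows <- lapply(bins, function(b) {
      v <- daily$value[daily$bin == b]
      v <- v[!is.na(v)]
      if (length(v) == 0L)
        return(data.frame(bin = b, estimate = NA_real_, q2.5 = NA_real_,
                          q25 = NA_real_, q75 = NA_real_, q97.5 = NA_real_,
                          n = 0L))
      bm <- boot_means(v, n_boot)
      q <- stats::quantile(bm, c(0.025, 0.25, 0.75, 0.975), names = FALSE,
                           type = 7)
      data.frame(bin = b, estimate = mean(v), q2.5 = q[1], q25 = q[2],
                 q75 = q[3], q97.5 = q[4], n = length(v))
    })
    do.call(rbind, rows)
  })
  attr(out, "n_boot") <- n_boot
  out
}

#' Bins with a significant forest/non-forest difference
#'
#' Resampling days jointly (pairing the two boxes by date, preserving
#' day-level synoptic correlation), bootstraps the mean paired difference
#' per bin; a bin is significant when the 95% percentile interval of the
#' difference excludes zero.
#'
#' @param forest,nonforest Aligned daily series (`data.frame` with `date`,
#'   `bin`, `value`); every shared date must carry the same bin in both.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed (mandatory).
#' @return `data.frame` with columns `bin`, `diff` (mean paired difference),
#'   `lo`, `hi` (95% interval), `n`, `significant`.
#' @export
significant_bins <- function(forest, nonforest, n_boot = 1000, seed) {
  need <- c("date", "bin", "value")
  stopifnot(all(need %in% names(forest)), all(need %in% names(nonforest)))
  m <- merge(forest[need], nonforest[need], by = "date",
             suffixes = c("_f", "_nf"))
  if (nrow(m) == 0L) stop("alignment error: series share no dates")
  if (any(m$bin_f != m$bin_nf))
    stop("alignment error: bins disagree on shared dates")
  m$d <- m$value_f - m$value_nf
  m <- m[!is.na(m$d), , drop = FALSE]
  bins <- sort(unique(m$bin_f))
  out <- with_seed(seed, {
    rows <- lapply(bins, function(b) {
      d <- m$d[m$bin_f == b]
      bm <- boot_means(d, n_boot)
      q <- stats::quantile(bm, c(0.025, 0.975), names = FALSE, type = 7)
      data.frame(bin = b, diff = mean(d), lo = q[1], hi = q[2],
                 n = length(d), significant = q[1] > 0 | q[2] < 0)
    })
    do.call(rbind, rows)
  })
  out
}
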
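# model evaluation: d(t) = c + b t + A sin^2(pi (t - phi)), period 1 year
sqsine_mu <- function(par, t) {
  par[["c"]] + par[["b"]] * t + par[["A"]] * sin(pi * (t - par[["phi"]]))^2
}

# decimal years since t0 from mid-dekad dates
years_since <- function(date, t0) (as.numeric(date) - as.numeric(t0)) / 365.25

#' Fit a squared sine with trend to a dekadal difference series
#'
#' Nonlinear least squares for `d(t) = c + b t + A sin^2(pi (t - phi))`, `t`
#' in decimal years since `t0`, with the period fixed at one year (the
#' seasonal cycle of the forest cloud enhancement). The fit is multi-started
#' over `phi` in {0, 0.25, 0.5, 0.75} (the linear parameters `c`, `b`, `A`
#' are solved by ordinary least squares at each start) and the best
#' converged solution by residual sum of squares is kept. The amplitude is
#' canonicalized to `A >= 0` and the phase to `phi` in `[0, 1)` using the
#' identity `A sin^2(x) = A - A sin^2(x - pi/2)`. Parameter 95% confidence
#' intervals come from the asymptotic (Jacobian-based) covariance.
#'
#' @param series `data.frame` with columns `date` and `value` (one row per
#'   dekad; `NA` values dropped).
#' @param t0 Reference date for `t = 0` (default: first non-missing date).
#' @return An object of class `sine_fit`: `coefficients` (named `c`, `b`,
#'   `A`, `phi`), `ci` (4 x 2 matrix of 95% bounds), `sigma` (residual SD),
#'   `n`, `t0`, `fitted`, `residuals`, `t`.
#' @export
fit_squared_sine <- function(series, t0 = NULL) {
  stopifnot(is.data.frame(series), all(c("date", "value") %in% names(series)))
  keep <- !is.na(series$value)
  date <- as.Date(series$date)[keep]
  value <- series$value[keep]
  n <- length(value)
  if (n < 8L) stop("need at least 8 non-missing dekads")
  span <- as.numeric(max(date) - min(date))
  if (span < 330) stop("series must span at least one year for phase identifiability")
  if (is.null(t0)) t0 <- min(date)
  t0 <- as.Date(t0)
  t <- years_since(date, t0)

  if (stats::sd(value) == 0) {
    # degenerate constant series: A = 0, phi = 0 by convention
    cf <- c(c = value[1], b = 0, A = 0, phi = 0)
    ci <- cbind(lo95 = cf, hi95 = cf)
    return(new_sine_fit(cf, ci, 0, n, t0, rep(value[1], n), rep(0, n), t, date))
  }

  fits <- list()
  for (phi0 in c(0, 0.25, 0.5, 0.75)) {
    s <- sin(pi * (t - phi0))^2
    lin <- stats::lm(value ~ t + s)
    start <- list(c = unname(stats::coef(lin)[1]),
                  b = unname(stats::coef(lin)[2]),
                  A = unname(stats::coef(lin)[3]), phi = phi0)
    if (is.na(start$A)) start$A <- stats::sd(value)
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ c + b * t + A * sin(pi * (t - phi))^2,
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0L) stop("squared-sine fit failed to converge from all starts")
  dev <- vapply(fits, stats::deviance, numeric(1))
  fit <- fits[[which.min(dev)]]

  cf <- stats::coef(fit)
  if (cf[["A"]] < 0) {
    # refit from the canonical parameterization for a clean covariance
    start2 <- list(c = cf[["c"]] + cf[["A"]], b = cf[["b"]],
                   A = -cf[["A"]], phi = (cf[["phi"]] + 0.5) %% 1)
    fit2 <- tryCatch(
      minpack.lm::nlsLM(value ~ c + b * t + A * sin(pi * (t - phi))^2,
                        start = start2,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit2) && stats::coef(fit2)[["A"]] >= 0) fit <- fit2
  }
  cf <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  dfres <- stats::df.residual(fit)
  flip <- cf[["A"]] < 0
  if (flip) {
    # canonical transform of estimates; SEs carried over (|dA'| = |dA|)
    cf2 <- c(c = cf[["c"]] + cf[["A"]], b = cf[["b"]],
             A = -cf[["A"]], phi = cf[["phi"]] + 0.5)
    cf <- cf2
  }
  cf[["phi"]] <- cf[["phi"]] %% 1
  tcrit <- stats::qt(0.975, dfres)
  se <- se[c("c", "b", "A", "phi")]
  ci <- cbind(lo95 = cf - tcrit * se, hi95 = cf + tcrit * se)
  new_sine_fit(cf, ci, sm$sigma, n, t0, stats::fitted(fit),
               stats::residuals(fit), t, date)
}

new_sine_fit <- function(cf, ci, sigma, n, t0, fitted, residuals, t, date) {
  rownames(ci) <- names(cf)
  structure(list(coefficients = cf, ci = ci, sigma = sigma, n = n, t0 = t0,
                 fitted = as.numeric(fitted), residuals = as.numeric(residuals),
                 t = t, date = date),
            class = "sine_fit")
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf("Squared-sine + trend fit (n = %d dekads, t0 = %s)\n",
              x$n, format(x$t0)))
  est <- x$coefficients
  for (p in names(est))
    cat(sprintf("  %-4s %+.4f  [%+.4f, %+.4f]\n", p, est[[p]],
                x$ci[p, 1], x$ci[p, 2]))
  cat(sprintf("  residual SD %.4f\n", x$sigma))
  invisible(x)
}

#' @export
coef.sine_fit <- function(object, ...) object$coefficients

#' Pre/post-breakpoint amplitude change of the seasonal cycle
#'
#' Splits the dekadal difference series at the breakpoint date (the storm
#' date), fits the squared-sine-with-trend model independently to each
#' segment, and reports both amplitudes with their 95% confidence intervals
#' and their ratio.
#'
#' @param series `data.frame` with columns `date`, `value`.
#' @param breakpoint Breakpoint date; dekads dated before it form the `pre`
#'   segment.
#' @return An object of class `amplitude_change`: `pre`, `post`
#'   ([fit_squared_sine()] objects), `A_pre`, `A_post`, `ci_pre`, `ci_post`,
#'   `ratio`, `breakpoint`.
#' @export
amplitude_change <- function(series, breakpoint) {
  stopifnot(is.data.frame(series), all(c("date", "value") %in% names(series)))
  breakpoint <- as.Date(breakpoint)
  date <- as.Date(series$date)
  pre <- series[date < breakpoint, , drop = FALSE]
  post <- series[date >= breakpoint, , drop = FALSE]
  if (nrow(pre) == 0L || nrow(post) == 0L)
    stop("breakpoint outside the series range")
  fp <- tryCatch(fit_squared_sine(pre),
                 error = function(e) stop("pre segment: ", conditionMessage(e)))
  fq <- tryCatch(fit_squared_sine(post),
                 error = function(e) stop("post segment: ", conditionMessage(e)))
  A_pre <- fp$coefficients[["A"]]; A_post <- fq$coefficients[["A"]]
  structure(list(pre = fp, post = fq, A_pre = A_pre, A_post = A_post,
                 ci_pre = fp$ci["A", ], ci_post = fq$ci["A", ],
                 ratio = if (A_pre > 0) A_post / A_pre else NA_real_,
                 breakpoint = breakpoint),
            class = "amplitude_change")
}

#' @export
print.amplitude_change <- function(x, ...) {
  cat(sprintf("Seasonal amplitude change at %s\n", format(x$breakpoint)))
  cat(sprintf("  A_pre  = %.3f [%.3f, %.3f] (n = %d)\n", x$A_pre,
              x$ci_pre[1], x$ci_pre[2], x$pre$n))
  cat(sprintf("  A_post = %.3f [%.3f, %.3f] (n = %d)\n", x$A_post,
              x$ci_post[1], x$ci_post[2], x$post$n))
  cat(sprintf("  ratio  = %.3f\n", x$ratio))
  invisible(x)
}
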
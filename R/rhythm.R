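#' Binned activity record
#'
#' A uniformly binned count time series (e.g. wheel-running events per bin),
#' optionally annotated with the light/dark schedule it was recorded under.
#' Bins are half-open `[start, start + width)`.
#'
#' @param counts Non-negative integer counts per bin.
#' @param bin_minutes Bin width in minutes.
#' @param start_min Start time of the first bin, minutes from experiment
#'   start (default 0).
#' @param schedule Optional [ld_schedule()] annotation.
#' @return An object of class `actogram`.
#' @export
actogram <- function(counts, bin_minutes, start_min = 0, schedule = NULL) {
  if (!is.numeric(counts) || length(counts) < 1L || any(!is.finite(counts)) ||
      any(counts < 0)) {
    stop_parameter("counts must be non-negative finite numbers")
  }
  bin_minutes <- check_number(bin_minutes, "bin_minutes", 0, strict = TRUE)
  start_min <- check_number(start_min, "start_min")
  if (!is.null(schedule) && !inherits(schedule, "ld_schedule")) {
    stop_parameter("schedule must be an ld_schedule or NULL")
  }
  structure(list(counts = as.numeric(counts), bin_minutes = bin_minutes,
                 start_min = start_min, schedule = schedule),
            class = "actogram")
}

#' @export
print.actogram <- function(x, ...) {
  span_h <- length(x$counts) * x$bin_minutes / 60
  cat(sprintf("actogram: %d bins of %g min (%.1f h, %.1f days), %g total counts\n",
              length(x$counts), x$bin_minutes, span_h, span_h / 24,
              sum(x$counts)))
  if (!is.null(x$schedule)) {
    cat(sprintf("  schedule: %g h light / %g h dark\n",
                x$schedule$light_hours, x$schedule$dark_hours))
  }
  invisible(x)
}

span_hours <- function(a) length(a$counts) * a$bin_minutes / 60

#' Mean activity profile folded at a period
#'
#' Averages the record across complete cycles of `fold_period_h`, giving the
#' mean count per phase bin (phases half-open). At least two complete fold
#' periods must be available and the fold period must be a whole number of
#' bins.
#'
#' @param a An [actogram()].
#' @param fold_period_h Folding period in hours (default 24).
#' @return Data frame with `phase_h` (phase-bin start, hours) and
#'   `mean_count`.
#' @export
folded_profile <- function(a, fold_period_h = 24) {
  stopifnot(inherits(a, "actogram"))
  bpc <- fold_period_h * 60 / a$bin_minutes
  if (abs(bpc - round(bpc)) > 1e-9) {
    stop_parameter("fold period must be a whole number of bins")
  }
  bpc <- as.integer(round(bpc))
  n_cycles <- length(a$counts) %/% bpc
  if (n_cycles < 2L) {
    stop_parameter("record must span at least two fold periods")
  }
  m <- matrix(a$counts[seq_len(bpc * n_cycles)], nrow = bpc)
  data.frame(phase_h = (seq_len(bpc) - 1L) * a$bin_minutes / 60,
             mean_count = rowMeans(m))
}

#' Total activity per 24 hours
#'
#' Mean total counts over the complete 24-h windows of the record.
#'
#' @param a An [actogram()].
#' @return Mean counts per complete 24-h day.
#' @export
total_daily_activity <- function(a) {
  stopifnot(inherits(a, "actogram"))
  bpd <- 24 * 60 / a$bin_minutes
  if (abs(bpd - round(bpd)) > 1e-9) {
    stop_parameter("bin width must divide 24 h")
  }
  bpd <- as.integer(round(bpd))
  n_days <- length(a$counts) %/% bpd
  if (n_days < 1L) {
    sdc_abort("record spans less than 24 h", "sdc_insufficient_data_error")
  }
  sum(a$counts[seq_len(bpd * n_days)]) / n_days
}

#' Morlet-wavelet periodogram of an activity record
#'
#' Continuous wavelet transform of the mean-subtracted counts with the
#' Morlet mother wavelet (central frequency `omega0`, default 6), computed
#' in the frequency domain, on a logarithmic grid of Fourier periods. Power
#' is averaged over time per period, excluding samples inside the cone of
#' influence (within an e-folding time `sqrt(2) * scale` of either record
#' edge); the dominant period is the argmax of this global power spectrum.
#' Periods whose cone of influence covers the whole record get `NA` power
#' and cannot be dominant.
#'
#' @param a An [actogram()].
#' @param period_min,period_max Period grid limits in hours; the grid must
#'   lie within `[2 * bin width, record span / 2]`.
#' @param n_periods Number of log-spaced grid points (default 200).
#' @param omega0 Morlet central frequency (dimensionless, default 6).
#' @return An object of class `morlet_periodogram`: list with `periods`
#'   (hours), `power` (time-averaged wavelet power), `dominant_period`
#'   (hours) and `omega0`.
#' @examples
#' a <- gen_actogram(ld_schedule(12, 12), days = 14, rate_dark = 5,
#'                   rate_light = 0.2, seed = 1)
#' p <- morlet_periodogram(a)
#' p$dominant_period
#' @export
morlet_periodogram <- function(a, period_min = 4, period_max = 32,
                               n_periods = 200, omega0 = 6) {
  stopifnot(inherits(a, "actogram"))
  period_min <- check_number(period_min, "period_min", 0, strict = TRUE)
  period_max <- check_number(period_max, "period_max", 0, strict = TRUE)
  n_periods <- check_count(n_periods, "n_periods", min = 2)
  omega0 <- check_number(omega0, "omega0", 0, strict = TRUE)
  dt <- a$bin_minutes / 60
  span <- span_hours(a)
  if (period_min < 2 * dt || period_max > span / 2 || period_min >= period_max) {
    stop_parameter(sprintf(
      "period grid must satisfy 2*bin (%.3g h) <= pmin < pmax <= span/2 (%.3g h)",
      2 * dt, span / 2))
  }
  x <- a$counts - mean(a$counts)
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xpad <- c(x, numeric(npad - n))
  xhat <- stats::fft(xpad)
  # Angular frequencies of the padded grid.
  k <- seq_len(npad) - 1L
  wk <- ifelse(k <= npad / 2, k, k - npad) * 2 * pi / (npad * dt)

  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  periods <- exp(seq(log(period_min), log(period_max), length.out = n_periods))
  scales <- periods / fourier_factor

  # Time distance to the nearer record edge, hours.
  t_idx <- seq_len(n)
  edge_dist <- pmin(t_idx - 1L, n - t_idx) * dt

  power <- vapply(scales, function(s) {
    psi_hat <- numeric(npad)
    pos <- wk > 0
    psi_hat[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-(s * wk[pos] - omega0)^2 / 2)
    w <- stats::fft(xhat * psi_hat, inverse = TRUE) / npad
    p <- Mod(w[seq_len(n)])^2
    inside <- edge_dist >= sqrt(2) * s
    if (!any(inside)) return(NA_real_)
    mean(p[inside])
  }, numeric(1))

  dominant <- periods[which.max(power)]
  structure(list(periods = periods, power = power,
                 dominant_period = dominant, omega0 = omega0,
                 n_bins = n, bin_minutes = a$bin_minutes),
            class = "morlet_periodogram")
}

#' @export
print.morlet_periodogram <- function(x, ...) {
  cat(sprintf("morlet_periodogram (omega0 = %g): %d periods in [%.3g, %.3g] h\n",
              x$omega0, length(x$periods), min(x$periods), max(x$periods)))
  cat(sprintf("  dominant period: %.2f h\n", x$dominant_period))
  invisible(x)
}

#' Plot a wavelet periodogram
#'
#' @param x A `morlet_periodogram`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.morlet_periodogram <- function(x, ...) {
  graphics::plot(x$periods, x$power, type = "l", log = "x",
                 xlab = "period (h)", ylab = "mean wavelet power", ...)
  graphics::abline(v = x$dominant_period, lty = 2, col = "red3")
  invisible(x)
}
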
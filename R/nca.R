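# Noncompartmental exposure metrics. All integration is by the linear
# trapezoid rule (no log-trapezoid), matching how the reference profiles
# were analysed; window edges falling between grid points are handled by
# linear interpolation.

.check_series <- function(times, concs) {
  if (length(times) != length(concs)) {
    stop("times and concs must have equal length", call. = FALSE)
  }
  if (length(times) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (any(concs < 0)) stop("concentrations must be >= 0", call. = FALSE)
  invisible(NULL)
}

.check_window <- function(times, t0, t1) {
  if (t0 >= t1) stop(sprintf("window [%g, %g] is empty", t0, t1), call. = FALSE)
  if (t0 < times[1] - 1e-9 || t1 > times[length(times)] + 1e-9) {
    stop(sprintf("window [%g, %g] lies outside the grid span [%g, %g]",
                 t0, t1, times[1], times[length(times)]), call. = FALSE)
  }
  invisible(NULL)
}

#' Area under the curve by the linear trapezoid rule
#'
#' @param times time grid (h), strictly increasing.
#' @param concs concentrations (ng/ml), >= 0.
#' @param t0,t1 integration window (h); edges between grid points are
#'   linearly interpolated. Defaults to the full grid span.
#' @return AUC over `[t0, t1]` (ng*h/ml).
#' @export
auc_trapezoid <- function(times, concs, t0 = times[1],
                          t1 = times[length(times)]) {
  .check_series(times, concs)
  .check_window(times, t0, t1)
  inside <- times > t0 & times < t1
  tt <- c(t0, times[inside], t1)
  cc <- c(approx(times, concs, xout = t0)$y, concs[inside],
          approx(times, concs, xout = t1)$y)
  sum(diff(tt) * (head_(cc) + tail_(cc)) / 2)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' Extrema of a concentration profile over a window
#'
#' Maximum and minimum over the grid points inside `[t0, t1]`; ties are
#' broken by the earliest time.
#'
#' @inheritParams auc_trapezoid
#' @return list with `cmax`, `tmax`, `cmin`, `tmin`.
#' @export
cmax_cmin <- function(times, concs, t0 = times[1], t1 = times[length(times)]) {
  .check_series(times, concs)
  .check_window(times, t0, t1)
  idx <- which(times >= t0 - 1e-9 & times <= t1 + 1e-9)
  if (!length(idx)) stop("no grid points inside the window", call. = FALSE)
  ct <- concs[idx]
  tt <- times[idx]
  imax <- which.max(ct)   # which.max returns the first (earliest) maximum
  imin <- which.min(ct)
  list(cmax = ct[imax], tmax = tt[imax], cmin = ct[imin], tmin = tt[imin])
}

#' Terminal half-life from the log-linear tail
#'
#' Fits `ln(conc)` against time over the trailing run of at least three
#' positive observations after the peak, choosing the run that maximizes the
#' adjusted R-squared of the least-squares line, and returns `ln(2)` over
#' the negative slope.
#'
#' @inheritParams auc_trapezoid
#' @return terminal half-life (h).
#' @export
terminal_half_life <- function(times, concs) {
  .check_series(times, concs)
  pos <- concs > 0
  imax <- which.max(concs)
  cand <- which(pos & seq_along(concs) > imax)
  if (length(cand) < 3) {
    stop("need at least 3 positive observations after the peak", call. = FALSE)
  }
  # trailing runs must be contiguous in the positive tail
  last <- cand[length(cand)]
  starts <- cand[cand <= last - 2]
  best_slope <- NULL
  best_r2 <- -Inf
  for (s in starts) {
    seg <- s:last
    if (any(!pos[seg])) next
    x <- times[seg]
    y <- log(concs[seg])
    n <- length(seg)
    slope <- cov(x, y) / var(x)
    rss <- sum((y - mean(y) - slope * (x - mean(x)))^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
    if (is.finite(adj_r2) && adj_r2 > best_r2) {
      best_r2 <- adj_r2
      best_slope <- slope
    }
  }
  if (is.null(best_slope)) stop("no valid terminal segment found", call. = FALSE)
  slope <- best_slope
  if (slope >= 0) {
    stop("terminal slope is nonnegative; half-life undefined", call. = FALSE)
  }
  log(2) / (-slope)
}

#' Time spent above a concentration threshold
#'
#' Total duration with concentration strictly above `threshold`, with
#' crossing times located by linear interpolation between grid points.
#'
#' @inheritParams auc_trapezoid
#' @param threshold concentration threshold (ng/ml), > 0.
#' @return time above threshold (h).
#' @export
time_above <- function(times, concs, threshold) {
  .check_series(times, concs)
  threshold <- .check_range(threshold, "threshold", 0, lower_open = TRUE)
  total <- 0
  for (i in seq_len(length(times) - 1L)) {
    t1 <- times[i]; t2 <- times[i + 1]
    c1 <- concs[i]; c2 <- concs[i + 1]
    a1 <- c1 > threshold
    a2 <- c2 > threshold
    if (a1 && a2) {
      total <- total + (t2 - t1)
    } else if (a1 != a2) {
      tc <- t1 + (threshold - c1) / (c2 - c1) * (t2 - t1)
      total <- total + if (a1) tc - t1 else t2 - tc
    }
  }
  total
}

#' Percent change of an alternative value versus a reference
#'
#' @param ref reference value, > 0.
#' @param alt alternative value.
#' @return `100 * (alt - ref) / ref` (%).
#' @export
percent_change <- function(ref, alt) {
  ref <- .check_range(ref, "ref", 0, lower_open = TRUE)
  alt <- .check_scalar(alt, "alt")
  100 * (alt - ref) / ref
}

# minimum after the first local maximum (the "trough" used for regimen
# comparisons: profiles start at zero, so the absolute window minimum is
# uninformative)
.post_peak_min <- function(times, concs, t0, t1) {
  idx <- which(times >= t0 - 1e-9 & times <= t1 + 1e-9)
  tt <- times[idx]; ct <- concs[idx]
  n <- length(ct)
  ip <- NULL
  for (i in seq_len(n - 1L)) {
    if (ct[i] > 0 && ct[i] >= ct[i + 1]) { ip <- i; break }
  }
  if (is.null(ip)) ip <- n  # monotone rising: trough is the last point
  min(ct[ip:n])
}

#' Noncompartmental summary of a concentration series
#'
#' Convenience wrapper computing the standard exposure metrics over a
#' stated window. The terminal half-life (and hence the extrapolated
#' `auc_inf`) is only defined for profiles with a clean log-linear tail; for
#' profiles still in the absorption/dosing phase both are returned as `NA`.
#'
#' @inheritParams auc_trapezoid
#' @param window analysis window `c(t0, t1)` (h).
#' @param threshold threshold for time-above (ng/ml).
#' @return an object of class `nca_result`: list with `auc_window`,
#'   `auc_inf`, `cmax`, `tmax`, `cmin_window`, `t_half`,
#'   `time_above_threshold`, `window`, `threshold`.
#' @export
nca <- function(times, concs, window = c(times[1], times[length(times)]),
                threshold = 1) {
  ext <- cmax_cmin(times, concs, window[1], window[2])
  t_half <- tryCatch(terminal_half_life(times, concs),
                     error = function(e) NA_real_)
  auc_last <- auc_trapezoid(times, concs)
  clast <- concs[length(concs)]
  auc_inf <- if (is.finite(t_half) && clast > 0) {
    auc_last + clast * t_half / log(2)
  } else NA_real_
  structure(list(
    auc_window = auc_trapezoid(times, concs, window[1], window[2]),
    auc_inf = auc_inf,
    cmax = ext$cmax, tmax = ext$tmax, cmin_window = ext$cmin,
    t_half = t_half,
    time_above_threshold = time_above(times, concs, threshold),
    window = window, threshold = threshold
  ), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> window [%g, %g] h, threshold %g ng/ml\n",
              x$window[1], x$window[2], x$threshold))
  cat(sprintf("  AUC(window) %.4g ng*h/ml  AUC(inf) %.4g ng*h/ml\n",
              x$auc_window, x$auc_inf))
  cat(sprintf("  Cmax %.4g ng/ml at %.4g h  Cmin %.4g ng/ml  t1/2 %.4g h\n",
              x$cmax, x$tmax, x$cmin_window, x$t_half))
  cat(sprintf("  time above threshold %.4g h\n", x$time_above_threshold))
  invisible(x)
}
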
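MONITOR_GASES <- c("o2", "n2o", "sevo")

# resolve a window argument ("before"/"during"/"after" or c(t_start, t_end))
resolve_window <- function(trace, window) {
  if (is.character(window)) {
    w <- disconnection_windows(trace)
    if (!window %in% names(w))
      stop("window must be one of ", paste(names(w), collapse = "/"),
           " or a numeric c(t_start, t_end)", call. = FALSE)
    w[[window]]
  } else {
    stopifnot(is.numeric(window), length(window) == 2L)
    window
  }
}

#' Per-minute monitor readings in a window
#'
#' The statistical comparison uses one reading per minute: 10 readings per
#' 10-min window per run, so three replicate runs pool to n = 30 values per
#' window. Readings are taken at whole minutes after the window start
#' (minute 1 through minute `width`), matched to the nearest trace sample,
#' and returned in percent.
#'
#' @param trace A [gas_trace()].
#' @param gas `"o2"`, `"n2o"` or `"sevo"`.
#' @param window `"before"`, `"during"`, `"after"`, or `c(t_start, t_end)`
#'   in min.
#' @return Numeric vector of readings, percent.
#' @export
minute_readings <- function(trace, gas, window) {
  gas <- match.arg(gas, MONITOR_GASES)
  w <- resolve_window(trace, window)
  at <- seq(w[1] + 1, w[2], by = 1)
  idx <- vapply(at, function(t) which.min(abs(trace$time_min - t)), integer(1))
  if (any(abs(trace$time_min[idx] - at) > attr(trace, "sample_interval") / 2 + 1e-9))
    stop("trace does not cover the requested window", call. = FALSE)
  100 * trace[[gas]][idx]
}

#' Windowed summary of inspired gas fractions
#'
#' Median, quartiles and range of a gas's monitor readings over one of the
#' 10-min comparison windows around the disconnection event (`before` /
#' `during` / `after`), in percent. By default the readings are the
#' per-minute subsample used by the statistical comparison
#' ([minute_readings()]); with `per_minute = FALSE` every trace sample in the
#' window is used. Quartiles are computed by linear interpolation between
#' order statistics (`stats::quantile()` type 7).
#'
#' @inheritParams minute_readings
#' @param per_minute Use the per-minute reading grid (default) or all samples.
#' @return A one-row data.frame: `gas`, `window`, `n`, `median`, `q25`,
#'   `q75`, `min`, `max` (percent).
#' @export
window_summary <- function(trace, gas, window, per_minute = TRUE) {
  gas <- match.arg(gas, MONITOR_GASES)
  if (per_minute) {
    vals <- minute_readings(trace, gas, window)
  } else {
    w <- resolve_window(trace, window)
    vals <- 100 * trace_window(trace, w[1], w[2])[[gas]]
  }
  s <- pooled_summary(vals)
  cbind(data.frame(gas = gas,
                   window = if (is.character(window)) window else "custom",
                   stringsAsFactors = FALSE), s)
}

# five-number summary (type-7 quartiles) of pooled readings, in percent
pooled_summary <- function(vals) {
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(vals), median = q[2], q25 = q[1], q75 = q[3],
             min = min(vals), max = max(vals))
}

#' Estimate a time constant by the 63% criterion
#'
#' Empirical time-constant estimator for an approximately exponential
#' transition observed in a monitor trace. Within the analysis window the
#' starting value `f_initial` is the reading at the window start and the
#' final value `f_final` is the window extremum — the minimum for a falling
#' signal (e.g. inspired O2 during bag disconnection) or the maximum for a
#' rising one; the direction is the sign of the net change across the
#' window. The estimate is the first time, linearly interpolated between
#' samples, at which the signal crosses
#' `f_initial + (1 - exp(-1)) * (f_final - f_initial)`, i.e. has covered
#' 63.2% of its total change, measured from the window start.
#'
#' The estimator is invariant to affine rescaling of the signal. A constant
#' signal has no defined time constant and raises an error.
#'
#' @inheritParams minute_readings
#' @param window `c(t_start, t_end)` in min, or `"during"` (default) for the
#'   disconnection phase window.
#' @return A `tau_estimate` list: `tau` (min), `f_initial`, `f_final`
#'   (percent), `direction` (`"falling"` or `"rising"`).
#' @examples
#' tr <- run_protocol(canonical_protocol("oxygen_air", 2))
#' estimate_tau_63(tr, "o2", "during")$tau
#' @export
estimate_tau_63 <- function(trace, gas, window = "during") {
  gas <- match.arg(gas, MONITOR_GASES)
  w <- resolve_window(trace, window)
  sub <- trace_window(trace, w[1], w[2])
  tt <- sub$time_min
  ff <- 100 * sub[[gas]]
  if (length(ff) < 2L || diff(range(ff)) == 0)
    stop("time constant undefined: signal is constant in the window",
         call. = FALSE)
  f_init <- ff[1L]
  falling <- ff[length(ff)] < f_init
  f_final <- if (falling) min(ff) else max(ff)
  if (f_final == f_init)
    stop("time constant undefined: no net change in the window", call. = FALSE)
  thr <- f_init + (1 - exp(-1)) * (f_final - f_init)
  crossed <- if (falling) ff <= thr else ff >= thr
  if (!any(crossed))
    stop("threshold never crossed: transition censored at the window end",
         call. = FALSE)
  i <- which(crossed)[1L]
  t_cross <- if (i == 1L) tt[1L] else {
    # linear interpolation between the bracketing samples
    tt[i - 1L] + (thr - ff[i - 1L]) / (ff[i] - ff[i - 1L]) * (tt[i] - tt[i - 1L])
  }
  structure(list(tau = t_cross - tt[1L], f_initial = f_init,
                 f_final = f_final,
                 direction = if (falling) "falling" else "rising"),
            class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  cat(sprintf("<tau_estimate> tau = %.2f min (%s, %.4g%% -> %.4g%%)\n",
              x$tau, x$direction, x$f_initial, x$f_final))
  invisible(x)
}

#' Friedman rank test across repeated-measures windows
#'
#' Nonparametric comparison of k paired treatments (here: the before /
#' during / after windows) over n blocks (here: the 30 minute-by-replicate
#' readings). Computes the tie-corrected Friedman chi-square statistic via
#' [stats::friedman.test()] and its chi-square p-value with `k - 1` degrees
#' of freedom. Fully tied data (every block constant) carry no information
#' about a treatment effect and return `statistic = 0`, `p_value = 1`.
#'
#' @param values Numeric matrix, `n_blocks x k_treatments`, no missing cells.
#' @return A `friedman_result` list: `statistic`, `df`, `p_value`,
#'   `n_blocks`, `k_treatments`.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 3, 3, byrow = TRUE)
#' friedman_test(m)$statistic # 6
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells are not allowed", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 blocks and 2 treatments", call. = FALSE)
  ht <- stats::friedman.test(values)
  stat <- unname(ht$statistic)
  p <- unname(ht$p.value)
  if (!is.finite(stat)) { # all blocks fully tied: tie-correction denominator 0
    stat <- 0
    p <- 1
  }
  structure(list(statistic = stat, df = ncol(values) - 1L, p_value = p,
                 n_blocks = nrow(values), k_treatments = ncol(values)),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf(
    "<friedman_result> chi-squared = %.4g, df = %d, p = %.3g (n = %d blocks x %d)\n",
    x$statistic, x$df, x$p_value, x$n_blocks, x$k_treatments))
  invisible(x)
}
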
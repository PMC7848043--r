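#' Gas trace container
#'
#' A `gas_trace` is a data frame with one row per monitor sample: `time_min`
#' (uniform, strictly increasing grid), `phase` (the protocol phase active at
#' that time) and the five gas fractions `o2`, `n2o`, `sevo`, `co2`, `n2`
#' (dimensionless, each row summing to 1 within 1e-9). The sampling interval
#' is stored in the `"sample_interval"` attribute.
#'
#' @param time_min Sample times, min.
#' @param phase Character vector of phase names.
#' @param comp Numeric matrix, one row per sample, columns `o2`, `n2o`,
#'   `sevo`, `co2`, `n2`.
#' @param sample_interval Sampling interval, min.
#' @return A `gas_trace` (classed data.frame).
#' @export
gas_trace <- function(time_min, phase, comp, sample_interval) {
  comp <- as.matrix(comp)
  stopifnot(length(time_min) == length(phase),
            nrow(comp) == length(time_min),
            ncol(comp) == 5L)
  colnames(comp) <- GASES
  if (length(time_min) > 1L) {
    dts <- diff(time_min)
    if (any(dts <= 0)) stop("trace times must be strictly increasing", call. = FALSE)
    if (max(dts) - min(dts) > 1e-8)
      stop("trace times must form a uniform grid", call. = FALSE)
  }
  if (any(comp < 0) || any(abs(rowSums(comp) - 1) > 1e-9))
    stop("every trace sample must be a valid gas composition", call. = FALSE)
  out <- data.frame(time_min = time_min, phase = phase, comp,
                    stringsAsFactors = FALSE)
  structure(out, sample_interval = sample_interval,
            class = c("gas_trace", "data.frame"))
}

#' @export
print.gas_trace <- function(x, ...) {
  cat(sprintf("<gas_trace> %d samples, %.3g-%.3g min (every %.3g s), phases: %s\n",
              nrow(x), min(x$time_min), max(x$time_min),
              60 * attr(x, "sample_interval"),
              paste(unique(x$phase), collapse = " > ")))
  print.data.frame(utils::head(as.data.frame(x), 4), digits = 4)
  if (nrow(x) > 4) cat("... ", nrow(x) - 4, " more rows\n", sep = "")
  invisible(x)
}

# Keep attributes/class through [ subsetting on rows.
#' @export
`[.gas_trace` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("time_min", GASES) %in% names(out))) {
    attr(out, "sample_interval") <- attr(x, "sample_interval")
    class(out) <- c("gas_trace", "data.frame")
  }
  out
}

#' Extract a time window from a trace
#'
#' @param trace A [gas_trace()].
#' @param t_start,t_end Window bounds, min (inclusive).
#' @return The sub-trace covering the window.
#' @export
trace_window <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "gas_trace"), t_end > t_start)
  keep <- trace$time_min >= t_start - 1e-9 & trace$time_min <= t_end + 1e-9
  if (!any(keep)) stop("trace does not cover the requested window", call. = FALSE)
  trace[keep, , drop = FALSE]
}

#' Run a protocol through the circuit model
#'
#' Integrates the well-mixed circuit balance (see [step_circuit()]) across all
#' phases of a protocol with a fixed explicit step `dt`, recording the
#' composition every `sample_interval` (default one sample per breath, 5 s at
#' 12 breaths/min). The run starts from room air; settings switch instantly
#' at phase boundaries; the reservoir-bag state follows each phase. During
#' the `room_air` phase the circuit is open to the atmosphere and the
#' composition is pinned to [room_air()]. The result is fully deterministic.
#'
#' @param protocol A [protocol()].
#' @param config A [circuit_config()]; its `bag_connected` field is
#'   overridden per phase.
#' @param patient A [patient_model()].
#' @param dt Integration step, min. Default 1/240 (0.25 s).
#' @param sample_interval Sampling interval, min; must be an integer multiple
#'   of `dt`. Default 1/12 (5 s).
#' @return A [gas_trace()] covering the whole protocol.
#' @examples
#' tr <- run_protocol(canonical_protocol("oxygen_air", 2))
#' range(tr$time_min) # 0 to 68 min
#' @export
run_protocol <- function(protocol, config = circuit_config(),
                         patient = patient_model(),
                         dt = 1/240, sample_interval = 1/12) {
  stopifnot(inherits(protocol, "protocol"), inherits(config, "circuit_config"))
  if (sample_interval < dt)
    stop("sample_interval must be at least dt", call. = FALSE)
  k <- sample_interval / dt
  if (abs(k - round(k)) > 1e-8)
    stop("sample_interval must be an integer multiple of dt", call. = FALSE)
  k <- as.integer(round(k))

  f <- unclass(room_air())
  times <- 0
  phases <- protocol$phases[[1]]$name
  comps <- list(f)
  t_now <- 0
  for (ph in protocol$phases) {
    n_samp <- round(ph$duration / sample_interval)
    if (abs(n_samp * sample_interval - ph$duration) > 1e-8)
      stop("phase duration must be a multiple of sample_interval", call. = FALSE)
    if (ph$ambient) {
      f <- unclass(room_air())
      for (s in seq_len(n_samp)) {
        t_now <- t_now + sample_interval
        times <- c(times, t_now); phases <- c(phases, ph$name)
        comps[[length(comps) + 1L]] <- f
      }
      next
    }
    cfg <- config
    cfg$bag_connected <- ph$bag_connected
    co <- balance_coefficients(cfg, ph$fg, patient)
    a <- (co$inflow - co$uptake) / co$v
    b <- co$q_out / co$v
    for (s in seq_len(n_samp)) {
      for (i in seq_len(k)) {
        f <- f + dt * (a - b * f)
        if (any(f < -1e-12))
          stop("step drove a gas fraction negative; refine dt", call. = FALSE)
        f[f < 0] <- 0
        f <- f / sum(f)
      }
      t_now <- t_now + sample_interval
      times <- c(times, t_now); phases <- c(phases, ph$name)
      comps[[length(comps) + 1L]] <- f
    }
  }
  # label boundary samples with the phase that starts there
  starts <- cumsum(c(0, vapply(protocol$phases, `[[`, numeric(1), "duration")))
  idx <- pmin(findInterval(times + 1e-9, starts[-length(starts)]),
              length(protocol$phases))
  phases <- vapply(protocol$phases[idx], `[[`, character(1), "name")
  gas_trace(times, phases, do.call(rbind, comps), sample_interval)
}

#' Analysis windows around the disconnection event
#'
#' Returns the start times of the three 10-min comparison windows: `before`
#' (the last 10 min of maintenance, ending at disconnection), `during` (the
#' 10 min with the bag off) and `after` (the first 10 min after
#' reconnection, even though the reconnected phase lasts longer).
#'
#' @param trace A [gas_trace()] with `disconnected` and `reconnected` phases.
#' @param width Window width, min. Default 10.
#' @return Named list of `c(t_start, t_end)` pairs.
#' @export
disconnection_windows <- function(trace, width = 10) {
  stopifnot(inherits(trace, "gas_trace"))
  t_disc <- suppressWarnings(min(trace$time_min[trace$phase == "disconnected"]))
  t_rec <- suppressWarnings(min(trace$time_min[trace$phase == "reconnected"]))
  if (!is.finite(t_disc) || !is.finite(t_rec))
    stop("trace has no disconnection/reconnection phases", call. = FALSE)
  list(before = c(t_disc - width, t_disc),
       during = c(t_disc, t_disc + width),
       after = c(t_rec, t_rec + width))
}
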
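#' Gas-monitor emulation model
#'
#' Describes how a workstation gas monitor turns the true circuit composition
#' into displayed readings: additive Gaussian measurement noise (in percent,
#' applied before quantization) and per-gas display resolution — whole
#' percent for O2 and N2O, 0.1 vol% for sevoflurane, matching the reporting
#' precision of clinical gas monitors. The default noise SD of 0.5% absolute
#' is a modelling choice (monitors do not publish an error model) picked so
#' replicate spread resembles bench interquartile ranges; it is documented in
#' the vignette and freely overridable.
#'
#' @param noise_sd Additive Gaussian noise SD per reading, percent.
#'   Default 0.5.
#' @param quant_o2,quant_n2o Display step for O2 and N2O, percent. Default 1.
#' @param quant_sevo Display step for sevoflurane, vol%. Default 0.1.
#' @param quant_co2 Display step for CO2, percent. Default 1.
#' @param sample_interval Monitor sampling interval, min. Default 1/12 (5 s,
#'   one reading per breath at 12 breaths/min).
#' @param seed Integer seed driving the noise stream.
#' @return A `monitor_model` object.
#' @export
monitor_model <- function(noise_sd = 0.5, quant_o2 = 1, quant_n2o = 1,
                          quant_sevo = 0.1, quant_co2 = 1,
                          sample_interval = 1/12, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (any(c(quant_o2, quant_n2o, quant_sevo, quant_co2) <= 0))
    stop("quantization steps must be positive", call. = FALSE)
  structure(list(noise_sd = noise_sd, quant_o2 = quant_o2,
                 quant_n2o = quant_n2o, quant_sevo = quant_sevo,
                 quant_co2 = quant_co2, sample_interval = sample_interval,
                 seed = as.integer(seed)),
            class = "monitor_model")
}

# evaluate expr with a private RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old))
    rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Pass a trace through the monitor model
#'
#' Adds Gaussian measurement noise (percent scale) to each O2/N2O/sevoflurane/
#' CO2 reading, rounds to the gas's display step, and clamps to \[0, 100\]%.
#' Nitrogen is not read by a gas monitor and is recomputed as the balance so
#' the trace invariant (fractions sum to 1) is preserved. Deterministic for
#' a given `monitor$seed`.
#'
#' @param trace A [gas_trace()].
#' @param monitor A [monitor_model()].
#' @return A quantized [gas_trace()].
#' @examples
#' tr <- run_protocol(canonical_protocol("oxygen_air", 2))
#' q <- quantize_trace(tr, monitor_model(noise_sd = 0))
#' all(q$o2 * 100 == round(q$o2 * 100)) # integer-percent O2
#' @export
quantize_trace <- function(trace, monitor) {
  stopifnot(inherits(trace, "gas_trace"), inherits(monitor, "monitor_model"))
  steps <- c(o2 = monitor$quant_o2, n2o = monitor$quant_n2o,
             sevo = monitor$quant_sevo, co2 = monitor$quant_co2)
  n <- nrow(trace)
  read <- with_seed(monitor$seed, {
    out <- sapply(names(steps), function(g) {
      pct <- 100 * trace[[g]]
      if (monitor$noise_sd > 0)
        pct <- pct + stats::rnorm(n, 0, monitor$noise_sd)
      pmin(100, pmax(0, steps[[g]] * round(pct / steps[[g]])))
    })
    matrix(out, nrow = n, dimnames = list(NULL, names(steps)))
  })
  frac <- read / 100
  n2 <- pmax(0, 1 - rowSums(frac))
  comp <- cbind(frac[, c("o2", "n2o", "sevo", "co2")], n2 = n2)
  # guard against noise pushing a row's total above 100%
  comp <- comp / rowSums(comp)
  gas_trace(trace$time_min, trace$phase, comp, attr(trace, "sample_interval"))
}

#' Generate replicate monitor traces for a protocol
#'
#' Runs the deterministic circuit simulation once and passes it through the
#' monitor model `n_reps` times with independent noise streams derived from
#' the master seed by fixed offsets (`seed + (rep - 1) * 10007`). This
#' mirrors a bench design of repeated runs on the same hardware: the
#' underlying trajectory is shared, the measurement noise is not.
#'
#' @inheritParams run_protocol
#' @param monitor A [monitor_model()]; its `sample_interval` is used for the
#'   simulation sampling grid.
#' @param n_reps Number of replicate traces. Default 3.
#' @param dt Integration step, min.
#' @return List of `n_reps` quantized [gas_trace()] objects.
#' @export
generate_replicates <- function(protocol, config = circuit_config(),
                                patient = patient_model(),
                                monitor = monitor_model(), n_reps = 3,
                                dt = 1/240) {
  stopifnot(n_reps >= 1)
  base <- run_protocol(protocol, config, patient, dt = dt,
                       sample_interval = monitor$sample_interval)
  lapply(seq_len(n_reps), function(r) {
    m <- monitor
    m$seed <- monitor$seed + (r - 1L) * 10007L
    quantize_trace(base, m)
  })
}

#' Synthetic exponential transition trace
#'
#' Builds a single-gas exponential test trace directly from the closed-form
#' wash-in/wash-out expression ([wash_in_fraction()]) at a known time
#' constant, for estimator-recovery checks: the named gas follows
#' `f0 -> f_inf` with time constant `tau`; nitrogen takes the balance. The
#' whole trace is labelled `disconnected` so the `"during"` window spans it.
#'
#' @param f0,f_inf Start and asymptotic fractions of `gas`, in \[0, 1\].
#' @param tau True time constant, min.
#' @param gas Which monitor gas carries the transition. Default `"o2"`.
#' @param duration Trace length, min. Default 10.
#' @param sample_interval Sampling interval, min. Default 1/12.
#' @return A [gas_trace()].
#' @export
synthetic_exponential_trace <- function(f0, f_inf, tau, gas = "o2",
                                        duration = 10,
                                        sample_interval = 1/12) {
  gas <- match.arg(gas, MONITOR_GASES)
  tt <- seq(0, duration, by = sample_interval)
  f <- wash_in_fraction(f0, f_inf, tt, tau)
  comp <- matrix(0, length(tt), 5, dimnames = list(NULL, GASES))
  comp[, gas] <- f
  comp[, "n2"] <- 1 - f
  gas_trace(tt, rep("disconnected", length(tt)), comp, sample_interval)
}
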
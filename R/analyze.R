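#' Before/during/after analysis of replicate traces
#'
#' Pools the per-minute monitor readings of the replicates over the three
#' 10-min comparison windows (with 3 replicates and 10 readings per window
#' this is n = 30 values per window), summarises each window
#' (median, type-7 quartiles, range, in percent), and runs the Friedman rank
#' test across the windows with one block per replicate-by-minute reading.
#'
#' @param reps List of [gas_trace()] replicates covering the disconnection
#'   protocol.
#' @param gases Monitor gases to analyse. Default `c("o2", "sevo")`; include
#'   `"n2o"` for a nitrous-oxide carrier.
#' @return List with elements `summary` (data.frame: gas, window, n, median,
#'   q25, q75, min, max) and `friedman` (data.frame: gas, statistic, df,
#'   p_value, n_blocks).
#' @export
analyze_replicates <- function(reps, gases = c("o2", "sevo")) {
  stopifnot(length(reps) >= 1L,
            all(vapply(reps, inherits, logical(1), "gas_trace")))
  windows <- c("before", "during", "after")
  summaries <- list()
  fried <- list()
  for (g in gases) {
    per_win <- lapply(windows, function(w)
      unlist(lapply(reps, minute_readings, gas = g, window = w)))
    names(per_win) <- windows
    for (w in windows)
      summaries[[paste(g, w)]] <-
        cbind(data.frame(gas = g, window = w, stringsAsFactors = FALSE),
              pooled_summary(per_win[[w]]))
    ft <- friedman_test(do.call(cbind, per_win))
    fried[[g]] <- data.frame(gas = g, statistic = ft$statistic, df = ft$df,
                             p_value = ft$p_value, n_blocks = ft$n_blocks,
                             stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
       friedman = do.call(rbind, c(fried, make.row.names = FALSE)))
}

#' Replicate-median time constants during disconnection
#'
#' Applies the 63% criterion ([estimate_tau_63()]) to the disconnection
#' window of each replicate and reports the median and quartiles across
#' replicates, per gas.
#'
#' @inheritParams analyze_replicates
#' @return data.frame: gas, tau_median, tau_q25, tau_q75, n_reps (min).
#' @export
tau_table <- function(reps, gases = c("o2", "sevo")) {
  rows <- lapply(gases, function(g) {
    taus <- vapply(reps, function(tr) estimate_tau_63(tr, g, "during")$tau,
                   numeric(1))
    q <- stats::quantile(taus, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(gas = g, tau_median = q[2], tau_q25 = q[1], tau_q75 = q[3],
               n_reps = length(taus), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full study grid and tabulate the results
#'
#' Simulates the canonical six-phase protocol for both carrier gases
#' (oxygen/air and oxygen/nitrous oxide) at maintenance FGF 0.5, 1 and 2
#' L/min, with `n_reps` monitor replicates each, and assembles the three
#' result tables: inspired-fraction summaries before/during/after
#' disconnection with Friedman p-values for each carrier, and the
#' 63%-criterion time constants of the disconnection transition.
#'
#' @param seed Master seed for the monitor noise streams.
#' @param fgf_levels Maintenance FGF grid, L/min. Default `c(0.5, 1, 2)`.
#' @param n_reps Replicates per condition. Default 3.
#' @param config A [circuit_config()].
#' @param patient A [patient_model()].
#' @param monitor_noise_sd Monitor noise SD, percent. Default 0.5.
#' @param dt Integration step, min.
#' @return List of class `disconnection_tables` with data.frames `inspired`
#'   (carrier, fgf, gas, window, n, median, q25, q75, min, max, p_value) and
#'   `tau` (carrier, fgf, gas, tau_median, tau_q25, tau_q75).
#' @export
reproduce_tables <- function(seed = 1, fgf_levels = c(0.5, 1, 2), n_reps = 3,
                             config = circuit_config(),
                             patient = patient_model(),
                             monitor_noise_sd = 0.5, dt = 1/240) {
  inspired <- list()
  taus <- list()
  cond <- 0L
  for (carrier in c("oxygen_air", "oxygen_n2o")) {
    gases <- if (carrier == "oxygen_air") c("o2", "sevo") else
      c("o2", "sevo", "n2o")
    for (fgf in fgf_levels) {
      cond <- cond + 1L
      mon <- monitor_model(noise_sd = monitor_noise_sd,
                           seed = seed + cond * 1000003L)
      reps <- generate_replicates(canonical_protocol(carrier, fgf),
                                  config, patient, mon, n_reps, dt = dt)
      an <- analyze_replicates(reps, gases)
      s <- merge(an$summary, an$friedman[, c("gas", "p_value")], by = "gas")
      inspired[[cond]] <- cbind(data.frame(carrier = carrier, fgf = fgf,
                                           stringsAsFactors = FALSE), s)
      taus[[cond]] <- cbind(data.frame(carrier = carrier, fgf = fgf,
                                       stringsAsFactors = FALSE),
                            tau_table(reps, gases))
    }
  }
  structure(list(inspired = do.call(rbind, c(inspired, make.row.names = FALSE)),
                 tau = do.call(rbind, c(taus, make.row.names = FALSE))),
            class = "disconnection_tables")
}

#' @export
print.disconnection_tables <- function(x, ...) {
  cat("Inspired-fraction summaries (%, per carrier/FGF/window):\n")
  print(x$inspired, digits = 4)
  cat("\nTime constants during disconnection (min):\n")
  print(x$tau, digits = 3)
  invisible(x)
}
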
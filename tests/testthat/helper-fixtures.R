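# Shared fixtures and independent oracles for the test suite.

# Exhaustive within-block permutation null for the Friedman statistic
# (k = 3 columns): enumerates all 6^n assignments of the within-row rank
# orderings and returns P(Q_perm >= Q_obs). Independent of friedman_test()
# except for the observed statistic's definition, which is recomputed here
# from first principles (tie-corrected rank formula).
perm_null_p <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  stopifnot(k == 3L)
  tie_corrected_q <- function(R) {
    ties <- tapply(c(R), row(R), table)
    12 * sum((colSums(R) - n * (k + 1) / 2)^2) /
      (n * k * (k + 1) - sum(unlist(lapply(ties, function(u) u^3 - u))) / (k - 1))
  }
  ranks <- t(apply(m, 1, rank))
  obs <- tie_corrected_q(ranks)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  sel <- as.matrix(expand.grid(rep(list(1:6), n)))
  stats <- apply(sel, 1, function(s) {
    R <- do.call(rbind, lapply(seq_len(n), function(r) ranks[r, perms[s[r], ]]))
    tie_corrected_q(R)
  })
  list(q = obs, p_exact = mean(stats >= obs - 1e-12))
}

# single constant-settings phase protocol, for closed-form comparisons
one_phase_protocol <- function(fgf, delivered, duration = 10,
                               name = "maintenance") {
  protocol(list(protocol_phase(name, duration,
                               fresh_gas_settings(fgf, delivered))),
           carrier = "oxygen_air", fgf_maintenance = fgf)
}

# small trace with prescribed per-minute O2 readings (percent), labelled so
# numeric windows can address it directly
trace_from_o2_pct <- function(o2_pct, sample_interval = 1) {
  n <- length(o2_pct)
  comp <- cbind(o2 = o2_pct / 100, n2o = 0, sevo = 0, co2 = 0,
                n2 = 1 - o2_pct / 100)
  gas_trace(seq(0, by = sample_interval, length.out = n),
            rep("maintenance", n), comp, sample_interval)
}
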
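#' Exponential wash-in/wash-out of a well-mixed circuit
#'
#' Closed-form time course of a gas fraction in an ideally mixed compartment
#' flushed at constant settings:
#' `F(t) = f0 + (f_del - f0) * (1 - exp(-t/tau))`.
#' At `t = tau` the fraction has covered 63.2% of its total change — the
#' classic 63% criterion. The same expression describes wash-out when
#' `f_del < f0`.
#'
#' @param f0 Starting fraction, in \[0, 1\].
#' @param f_del Delivered (asymptotic) fraction, in \[0, 1\].
#' @param t Time since the settings change, min (vectorized).
#' @param tau Time constant, min (> 0).
#' @return Fraction at time `t`, always between `f0` and `f_del`.
#' @seealso [tau_simple()], [tau_conway()]
#' @examples
#' wash_in_fraction(0, 0.68, t = 5.6, tau = 5.6) / 0.68 # 0.632
#' @export
wash_in_fraction <- function(f0, f_del, t, tau) {
  if (!is.numeric(tau) || any(tau <= 0))
    stop("tau must be positive", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (any(c(f0, f_del) < 0) || any(c(f0, f_del) > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  f0 + (f_del - f0) * (1 - exp(-t / tau))
}

#' Theoretical circuit time constant, tau = V_tot / FGF
#'
#' For an ideally mixed circle system with no uptake, the wash-in/wash-out
#' time constant is the total gas volume divided by the fresh gas flow. With
#' V_tot = 5.6 L this gives 11.2, 5.6 and 2.8 min at FGF 0.5, 1 and 2 L/min.
#'
#' @param v_tot Total circuit gas volume, L (> 0).
#' @param fgf Fresh gas flow, L/min (> 0, vectorized).
#' @return Time constant(s), min.
#' @export
tau_simple <- function(v_tot, fgf) {
  if (any(v_tot <= 0)) stop("v_tot must be positive", call. = FALSE)
  if (any(fgf <= 0)) stop("fgf must be positive", call. = FALSE)
  v_tot / fgf
}

#' Uptake-corrected time constant (Conway form)
#'
#' `tau = V_S / (Vdot_D - Vdot_uptake)`: the time constant of a breathing
#' system of volume `V_S` (circuit plus lungs) flushed at delivery rate
#' `Vdot_D` while gas is removed from the system by constant uptake
#' `Vdot_uptake`. Reduces to [tau_simple()] when uptake is zero. A delivery
#' rate at or below the uptake rate has no physical steady state and is an
#' error.
#'
#' @param v_s System volume, L (> 0).
#' @param vd_dot Delivery (fresh gas) rate, L/min.
#' @param vuptake_dot Constant uptake rate, L/min (>= 0).
#' @return Time constant, min.
#' @export
tau_conway <- function(v_s, vd_dot, vuptake_dot = 0) {
  if (any(v_s <= 0)) stop("v_s must be positive", call. = FALSE)
  if (any(vuptake_dot < 0)) stop("vuptake_dot must be non-negative", call. = FALSE)
  if (any(vd_dot <= vuptake_dot))
    stop("vd_dot must exceed vuptake_dot: no steady state otherwise",
         call. = FALSE)
  v_s / (vd_dot - vuptake_dot)
}

#' Circuit state at a time point
#'
#' @param t Time, min.
#' @param comp A [gas_composition()].
#' @return A `circuit_state` object.
#' @export
circuit_state <- function(t = 0, comp = room_air()) {
  validate_gas_composition(comp)
  structure(list(t = t, comp = comp), class = "circuit_state")
}

# Per-gas volumetric balance coefficients for constant settings.
# Returns list(inflow = L/min per gas, q_out = venting flow L/min, v = L).
balance_coefficients <- function(config, fg, patient) {
  eff_fgf <- fg$fgf * if (config$bag_connected) 1 else config$fgf_retained_fraction
  entrain <- if (config$bag_connected) 0 else config$entrain_flow
  inflow <- eff_fgf * unclass(fg$delivered) + entrain * unclass(room_air())
  # CO2 is produced by the patient and removed by an ideal absorber within the
  # same step, so it contributes neither inflow nor venting volume.
  uptake <- c(o2 = patient$vo2, n2o = patient$n2o_uptake,
              sevo = patient$sevo_uptake, co2 = 0, n2 = 0)
  q_out <- sum(inflow) - sum(uptake)
  if (q_out < 0)
    stop("gas uptake exceeds total inflow: the circuit volume cannot be ",
         "maintained at these settings", call. = FALSE)
  list(inflow = inflow, uptake = uptake, q_out = q_out,
       v = total_volume(config) + patient$frc)
}

#' Advance the circuit state by one explicit time step
#'
#' One forward-Euler step of the well-mixed per-gas volume balance. Inflow is
#' the effective fresh gas (scaled by `fgf_retained_fraction` when the bag is
#' disconnected) at the delivered composition, plus room-air entrainment
#' through the open bag port when disconnected. Gas leaves by constant-rate
#' patient uptake (O2, agents), by ideal CO2 absorption (all CO2 produced is
#' removed within the step, so inspired CO2 stays 0), and by venting of excess
#' gas at the circuit composition at exactly the rate that keeps the circuit
#' volume constant. The updated composition is renormalized to sum to 1
#' within 1e-9.
#'
#' `dt` must be small relative to the fastest time constant; a step that
#' would drive any fraction negative raises an error asking for a smaller
#' step.
#'
#' @param state A [circuit_state()].
#' @param dt Step size, min (> 0). Default 1/240 (0.25 s).
#' @param config A [circuit_config()].
#' @param fg A [fresh_gas_settings()].
#' @param patient A [patient_model()].
#' @return The advanced `circuit_state`.
#' @export
step_circuit <- function(state, dt = 1/240, config, fg, patient = no_patient()) {
  stopifnot(inherits(state, "circuit_state"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  co <- balance_coefficients(config, fg, patient)
  f <- unclass(state$comp)
  f_new <- f + (dt / co$v) * (co$inflow - co$uptake - co$q_out * f)
  if (any(f_new < -1e-12))
    stop("step drove a gas fraction negative; refine the step size dt",
         call. = FALSE)
  f_new[f_new < 0] <- 0
  f_new <- f_new / sum(f_new)
  circuit_state(t = state$t + dt,
                comp = structure(f_new, class = "gas_composition"))
}
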
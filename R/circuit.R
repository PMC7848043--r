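#' Circle-system circuit configuration
#'
#' Describes the gas-holding geometry of a fresh-gas-decoupled circle system
#' and its leak behaviour when the reservoir bag is removed. The total gas
#' volume is derived as
#' `v_internal - v_absorber_default + v_absorber_used + v_hose`: the
#' workstation's internal volume is quoted with its default refillable CO2
#' absorber installed, so swapping in a different absorber replaces that
#' volume, and the breathing hoses add theirs.
#'
#' The leak model is lumped: when `bag_connected` is `FALSE`, fresh gas keeps
#' reaching the circuit at the fraction `fgf_retained_fraction` of the set FGF,
#' and room air is entrained continuously at `entrain_flow` L/min through the
#' open bag port. The default `entrain_flow = 1.7` L/min is a calibration
#' against bench time-constant measurements of this scenario (see the package
#' vignette); both parameters are user-overridable.
#'
#' @param v_internal Workstation internal gas volume including its default
#'   absorber, L. Default 4.7.
#' @param v_absorber_default Volume of the default absorber included in
#'   `v_internal`, L. Default 1.5.
#' @param v_absorber_used Volume of the absorber actually fitted, L.
#'   Default 1.2 (compact click-on absorber).
#' @param v_hose Breathing-circle (hose) volume, L. Default 1.2.
#' @param bag_connected Is the reservoir bag connected? Default `TRUE`.
#' @param entrain_flow Room-air inflow through the open bag port when the bag
#'   is disconnected, L/min. Default 1.7.
#' @param fgf_retained_fraction Fraction of the set fresh gas flow still
#'   reaching the circuit when the bag is disconnected, in \[0, 1\].
#'   Default 1.
#' @return A `circuit_config` object (list).
#' @seealso [total_volume()]
#' @examples
#' cfg <- circuit_config()
#' total_volume(cfg) # 5.6 L
#' @export
circuit_config <- function(v_internal = 4.7,
                           v_absorber_default = 1.5,
                           v_absorber_used = 1.2,
                           v_hose = 1.2,
                           bag_connected = TRUE,
                           entrain_flow = 1.7,
                           fgf_retained_fraction = 1.0) {
  stopifnot(is.numeric(v_internal), is.numeric(v_absorber_default),
            is.numeric(v_absorber_used), is.numeric(v_hose),
            is.logical(bag_connected), length(bag_connected) == 1L)
  if (v_internal <= 0 || v_absorber_default <= 0 || v_absorber_used <= 0)
    stop("component volumes must be positive", call. = FALSE)
  if (v_hose < 0) stop("hose volume must be non-negative", call. = FALSE)
  if (entrain_flow < 0) stop("entrain_flow must be non-negative", call. = FALSE)
  if (fgf_retained_fraction < 0 || fgf_retained_fraction > 1)
    stop("fgf_retained_fraction must lie in [0, 1]", call. = FALSE)
  cfg <- structure(list(
    v_internal = v_internal,
    v_absorber_default = v_absorber_default,
    v_absorber_used = v_absorber_used,
    v_hose = v_hose,
    bag_connected = bag_connected,
    entrain_flow = entrain_flow,
    fgf_retained_fraction = fgf_retained_fraction
  ), class = "circuit_config")
  total_volume(cfg) # validates positivity of the derived volume
  cfg
}

#' Total gas volume of the circuit
#'
#' `V_tot = v_internal - v_absorber_default + v_absorber_used + v_hose`.
#' With the defaults (4.7 - 1.5 + 1.2 + 1.2) this is 5.6 L.
#'
#' @param config A [circuit_config()].
#' @return Total gas volume in L.
#' @export
total_volume <- function(config) {
  stopifnot(inherits(config, "circuit_config"))
  v <- with(config, v_internal - v_absorber_default + v_absorber_used + v_hose)
  if (v <= 0)
    stop("invalid configuration: derived total gas volume is not positive",
         call. = FALSE)
  v
}

#' @export
print.circuit_config <- function(x, ...) {
  cat("<circuit_config>  V_tot =", format(total_volume(x)), "L;",
      if (x$bag_connected) "bag connected" else
        sprintf("bag DISCONNECTED (entrain %.2g L/min, FGF retained %.0f%%)",
                x$entrain_flow, 100 * x$fgf_retained_fraction), "\n")
  invisible(x)
}

#' Fresh-gas settings
#'
#' The fresh gas flow and delivered composition set on the machine. Machine
#' settings are usually quoted in percent O2 and vol% agent; use
#' [delivered_mix()] to build the composition from those.
#'
#' @param fgf Fresh gas flow, L/min (must be >= 0).
#' @param delivered A [gas_composition()] of the delivered mixture.
#' @return A `fresh_gas_settings` object.
#' @examples
#' fresh_gas_settings(0.5, delivered_mix(o2_pct = 68, sevo_volpct = 5))
#' @export
fresh_gas_settings <- function(fgf, delivered) {
  stopifnot(is.numeric(fgf), length(fgf) == 1L)
  if (fgf < 0) stop("fgf must be non-negative", call. = FALSE)
  validate_gas_composition(delivered)
  structure(list(fgf = fgf, delivered = delivered),
            class = "fresh_gas_settings")
}

#' Delivered mixture from machine dial settings
#'
#' Converts vaporizer/flowmeter settings (percent oxygen, vol% sevoflurane,
#' balance gas) to a [gas_composition()]. Percentages are divided by 100; the
#' balance gas (`"n2"` for an oxygen/air carrier, `"n2o"` for oxygen/nitrous
#' oxide) absorbs the rounding residue so fractions sum to exactly 1.
#'
#' @param o2_pct Delivered oxygen, percent.
#' @param sevo_volpct Vaporizer sevoflurane, vol%.
#' @param balance `"n2"` or `"n2o"`.
#' @return A [gas_composition()].
#' @export
delivered_mix <- function(o2_pct, sevo_volpct = 0, balance = c("n2", "n2o")) {
  balance <- match.arg(balance)
  o2 <- o2_pct / 100
  sevo <- sevo_volpct / 100
  rest <- 1 - o2 - sevo
  if (rest < -1e-9) stop("settings exceed 100%", call. = FALSE)
  rest <- max(rest, 0)
  if (balance == "n2") gas_composition(o2 = o2, sevo = sevo, n2 = rest)
  else gas_composition(o2 = o2, sevo = sevo, n2o = rest, n2 = 0)
}

#' Oxygen delivery rate of a fresh-gas setting
#'
#' The volumetric oxygen inflow, `fgf * fO2_delivered`, reported in mL/min.
#' At minimal flow this bookkeeping is what decides whether delivery covers
#' patient consumption: 68% of 0.5 L/min is 340 mL O2/min, 60% of 0.5 L/min
#' is 300 mL O2/min.
#'
#' @param fg A [fresh_gas_settings()].
#' @return Oxygen delivery in mL/min.
#' @export
o2_delivery <- function(fg) {
  stopifnot(inherits(fg, "fresh_gas_settings"))
  1000 * fg$fgf * fg$delivered[["o2"]]
}

#' Patient gas-exchange model
#'
#' Constant-rate gas exchange of the (simulated) patient, lumped with the
#' circuit: oxygen consumption, CO2 production, and optional constant uptake
#' of the anesthetic agents. Rates are given in mL/min (as on a simulator
#' control panel) and stored in L/min. The patient's functional residual
#' capacity can be added to the mixing volume via `frc`, but defaults to 0 so
#' the mixing volume is the circuit's V_tot alone.
#'
#' @param vo2 Oxygen consumption, mL/min. Default 250 (a 70-kg adult as set on
#'   the patient simulator; bench oxygen bookkeeping suggests the effective
#'   value can run 300-340 mL/min, see the vignette).
#' @param vco2 CO2 production, mL/min. Default 200 (respiratory quotient 0.8).
#' @param sevo_uptake,n2o_uptake Constant agent uptake, mL vapor/min.
#'   Default 0.
#' @param frc Patient gas volume lumped with the circuit, L. Default 0.
#' @return A `patient_model` object with rates in L/min.
#' @export
patient_model <- function(vo2 = 250, vco2 = 200,
                          sevo_uptake = 0, n2o_uptake = 0, frc = 0) {
  rates <- c(vo2 = vo2, vco2 = vco2,
             sevo_uptake = sevo_uptake, n2o_uptake = n2o_uptake)
  if (any(rates < 0) || frc < 0)
    stop("patient rates and frc must be non-negative", call. = FALSE)
  structure(list(vo2 = vo2 / 1000, vco2 = vco2 / 1000,
                 sevo_uptake = sevo_uptake / 1000,
                 n2o_uptake = n2o_uptake / 1000, frc = frc),
            class = "patient_model")
}

# Zero-exchange patient, handy for closed-form comparisons.
#' @rdname patient_model
#' @export
no_patient <- function() patient_model(0, 0, 0, 0, 0)
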
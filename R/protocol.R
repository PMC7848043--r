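PHASE_NAMES <- c("room_air", "preoxygenation", "initial", "maintenance",
                 "disconnected", "reconnected")

#' A protocol phase
#'
#' One constant-settings segment of a simulation protocol. The `room_air`
#' phase is special: the circuit is open to the atmosphere (patient breathing
#' room air before connection), so the composition is held at [room_air()]
#' rather than integrated.
#'
#' @param name One of `"room_air"`, `"preoxygenation"`, `"initial"`,
#'   `"maintenance"`, `"disconnected"`, `"reconnected"`.
#' @param duration Phase duration, min (> 0).
#' @param fg A [fresh_gas_settings()] in force during the phase.
#' @param bag_connected Is the reservoir bag connected during this phase?
#' @return A `protocol_phase` object.
#' @export
protocol_phase <- function(name, duration, fg,
                           bag_connected = !identical(name, "disconnected")) {
  name <- match.arg(name, PHASE_NAMES)
  if (duration <= 0) stop("phase duration must be positive", call. = FALSE)
  stopifnot(inherits(fg, "fresh_gas_settings"))
  structure(list(name = name, duration = duration, fg = fg,
                 bag_connected = isTRUE(bag_connected),
                 ambient = identical(name, "room_air")),
            class = "protocol_phase")
}

#' A multi-phase simulation protocol
#'
#' @param phases List of [protocol_phase()] objects, in order. Exactly the
#'   `disconnected` phase (if present) may have `bag_connected = FALSE`.
#' @param carrier `"oxygen_air"` or `"oxygen_n2o"` (metadata).
#' @param fgf_maintenance Maintenance-phase fresh gas flow, L/min (metadata).
#' @return A `protocol` object.
#' @export
protocol <- function(phases, carrier = NA_character_, fgf_maintenance = NA_real_) {
  stopifnot(length(phases) >= 1L,
            all(vapply(phases, inherits, logical(1), "protocol_phase")))
  disc <- vapply(phases, function(p) !p$bag_connected, logical(1))
  wrong <- vapply(phases, function(p)
    !p$bag_connected && p$name != "disconnected", logical(1))
  if (any(wrong))
    stop("only the 'disconnected' phase may have bag_connected = FALSE",
         call. = FALSE)
  structure(list(phases = phases, carrier = carrier,
                 fgf_maintenance = fgf_maintenance),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol> carrier =", x$carrier,
      " maintenance FGF =", x$fgf_maintenance, "L/min\n")
  for (p in x$phases)
    cat(sprintf("  %-15s %5.1f min  FGF %.2g L/min  O2 %.0f%%  sevo %.2g vol%%%s\n",
                p$name, p$duration, p$fg$fgf, 100 * p$fg$delivered[["o2"]],
                100 * p$fg$delivered[["sevo"]],
                if (p$bag_connected) "" else "  [bag off]"))
  invisible(x)
}

#' The canonical six-phase disconnection protocol
#'
#' Builds the bench protocol used throughout the package: (1) room-air
#' breathing 5 min, (2) preoxygenation with 100% O2 at 6 L/min for 3 min,
#' (3) initial phase 10 min, (4) maintenance 20 min, (5) reservoir bag
#' disconnected 10 min, (6) bag reconnected 20 min; phases 4-6 share the
#' maintenance fresh-gas settings and only phase 5 has the bag off.
#'
#' Carrier-specific settings:
#' * `oxygen_air` — initial: 40% O2, 3.5 vol% sevoflurane at 4 L/min;
#'   maintenance: 68% O2, 5 vol% sevoflurane (balance N2).
#' * `oxygen_n2o` — initial: 32% O2, 2 vol% sevoflurane at 4.4 L/min;
#'   maintenance: 60% O2, 3.5 vol% sevoflurane (balance N2O).
#'
#' These delivered fractions follow minimal-flow inhalational-anesthesia
#' practice at FGF 0.5 L/min; the same settings are applied at 1 and 2 L/min
#' so the pre-disconnection inspired fractions spread out across FGF levels.
#'
#' @param carrier `"oxygen_air"` or `"oxygen_n2o"`.
#' @param fgf_maintenance Maintenance FGF, L/min; the canonical levels are
#'   0.5, 1 and 2 (other values are allowed with a warning).
#' @return A [protocol()] with total duration 68 min.
#' @examples
#' canonical_protocol("oxygen_air", 1.0)
#' @export
canonical_protocol <- function(carrier = c("oxygen_air", "oxygen_n2o"),
                               fgf_maintenance = 0.5) {
  carrier <- match.arg(carrier)
  if (!fgf_maintenance %in% c(0.5, 1.0, 2.0))
    warning("non-canonical maintenance FGF: ", fgf_maintenance, " L/min")
  if (carrier == "oxygen_air") {
    fg_init <- fresh_gas_settings(4.0, delivered_mix(40, 3.5, "n2"))
    fg_main <- fresh_gas_settings(fgf_maintenance, delivered_mix(68, 5, "n2"))
  } else {
    fg_init <- fresh_gas_settings(4.4, delivered_mix(32, 2, "n2o"))
    fg_main <- fresh_gas_settings(fgf_maintenance, delivered_mix(60, 3.5, "n2o"))
  }
  fg_air <- fresh_gas_settings(0, room_air())
  fg_preox <- fresh_gas_settings(6, gas_composition(o2 = 1))
  protocol(list(
    protocol_phase("room_air", 5, fg_air),
    protocol_phase("preoxygenation", 3, fg_preox),
    protocol_phase("initial", 10, fg_init),
    protocol_phase("maintenance", 20, fg_main),
    protocol_phase("disconnected", 10, fg_main, bag_connected = FALSE),
    protocol_phase("reconnected", 20, fg_main)
  ), carrier = carrier, fgf_maintenance = fgf_maintenance)
}
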
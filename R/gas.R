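# Gas species tracked by the circuit model, in fixed internal order.
GASES <- c("o2", "n2o", "sevo", "co2", "n2")

#' Gas composition of the circuit or of delivered fresh gas
#'
#' A `gas_composition` is a named numeric vector of dry-gas fractions for the
#' five species the model tracks: oxygen, nitrous oxide, sevoflurane, carbon
#' dioxide and nitrogen. Fractions are dimensionless, each in \[0, 1\], and
#' must sum to 1 within `1e-9`. When `n2` is omitted it is computed as the
#' balance, absorbing any rounding residue, which is the convenient way to
#' express fresh-gas mixtures set on a machine ("68% O2, 5 vol% sevoflurane,
#' balance air/N2").
#'
#' @param o2,n2o,sevo,co2 Gas fractions in \[0, 1\] (not percent).
#' @param n2 Nitrogen fraction; if `NULL` (default), set to the balance
#'   `1 - (o2 + n2o + sevo + co2)`.
#' @return A `gas_composition` object (named numeric vector of length 5).
#' @examples
#' room_air()
#' gas_composition(o2 = 0.68, sevo = 0.05) # balance N2
#' @export
gas_composition <- function(o2 = 0, n2o = 0, sevo = 0, co2 = 0, n2 = NULL) {
  if (is.null(n2)) {
    n2 <- 1 - (o2 + n2o + sevo + co2)
    if (n2 < 0 && n2 > -1e-9) n2 <- 0
  }
  comp <- c(o2 = o2, n2o = n2o, sevo = sevo, co2 = co2, n2 = n2)
  validate_gas_composition(comp)
  structure(comp, class = "gas_composition")
}

validate_gas_composition <- function(comp) {
  if (!is.numeric(comp) || length(comp) != 5L || anyNA(comp))
    stop("gas composition must be 5 finite fractions", call. = FALSE)
  if (any(comp < 0))
    stop("gas fractions must be non-negative", call. = FALSE)
  if (abs(sum(comp) - 1) > 1e-9)
    stop("gas fractions must sum to 1 within 1e-9 (got ",
         format(sum(comp), digits = 12), ")", call. = FALSE)
  invisible(comp)
}

#' Atmospheric (room) air composition
#'
#' Dry room air as the entrainment source: 21% oxygen, 79% nitrogen.
#'
#' @return A [gas_composition()].
#' @export
room_air <- function() gas_composition(o2 = 0.21, n2 = 0.79)

#' @export
print.gas_composition <- function(x, ...) {
  cat("<gas_composition>  ",
      paste(sprintf("%s=%.4g%%", names(x), 100 * unclass(x)), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}
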
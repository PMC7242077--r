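#' Osmotic potential of a PEG 6000 solution
#'
#' Michel & Kaufman's empirical polynomial for the osmotic potential of
#' polyethylene glycol 6000 solutions as a function of concentration C
#' (g PEG per kg water) and temperature T (degrees Celsius):
#'
#' `Psi(bar) = -1.18e-2 C - 1.18e-4 C^2 + 2.67e-4 C T + 8.39e-7 C^2 T`
#'
#' converted to megapascals (1 bar = 0.1 MPa). At 400 g/kg and 20 C the
#' potential is -1.88 MPa, the osmotic-shock dose used for leaf-disc
#' stress assays. The polynomial's validity envelope is roughly
#' C in [0, 800] g/kg and T in [5, 35] C; outside it a warning is
#' raised but the value is still computed.
#'
#' @param concentration C, g PEG 6000 per kg H2O (vectorized).
#' @param temperature T, degrees Celsius.
#' @param units `"MPa"` (default) or `"bar"`.
#' @return Osmotic potential (negative for C > 0).
#' @examples
#' pegOsmoticPotential(400, 20)   # -1.88 MPa
#' @export
pegOsmoticPotential <- function(concentration, temperature = 20,
                                units = c("MPa", "bar")) {
  units <- match.arg(units)
  C <- concentration; Tc <- temperature
  if (any(C < 0)) stop("PEG concentration must be >= 0", call. = FALSE)
  if (any(C > 800) || any(Tc < 5) || any(Tc > 35))
    warning("outside the validity envelope (C <= 800 g/kg, 5-35 C); value computed anyway",
            call. = FALSE)
  bar <- -1.18e-2 * C - 1.18e-4 * C^2 + 2.67e-4 * C * Tc +
    8.39e-7 * C^2 * Tc
  if (units == "bar") bar else bar / 10
}

#' PEG 6000 concentration for a target osmotic potential
#'
#' Inverts [pegOsmoticPotential()] by bracketed bisection
#' ([stats::uniroot()]) on C in [0, 800] g/kg to design an osmotic
#' shock of a given strength.
#'
#' @param targetMPa target osmotic potential in MPa; must be negative
#'   and achievable within the envelope.
#' @param temperature degrees Celsius.
#' @return Concentration in g PEG 6000 per kg H2O, to 1e-6 g/kg.
#' @examples
#' pegConcentrationForPotential(-1.88, 20)   # ~400 g/kg
#' @export
pegConcentrationForPotential <- function(targetMPa, temperature = 20) {
  if (!is.finite(targetMPa) || targetMPa >= 0)
    stop("target osmotic potential must be negative", call. = FALSE)
  psiMax <- pegOsmoticPotential(800, temperature)
  if (targetMPa < psiMax)
    stop(sprintf(
      "target %.3g MPa unachievable: the envelope reaches only [%.3g, 0] MPa at %g C",
      targetMPa, psiMax, temperature), call. = FALSE)
  f <- function(C) pegOsmoticPotential(C, temperature) - targetMPa
  stats::uniroot(f, c(0, 800), tol = 1e-6)$root
}
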
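# Forward FvCB C3 photosynthesis model with mesophyll-conductance coupling.
#
# Net assimilation is the minimum of three limitation-specific rates
# (Rubisco carboxylation, RuBP regeneration via electron transport, triose
# phosphate utilization), each evaluated at the chloroplastic CO2 partial
# pressure Cc = Ci - An/gm. The gm coupling turns each limitation into a
# quadratic in An, solved in closed form (lower root).

#' Photosynthetic capacity set
#'
#' The four capacity parameters of the FvCB model at one evaluation
#' temperature: maximum Rubisco carboxylation capacity `Vcmax`, electron
#' transport rate `J` at the measurement irradiance of 1500 umol photons
#' m^-2 s^-1, triose-phosphate utilization rate `TPU`, and
#' non-photorespiratory day respiration `Rd`.
#'
#' @param Vcmax Maximum Rubisco carboxylation capacity (umol m^-2 s^-1), > 0.
#' @param J Electron transport rate at 1500 umol photons m^-2 s^-1
#'   (umol electrons m^-2 s^-1), > 0.
#' @param TPU Triose-phosphate utilization rate (umol m^-2 s^-1), > 0.
#' @param Rd Day respiration (umol m^-2 s^-1), >= 0. Defaults to 0; when Rd
#'   is pinned to 0 in fitting, fitted Vcmax and J absorb it.
#' @return An object of class `photo_capacity`.
#' @export
photo_capacity <- function(Vcmax, J, TPU, Rd = 0) {
  if (any(!is.finite(c(Vcmax, J, TPU, Rd))))
    stop("invalid parameter: non-finite capacity")
  if (Vcmax <= 0 || J <= 0 || TPU <= 0)
    stop("invalid parameter: Vcmax, J, TPU must be > 0")
  if (Rd < 0) stop("invalid parameter: Rd must be >= 0")
  structure(list(Vcmax = Vcmax, J = J, TPU = TPU, Rd = Rd),
            class = "photo_capacity")
}

#' @export
print.photo_capacity <- function(x, ...) {
  cat(sprintf(
    "Photosynthetic capacity: Vcmax %.2f, J1500 %.2f, TPU %.2f, Rd %.2f umol m-2 s-1\n",
    x$Vcmax, x$J, x$TPU, x$Rd))
  invisible(x)
}

#' Limitation-specific assimilation rates at a known Cc
#'
#' Evaluates the three FvCB limitation rates at the chloroplastic CO2
#' partial pressure `Cc`:
#' `Ac = Vcmax (Cc - Gamma*) / (Cc + Kair) - Rd` (carboxylation),
#' `Aj = J (Cc - Gamma*) / (4 Cc + 8 Gamma*) - Rd` (RuBP regeneration),
#' `Ap = 3 TPU - Rd` (phosphate recycling). At `Cc = Gamma*` both Ac and Aj
#' equal `-Rd`.
#'
#' @param Cc Chloroplastic CO2 partial pressure (Pa), > 0; may be a vector.
#' @param cap A [photo_capacity()] object.
#' @param gammastar Photorespiratory compensation point (Pa), > 0.
#' @param Kair Apparent Michaelis-Menten constant in 21% O2 (Pa), > 0.
#' @return A list with vectors `Ac`, `Aj`, `Ap` (umol m^-2 s^-1).
#' @export
limiting_rates <- function(Cc, cap, gammastar, Kair) {
  if (any(!is.finite(Cc)) || any(Cc <= 0))
    stop("invalid input: Cc must be finite and > 0")
  if (gammastar <= 0 || Kair <= 0)
    stop("invalid input: gammastar and Kair must be > 0")
  list(
    Ac = cap$Vcmax * (Cc - gammastar) / (Cc + Kair) - cap$Rd,
    Aj = cap$J * (Cc - gammastar) / (4 * Cc + 8 * gammastar) - cap$Rd,
    Ap = rep(3 * cap$TPU - cap$Rd, length(Cc))
  )
}

# Lower root of A^2 - b A + c = 0 arising from substituting Cc = Ci - A/gm
# into a limitation of the form A = V (Cc - gstar)/(Cc + K) - Rd.
#' @keywords internal
.quad_lim <- function(gm, Ci, V, K, gstar, Rd) {
  b <- gm * (Ci + K) + V - Rd
  cc <- gm * (V * (Ci - gstar) - Rd * (Ci + K))
  disc <- b^2 - 4 * cc
  if (any(disc < 0))
    stop("numerical solution error: no real root for limitation (disc < 0)")
  (b - sqrt(disc)) / 2
}

#' Net assimilation with mesophyll-conductance coupling
#'
#' Solves the FvCB model at one observation: for each limitation the
#' coupled system `A = f(Cc)`, `Cc = Ci - A/gm(T)` is solved in closed form
#' (quadratic, lower root), and the net rate is the minimum of the three
#' consistent solutions. Ties in the minimum are labelled by the fixed
#' priority carboxylation < regeneration < tpu (labels only; An is
#' unaffected). Negative An at low Ci is a valid output (respiration-
#' dominated region).
#'
#' @param Ci Intercellular CO2 partial pressure (Pa), > 0; may be a vector.
#' @param T_leaf Leaf temperature (K).
#' @param cfg A [kinetic_config()]; gm, Kair and Gamma* are temperature-
#'   scaled from it.
#' @param cap A [photo_capacity()] at the evaluation temperature.
#' @return A data.frame with columns `An` (umol m^-2 s^-1), `limitation`
#'   (one of "carboxylation", "regeneration", "tpu") and `Cc` (Pa).
#' @export
net_assimilation <- function(Ci, T_leaf, cfg, cap) {
  if (any(!is.finite(Ci)) || any(Ci <= 0))
    stop("invalid input: Ci must be finite and > 0")
  kin <- .kinetics_at(cfg, T_leaf)
  Ac <- .quad_lim(kin$gm, Ci, cap$Vcmax, kin$Kair_pa, kin$gammastar_pa, cap$Rd)
  Aj <- .quad_lim(kin$gm, Ci, cap$J / 4, 2 * kin$gammastar_pa,
                  kin$gammastar_pa, cap$Rd)
  Ap <- rep(3 * cap$TPU - cap$Rd, length(Ci))
  rates <- cbind(carboxylation = Ac, regeneration = Aj, tpu = Ap)
  idx <- apply(rates, 1L, which.min)  # which.min takes first on ties
  An <- rates[cbind(seq_along(Ci), idx)]
  data.frame(An = An,
             limitation = colnames(rates)[idx],
             Cc = Ci - An / kin$gm,
             stringsAsFactors = FALSE)
}

#' Forward A-Ci curve prediction in field units
#'
#' Convenience wrapper around [net_assimilation()] taking Ci as a mole
#' fraction (umol mol^-1) and leaf temperature in degrees Celsius, as
#' recorded by gas-exchange systems.
#'
#' @param Ci_umol Intercellular CO2 mole fraction (umol mol^-1); vector.
#' @param T_leaf_C Leaf temperature (degC).
#' @param cfg A [kinetic_config()].
#' @param cap A [photo_capacity()] at `T_leaf_C`.
#' @return As [net_assimilation()], plus a `Ci` column (umol mol^-1).
#' @export
aci_predict <- function(Ci_umol, T_leaf_C, cfg, cap) {
  out <- net_assimilation(to_partial_pressure(Ci_umol, cfg$pressure),
                          celsius_to_kelvin(T_leaf_C), cfg, cap)
  cbind(Ci = Ci_umol, out)
}
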
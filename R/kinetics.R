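# Kinetic constants and temperature-scaling functions.
#
# All temperatures are Kelvin internally; user-facing constructors accept
# degrees Celsius and convert once at the boundary. CO2 quantities are carried
# in Pa internally because mesophyll conductance has Pa^-1 units; mole-fraction
# inputs (umol mol^-1) are converted with the configured atmospheric pressure.

#' Universal gas constant (J mol^-1 K^-1)
#' @keywords internal
.RGAS <- 8.314

#' Convert degrees Celsius to Kelvin
#'
#' @param x Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' Convert Kelvin to degrees Celsius
#'
#' @param x Temperature in Kelvin.
#' @return Temperature in degrees Celsius.
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' FvCB kinetic configuration for a species
#'
#' Bundles the species-level kinetic constants of the Farquhar-von
#' Caemmerer-Berry (FvCB) photosynthesis model and their temperature
#' sensitivities: mesophyll conductance `gm` at 25 degC, the apparent
#' Michaelis-Menten constant for carboxylation in 21% O2 (`Kair`), the
#' photorespiratory CO2 compensation point Gamma* -- each with an Arrhenius
#' activation energy -- plus the atmospheric pressure used for mole-fraction
#' to partial-pressure conversion.
#'
#' @param gm_ref Mesophyll conductance at the reference temperature
#'   (umol m^-2 s^-1 Pa^-1).
#' @param Ea_gm Activation energy of gm (kJ mol^-1).
#' @param Kair_ref Apparent Michaelis-Menten constant for carboxylation in
#'   21% O2 at the reference temperature (umol mol^-1).
#' @param Ea_Kair Activation energy applied to Kair (kJ mol^-1).
#' @param gammastar_ref Photorespiratory CO2 compensation point at the
#'   reference temperature (umol mol^-1).
#' @param Ea_gammastar Activation energy of Gamma* (kJ mol^-1).
#' @param pressure Atmospheric pressure (kPa); must lie in [50, 110].
#' @param T_ref Reference temperature (K); default 298.15 K (25 degC).
#' @return An object of class `kinetic_config` (a named list).
#' @seealso [wheat_kinetics()] for the packaged wheat defaults.
#' @export
kinetic_config <- function(gm_ref, Ea_gm, Kair_ref, Ea_Kair,
                           gammastar_ref, Ea_gammastar,
                           pressure = 96, T_ref = 298.15) {
  vals <- c(gm_ref = gm_ref, Ea_gm = Ea_gm, Kair_ref = Kair_ref,
            Ea_Kair = Ea_Kair, gammastar_ref = gammastar_ref,
            Ea_gammastar = Ea_gammastar, pressure = pressure, T_ref = T_ref)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid parameter: all kinetic constants must be finite and > 0")
  if (pressure < 50 || pressure > 110)
    stop("invalid parameter: pressure must lie in [50, 110] kPa")
  structure(as.list(vals), class = "kinetic_config")
}

#' Packaged wheat kinetic constants
#'
#' Loads the wheat FvCB kinetic parameter set shipped with the package
#' (`inst/extdata/wheat_default.json`): gm 5.5 umol m^-2 s^-1 Pa^-1
#' (Ea 47.65 kJ mol^-1), Kair 772 umol mol^-1 (Ea 93.72 kJ mol^-1),
#' Gamma* 37.74 umol mol^-1 (Ea 24.42 kJ mol^-1), pressure 96 kPa.
#'
#' @return A `kinetic_config` object.
#' @export
wheat_kinetics <- function() {
  path <- system.file("extdata", "wheat_default.json",
                      package = "photothermal", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  kinetic_config(gm_ref = raw$gm_ref, Ea_gm = raw$Ea_gm,
                 Kair_ref = raw$Kair_ref, Ea_Kair = raw$Ea_Kair,
                 gammastar_ref = raw$gammastar_ref,
                 Ea_gammastar = raw$Ea_gammastar,
                 pressure = raw$pressure, T_ref = raw$T_ref)
}

#' @export
print.kinetic_config <- function(x, ...) {
  cat("FvCB kinetic configuration\n")
  cat(sprintf("  gm(ref)       %8.3f umol m-2 s-1 Pa-1  (Ea %.2f kJ mol-1)\n",
              x$gm_ref, x$Ea_gm))
  cat(sprintf("  Kair(ref)     %8.2f umol mol-1         (Ea %.2f kJ mol-1)\n",
              x$Kair_ref, x$Ea_Kair))
  cat(sprintf("  Gamma*(ref)   %8.2f umol mol-1         (Ea %.2f kJ mol-1)\n",
              x$gammastar_ref, x$Ea_gammastar))
  cat(sprintf("  pressure      %8.1f kPa; T_ref %.2f K\n", x$pressure, x$T_ref))
  invisible(x)
}

#' Simple Arrhenius temperature scaling
#'
#' Scales a trait value from the reference temperature to `T` with
#' `k_ref * exp(Ea * (T - T_ref) / (T_ref * R * T))`. `Ea` is supplied in
#' kJ mol^-1 and converted to J mol^-1 internally.
#'
#' @param k_ref Trait value at `T_ref` (> 0, trait units).
#' @param Ea Activation energy (kJ mol^-1); `Ea = 0` gives no temperature
#'   dependence.
#' @param T Evaluation temperature (K), in (250, 350).
#' @param T_ref Reference temperature (K), default 298.15.
#' @return Trait value at `T` (same units as `k_ref`).
#' @export
arrhenius_scale <- function(k_ref, Ea, T, T_ref = 298.15) {
  if (any(!is.finite(c(k_ref, Ea, T, T_ref))))
    stop("invalid parameter: non-finite input to arrhenius_scale")
  if (any(k_ref <= 0)) stop("invalid parameter: k_ref must be > 0")
  if (any(T <= 250 | T >= 350) || any(T_ref <= 250 | T_ref >= 350))
    stop("invalid parameter: temperatures must lie in (250, 350) K")
  k_ref * exp(Ea * 1000 * (T - T_ref) / (T_ref * .RGAS * T))
}

#' Peaked Arrhenius temperature response (with deactivation)
#'
#' Arrhenius rise moderated by an entropy-driven deactivation term, in the
#' normalized parameterization where the curve passes through `k_ref` at
#' `T_ref` exactly:
#' \deqn{k(T) = k_{ref}\; e^{E_a (T - T_{ref}) / (T_{ref} R T)}\;
#'   \frac{1 + e^{(T_{ref}\Delta S - E_d)/(T_{ref} R)}}
#'        {1 + e^{(T \Delta S - E_d)/(T R)}}}
#' The curve is unimodal in `T` with an interior maximum at
#' [topt_from_peaked()].
#'
#' @param k_ref Trait value at `T_ref` (> 0).
#' @param Ea Activation energy (kJ mol^-1), 0 < Ea < Ed.
#' @param Ed Deactivation energy (kJ mol^-1); conventionally held fixed at
#'   200.
#' @param dS Entropy factor (kJ mol^-1 K^-1), > 0.
#' @param T Evaluation temperature (K); may be a vector.
#' @param T_ref Reference temperature (K), default 298.15.
#' @return Trait value(s) at `T`.
#' @export
peaked_arrhenius <- function(k_ref, Ea, Ed = 200, dS, T, T_ref = 298.15) {
  if (any(!is.finite(c(k_ref, Ea, Ed, dS, T, T_ref))))
    stop("invalid parameter: non-finite input to peaked_arrhenius")
  if (Ed <= Ea) stop("invalid parameter: Ed must exceed Ea")
  if (Ea <= 0 || dS <= 0 || k_ref <= 0)
    stop("invalid parameter: k_ref, Ea, dS must be > 0")
  Rk <- .RGAS / 1000  # kJ mol-1 K-1, consistent with Ea/Ed/dS in kJ
  num <- 1 + exp((T_ref * dS - Ed) / (T_ref * Rk))
  den <- 1 + exp((T * dS - Ed) / (T * Rk))
  k_ref * exp(Ea * (T - T_ref) / (T_ref * Rk * T)) * num / den
}

#' Optimum temperature of the peaked Arrhenius response
#'
#' Closed form of the interior maximizer:
#' `T_opt = Ed / (dS - R * log(Ea / (Ed - Ea)))` with all energies in
#' kJ mol^-1 and R = 0.008314 kJ mol^-1 K^-1.
#'
#' @param Ea Activation energy (kJ mol^-1).
#' @param Ed Deactivation energy (kJ mol^-1), Ed > Ea.
#' @param dS Entropy factor (kJ mol^-1 K^-1).
#' @return Optimum temperature (K).
#' @export
topt_from_peaked <- function(Ea, Ed = 200, dS) {
  if (any(!is.finite(c(Ea, Ed, dS))))
    stop("invalid parameter: non-finite input to topt_from_peaked")
  if (Ed <= Ea) stop("invalid parameter: Ed must exceed Ea (Ed - Ea <= 0)")
  if (Ea <= 0) stop("invalid parameter: Ea must be > 0")
  Rk <- .RGAS / 1000
  denom <- dS - Rk * log(Ea / (Ed - Ea))
  if (denom <= 0)
    stop("invalid parameter: dS - R*log(Ea/(Ed-Ea)) must be > 0 (got ",
         signif(denom, 4), ")")
  Ed / denom
}

#' Entropy factor giving a prescribed optimum temperature
#'
#' Inverse of [topt_from_peaked()]: the `dS` for which the peaked Arrhenius
#' response with activation energy `Ea` and deactivation energy `Ed` peaks at
#' `T_opt`. Used by the synthetic-data generators to state ground truth in
#' terms of the optimum.
#'
#' @param T_opt Desired optimum temperature (K).
#' @param Ea Activation energy (kJ mol^-1).
#' @param Ed Deactivation energy (kJ mol^-1).
#' @return Entropy factor dS (kJ mol^-1 K^-1).
#' @export
ds_for_topt <- function(T_opt, Ea, Ed = 200) {
  if (Ed <= Ea || Ea <= 0 || T_opt <= 0)
    stop("invalid parameter: require Ed > Ea > 0 and T_opt > 0")
  Rk <- .RGAS / 1000
  Ed / T_opt + Rk * log(Ea / (Ed - Ea))
}

#' Mole fraction to partial pressure
#'
#' Converts a CO2 mole fraction (umol mol^-1) to a partial pressure (Pa) at
#' the given atmospheric pressure: `x * 1e-6 * pressure * 1e3`. At 96 kPa,
#' 400 umol mol^-1 corresponds to 38.4 Pa.
#'
#' @param x Mole fraction (umol mol^-1), >= 0; may be a vector.
#' @param pressure Atmospheric pressure (kPa), > 0.
#' @return Partial pressure (Pa).
#' @export
to_partial_pressure <- function(x, pressure) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("invalid parameter: mole fraction must be finite and >= 0")
  if (!is.finite(pressure) || pressure <= 0)
    stop("invalid parameter: pressure must be > 0")
  x * 1e-6 * pressure * 1e3
}

# Temperature-scaled kinetic quantities, all in Pa / Pa-units at leaf
# temperature T (K). Used by the forward model and the fitter.
#' @keywords internal
.kinetics_at <- function(cfg, T) {
  list(
    gm = arrhenius_scale(cfg$gm_ref, cfg$Ea_gm, T, cfg$T_ref),
    Kair_pa = to_partial_pressure(
      arrhenius_scale(cfg$Kair_ref, cfg$Ea_Kair, T, cfg$T_ref), cfg$pressure),
    gammastar_pa = to_partial_pressure(
      arrhenius_scale(cfg$gammastar_ref, cfg$Ea_gammastar, T, cfg$T_ref),
      cfg$pressure)
  )
}
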
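# Shared fixtures: the standard CO2 staircase, small kinetic configs, and an
# independent brute-force solver used as the oracle for the closed-form FvCB
# solution.

CI_SEQ <- c(30, 50, 100, 150, 250, 400, 400, 600, 800, 1000, 1200, 1400, 400)

# evaluate expr under a fixed seed without disturbing the test RNG stream
.with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

test_cfg <- function() kinetic_config(
  gm_ref = 5.5, Ea_gm = 47.65, Kair_ref = 772, Ea_Kair = 93.72,
  gammastar_ref = 37.74, Ea_gammastar = 24.42, pressure = 96)

# independent fixed-point solver: bisection on A - min(limitations at
# Cc = Ci - A/gm). Shares no code with the quadratic closed form.
bisect_fvcb <- function(Ci_pa, T_K, cfg, cap, tol = 1e-10) {
  gm <- arrhenius_scale(cfg$gm_ref, cfg$Ea_gm, T_K, cfg$T_ref)
  Kair <- to_partial_pressure(
    arrhenius_scale(cfg$Kair_ref, cfg$Ea_Kair, T_K, cfg$T_ref), cfg$pressure)
  gs <- to_partial_pressure(
    arrhenius_scale(cfg$gammastar_ref, cfg$Ea_gammastar, T_K, cfg$T_ref),
    cfg$pressure)
  g <- function(A) {
    Cc <- Ci_pa - A / gm
    if (Cc <= 0) return(Inf)
    rates <- c(cap$Vcmax * (Cc - gs) / (Cc + Kair),
               cap$J * (Cc - gs) / (4 * Cc + 8 * gs),
               3 * cap$TPU) - cap$Rd
    A - min(rates)
  }
  # below the compensation point Aj tends to -J/8 - Rd; bracket generously
  lo <- -cap$J / 4 - cap$Rd - 5
  hi <- min(cap$Vcmax, gm * Ci_pa * 0.999999)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# noiseless forward curve at one temperature
make_curve <- function(cap, T_C = 25, cfg = test_cfg(), ci = CI_SEQ, ...) {
  an <- aci_predict(ci, T_C, cfg, cap)$An
  aci_curve(ci, an, T_C, pressure = cfg$pressure, ...)
}

# piecewise-linear F0 ramp with known intersection
make_ramp <- function(tcrit = 44, baseline = 500, flat_slope = 0,
                      steep_slope = 100, from = 20, to = 65, by = 0.1,
                      noise_sd = 0, seed = NULL, ...) {
  tt <- seq(from, to, by = by)
  f0 <- baseline + flat_slope * (tt - from) +
    ifelse(tt > tcrit, steep_slope * (tt - tcrit), 0)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f0 <- pmax(f0 + rnorm(length(tt), 0, noise_sd), 1)
  }
  fluorescence_ramp(tt, f0, ...)
}
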
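# Synthetic-data generators with known ground truth for every input the
# pipeline consumes: A-Ci curve sets across the measurement-temperature grid,
# F0 temperature ramps, and metabolite abundance tables with class-structured
# treatment effects. Each generator is deterministic for a fixed seed and, at
# zero noise, is inverted by its pipeline stage (round-trip property).

#' Experimental design for the synthetic study
#'
#' The 4-genotype x 3-night-temperature x 2-leaf-class design: two
#' heat-susceptible genotypes (1704, 1898) and two heat-tolerant ones
#' (2254, Mace); night temperatures 15, 20, 25 degC; newly developed
#' versus pre-existing flag leaves; A-Ci curves at measurement temperatures
#' 20-50 degC over the standard 13-step CO2 sequence.
#'
#' @param genotypes Named character vector: genotype id -> archetype
#'   ("tolerant" or "susceptible").
#' @param night_temps Night temperature treatments (degC).
#' @param leaf_classes Leaf classes simulated.
#' @param reps_gas,reps_tcrit,reps_metab Replicates per cell for
#'   gas-exchange curves, Tcrit ramps, metabolite samples.
#' @param meas_temps A-Ci measurement temperatures (degC).
#' @param ci_sequence Chamber CO2 staircase (umol mol^-1); the standard
#'   sequence duplicates 400 mid-sequence and closes with a 400 recovery
#'   point.
#' @return Object of class `study_design`.
#' @export
study_design <- function(
    genotypes = c("1704" = "susceptible", "1898" = "susceptible",
                  "2254" = "tolerant", "Mace" = "tolerant"),
    night_temps = c(15, 20, 25),
    leaf_classes = c("newly developed", "pre-existing"),
    reps_gas = 4, reps_tcrit = 6, reps_metab = 4,
    meas_temps = c(20, 25, 30, 35, 40, 50),
    ci_sequence = c(30, 50, 100, 150, 250, 400, 400, 600, 800, 1000,
                    1200, 1400, 400)) {
  if (reps_gas < 1 || reps_tcrit < 1 || reps_metab < 1)
    stop("invalid parameter: replicates must be >= 1")
  if (any(ci_sequence <= 0))
    stop("invalid parameter: Ci sequence must be positive")
  structure(list(genotypes = genotypes, night_temps = night_temps,
                 leaf_classes = leaf_classes, reps_gas = reps_gas,
                 reps_tcrit = reps_tcrit, reps_metab = reps_metab,
                 meas_temps = meas_temps, ci_sequence = ci_sequence),
            class = "study_design")
}

# night-temperature effect multipliers realizing the two archetypes in
# newly developed leaves; pre-existing leaves carry no effect
#' @keywords internal
.night_mult <- function(archetype, leaf_class, night_temp,
                        vcmax_ratio_25 = 1.3, j_ratio_25_tol = 1.2,
                        j_ratio_25_sus = 0.8) {
  if (leaf_class != "newly developed")
    return(c(Vcmax = 1, J = 1))
  w <- (night_temp - 15) / 10  # 0 at 15 degC, 1 at 25 degC
  if (archetype == "tolerant")
    c(Vcmax = 1 + w * (vcmax_ratio_25 - 1),
      J = 1 + w * (j_ratio_25_tol - 1))
  else
    c(Vcmax = 1, J = 1 + w * (j_ratio_25_sus - 1))
}

#' Ground-truth parameter book for the synthetic study
#'
#' Builds the per-cell true parameters that the generators realize and the
#' pipeline is expected to recover: a peaked Arrhenius temperature function
#' for Vcmax (Ed fixed at 200 kJ mol^-1), quadratic (vertex-form)
#' temperature functions for J1500 and TPU, day respiration, per-cell true
#' Tcrit, metabolite class effects, and the noise levels.
#'
#' Archetypes: in newly developed leaves, tolerant genotypes raise Vcmax
#' (x1.3 at 25 degC nights, within the reported 24-43% range) and J
#' (x1.2), while susceptible genotypes lower J (x0.8); pre-existing leaves
#' carry no night-temperature effect. True Tcrit genotype means default to
#' the published genotype means for newly developed leaves (1704 45.7,
#' 1898 45.2, 2254 44.6, Mace 43.8 degC) with no night effect.
#'
#' @param design A [study_design()].
#' @param An_sd Additive An noise SD (umol m^-2 s^-1; default 0.5, typical
#'   IRGA repeatability).
#' @param F0_sd_frac F0 noise SD as a fraction of baseline (default 0.01).
#' @param tcrit_between_sd Between-leaf SD of true Tcrit (degC, default 0.5).
#' @param metab_log_sd Log-scale metabolite noise SD (default 0.3).
#' @param metab_fold Planted fold-change at 25 degC nights for responsive
#'   classes in responsive genotypes (default 2).
#' @param n_compounds Number of metabolites (default 162).
#' @return Object of class `truth_book`: `aci` (per-cell data.frame),
#'   `tcrit` (per-cell data.frame), `metab` (class map + effects), `noise`.
#' @export
default_truth <- function(design, An_sd = 0.5, F0_sd_frac = 0.01,
                          tcrit_between_sd = 0.5, metab_log_sd = 0.3,
                          metab_fold = 2, n_compounds = 162) {
  cells <- expand.grid(genotype = names(design$genotypes),
                       night_temp = design$night_temps,
                       leaf_class = design$leaf_classes,
                       stringsAsFactors = FALSE)
  base_vcmax <- c("1704" = 150, "1898" = 140, "2254" = 155, "Mace" = 160)
  base_j <- c("1704" = 200, "1898" = 190, "2254" = 195, "Mace" = 210)
  base_tcrit <- c("1704" = 45.7, "1898" = 45.2, "2254" = 44.6,
                  "Mace" = 43.8)
  gn <- names(design$genotypes)
  bv <- if (all(gn %in% names(base_vcmax))) base_vcmax[gn]
        else stats::setNames(rep(150, length(gn)), gn)
  bj <- if (all(gn %in% names(base_j))) base_j[gn]
        else stats::setNames(rep(200, length(gn)), gn)
  bt <- if (all(gn %in% names(base_tcrit))) base_tcrit[gn]
        else stats::setNames(rep(45, length(gn)), gn)

  aci <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$genotype[i]; nt <- cells$night_temp[i]
    lc <- cells$leaf_class[i]
    mult <- .night_mult(design$genotypes[[g]], lc, nt)
    data.frame(
      genotype = g, night_temp = nt, leaf_class = lc,
      Vcmax_kref = bv[[g]] * mult[["Vcmax"]], Vcmax_Ea = 65,
      Vcmax_Ed = 200,
      Vcmax_dS = ds_for_topt(celsius_to_kelvin(39), 65, 200),
      J_max = bj[[g]] * mult[["J"]], J_Topt = 30.5, J_curv = -0.25,
      TPU_max = 13, TPU_Topt = 30, TPU_curv = -0.02,
      Rd = 1, stringsAsFactors = FALSE)
  }))

  tcrit <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$genotype[i]; nt <- cells$night_temp[i]
    lc <- cells$leaf_class[i]
    # pre-existing Mace-type response: Tcrit rises with warm nights
    shift <- if (lc == "pre-existing" &&
                 design$genotypes[[g]] == "tolerant")
      0.08 * (nt - 15) else 0
    data.frame(genotype = g, night_temp = nt, leaf_class = lc,
               Tcrit = bt[[g]] + shift, stringsAsFactors = FALSE)
  }))

  classes <- .metab_classes(n_compounds)
  responsive <- names(classes)[classes %in%
                                 c("monosaccharide", "fatty_acid_saturated")]
  structure(list(
    aci = aci, tcrit = tcrit,
    metab = list(classes = classes,
                 responsive_compounds = responsive,
                 responsive_genotypes =
                   names(design$genotypes)[
                     design$genotypes == "tolerant" |
                       names(design$genotypes) == "1898"],
                 fold_at_25 = metab_fold),
    noise = list(An_sd = An_sd, F0_sd_frac = F0_sd_frac,
                 tcrit_between_sd = tcrit_between_sd,
                 metab_log_sd = metab_log_sd)
  ), class = "truth_book")
}

# class labels for the simulated compound panel; the first five
# monosaccharides and two saturated fatty acids are the planted responders
#' @keywords internal
.metab_classes <- function(n_compounds) {
  pool <- c(monosaccharide = 12, disaccharide = 6, sugar_alcohol = 8,
            amino_acid = 30, organic_acid = 30, TCA_intermediate = 8,
            fatty_acid_saturated = 6, fatty_acid_unsaturated = 8)
  if (n_compounds < sum(pool) + 1)
    stop("invalid parameter: n_compounds too small for the class layout")
  cls <- c(rep(names(pool), pool),
           rep("unknown", n_compounds - sum(pool)))
  stats::setNames(cls, sprintf("m%03d", seq_len(n_compounds)))
}

#' True capacity set at a leaf temperature
#'
#' Evaluates a truth-book A-Ci row at a leaf temperature: Vcmax from the
#' peaked Arrhenius function, J1500 and TPU from their vertex-form
#' quadratics (floored at a small positive value), Rd constant.
#'
#' @param truth_row One row of `truth_book$aci`.
#' @param T_leaf_C Leaf temperature (degC).
#' @return A [photo_capacity()].
#' @export
true_capacity_at <- function(truth_row, T_leaf_C) {
  TK <- celsius_to_kelvin(T_leaf_C)
  vc <- peaked_arrhenius(truth_row$Vcmax_kref, truth_row$Vcmax_Ea,
                         truth_row$Vcmax_Ed, truth_row$Vcmax_dS, TK)
  j <- truth_row$J_max + truth_row$J_curv * (T_leaf_C - truth_row$J_Topt)^2
  tpu <- truth_row$TPU_max +
    truth_row$TPU_curv * (T_leaf_C - truth_row$TPU_Topt)^2
  photo_capacity(vc, max(j, 1), max(tpu, 0.5), truth_row$Rd)
}

#' Simulate a gas-exchange A-Ci dataset
#'
#' One A-Ci curve per cell x replicate x measurement temperature:
#' capacities from the truth book evaluated at each temperature, An from
#' the forward FvCB model over the design's Ci sequence, additive Gaussian
#' noise. A descriptive stomatal-conductance covariate (curvilinear in
#' temperature, never used in fitting) is attached to each curve.
#'
#' @param design A [study_design()].
#' @param truth A [default_truth()] truth book.
#' @param cfg A [kinetic_config()] (default [wheat_kinetics()]).
#' @param seed RNG seed.
#' @param leaf_classes Subset of leaf classes to generate (default all in
#'   the design).
#' @return List with `curves` (list of [aci_curve()]) and `truth`.
#' @export
simulate_aci_dataset <- function(design, truth = default_truth(design),
                                 cfg = wheat_kinetics(), seed = 1,
                                 leaf_classes = design$leaf_classes) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_book"))
  an_sd <- truth$noise$An_sd
  curves <- .with_seed(seed, {
    out <- list()
    for (g in names(design$genotypes)) for (nt in design$night_temps)
      for (lc in leaf_classes) {
        row <- truth$aci[truth$aci$genotype == g &
                           truth$aci$night_temp == nt &
                           truth$aci$leaf_class == lc, ]
        if (!nrow(row))
          stop("truth book missing cell: ", g, " / ", nt, " / ", lc)
        for (rep_i in seq_len(design$reps_gas))
          for (Tm in design$meas_temps) {
            cap <- true_capacity_at(row, Tm)
            an <- aci_predict(design$ci_sequence, Tm, cfg, cap)$An +
              stats::rnorm(length(design$ci_sequence), 0, an_sd)
            cv <- aci_curve(design$ci_sequence, an, Tm,
                            pressure = cfg$pressure, genotype = g,
                            night_temp = nt, leaf_class = lc,
                            replicate = sprintf("%s_n%02d_%s_r%d",
                                                g, nt, substr(lc, 1, 3),
                                                rep_i))
            # descriptive gs covariate (mol m-2 s-1): dip then uptick
            dT <- Tm - 20
            gs0 <- 0.38 * (1 + 0.1 * (nt - 15) / 10 *
                             if (design$genotypes[[g]] == "tolerant") 1 else -1)
            cv$data$gs <- pmax(gs0 - 0.008 * dT + 3e-4 * dT^2 +
                                 stats::rnorm(nrow(cv$data), 0, 0.01), 0.01)
            out[[length(out) + 1L]] <- cv
          }
      }
    out
  })
  list(curves = curves, truth = truth)
}

#' Simulate F0 fluorescence temperature ramps
#'
#' Ramps from `T_start` to `T_end` degC at the design density: a flat
#' baseline with small drift, a linear steep rise of `rise_rate` beginning
#' at the replicate's true Tcrit (cell truth plus between-leaf variation),
#' a post-peak decline, and Gaussian noise proportional to baseline.
#'
#' @param design A [study_design()].
#' @param truth A [default_truth()] truth book; true Tcrit must lie in
#'   (30, 60) degC.
#' @param seed RNG seed.
#' @param leaf_classes Leaf classes to generate.
#' @param samples_per_C Sampling density (default 10 per degC).
#' @param T_start,T_end Ramp range (default 20-65 degC).
#' @param baseline Baseline F0 (arbitrary units, default 500).
#' @param drift_slope Baseline drift (units per degC, default 0.5).
#' @param rise_rate Steep-phase slope (units per degC, default 100).
#' @param rise_span Temperature extent of the steep rise before the
#'   post-peak decline (degC, default 12; must be > 0).
#' @return List with `ramps` (list of [fluorescence_ramp()]), `truth`, and
#'   `true_tcrit` (long data.frame of per-replicate true values).
#' @export
simulate_f0_ramps <- function(design, truth = default_truth(design),
                              seed = 1,
                              leaf_classes = design$leaf_classes,
                              samples_per_C = 10, T_start = 20, T_end = 65,
                              baseline = 500, drift_slope = 0.5,
                              rise_rate = 100, rise_span = 12) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_book"))
  if (rise_span <= 0)
    stop("invalid parameter: rise_span must be > 0 (degenerate steep segment)")
  if (truth$noise$F0_sd_frac < 0)
    stop("invalid parameter: noise sd must be >= 0")
  if (any(truth$tcrit$Tcrit <= 30 | truth$tcrit$Tcrit >= 60))
    stop("invalid parameter: true Tcrit must lie in (30, 60) degC")
  tt <- seq(T_start, T_end, by = 1 / samples_per_C)
  res <- .with_seed(seed, {
    ramps <- list(); rec <- list()
    for (g in names(design$genotypes)) for (nt in design$night_temps)
      for (lc in leaf_classes) {
        row <- truth$tcrit[truth$tcrit$genotype == g &
                             truth$tcrit$night_temp == nt &
                             truth$tcrit$leaf_class == lc, ]
        if (!nrow(row))
          stop("truth book missing cell: ", g, " / ", nt, " / ", lc)
        for (rep_i in seq_len(design$reps_tcrit)) {
          tc <- row$Tcrit + stats::rnorm(1, 0, truth$noise$tcrit_between_sd)
          f0 <- baseline + drift_slope * (tt - T_start)
          steep <- tt > tc & tt <= tc + rise_span
          f0[steep] <- f0[steep] + rise_rate * (tt[steep] - tc)
          post <- tt > tc + rise_span
          f0[post] <- f0[which(steep)[sum(steep)]] -
            60 * (tt[post] - (tc + rise_span))
          f0 <- pmax(f0 + stats::rnorm(length(tt), 0,
                                       truth$noise$F0_sd_frac * baseline),
                     1)
          ramps[[length(ramps) + 1L]] <-
            fluorescence_ramp(tt, f0, genotype = g, night_temp = nt,
                              leaf_class = lc,
                              replicate = sprintf("%s_n%02d_%s_r%d", g, nt,
                                                  substr(lc, 1, 3), rep_i))
          rec[[length(rec) + 1L]] <-
            data.frame(genotype = g, night_temp = nt, leaf_class = lc,
                       replicate = rep_i, true_tcrit = tc)
        }
      }
    list(ramps = ramps, rec = do.call(rbind, rec))
  })
  list(ramps = res$ramps, truth = truth, true_tcrit = res$rec)
}

#' Simulate a metabolite abundance table
#'
#' Log-normal compound abundances with class-structured treatment effects:
#' monosaccharides and saturated fatty acids are elevated by the configured
#' fold at 25 degC nights (interpolated on the log scale at 20 degC) in the
#' responsive genotypes; the non-responsive genotype (1704 by default)
#' carries no effect. Internal-standard and fresh-mass nuisance variation
#' is layered on so that [normalize_abundance()] inverts it. Samples are
#' newly developed leaves (the tissue profiled in the source design).
#'
#' @param design A [study_design()].
#' @param truth A [default_truth()] truth book.
#' @param seed RNG seed.
#' @param null_effects Generate with all planted effects removed (type-I
#'   calibration input)?
#' @return List with `table` (a raw [metabolite_table()]) and `truth`.
#' @export
simulate_metabolite_table <- function(design, truth = default_truth(design),
                                      seed = 1, null_effects = FALSE) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_book"))
  mt <- truth$metab
  classes <- mt$classes
  p <- length(classes)
  samples <- expand.grid(rep = seq_len(design$reps_metab),
                         night_temp = design$night_temps,
                         genotype = names(design$genotypes),
                         stringsAsFactors = FALSE)
  n <- nrow(samples)
  .with_seed(seed, {
    base <- exp(stats::runif(p, log(1e3), log(1e6)))  # per-compound level
    lfold <- matrix(0, n, p, dimnames = list(NULL, names(classes)))
    if (!null_effects) {
      for (i in seq_len(n)) {
        if (samples$genotype[i] %in% mt$responsive_genotypes) {
          w <- (samples$night_temp[i] - 15) / 10
          lfold[i, mt$responsive_compounds] <- w * log(mt$fold_at_25)
        }
      }
    }
    conc <- exp(matrix(log(base), n, p, byrow = TRUE) + lfold +
                  matrix(stats::rnorm(n * p, 0, truth$noise$metab_log_sd),
                         n, p))
    mass <- stats::runif(n, 0.08, 0.20)
    istd <- exp(stats::rnorm(n, log(1e5), 0.2))
    raw <- conc * mass * (istd / mean(istd))
    tab <- metabolite_table(raw, istd, mass, classes,
                            genotype = samples$genotype,
                            night_temp = samples$night_temp)
    list(table = tab, truth = truth)
  })
}
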
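# Synthetic-data generators: determinism, design fidelity, round trips.

small_design <- function() study_design(
  genotypes = c("1704" = "susceptible", "Mace" = "tolerant"),
  night_temps = c(15, 25), leaf_classes = "newly developed",
  reps_gas = 1, reps_tcrit = 2, reps_metab = 3,
  meas_temps = c(25, 35))

test_that("generators are deterministic for a fixed seed", {
  des <- small_design()
  tr <- default_truth(des)
  a1 <- simulate_aci_dataset(des, tr, seed = 5)
  a2 <- simulate_aci_dataset(des, tr, seed = 5)
  expect_identical(lapply(a1$curves, `[[`, "data"),
                   lapply(a2$curves, `[[`, "data"))
  r1 <- simulate_f0_ramps(des, tr, seed = 5)
  r2 <- simulate_f0_ramps(des, tr, seed = 5)
  expect_identical(lapply(r1$ramps, `[[`, "F0"),
                   lapply(r2$ramps, `[[`, "F0"))
  m1 <- simulate_metabolite_table(des, tr, seed = 5)
  m2 <- simulate_metabolite_table(des, tr, seed = 5)
  expect_identical(m1$table$abundances, m2$table$abundances)
  # different seed changes the data
  m3 <- simulate_metabolite_table(des, tr, seed = 6)
  expect_false(identical(m1$table$abundances, m3$table$abundances))
})

test_that("design fidelity: counts, Ci sequence and temperature grids", {
  des <- small_design()
  tr <- default_truth(des)
  sim <- simulate_aci_dataset(des, tr, seed = 1)
  # cells x reps x measurement temperatures
  expect_length(sim$curves, 2 * 2 * 1 * 2)
  for (cv in sim$curves) {
    expect_identical(cv$data$Ci, des$ci_sequence)
    expect_true(unique(cv$data$T_leaf) %in% des$meas_temps)
  }
  ramps <- simulate_f0_ramps(des, tr, seed = 1)
  expect_length(ramps$ramps, 2 * 2 * 2)
  expect_equal(range(ramps$ramps[[1]]$temperature), c(20, 65))
  met <- simulate_metabolite_table(des, tr, seed = 1)
  expect_equal(dim(met$table$abundances), c(2 * 2 * 3, 162))
})

test_that("archetypes are realized in the truth book", {
  des <- study_design()
  tr <- default_truth(des)
  get <- function(g, nt, lc = "newly developed")
    tr$aci[tr$aci$genotype == g & tr$aci$night_temp == nt &
             tr$aci$leaf_class == lc, ]
  # tolerant: Vcmax rises x1.3 from 15 to 25 degC nights
  expect_equal(get("Mace", 25)$Vcmax_kref / get("Mace", 15)$Vcmax_kref, 1.3)
  # susceptible: J declines
  expect_lt(get("1704", 25)$J_max, get("1704", 15)$J_max)
  expect_equal(get("1704", 25)$Vcmax_kref, get("1704", 15)$Vcmax_kref)
  # pre-existing leaves: no night effect on capacities
  expect_equal(get("Mace", 25, "pre-existing")$Vcmax_kref,
               get("Mace", 15, "pre-existing")$Vcmax_kref)
})

test_that("zero-noise A-Ci round trip recovers the truth book", {
  des <- small_design()
  tr <- default_truth(des, An_sd = 0)
  cfg <- wheat_kinetics()
  sim <- simulate_aci_dataset(des, tr, cfg, seed = 1)
  cv <- sim$curves[[1]]
  row <- tr$aci[tr$aci$genotype == cv$genotype &
                  tr$aci$night_temp == cv$night_temp &
                  tr$aci$leaf_class == cv$leaf_class, ]
  cap_true <- true_capacity_at(row, mean(cv$data$T_leaf))
  fit <- fit_aci(cv, cfg)
  est <- c(fit$cap$Vcmax, fit$cap$J, fit$cap$TPU, fit$cap$Rd)
  tru <- c(cap_true$Vcmax, cap_true$J, cap_true$TPU, cap_true$Rd)
  expect_lt(max(abs(est / tru - 1)), 1e-3)
})

test_that("zero-noise F0 round trip recovers true Tcrit to 1e-3 degC", {
  des <- small_design()
  tr <- default_truth(des, F0_sd_frac = 0, tcrit_between_sd = 0)
  sim <- simulate_f0_ramps(des, tr, seed = 1)
  for (i in c(1, 3)) {
    r <- sim$ramps[[i]]
    truth <- sim$true_tcrit$true_tcrit[i]
    est <- estimate_tcrit(r, smooth_window = 0)
    expect_lt(abs(est$Tcrit - truth), 1e-3)
  }
  expect_error(simulate_f0_ramps(des, tr, rise_span = 0), "rise_span")
})

test_that("planted metabolite effects are recovered; nulls carry none", {
  des <- study_design(reps_metab = 4, leaf_classes = "newly developed")
  tr <- default_truth(des)
  sim <- simulate_metabolite_table(des, tr, seed = 3)
  norm <- normalize_abundance(sim$table)
  rk <- responsive_metabolites(norm,
                               genotypes = tr$metab$responsive_genotypes)
  planted <- tr$metab$responsive_compounds
  top <- rk$compound[seq_along(planted)]
  expect_gt(mean(planted %in% top), 0.8)  # planted set dominates the ranking
  # null generator: no compound-level lfc beyond noise
  sim0 <- simulate_metabolite_table(des, tr, seed = 3, null_effects = TRUE)
  rk0 <- responsive_metabolites(normalize_abundance(sim0$table),
                                genotypes = tr$metab$responsive_genotypes)
  # max over 162 null compounds stays well below the planted fold of 2
  expect_lt(max(abs(rk0$mean_lfc)), 0.9)
  expect_lt(median(abs(rk0$mean_lfc)), 0.25)
})

test_that("truth book missing a cell is a named error", {
  des <- small_design()
  tr <- default_truth(des)
  tr$aci <- tr$aci[tr$aci$genotype != "Mace", ]
  expect_error(simulate_aci_dataset(des, tr, seed = 1), "Mace")
})
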
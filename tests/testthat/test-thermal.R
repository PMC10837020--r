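# Temperature-response fits, comparative regressions, ANOVA/post-hoc.

test_that("fit_peaked recovers noiseless parameters and keeps Ed fixed", {
  Ts <- c(20, 25, 30, 35, 40, 50)
  set.seed(21)
  for (i in 1:5) {
    Ea <- runif(1, 45, 90)
    topt <- runif(1, 300, 318)
    dS <- ds_for_topt(topt, Ea, 200)
    k <- runif(1, 100, 500)
    val <- peaked_arrhenius(k, Ea, 200, dS, celsius_to_kelvin(Ts))
    pf <- fit_peaked(thermal_series("Vcmax", Ts, val))
    expect_lt(max(abs(pf$params[c("k_ref", "Ea", "dS")] /
                        c(k, Ea, dS) - 1)), 5e-3)
    expect_identical(unname(pf$params[["Ed"]]), 200)
    expect_equal(pf$T_opt, kelvin_to_celsius(topt), tolerance = 0.05)
    # value at the optimum is the curve evaluated there, exactly
    expect_equal(pf$value_at_Topt,
                 peaked_arrhenius(pf$params[["k_ref"]], pf$params[["Ea"]],
                                  200, pf$params[["dS"]],
                                  celsius_to_kelvin(pf$T_opt)))
  }
})

test_that("strictly increasing series yields the unresolved flag", {
  Ts <- c(20, 25, 30, 35, 40, 50)
  val <- exp(0.06 * Ts)  # no interior maximum in range
  pf <- fit_peaked(thermal_series("Vcmax", Ts, val))
  expect_false(pf$converged)
  expect_identical(pf$flag, "no optimum resolvable")
  expect_true(is.na(pf$T_opt))
})

test_that("fit_peaked noisy T_opt error is controlled (seeded MC)", {
  Ts <- c(20, 25, 30, 35, 40, 50)
  truth <- peaked_arrhenius(300, 65, 200, 0.66, celsius_to_kelvin(Ts))
  topt_true <- kelvin_to_celsius(topt_from_peaked(65, 200, 0.66))
  errs <- .with_seed_test(31, replicate(30, {
    val <- truth * (1 + rnorm(length(Ts), 0, 0.05))
    pf <- tryCatch(fit_peaked(thermal_series("Vcmax", Ts, val)),
                   error = function(e) NULL)
    if (is.null(pf) || is.na(pf$T_opt)) NA_real_
    else abs(pf$T_opt - topt_true)
  }))
  expect_lt(median(errs, na.rm = TRUE), 1.5)
})

test_that("fit_quadratic: exact vertex recovery and no-optimum flag", {
  Ts <- c(15, 20, 25, 30, 35, 40)
  s <- thermal_series("An", Ts, -0.1 * (Ts - 25)^2 + 30)
  qf <- fit_quadratic(s)
  expect_equal(qf$T_opt, 25, tolerance = 1e-9)
  expect_equal(qf$value_at_Topt, 30, tolerance = 1e-9)
  # known vertex (27.5, 24.0): closed-form OLS oracle via normal equations
  y <- -0.2 * (Ts - 27.5)^2 + 24
  X <- cbind(1, Ts, Ts^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  qf2 <- fit_quadratic(thermal_series("An", Ts, y))
  expect_equal(unname(qf2$coefficients[c("c", "b", "a")]), c(beta),
               tolerance = 1e-8)
  expect_equal(qf2$T_opt, 27.5, tolerance = 1e-8)
  # upward curvature: flagged, no optimum reported
  up <- fit_quadratic(thermal_series("An", Ts, 0.1 * (Ts - 25)^2))
  expect_false(up$has_optimum)
  expect_identical(up$flag, "no optimum in range")
  expect_error(fit_quadratic(thermal_series("An", c(20, 20, 25),
                                            c(1, 1, 2))),
               "rank deficiency")
})

test_that("compare_regressions: common, shifted and distinct groups", {
  Ts <- c(15, 20, 25, 30, 35, 40)
  base <- -0.1 * (Ts - 25)^2 + 30
  # all groups from one quadratic, noiseless: F = 0, simplest model wins
  common <- data.frame(T_leaf = rep(Ts, 2), value = rep(base, 2),
                       group = rep(c("a", "b"), each = 6))
  rc <- compare_regressions(common)
  expect_identical(rc$selected, "M0")
  expect_true(all(rc$tests$F == 0))
  expect_true(all(rc$tests$p == 1))

  # intercept shift of 10 with small noise: separate-intercepts model; the
  # F statistic must match a from-scratch extra-sum-of-squares computation
  noise <- .with_seed_test(41, rnorm(12, 0, 0.1))
  shifted <- data.frame(T_leaf = rep(Ts, 2),
                        value = c(base, base + 10) + noise,
                        group = rep(c("a", "b"), each = 6))
  rc2 <- compare_regressions(shifted)
  expect_identical(rc2$selected, "M1")
  lsq_rss <- function(X, y) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  X0 <- cbind(1, shifted$T_leaf, shifted$T_leaf^2)
  X1 <- cbind(X0, shifted$group == "b")
  r0 <- lsq_rss(X0, shifted$value); r1 <- lsq_rss(X1, shifted$value)
  F_hand <- ((r0 - r1) / 1) / (r1 / (12 - 4))
  expect_equal(rc2$tests$F[rc2$tests$comparison == "M0 vs M1"], F_hand,
               tolerance = 1e-8)

  # fully distinct curvatures: advanced model selected
  distinct <- data.frame(
    T_leaf = rep(Ts, 2),
    value = c(base, 0.2 * (Ts - 20)^2 + 5) + noise,
    group = rep(c("a", "b"), each = 6))
  expect_identical(compare_regressions(distinct)$selected, "M2")
})

test_that("rss ordering M0 >= M1 >= M2 holds on random datasets", {
  set.seed(51)
  for (i in 1:30) {
    df <- data.frame(T_leaf = rep(c(15, 20, 25, 30, 35, 40), 2),
                     value = rnorm(12, 20, 5),
                     group = rep(c("a", "b"), each = 6))
    rc <- compare_regressions(df)
    expect_true(rc$rss[["M0"]] >= rc$rss[["M1"]] - 1e-10)
    expect_true(rc$rss[["M1"]] >= rc$rss[["M2"]] - 1e-10)
    expect_true(all(rc$tests$F >= 0))
  }
})

test_that("anova_posthoc: hand-worked one-way decomposition", {
  # integer 3-group textbook case: SSB = 54, SSW = 6, F = 27
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_posthoc(y, g, method = "LSD")
  expect_equal(res$table$SS, c(54, 6))
  expect_equal(res$table$F[1], 27)
  expect_equal(res$table$p[1], pf(27, 2, 6, lower.tail = FALSE))
  # all three groups separated at this effect size
  expect_equal(length(unique(res$groups$letters)), 3)
})

test_that("anova_posthoc: identical groups and pure interaction", {
  same <- anova_posthoc(rep(c(5, 6), 4), rep(c("a", "b"), each = 4))
  expect_equal(same$table$F[1], 0)
  expect_equal(same$table$p[1], 1)
  expect_equal(length(unique(same$groups$letters)), 1)

  # balanced 2x2 with a pure interaction pattern: +d, -d, -d, +d
  d <- 3
  cell <- expand.grid(rep = 1:4, A = c("a1", "a2"), B = c("b1", "b2"))
  mu <- with(cell, ifelse((A == "a1") == (B == "b1"), d, -d))
  y <- mu + .with_seed_test(61, rnorm(nrow(cell), 0, 0.5))
  res <- anova_posthoc(y, cell$A, cell$B)
  Fs <- setNames(res$table$F, res$table$term)
  expect_lt(Fs[["f1"]], qf(0.95, 1, 12))       # main effects ~ null
  expect_lt(Fs[["f2"]], qf(0.95, 1, 12))
  expect_gt(Fs[["f1:f2"]], qf(0.999, 1, 12))   # interaction dominates
  expect_error(anova_posthoc(c(1, 2), c("a", "b")),
               "insufficient replication")
})
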
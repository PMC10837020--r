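# Temperature-response fitting of photosynthetic capacities and assimilation
# (peaked Arrhenius for Vcmax; quadratic for J1500, TPU and An), plus the
# comparative-regression model selection and ANOVA/post-hoc statistics used to
# compare genotypes and night-temperature treatments.

#' Capacity-vs-leaf-temperature series
#'
#' @param trait Trait name (e.g. "Vcmax", "J1500", "TPU", "An", "gs").
#' @param T_leaf Leaf temperatures (degC).
#' @param value Trait values at each temperature.
#' @param replicate Optional replicate ids.
#' @param group Optional single group label (genotype x night-temperature x
#'   leaf-class cell).
#' @return Object of class `thermal_series`.
#' @export
thermal_series <- function(trait, T_leaf, value, replicate = NULL,
                           group = NA_character_) {
  n <- length(T_leaf)
  if (length(value) != n) stop("T_leaf and value lengths differ")
  keep <- is.finite(T_leaf) & is.finite(value)
  structure(list(trait = trait,
                 data = data.frame(
                   T_leaf = T_leaf[keep], value = value[keep],
                   replicate = if (is.null(replicate)) NA_character_
                               else rep_len(replicate, n)[keep]),
                 group = group),
            class = "thermal_series")
}

#' Fit a peaked Arrhenius temperature response
#'
#' Nonlinear least squares fit of [peaked_arrhenius()] to a
#' capacity-vs-temperature series, estimating `k_ref` (value at 25 degC),
#' activation energy `Ea` and entropy factor `dS`, with the deactivation
#' energy `Ed` held fixed (default 200 kJ mol^-1). Five multistart
#' initializations (bounded L-BFGS-B) guard against local minima; the
#' optimum temperature is computed by the closed form [topt_from_peaked()].
#'
#' A series with no interior maximum inside the measured temperature range
#' (e.g. strictly increasing over the range) returns `converged = FALSE`
#' with flag `"no optimum resolvable"` rather than an extrapolated optimum.
#'
#' @param series A [thermal_series()] with >= 4 distinct temperatures
#'   spanning >= 15 degC.
#' @param Ed_fixed Deactivation energy held fixed (kJ mol^-1).
#' @return Object of class `peaked_fit`: `params` (k_ref, Ea, Ed, dS),
#'   `T_opt` (degC), `value_at_Topt`, `rss`, `converged`, `flag`, `se`.
#' @export
fit_peaked <- function(series, Ed_fixed = 200) {
  stopifnot(inherits(series, "thermal_series"))
  d <- series$data
  Tu <- unique(round(d$T_leaf, 6))
  if (length(Tu) < 4)
    stop("insufficient data: peaked fit needs >= 4 distinct temperatures")
  if (diff(range(d$T_leaf)) < 15)
    stop("insufficient data: temperatures must span >= 15 degC")
  TK <- celsius_to_kelvin(d$T_leaf)
  Rk <- .RGAS / 1000

  obj <- function(p) {
    pred <- tryCatch(
      peaked_arrhenius(p[["k_ref"]], p[["Ea"]], Ed_fixed, p[["dS"]], TK),
      error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e12)
    sum((d$value - pred)^2)
  }

  k0 <- d$value[which.min(abs(d$T_leaf - 25))]
  if (k0 <= 0) k0 <- max(mean(abs(d$value)), 1e-3)
  Tpk <- celsius_to_kelvin(d$T_leaf[which.max(d$value)])
  starts <- list(
    c(k_ref = k0, Ea = 65, dS = ds_for_topt(Tpk, 65, Ed_fixed)),
    c(k_ref = k0, Ea = 40, dS = ds_for_topt(Tpk, 40, Ed_fixed)),
    c(k_ref = k0, Ea = 90, dS = ds_for_topt(Tpk + 5, 90, Ed_fixed)),
    c(k_ref = k0 * 0.5, Ea = 65, dS = ds_for_topt(Tpk + 10, 65, Ed_fixed)),
    c(k_ref = k0 * 2, Ea = 50, dS = 0.65))

  lo <- c(k_ref = 1e-6, Ea = 1, dS = 0.05)
  hi <- c(k_ref = 1e5, Ea = Ed_fixed - 1, dS = 3)
  best <- NULL
  for (p0 in starts) {
    fit <- .optim_bounded(p0, obj, lo, hi)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("convergence error: all peaked-fit starts failed")
  pre <- best$value
  best <- .optim_polish(best, obj, lo, hi)
  stationary <- best$convergence == 0 ||
    best$value >= pre * (1 - 1e-8) - 1e-12

  p <- best$par
  topt_K <- tryCatch(topt_from_peaked(p[["Ea"]], Ed_fixed, p[["dS"]]),
                     error = function(e) NA_real_)
  topt_C <- kelvin_to_celsius(topt_K)
  resolved <- is.finite(topt_C) &&
    topt_C >= min(d$T_leaf) && topt_C <= max(d$T_leaf)
  se <- .aci_se(p, obj, best$value, nrow(d))

  structure(list(
    trait = series$trait, group = series$group,
    params = c(k_ref = unname(p[["k_ref"]]), Ea = unname(p[["Ea"]]),
               Ed = Ed_fixed, dS = unname(p[["dS"]])),
    T_opt = if (resolved) topt_C else NA_real_,
    value_at_Topt = if (resolved)
      peaked_arrhenius(p[["k_ref"]], p[["Ea"]], Ed_fixed, p[["dS"]], topt_K)
      else NA_real_,
    rss = best$value, se = se,
    converged = resolved && stationary,
    flag = if (resolved) "ok" else "no optimum resolvable"
  ), class = "peaked_fit")
}

#' @export
print.peaked_fit <- function(x, ...) {
  cat(sprintf("Peaked Arrhenius fit [%s]: ", x$trait))
  if (identical(x$flag, "ok"))
    cat(sprintf("T_opt %.2f degC, value %.2f (Ea %.1f, dS %.4f, Ed %.0f), rss %.4g\n",
                x$T_opt, x$value_at_Topt, x$params[["Ea"]], x$params[["dS"]],
                x$params[["Ed"]], x$rss))
  else cat(x$flag, "\n")
  invisible(x)
}

#' Fit a quadratic temperature response
#'
#' Ordinary least squares fit of `value = a T^2 + b T + c`. The optimum
#' `T_opt = -b / (2a)` and the value there are reported only when the
#' curvature is negative (interior maximum); upward-curving series are
#' flagged `"no optimum in range"`.
#'
#' @param series A [thermal_series()] with >= 3 distinct temperatures.
#' @return Object of class `quad_fit`: `coefficients` (a, b, c), `T_opt`,
#'   `value_at_Topt`, `rss`, `has_optimum`, `flag`.
#' @export
fit_quadratic <- function(series) {
  stopifnot(inherits(series, "thermal_series"))
  d <- series$data
  if (length(unique(round(d$T_leaf, 6))) < 3)
    stop("rank deficiency: quadratic fit needs >= 3 distinct temperatures")
  fit <- stats::lm(value ~ I(T_leaf^2) + T_leaf, data = d)
  if (anyNA(stats::coef(fit)))
    stop("rank deficiency: degenerate design in quadratic fit")
  co <- stats::coef(fit)
  a <- unname(co[["I(T_leaf^2)"]]); b <- unname(co[["T_leaf"]])
  cc <- unname(co[["(Intercept)"]])
  has_opt <- a < 0
  topt <- if (has_opt) -b / (2 * a) else NA_real_
  structure(list(
    trait = series$trait, group = series$group,
    coefficients = c(a = a, b = b, c = cc),
    T_opt = topt,
    value_at_Topt = if (has_opt) a * topt^2 + b * topt + cc else NA_real_,
    rss = sum(stats::resid(fit)^2),
    has_optimum = has_opt,
    flag = if (has_opt) "ok" else "no optimum in range",
    lm = fit
  ), class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("Quadratic fit [%s]: ", x$trait))
  if (x$has_optimum)
    cat(sprintf("T_opt %.2f degC, value %.3f, rss %.4g\n",
                x$T_opt, x$value_at_Topt, x$rss))
  else cat(x$flag, "\n")
  invisible(x)
}

#' Comparative-regression model selection across groups
#'
#' Tests whether one temperature-response quadratic describes all groups
#' (M0, the simplest model) or whether groups need separate intercepts
#' (M1) or fully separate curves (M2, the advanced model), using
#' extra-sum-of-squares F-tests on the nested fits. The simplest model not
#' rejected at `alpha` is selected.
#'
#' @param series_by_group Named list of [thermal_series()], or a data.frame
#'   with columns `T_leaf`, `value`, `group`.
#' @param alpha Significance level for the F-tests (default 0.05).
#' @return Object of class `regression_comparison`: per-model `rss`, `df`,
#'   the F-test table (`comparison`, `F`, `df1`, `df2`, `p`) and
#'   `selected` (one of "M0", "M1", "M2").
#' @export
compare_regressions <- function(series_by_group, alpha = 0.05) {
  if (is.list(series_by_group) && !is.data.frame(series_by_group)) {
    df <- do.call(rbind, lapply(names(series_by_group), function(g) {
      s <- series_by_group[[g]]
      data.frame(T_leaf = s$data$T_leaf, value = s$data$value, group = g)
    }))
  } else df <- series_by_group
  df$group <- factor(df$group)
  if (nlevels(df$group) < 2)
    stop("compare_regressions needs >= 2 groups")
  for (g in levels(df$group)) {
    if (length(unique(round(df$T_leaf[df$group == g], 6))) < 3)
      stop("degenerate group for quadratic fit: ", g)
  }
  m0 <- stats::lm(value ~ I(T_leaf^2) + T_leaf, data = df)
  m1 <- stats::lm(value ~ group + I(T_leaf^2) + T_leaf, data = df)
  m2 <- stats::lm(value ~ group * (I(T_leaf^2) + T_leaf), data = df)
  rss <- vapply(list(M0 = m0, M1 = m1, M2 = m2),
                function(m) sum(stats::resid(m)^2), numeric(1))
  dfres <- vapply(list(M0 = m0, M1 = m1, M2 = m2),
                  function(m) stats::df.residual(m), numeric(1))

  ftest <- function(red, full) {
    d1 <- dfres[[red]] - dfres[[full]]
    d2 <- dfres[[full]]
    num <- max(rss[[red]] - rss[[full]], 0)
    if (num <= 1e-12 * max(rss[[red]], 1e-12) || d2 <= 0) {
      Fv <- 0; p <- 1
    } else if (rss[[full]] <= 1e-12 * num) {
      Fv <- Inf; p <- 0
    } else {
      Fv <- (num / d1) / (rss[[full]] / d2)
      p <- stats::pf(Fv, d1, d2, lower.tail = FALSE)
    }
    data.frame(comparison = paste(red, "vs", full), F = Fv,
               df1 = d1, df2 = d2, p = p)
  }
  tests <- rbind(ftest("M0", "M1"), ftest("M1", "M2"), ftest("M0", "M2"))

  p01 <- tests$p[1]; p12 <- tests$p[2]; p02 <- tests$p[3]
  selected <- if (p02 >= alpha && p01 >= alpha) "M0"
              else if (p12 >= alpha) "M1" else "M2"
  structure(list(rss = rss, df_residual = dfres, tests = tests,
                 selected = selected, alpha = alpha,
                 models = list(M0 = m0, M1 = m1, M2 = m2)),
            class = "regression_comparison")
}

#' @export
print.regression_comparison <- function(x, ...) {
  cat("Comparative regression (common vs separate quadratics)\n")
  print(data.frame(model = names(x$rss), rss = unname(x$rss),
                   df_residual = unname(x$df_residual)), row.names = FALSE)
  print(x$tests, row.names = FALSE)
  cat("Selected model (alpha =", x$alpha, "):", x$selected, "\n")
  invisible(x)
}

#' ANOVA with post-hoc mean separation letters
#'
#' One- or two-way fixed-effects ANOVA on replicate values, with pairwise
#' mean separation by Fisher's LSD or Tukey's HSD and compact letter
#' display. Two factors are crossed with interaction (genotype x night
#' temperature layout); post-hoc comparisons are run on the cell
#' (factor-combination) means.
#'
#' @param values Numeric response vector.
#' @param f1 First factor (coerced to factor).
#' @param f2 Optional second factor; if supplied, the model is
#'   `values ~ f1 * f2`.
#' @param method "HSD" (Tukey, default) or "LSD" (Fisher).
#' @param alpha Significance level for letters (default 0.05).
#' @return Object of class `anova_posthoc`: `table` (SS, df, MS, F, p per
#'   term), `groups` (cell means, n, letters), `method`, `alpha`.
#' @export
anova_posthoc <- function(values, f1, f2 = NULL, method = c("HSD", "LSD"),
                          alpha = 0.05) {
  method <- match.arg(method)
  f1 <- factor(f1)
  d <- data.frame(y = values, f1 = f1)
  if (!is.null(f2)) d$f2 <- factor(f2)
  cell <- if (is.null(f2)) d$f1 else interaction(d$f1, d$f2, sep = ":")
  if (nlevels(droplevels(cell)) < 2) stop("need >= 2 groups")
  if (any(table(droplevels(cell)) < 2) ||
      length(values) - nlevels(droplevels(cell)) <= 0)
    stop("insufficient replication: zero error degrees of freedom")

  form <- if (is.null(f2)) y ~ f1 else y ~ f1 * f2
  fit <- stats::aov(form, data = d)
  an <- stats::anova(fit)
  tab <- data.frame(term = rownames(an), df = an$Df, SS = an$`Sum Sq`,
                    MS = an$`Mean Sq`, F = an$`F value`, p = an$`Pr(>F)`,
                    row.names = NULL)
  # identical groups give 0/0; report F = 0, p = 1
  zero <- !is.na(tab$F) & tab$SS < 1e-12 * max(sum(tab$SS), 1e-12)
  tab$F[zero] <- 0; tab$p[zero] <- 1
  if (all(tab$SS[-nrow(tab)] < 1e-12) && tab$SS[nrow(tab)] < 1e-12) {
    tab$F[-nrow(tab)] <- 0; tab$p[-nrow(tab)] <- 1
  }

  cell <- droplevels(cell)
  mse <- tab$MS[nrow(tab)]
  dfe <- tab$df[nrow(tab)]
  means <- tapply(d$y, cell, mean)
  ns <- tapply(d$y, cell, length)
  letters <- .cld_letters(means, ns, mse, dfe, method, alpha)
  groups <- data.frame(group = names(means), mean = as.numeric(means),
                       n = as.numeric(ns),
                       letters = letters[names(means)],
                       row.names = NULL)
  groups <- groups[order(-groups$mean), ]
  structure(list(table = tab, groups = groups, method = method,
                 alpha = alpha),
            class = "anova_posthoc")
}

# pairwise significance matrix -> compact letters. Groups are ordered by
# decreasing mean; each group's non-significant neighbourhood is treated as
# an interval in that order (exact for balanced designs), intervals are
# deduplicated and lettered.
#' @keywords internal
.cld_letters <- function(means, ns, mse, dfe, method, alpha) {
  g <- length(means)
  ord <- order(-means)
  m <- means[ord]; n <- ns[ord]
  sig <- matrix(FALSE, g, g)
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    sed <- sqrt(mse * (1 / n[i] + 1 / n[j]))
    if (mse <= 0 || sed == 0) { sig[i, j] <- sig[j, i] <- abs(m[i] - m[j]) > 0; next }
    if (method == "LSD") {
      p <- 2 * stats::pt(abs(m[i] - m[j]) / sed, dfe, lower.tail = FALSE)
    } else {
      p <- stats::ptukey(abs(m[i] - m[j]) / (sed / sqrt(2)), g, dfe,
                         lower.tail = FALSE)
    }
    sig[i, j] <- sig[j, i] <- p < alpha
  }
  intervals <- unique(lapply(seq_len(g), function(i) {
    lo <- i; hi <- i
    while (lo > 1 && !sig[i, lo - 1]) lo <- lo - 1
    while (hi < g && !sig[i, hi + 1]) hi <- hi + 1
    c(lo, hi)
  }))
  keep <- vapply(seq_along(intervals), function(k) {
    !any(vapply(intervals[-k], function(iv)
      iv[1] <= intervals[[k]][1] && iv[2] >= intervals[[k]][2] &&
        !identical(iv, intervals[[k]]), logical(1)))
  }, logical(1))
  intervals <- intervals[keep]
  intervals <- intervals[order(vapply(intervals, `[`, numeric(1), 1))]
  lett <- rep("", g)
  for (k in seq_along(intervals)) {
    iv <- intervals[[k]]
    lett[iv[1]:iv[2]] <- paste0(lett[iv[1]:iv[2]], letters[k])
  }
  out <- stats::setNames(lett, names(m))
  out[names(means)]
}

#' @export
print.anova_posthoc <- function(x, ...) {
  cat(sprintf("ANOVA with %s post-hoc (alpha %.2f)\n", x$method, x$alpha))
  print(x$table, row.names = FALSE)
  print(x$groups, row.names = FALSE)
  invisible(x)
}
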
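# A-Ci curve fitting: estimate Vcmax, J1500, TPU (and optionally Rd) from one
# CO2-response curve at one leaf temperature by nonlinear least squares on the
# full min-rule forward model. No user-specified limitation transition point:
# the fitted model assigns limitations per observation.

# physiological parameter envelopes used to stabilize multistart
.ACI_LOWER <- c(Vcmax = 1e-3, J = 1e-3, TPU = 1e-3, Rd = 0)
.ACI_UPPER <- c(Vcmax = 1500, J = 800, TPU = 60, Rd = 10)

#' Construct an A-Ci curve
#'
#' One CO2-response curve measured on one leaf at one (approximately
#' constant) leaf temperature and saturating irradiance. The standard
#' measurement protocol steps chamber CO2 through
#' 30, 50, 100, 150, 250, 400, 400, 600, 800, 1000, 1200, 1400, 400
#' umol mol^-1; the duplicated 400 points (two mid-sequence, one final
#' recovery) are all retained.
#'
#' @param Ci Intercellular CO2 mole fraction (umol mol^-1), > 0.
#' @param An Net assimilation (umol m^-2 s^-1).
#' @param T_leaf Leaf temperature (degC); scalar or per-observation. All
#'   temperatures within a curve must agree to < 1.5 degC.
#' @param irradiance Photon flux (umol m^-2 s^-1), nominally 1500.
#' @param pressure Atmospheric pressure (kPa).
#' @param genotype,night_temp,leaf_class,replicate Metadata carried through
#'   to fits and pooling.
#' @return An object of class `aci_curve`.
#' @export
aci_curve <- function(Ci, An, T_leaf, irradiance = 1500, pressure = 96,
                      genotype = NA_character_, night_temp = NA_real_,
                      leaf_class = "newly developed",
                      replicate = NA_character_) {
  n <- length(Ci)
  if (length(An) != n) stop("Ci and An lengths differ")
  if (n < 6) stop("insufficient data: an A-Ci curve needs >= 6 observations")
  if (any(!is.finite(Ci)) || any(Ci <= 0)) stop("invalid input: Ci must be > 0")
  T_leaf <- rep_len(T_leaf, n)
  if (diff(range(T_leaf)) >= 1.5)
    stop("invalid input: leaf temperatures within one curve differ by >= 1.5 degC")
  structure(list(
    data = data.frame(Ci = Ci, An = An, T_leaf = T_leaf,
                      irradiance = rep_len(irradiance, n),
                      pressure = rep_len(pressure, n)),
    genotype = genotype, night_temp = night_temp,
    leaf_class = leaf_class, replicate = replicate
  ), class = "aci_curve")
}

#' @export
print.aci_curve <- function(x, ...) {
  cat(sprintf("A-Ci curve: %d points, T_leaf %.1f degC, genotype %s, night %s degC\n",
              nrow(x$data), mean(x$data$T_leaf), x$genotype,
              format(x$night_temp)))
  invisible(x)
}

# residual sum of squares of the forward model against a curve
#' @keywords internal
.aci_rss <- function(par, Ci_pa, An_obs, T_K, cfg) {
  cap <- list(Vcmax = par[["Vcmax"]], J = par[["J"]],
              TPU = par[["TPU"]], Rd = par[["Rd"]])
  pred <- tryCatch(net_assimilation(Ci_pa, T_K, cfg, cap)$An,
                   error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred))) return(1e12)
  sum((An_obs - pred)^2)
}

# deterministic starts (coarse grid plus single-point inversions of each
# limitation formula at the temperature-scaled kinetics) and seeded random
# starts (seed 1704)
#' @keywords internal
.aci_starts <- function(An_obs, Ci_pa, kin, fit_Rd, n_random = 3,
                        seed = 1704) {
  Amax <- max(An_obs)
  Rd0 <- if (fit_Rd) max(0.5, -min(An_obs)) else 0
  clamp <- function(x, lo, hi) min(hi, max(lo, x))
  # invert Ac at low-Ci points and Aj at mid-Ci points, taking Cc ~ Ci;
  # over-estimates when the point is limited by another process, which is
  # exactly what a multistart needs to seed distinct basins
  inv_v <- function(i) (An_obs[i] + Rd0) * (Ci_pa[i] + kin$Kair_pa) /
    (Ci_pa[i] - kin$gammastar_pa)
  inv_j <- function(i) (An_obs[i] + Rd0) *
    (4 * Ci_pa[i] + 8 * kin$gammastar_pa) / (Ci_pa[i] - kin$gammastar_pa)
  lowi <- order(Ci_pa)[3:4]
  midi <- order(Ci_pa)[c(8, 10)]
  v0 <- vapply(lowi, function(i)
    clamp(inv_v(i), 10, 1400), numeric(1))
  j0 <- clamp(mean(vapply(midi, inv_j, numeric(1))), 10, 780)
  tpu0 <- clamp((Amax + Rd0) / 3, 1, 55)
  scaled <- function(f) c(Vcmax = clamp(f * 4 * (Amax + Rd0), 5, 1400),
                          J = clamp(f * 5 * (Amax + Rd0), 5, 780),
                          TPU = clamp(f * (Amax + Rd0) / 2.5, 0.5, 55),
                          Rd = Rd0)
  starts <- list(
    c(Vcmax = 100, J = 150, TPU = 10, Rd = Rd0),
    c(Vcmax = v0[1], J = j0, TPU = tpu0, Rd = Rd0),
    c(Vcmax = v0[2], J = j0, TPU = tpu0, Rd = Rd0),
    c(Vcmax = v0[2] * 1.5, J = j0, TPU = tpu0, Rd = Rd0),
    scaled(0.5), scaled(1), scaled(2),
    c(Vcmax = 50, J = 80, TPU = 5, Rd = Rd0),
    c(Vcmax = 400, J = 300, TPU = 20, Rd = Rd0),
    c(Vcmax = 800, J = 500, TPU = 40, Rd = Rd0))
  rng <- .with_seed(seed, replicate(n_random, {
    c(Vcmax = stats::runif(1, 20, 1000), J = stats::runif(1, 20, 600),
      TPU = stats::runif(1, 2, 50), Rd = stats::runif(1, 0, 5))
  }, simplify = FALSE))
  c(starts, rng)
}

#' Fit the FvCB model to one A-Ci curve
#'
#' Minimizes the residual sum of squares between observed An and the
#' min-rule forward model ([net_assimilation()]) over the capacity
#' parameters, letting the fitted model assign the limiting process at each
#' observation. Mesophyll conductance is fixed from `cfg` (temperature-
#' scaled), never fitted. Bounded multistart optimization (7 deterministic +
#' 3 seeded random starts, L-BFGS-B) guards against local minima.
#'
#' If no observation is TPU-limited at the optimum, `TPU` is not
#' identifiable from the curve and is reported as a lower bound with
#' `tpu_identifiable = FALSE`.
#'
#' A QC warning (not an exclusion) is raised when the final 400 umol mol^-1
#' recovery point deviates more than 15% from the mean of the mid-sequence
#' 400 points (instrument drift check).
#'
#' @param curve An [aci_curve()].
#' @param cfg A [kinetic_config()].
#' @param fit_Rd Fit day respiration (default TRUE)? If FALSE, Rd is fixed
#'   at `Rd_fixed` and absorbed by Vcmax/J.
#' @param Rd_fixed Value of Rd when `fit_Rd = FALSE`.
#' @param n_random Number of seeded random multistarts (default 3).
#' @param seed Seed for the random starts (default 1704).
#' @return An object of class `aci_fit` with elements `cap`
#'   ([photo_capacity()] at the curve temperature), `T_leaf` (degC), `rss`,
#'   `se` (approximate, from the residual-weighted numerical Hessian),
#'   `limitation_labels`, `tpu_identifiable`, `converged`, `n_used`, and the
#'   curve metadata.
#' @export
fit_aci <- function(curve, cfg, fit_Rd = TRUE, Rd_fixed = 0,
                    n_random = 3, seed = 1704) {
  stopifnot(inherits(curve, "aci_curve"))
  d <- curve$data
  ok <- is.finite(d$Ci) & is.finite(d$An)
  d <- d[ok, , drop = FALSE]
  if (nrow(d) < 6)
    stop("insufficient data: fewer than 6 usable observations")
  .qc_recovery_point(d)

  T_K <- celsius_to_kelvin(mean(d$T_leaf))
  Ci_pa <- to_partial_pressure(d$Ci, cfg$pressure)

  free <- if (fit_Rd) c("Vcmax", "J", "TPU", "Rd") else c("Vcmax", "J", "TPU")
  obj <- function(p) {
    par <- c(p, if (!fit_Rd) c(Rd = Rd_fixed))
    .aci_rss(par, Ci_pa, d$An, T_K, cfg)
  }

  best <- NULL
  for (st in .aci_starts(d$An, Ci_pa, .kinetics_at(cfg, T_K), fit_Rd,
                         n_random, seed)) {
    p0 <- st[free]
    fit <- .optim_bounded(p0, obj, .ACI_LOWER[free], .ACI_UPPER[free])
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("convergence error: all multistart optimizations failed")
  pre <- best$value
  best <- .optim_polish(best, obj, .ACI_LOWER[free], .ACI_UPPER[free])
  # L-BFGS-B line searches can abort on the min-rule kinks even at the
  # optimum; treat a polish pass with no meaningful improvement as converged
  stationary <- best$convergence == 0 ||
    best$value >= pre * (1 - 1e-8) - 1e-12

  par <- c(best$par, if (!fit_Rd) c(Rd = Rd_fixed))
  cap <- photo_capacity(par[["Vcmax"]], par[["J"]], par[["TPU"]], par[["Rd"]])
  pred <- net_assimilation(Ci_pa, T_K, cfg, cap)
  tpu_ok <- any(pred$limitation == "tpu")
  se <- .aci_se(best$par, obj, best$value, nrow(d))

  structure(list(
    cap = cap, T_leaf = mean(d$T_leaf), rss = best$value, se = se,
    limitation_labels = pred$limitation, tpu_identifiable = tpu_ok,
    converged = stationary, n_used = nrow(d),
    genotype = curve$genotype, night_temp = curve$night_temp,
    leaf_class = curve$leaf_class, replicate = curve$replicate
  ), class = "aci_fit")
}

#' @keywords internal
.qc_recovery_point <- function(d) {
  is400 <- abs(d$Ci - 400) < 25
  if (sum(is400) >= 2) {
    idx <- which(is400)
    final <- idx[length(idx)]
    mid <- idx[idx < final]
    if (length(mid) && final == nrow(d)) {
      m <- mean(d$An[mid])
      if (is.finite(m) && abs(m) > 1e-9 && abs(d$An[final] - m) / abs(m) > 0.15)
        warning("QC: final 400 umol mol-1 recovery An deviates > 15% from ",
                "mid-sequence mean (possible drift); points retained",
                call. = FALSE)
    }
  }
  invisible(NULL)
}

# approximate standard errors from a numerical Hessian of rss/2 scaled by
# the residual variance; NA when the Hessian is not positive definite
#' @keywords internal
.aci_se <- function(par, obj, rss, n) {
  k <- length(par)
  if (n <= k) return(stats::setNames(rep(NA_real_, k), names(par)))
  s2 <- rss / (n - k)
  H <- tryCatch(stats::optimHess(par, obj), error = function(e) NULL)
  if (is.null(H)) return(stats::setNames(rep(NA_real_, k), names(par)))
  cov <- tryCatch(solve(H / 2) * s2, error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) < 0))
    return(stats::setNames(rep(NA_real_, k), names(par)))
  stats::setNames(sqrt(diag(cov)), names(par))
}

#' @export
print.aci_fit <- function(x, ...) {
  cat(sprintf("FvCB fit at %.1f degC (rss %.4g, n %d, converged %s)\n",
              x$T_leaf, x$rss, x$n_used, x$converged))
  print(x$cap)
  if (!x$tpu_identifiable)
    cat("  note: no TPU-limited observation; TPU is a lower bound\n")
  invisible(x)
}

#' Standardize fitted capacities to a reference temperature
#'
#' Rescales each capacity by the ratio of its temperature-response function
#' at `T_to` versus `T_from`. Scaling parameters are supplied per trait as
#' either `list(Ea = ...)` (simple Arrhenius) or
#' `list(Ea = ..., Ed = ..., dS = ...)` (peaked). Identity when
#' `T_from == T_to`. `Rd` is carried through unscaled unless a scaling entry
#' is supplied for it.
#'
#' @param cap A [photo_capacity()] (or an `aci_fit`, whose `cap` is used).
#' @param T_from Temperature the capacities refer to (degC).
#' @param T_to Target temperature (degC), e.g. 25 or 28.
#' @param scaling Named list of per-trait scaling parameters, names among
#'   `Vcmax`, `J`, `TPU`, `Rd`.
#' @return A [photo_capacity()] at `T_to`.
#' @export
standardize_capacity <- function(cap, T_from, T_to, scaling) {
  if (inherits(cap, "aci_fit")) cap <- cap$cap
  if (T_from <= 0 || T_from >= 60 || T_to <= 0 || T_to >= 60)
    stop("invalid parameter: temperatures must lie in (0, 60) degC")
  if (T_from == T_to) return(cap)
  Tf <- celsius_to_kelvin(T_from); Tt <- celsius_to_kelvin(T_to)
  ratio <- function(p) {
    if (is.null(p)) return(NULL)
    if (!is.null(p$Ed) && !is.null(p$dS))
      peaked_arrhenius(1, p$Ea, p$Ed, p$dS, Tt) /
        peaked_arrhenius(1, p$Ea, p$Ed, p$dS, Tf)
    else if (!is.null(p$Ea))
      arrhenius_scale(1, p$Ea, Tt) / arrhenius_scale(1, p$Ea, Tf)
    else stop("configuration error: scaling entry lacks Ea")
  }
  out <- unclass(cap)
  for (tr in c("Vcmax", "J", "TPU")) {
    r <- ratio(scaling[[tr]])
    if (is.null(r))
      stop("configuration error: missing scaling parameters for trait ", tr)
    out[[tr]] <- out[[tr]] * r
  }
  rR <- ratio(scaling[["Rd"]])
  if (!is.null(rR)) out$Rd <- out$Rd * rR
  photo_capacity(out$Vcmax, out$J, out$TPU, out$Rd)
}

#' Pool A-Ci fits into capacity-vs-temperature series
#'
#' Aggregates a list of `aci_fit` objects into per-cell (grouping variable
#' combination) means, SDs and counts for each capacity, and returns both
#' the cell summary and the point-level long table used for
#' temperature-response fitting. Cells with no fits are absent, not
#' zero-filled.
#'
#' @param fits List of `aci_fit` objects.
#' @param by Character vector of grouping fields; any of `genotype`,
#'   `night_temp`, `leaf_class`, `T_leaf` (default all four).
#' @return A list with `points` (long data.frame: grouping fields, trait,
#'   value, replicate) and `summary` (grouping fields, trait, mean, sd, n).
#' @export
pool_fits <- function(fits, by = c("genotype", "night_temp",
                                   "leaf_class", "T_leaf")) {
  if (!length(fits)) stop("aggregation error: no fits supplied")
  rows <- lapply(fits, function(f) {
    data.frame(genotype = f$genotype, night_temp = f$night_temp,
               leaf_class = f$leaf_class, T_leaf = f$T_leaf,
               replicate = f$replicate,
               trait = c("Vcmax", "J1500", "TPU", "Rd"),
               value = c(f$cap$Vcmax, f$cap$J, f$cap$TPU, f$cap$Rd),
               stringsAsFactors = FALSE)
  })
  points <- do.call(rbind, rows)
  agg <- stats::aggregate(points$value,
                          by = c(points[by], list(trait = points$trait)),
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  summary <- cbind(agg[setdiff(names(agg), "x")], as.data.frame(agg$x))
  list(points = points, summary = summary)
}
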
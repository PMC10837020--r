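# Critical temperature of PSII (Tcrit) from minimum-fluorescence (F0)
# temperature ramps. Tcrit is the intersection of two regression lines fitted
# to the flat (baseline) and steep (rise) portions of the F0-temperature
# curve; the segment boundary is chosen by exhaustive two-segment least
# squares over every admissible split, which is reproducible and
# operator-free.

#' Construct a fluorescence temperature ramp
#'
#' A continuous F0 trace recorded while leaf temperature ramps at a nominal
#' 1 degC min^-1 (20 to 65 degC in the standard protocol).
#'
#' @param temperature Strictly increasing temperatures (degC).
#' @param F0 Minimum chlorophyll a fluorescence (arbitrary units), > 0.
#' @param ramp_rate Nominal ramp rate (degC min^-1).
#' @param genotype,night_temp,leaf_class,replicate Metadata.
#' @return Object of class `fluorescence_ramp`.
#' @export
fluorescence_ramp <- function(temperature, F0, ramp_rate = 1,
                              genotype = NA_character_,
                              night_temp = NA_real_,
                              leaf_class = "newly developed",
                              replicate = NA_character_) {
  if (length(temperature) != length(F0))
    stop("temperature and F0 lengths differ")
  if (any(diff(temperature) <= 0))
    stop("invalid input: temperatures must be strictly increasing")
  if (length(temperature) < 50 || diff(range(temperature)) < 30)
    stop("invalid input: a ramp needs >= 50 samples spanning >= 30 degC")
  if (any(!is.finite(F0)) || any(F0 <= 0))
    stop("invalid input: F0 must be finite and > 0")
  structure(list(temperature = temperature, F0 = F0, ramp_rate = ramp_rate,
                 genotype = genotype, night_temp = night_temp,
                 leaf_class = leaf_class, replicate = replicate),
            class = "fluorescence_ramp")
}

#' Moving-average smoothing of a ramp
#'
#' Centered moving average over a temperature window; endpoints use
#' shrunken (one-sided) windows. `window = 0` returns the input unchanged.
#'
#' @param ramp A [fluorescence_ramp()].
#' @param window Full smoothing window (degC), >= 0 and at most half the
#'   ramp span.
#' @return A smoothed [fluorescence_ramp()].
#' @export
smooth_ramp <- function(ramp, window) {
  stopifnot(inherits(ramp, "fluorescence_ramp"))
  if (!is.finite(window) || window < 0)
    stop("invalid parameter: window must be >= 0")
  if (window == 0) return(ramp)
  span <- diff(range(ramp$temperature))
  if (window > span / 2)
    stop("invalid parameter: window exceeds half the ramp span")
  tt <- ramp$temperature
  half <- window / 2
  sm <- vapply(seq_along(tt), function(i) {
    mean(ramp$F0[tt >= tt[i] - half & tt <= tt[i] + half])
  }, numeric(1))
  out <- ramp
  out$F0 <- sm
  out
}

# OLS slope/intercept/rss for every prefix (and via reversal, suffix) of
# (x, y) in O(n) using running sums.
#' @keywords internal
.prefix_ols <- function(x, y) {
  n <- length(x)
  sx <- cumsum(x); sy <- cumsum(y)
  sxx <- cumsum(x^2); sxy <- cumsum(x * y); syy <- cumsum(y^2)
  k <- seq_len(n)
  vx <- sxx - sx^2 / k
  cxy <- sxy - sx * sy / k
  slope <- ifelse(vx > 0, cxy / vx, 0)
  intercept <- (sy - slope * sx) / k
  rss <- pmax(syy - sy^2 / k - ifelse(vx > 0, cxy^2 / vx, 0), 0)
  list(slope = slope, intercept = intercept, rss = rss, vx = vx)
}

#' Estimate Tcrit from an F0 temperature ramp
#'
#' Fits two regression lines to the flat and steep portions of the
#' F0-temperature curve and returns their intersection as Tcrit. The
#' flat/steep boundary is chosen by exhaustive search over all admissible
#' splits (each segment at least `max(min_seg, ceil(min_seg_frac * n))`
#' points), minimizing the combined two-segment residual sum of squares.
#' Samples above the F0 maximum (the post-peak decline near the top of the
#' ramp) are excluded before fitting, since the method targets the initial
#' rise. A breakpoint is only declared when the steep slope exceeds
#' `slope_ratio * |flat slope| + 3 * residual SD per degC`; below this
#' contrast (e.g. a flat trace) a no-breakpoint error is raised rather than
#' a fabricated Tcrit.
#'
#' @param ramp A [fluorescence_ramp()].
#' @param smooth_window Moving-average window applied first (degC; default
#'   0.5; 0 disables).
#' @param min_seg_frac Minimum fraction of samples per segment (default 0.1).
#' @param min_seg Absolute minimum samples per segment (default 5).
#' @param slope_ratio Required steep:flat slope contrast (default 5).
#' @return Object of class `tcrit_result`: `Tcrit` (degC), `flat_line` and
#'   `steep_line` (slope, intercept), `breakpoint` (degC), `rss_total`,
#'   `in_range` flag, per-segment `r_squared` and `n`, and the ramp
#'   metadata.
#' @export
estimate_tcrit <- function(ramp, smooth_window = 0.5, min_seg_frac = 0.1,
                           min_seg = 5, slope_ratio = 5) {
  stopifnot(inherits(ramp, "fluorescence_ramp"))
  sm <- smooth_ramp(ramp, smooth_window)
  peak <- which.max(sm$F0)
  x <- sm$temperature[seq_len(peak)]
  y <- sm$F0[seq_len(peak)]
  n <- length(x)
  m <- max(min_seg, ceiling(min_seg_frac * n))
  if (n < 2 * m)
    stop("no breakpoint: too few samples before the F0 peak")

  fwd <- .prefix_ols(x, y)
  rev_ <- .prefix_ols(rev(x), rev(y))
  ks <- m:(n - m)                       # boundary: flat = 1..k, steep = k+1..n
  total <- fwd$rss[ks] + rev_$rss[n - ks]
  k <- ks[which.min(total)]

  a1 <- fwd$slope[k]; b1 <- fwd$intercept[k]
  a2 <- rev_$slope[n - k]; b2 <- rev_$intercept[n - k]
  steep_n <- n - k
  resid_sd <- sqrt((fwd$rss[k] + rev_$rss[n - k]) / max(n - 4, 1))
  if (a2 <= a1 || a2 < slope_ratio * abs(a1) + 3 * resid_sd)
    stop("no breakpoint: steep/flat slope contrast below threshold ",
         "(steep ", signif(a2, 4), ", flat ", signif(a1, 4), ")")

  tcrit <- (b1 - b2) / (a2 - a1)
  in_range <- tcrit >= min(ramp$temperature) && tcrit <= max(ramp$temperature)
  r2 <- function(rss, yy) {
    tot <- sum((yy - mean(yy))^2)
    if (tot <= 0) 1 else 1 - rss / tot
  }
  structure(list(
    Tcrit = tcrit,
    flat_line = c(slope = a1, intercept = b1),
    steep_line = c(slope = a2, intercept = b2),
    breakpoint = x[k], rss_total = unname(min(total)),
    in_range = in_range,
    r_squared = c(flat = r2(fwd$rss[k], y[1:k]),
                  steep = r2(rev_$rss[n - k], y[(k + 1):n])),
    n = c(flat = k, steep = steep_n),
    genotype = ramp$genotype, night_temp = ramp$night_temp,
    leaf_class = ramp$leaf_class, replicate = ramp$replicate
  ), class = "tcrit_result")
}

#' @export
print.tcrit_result <- function(x, ...) {
  cat(sprintf("Tcrit %.2f degC (breakpoint %.2f; flat slope %.3f, steep slope %.3f%s)\n",
              x$Tcrit, x$breakpoint, x$flat_line[["slope"]],
              x$steep_line[["slope"]],
              if (x$in_range) "" else "; OUT OF RAMP RANGE"))
  invisible(x)
}

#' Summarize Tcrit results by group
#'
#' Per genotype x night-temperature x leaf-class mean, SD and n of Tcrit,
#' in a shape that feeds directly into [anova_posthoc()].
#'
#' @param results List of `tcrit_result` objects.
#' @param by Grouping fields (default genotype, night_temp, leaf_class).
#' @return A list with `summary` (group means, SD, n) and `values` (long
#'   per-replicate table).
#' @export
summarize_tcrit <- function(results,
                            by = c("genotype", "night_temp", "leaf_class")) {
  if (!length(results)) stop("empty group: no Tcrit results supplied")
  values <- do.call(rbind, lapply(results, function(r) {
    data.frame(genotype = r$genotype, night_temp = r$night_temp,
               leaf_class = r$leaf_class, replicate = r$replicate,
               Tcrit = r$Tcrit, stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(values$Tcrit, by = values[by],
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  summary <- cbind(agg[setdiff(names(agg), "x")], as.data.frame(agg$x))
  list(summary = summary, values = values)
}
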
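# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards. Keeps every stochastic routine reproducible without
# side effects on the session.
#' @keywords internal
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# bounded L-BFGS-B with parameter-relative finite-difference steps; NULL on
# failure so multistart loops can skip bad starts
#' @keywords internal
.optim_bounded <- function(p0, obj, lower, upper, maxit = 500) {
  tryCatch(
    stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = maxit, factr = 1e4,
                                parscale = pmax(abs(p0), 1e-2),
                                ndeps = pmax(abs(p0), 1e-2) * 1e-7)),
    error = function(e) NULL)
}

# refinement pass from the incumbent optimum; gradient steps sized to the
# incumbent parameters recover the last digits lost to the coarse default
#' @keywords internal
.optim_polish <- function(best, obj, lower, upper) {
  pol <- .optim_bounded(best$par, obj, lower, upper)
  if (!is.null(pol) && pol$value <= best$value) pol else best
}
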
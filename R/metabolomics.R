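# GC-MS metabolite table statistics: the normalization chain (internal
# standard -> fresh mass -> per-compound average-signal weighting), PCA, a
# permutation-based multivariate ANOVA (PERMANOVA, squared Euclidean distance
# on autoscaled abundances), and consistent-responder ranking.

#' Construct a metabolite abundance table
#'
#' Samples x compounds abundance matrix with the per-sample internal
#' standard signal and fresh mass used for normalization, per-compound
#' class labels, and sample metadata.
#'
#' @param abundances Numeric matrix (samples x compounds), non-negative;
#'   NAs allowed (imputed during normalization as half the compound's
#'   minimum observed value, a common GC-MS convention).
#' @param istd_signal Per-sample internal-standard signal, > 0.
#' @param fresh_mass Per-sample fresh mass (g), > 0.
#' @param compound_class Per-compound class labels ("unknown" permitted).
#' @param genotype,night_temp Per-sample metadata.
#' @param normalized Internal flag; do not set.
#' @return Object of class `metabolite_table`.
#' @export
metabolite_table <- function(abundances, istd_signal, fresh_mass,
                             compound_class = NULL,
                             genotype = NULL, night_temp = NULL,
                             normalized = FALSE) {
  abundances <- as.matrix(abundances)
  n <- nrow(abundances); p <- ncol(abundances)
  if (is.null(colnames(abundances)))
    colnames(abundances) <- paste0("compound_", seq_len(p))
  if (any(abundances < 0, na.rm = TRUE))
    stop("invalid input: negative abundances")
  if (length(istd_signal) != n || any(istd_signal <= 0))
    stop("invalid input: istd_signal must be per-sample and > 0")
  if (length(fresh_mass) != n || any(fresh_mass <= 0))
    stop("invalid input: fresh_mass must be per-sample and > 0")
  if (is.null(compound_class)) compound_class <- rep("unknown", p)
  if (length(compound_class) != p)
    stop("invalid input: compound_class must cover all compounds")
  structure(list(
    abundances = abundances,
    istd_signal = istd_signal, fresh_mass = fresh_mass,
    compound_class = stats::setNames(as.character(compound_class),
                                     colnames(abundances)),
    genotype = if (is.null(genotype)) rep(NA_character_, n) else genotype,
    night_temp = if (is.null(night_temp)) rep(NA_real_, n) else night_temp,
    normalized = normalized
  ), class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("Metabolite table: %d samples x %d compounds (%s), %d classes\n",
              nrow(x$abundances), ncol(x$abundances),
              if (x$normalized) "normalized" else "raw",
              length(unique(x$compound_class))))
  invisible(x)
}

#' Normalize a metabolite abundance table
#'
#' Applies the three-step normalization chain: each sample's abundances are
#' divided by its internal-standard signal relative to the mean signal
#' (`istd_i / mean(istd)`) and by its fresh mass; each compound is then
#' weighted by (divided by) its across-sample mean, so every compound has a
#' post-normalization mean of exactly 1. Missing values are first imputed
#' as half the compound's minimum observed abundance (count reported in
#' attribute `n_imputed`); all-zero compounds cannot be mean-weighted and
#' are excluded with a warning.
#'
#' @param raw A [metabolite_table()].
#' @return A normalized [metabolite_table()] (with `istd_signal` and
#'   `fresh_mass` reset to 1, since their effect has been removed).
#' @export
normalize_abundance <- function(raw) {
  stopifnot(inherits(raw, "metabolite_table"))
  A <- raw$abundances
  n_imp <- 0L
  for (j in seq_len(ncol(A))) {
    na <- is.na(A[, j])
    if (any(na)) {
      obs <- A[!na, j]
      A[na, j] <- if (length(obs)) min(obs) / 2 else 0
      n_imp <- n_imp + sum(na)
    }
  }
  A <- A / (raw$istd_signal / mean(raw$istd_signal)) / raw$fresh_mass
  cm <- colMeans(A)
  dead <- cm <= 0
  if (any(dead)) {
    warning("excluding ", sum(dead), " all-zero compound(s): ",
            paste(colnames(A)[dead], collapse = ", "), call. = FALSE)
    A <- A[, !dead, drop = FALSE]
    cm <- cm[!dead]
  }
  A <- sweep(A, 2, cm, "/")
  out <- metabolite_table(A, rep(1, nrow(A)), rep(1, nrow(A)),
                          raw$compound_class[colnames(A)],
                          raw$genotype, raw$night_temp, normalized = TRUE)
  attr(out, "n_imputed") <- n_imp
  out
}

#' PCA of a normalized metabolite table
#'
#' Centered (and optionally unit-variance scaled) principal component
#' decomposition via [stats::prcomp()].
#'
#' @param table A [metabolite_table()] (>= 3 samples, >= 2 compounds).
#' @param scale Scale compounds to unit variance (default TRUE).
#' @param n_components Number of components to return; truncated to the
#'   matrix rank with a warning if larger.
#' @return A list with `scores` (samples x components), `loadings`
#'   (orthonormal, compounds x components), `explained` (variance
#'   fractions) and `sdev`.
#' @export
pca_decompose <- function(table, scale = TRUE, n_components = 2) {
  stopifnot(inherits(table, "metabolite_table"))
  A <- table$abundances
  if (nrow(A) < 3 || ncol(A) < 2)
    stop("PCA needs >= 3 samples and >= 2 compounds")
  sds <- apply(A, 2, stats::sd)
  if (scale && any(sds == 0)) A <- A[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(A, center = TRUE, scale. = scale)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (n_components > rank) {
    warning("requested ", n_components, " components; rank is ", rank,
            " - truncating", call. = FALSE)
    n_components <- rank
  }
  idx <- seq_len(n_components)
  list(scores = pc$x[, idx, drop = FALSE],
       loadings = pc$rotation[, idx, drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[idx],
       sdev = pc$sdev[idx])
}

# sequential (type I) projection matrices for the model terms; computed once
# and reused across permutations (meta is fixed, only Y rows permute)
#' @keywords internal
.mv_hats <- function(meta, terms) {
  n <- nrow(meta)
  H_prev <- matrix(1 / n, n, n)
  diffs <- vector("list", length(terms))
  dfs <- numeric(length(terms))
  rank_prev <- 1
  for (k in seq_along(terms)) {
    form <- paste(c("1", terms[seq_len(k)]), collapse = " + ")
    X <- stats::model.matrix(stats::as.formula(paste("~", form)), data = meta)
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    H <- tcrossprod(Q)
    diffs[[k]] <- H - H_prev
    dfs[k] <- qx$rank - rank_prev
    H_prev <- H; rank_prev <- qx$rank
  }
  list(diffs = diffs, dfs = dfs, M_res = diag(n) - H_prev,
       df_res = n - rank_prev, H_full = H_prev)
}

# per-term and residual multivariate SS of Y under precomputed projections
#' @keywords internal
.mv_ss <- function(Y, hats) {
  list(ss = vapply(hats$diffs, function(D) sum((D %*% Y)^2), numeric(1)),
       df = hats$dfs,
       ss_res = sum((hats$M_res %*% Y)^2),
       df_res = hats$df_res)
}

#' Permutation-based multivariate ANOVA (PERMANOVA)
#'
#' Partitions the squared Euclidean distances among samples (equivalently,
#' the multivariate sums of squares of the optionally autoscaled abundance
#' matrix) across the model terms genotype, night temperature and their
#' interaction, computing a pseudo-F per term and permutation p-values as
#' `(count of permuted F >= observed + 1) / (n_perm + 1)`. Main effects use
#' free permutation of sample rows; the interaction term permutes residuals
#' under the reduced (main-effects) model, a standard approximation flagged
#' in the output. With a single compound, the pseudo-F equals the classic
#' univariate ANOVA F.
#'
#' @param table A [metabolite_table()] (normalize first) or a plain numeric
#'   matrix.
#' @param genotype,night_temp Sample factors; taken from the table metadata
#'   when omitted.
#' @param terms Model terms in order; default main effects plus interaction
#'   when both factors vary.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed RNG seed (default 2254); fixed seed gives bit-reproducible
#'   p-values.
#' @param scale Autoscale compounds to unit variance first (default TRUE).
#' @return Object of class `permanova`: data.frame with term, Df, SS, MS,
#'   pseudo-F, R2 and `p_perm`, plus attributes `n_perm`, `seed`.
#' @export
permanova <- function(table, genotype = NULL, night_temp = NULL,
                      terms = NULL, n_perm = 999, seed = 2254,
                      scale = TRUE) {
  if (inherits(table, "metabolite_table")) {
    Y <- table$abundances
    if (is.null(genotype)) genotype <- table$genotype
    if (is.null(night_temp)) night_temp <- table$night_temp
  } else Y <- as.matrix(table)
  if (n_perm < 99) stop("n_perm must be >= 99")
  n <- nrow(Y)
  meta <- data.frame(row.names = seq_len(n))
  if (!is.null(genotype) && length(unique(genotype)) > 1)
    meta$genotype <- factor(genotype)
  if (!is.null(night_temp) && length(unique(night_temp)) > 1)
    meta$night_temp <- factor(night_temp)
  if (!ncol(meta)) stop("need >= 2 groups in at least one factor")
  singleton <- vapply(meta, function(f) any(table(f) < 2), logical(1))
  if (is.null(terms)) {
    terms <- names(meta)
    if (ncol(meta) == 2 && !any(singleton))
      terms <- c(terms, paste(names(meta), collapse = ":"))
    else if (ncol(meta) == 2 && any(singleton))
      warning("factor level with a single sample; interaction dropped",
              call. = FALSE)
  }
  if (scale) {
    sds <- apply(Y, 2, stats::sd)
    Y <- Y[, sds > 0, drop = FALSE]
    Y <- scale(Y)
  } else {
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }

  hats <- .mv_hats(meta, terms)
  obs <- .mv_ss(Y, hats)
  ms_res <- obs$ss_res / obs$df_res
  Fobs <- (obs$ss / obs$df) / ms_res
  Fobs[obs$ss <= 1e-12 * max(sum(obs$ss, obs$ss_res), 1e-12)] <- 0

  is_inter <- grepl(":", terms)
  if (any(is_inter)) {
    H_main <- .mv_hats(meta, terms[!is_inter])$H_full
    fit_main <- H_main %*% Y
    resid_main <- Y - fit_main
  }

  count_ge <- rep(1L, length(terms))  # observed counts as an extreme draw
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- .mv_ss(Y[sample.int(n), , drop = FALSE], hats)
      Fp <- (perm$ss / perm$df) / (perm$ss_res / perm$df_res)
      for (k in which(!is_inter))
        if (Fp[k] >= Fobs[k] - 1e-12) count_ge[k] <- count_ge[k] + 1L
      if (any(is_inter)) {
        # residual permutation under the reduced (main-effects) model
        Yr <- fit_main + resid_main[sample.int(n), , drop = FALSE]
        permi <- .mv_ss(Yr, hats)
        Fpi <- (permi$ss / permi$df) / (permi$ss_res / permi$df_res)
        for (k in which(is_inter))
          if (Fpi[k] >= Fobs[k] - 1e-12) count_ge[k] <- count_ge[k] + 1L
      }
    }
  })
  pvals <- count_ge / (n_perm + 1)
  pvals[Fobs == 0] <- 1

  tot <- sum(obs$ss) + obs$ss_res
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(obs$df, obs$df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, tot),
    MS = c(obs$ss / obs$df, ms_res, NA),
    pseudo_F = c(Fobs, NA, NA),
    R2 = c(obs$ss / tot, obs$ss_res / tot, 1),
    p_perm = c(pvals, NA, NA))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "interaction_note") <-
    if (any(is_inter)) "interaction p-value from reduced-model residual permutation (approximation)" else NULL
  class(out) <- c("permanova", "data.frame")
  out
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (squared Euclidean, %d permutations, seed %d)\n",
              attr(x, "n_perm"), attr(x, "seed")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  note <- attr(x, "interaction_note")
  if (!is.null(note)) cat("note:", note, "\n")
  invisible(x)
}

#' Rank metabolites by consistent response to night warming
#'
#' Per-compound log2 fold-change of the warm-night level versus the cool
#' reference level, computed within each genotype, with a consistency flag
#' set when the response has the same sign in every genotype tested.
#' Compounds are ranked by the absolute mean log fold-change; class labels
#' are carried through so class-level enrichment (e.g. monosaccharides,
#' saturated fatty acids) can be read off directly.
#'
#' @param table A normalized [metabolite_table()].
#' @param level_hi Warm night-temperature level (degC; default 25).
#' @param level_lo Reference level (degC; default 15).
#' @param genotypes Genotypes to include; defaults to all having both
#'   levels. Genotypes missing a level are excluded with a warning.
#' @return data.frame: compound, class, per-genotype `lfc_*` columns,
#'   `mean_lfc`, `consistent`, ordered by decreasing `|mean_lfc|`.
#' @export
responsive_metabolites <- function(table, level_hi = 25, level_lo = 15,
                                   genotypes = NULL) {
  stopifnot(inherits(table, "metabolite_table"))
  A <- table$abundances
  if (is.null(genotypes)) genotypes <- unique(table$genotype)
  keep <- vapply(genotypes, function(g) {
    sel <- table$genotype == g
    any(sel & table$night_temp == level_hi) &&
      any(sel & table$night_temp == level_lo)
  }, logical(1))
  if (any(!keep))
    warning("genotype(s) missing a contrast level, excluded: ",
            paste(genotypes[!keep], collapse = ", "), call. = FALSE)
  genotypes <- genotypes[keep]
  if (!length(genotypes)) stop("no genotype has both contrast levels")
  eps <- 1e-12
  lfc <- sapply(genotypes, function(g) {
    hi <- colMeans(A[table$genotype == g &
                       table$night_temp == level_hi, , drop = FALSE])
    lo <- colMeans(A[table$genotype == g &
                       table$night_temp == level_lo, , drop = FALSE])
    log2((hi + eps) / (lo + eps))
  })
  lfc <- matrix(lfc, ncol = length(genotypes),
                dimnames = list(colnames(A), paste0("lfc_", genotypes)))
  mean_lfc <- rowMeans(lfc)
  consistent <- apply(lfc, 1, function(v)
    all(v > 0) || all(v < 0)) & abs(mean_lfc) > eps
  out <- data.frame(compound = colnames(A),
                    class = unname(table$compound_class[colnames(A)]),
                    lfc, mean_lfc = mean_lfc, consistent = consistent,
                    row.names = NULL)
  out[order(-abs(out$mean_lfc)), ]
}
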
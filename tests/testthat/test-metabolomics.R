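# Metabolite normalization, PCA, PERMANOVA, responder ranking.

make_table <- function(A, istd = rep(1, nrow(A)), mass = rep(1, nrow(A)),
                       ...) {
  metabolite_table(A, istd, mass, ...)
}

test_that("normalization chain: forced unit means and hand-worked table", {
  # compound with post-istd/mass values [2, 4] -> [2/3, 4/3]
  A <- matrix(c(2, 4), 2, 1)
  out <- normalize_abundance(make_table(A))
  expect_equal(c(out$abundances), c(2 / 3, 4 / 3))
  expect_equal(colMeans(out$abundances), c(compound_1 = 1))

  # 3-sample hand example: istd {1,2,1}, mass {0.1,0.1,0.2}
  A2 <- matrix(c(10, 20, 30, 5, 5, 5), 3, 2)
  istd <- c(1, 2, 1); mass <- c(0.1, 0.1, 0.2)
  # by hand: divide by (istd/mean istd) then mass, then by column mean
  step <- A2 / (istd / mean(istd)) / mass
  expected <- sweep(step, 2, colMeans(step), "/")
  out2 <- normalize_abundance(make_table(A2, istd, mass))
  expect_equal(unname(out2$abundances), unname(expected), tolerance = 1e-12)
  expect_equal(unname(colMeans(out2$abundances)), c(1, 1))

  # identical istd and mass: pure global rescale preserves sample ordering
  A3 <- matrix(runif(12, 1, 100), 4, 3)
  out3 <- normalize_abundance(make_table(A3, rep(2, 4), rep(0.5, 4)))
  for (j in 1:3)
    expect_identical(order(out3$abundances[, j]), order(A3[, j]))
})

test_that("normalization is idempotent and guards zero columns/NAs", {
  A <- matrix(runif(20, 1, 10), 5, 4)
  once <- normalize_abundance(make_table(A))
  twice <- normalize_abundance(once)
  expect_equal(twice$abundances, once$abundances, tolerance = 1e-12)

  Az <- cbind(A, dead = 0)
  expect_warning(out <- normalize_abundance(make_table(Az)), "all-zero")
  expect_false("dead" %in% colnames(out$abundances))

  Ana <- A; Ana[2, 1] <- NA
  out2 <- normalize_abundance(make_table(Ana))
  expect_identical(attr(out2, "n_imputed"), 1L)
  expect_true(all(is.finite(out2$abundances)))
})

test_that("PCA: collinear data, orthonormal loadings, eigen oracle", {
  # samples on a line in compound space: one component carries ~100%
  t_ <- 1:6
  A <- cbind(2 * t_, -t_, 0.5 * t_) + 100
  tab <- make_table(A)
  pc <- pca_decompose(tab, scale = FALSE, n_components = 1)
  expect_gt(pc$explained[1], 0.999999)
  expect_equal(sqrt(sum(pc$loadings[, 1]^2)), 1, tolerance = 1e-10)

  # integer toy matrix: variances along components equal eigenvalues of the
  # covariance matrix from an independent dense eigendecomposition
  A2 <- matrix(c(1, 4, 2, 8, 3, 5, 9, 2, 7, 1, 6, 3), 4, 3)
  pc2 <- pca_decompose(make_table(A2), scale = FALSE, n_components = 3)
  ev <- eigen(cov(A2), symmetric = TRUE)$values
  expect_equal(pc2$sdev^2, ev[1:3], tolerance = 1e-10)
  # loadings pairwise orthogonal
  G <- crossprod(pc2$loadings)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_warning(pca_decompose(make_table(A2), n_components = 10),
                 "truncating")
})

test_that("univariate pseudo-F equals classic one-way ANOVA F", {
  set.seed(111)
  y <- rnorm(12, rep(c(0, 1, 3), each = 4))
  g <- rep(c("a", "b", "c"), each = 4)
  pm <- permanova(matrix(y, ncol = 1), genotype = g, n_perm = 99)
  Fa <- anova(aov(y ~ factor(g)))$`F value`[1]
  expect_equal(pm$pseudo_F[1], Fa, tolerance = 1e-8)
})

test_that("permanova matches vegan::adonis2 on Euclidean distances", {
  skip_if_not_installed("vegan")
  set.seed(112)
  Y <- matrix(rnorm(15 * 6), 15)
  g <- rep(c("a", "b", "c"), each = 5)
  pm <- permanova(Y, genotype = g, n_perm = 99, scale = FALSE)
  ad <- vegan::adonis2(Y ~ g, method = "euclidean", permutations = 99)
  expect_equal(pm$SS[1], ad$SumOfSqs[1], tolerance = 1e-10)
  expect_equal(pm$pseudo_F[1], ad$F[1], tolerance = 1e-10)
})

test_that("permanova: identical groups, determinism, order invariance", {
  A <- matrix(rep(c(1, 2, 3, 4), each = 6), 4, 6, byrow = FALSE)
  A <- rbind(A, A)  # two groups with identical multivariate samples
  g <- rep(c("a", "b"), each = 4)
  pm <- permanova(A + 0, genotype = g, n_perm = 99, scale = FALSE)
  expect_equal(pm$pseudo_F[1], 0)
  expect_equal(pm$p_perm[1], 1)

  set.seed(113)
  Y <- matrix(rnorm(12 * 8), 12)
  gg <- rep(c("a", "b", "c"), each = 4)
  p1 <- permanova(Y, genotype = gg, n_perm = 199, seed = 7)
  p2 <- permanova(Y, genotype = gg, n_perm = 199, seed = 7)
  expect_identical(p1$p_perm, p2$p_perm)  # bit-reproducible for fixed seed

  idx <- sample(12)
  p3 <- permanova(Y[idx, ], genotype = gg[idx], n_perm = 199, seed = 7)
  expect_equal(p3$pseudo_F[1], p1$pseudo_F[1], tolerance = 1e-10)
})

test_that("responsive_metabolites ranks planted responders on top", {
  # 150 compounds, 5 planted monosaccharide responders doubled at 25 degC
  set.seed(114)
  n_comp <- 150
  cls <- c(rep("monosaccharide", 5), rep("unknown", n_comp - 5))
  geno <- rep(c("g1", "g2", "g3"), each = 8)
  night <- rep(rep(c(15, 25), each = 4), 3)
  base <- exp(runif(n_comp, 2, 6))
  A <- matrix(base, 24, n_comp, byrow = TRUE) *
    exp(matrix(rnorm(24 * n_comp, 0, 0.1), 24))
  A[night == 25, 1:5] <- A[night == 25, 1:5] * 2
  tab <- normalize_abundance(
    metabolite_table(A, rep(1, 24), rep(1, 24), cls,
                     genotype = geno, night_temp = night))
  rk <- responsive_metabolites(tab)
  top10 <- rk$compound[1:10]
  expect_true(all(colnames(A)[1:5] %in% top10))
  expect_true(all(rk$consistent[rk$compound %in% colnames(A)[1:5]]))

  # identical means in both levels: lfc 0, not flagged
  A0 <- matrix(rep(c(3, 3), each = 12), 24, 1)
  tab0 <- metabolite_table(A0, rep(1, 24), rep(1, 24), "unknown",
                           genotype = geno, night_temp = night)
  rk0 <- responsive_metabolites(tab0)
  expect_equal(rk0$mean_lfc, 0)
  expect_false(rk0$consistent)

  # genotype missing one level is excluded with a warning
  expect_warning(
    responsive_metabolites(tab, genotypes = c("g1", "absent")), "excluded")
})
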
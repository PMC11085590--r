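test_that("curve PCA is centered, sign-fixed, and reconstructs the data", {
  set.seed(11)
  tt <- seq(0, 8, by = 2 / 60)
  # exactly rank-1 family: each curve a scalar multiple of one template
  asym <- runif(20, 60, 95)
  rank1 <- asym %*% t(1 - exp(-1.2 * tt))
  pc <- pca_curves(rank1, 3)
  expect_gt(pc$variance_share[1], 1 - 1e-10)
  expect_equal(colMeans(pc$scores), rep(0, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(colSums(pc$loadings) >= 0))

  # general matrix: shares sum to 1 and full reconstruction round-trips
  m <- matrix(rnorm(15 * 30), 15, 30)
  pc_all <- pca_curves(m, 14)
  expect_equal(sum(pc_all$variance_share), 1, tolerance = 1e-12)
  recon <- pc_all$scores %*% t(pc_all$loadings)
  centered <- sweep(m, 2, colMeans(m))
  expect_lt(max(abs(recon - centered)), 1e-8)

  # variance shares invariant to adding a constant to every curve
  pc_shift <- pca_curves(m + 100, 5)
  expect_equal(pc_shift$variance_share, pca_curves(m, 5)$variance_share,
               tolerance = 1e-10)

  expect_error(pca_curves(m[1, , drop = FALSE], 1), "at least 2")
  expect_error(pca_curves(m, 20), "rank")
})

test_that("maximum swing rate matches analytic slopes", {
  tt <- seq(0, 8, by = 2 / 60)
  # linear ramp 12 deg/h: exact for any window
  expect_equal(max_swing_rate(12 * tt, window = 5), 12, tolerance = 1e-10)
  expect_equal(max_swing_rate(12 * tt, window = 11), 12, tolerance = 1e-10)
  # constant curve: zero
  expect_equal(max_swing_rate(rep(45, 241)), 0)
  # offset invariance
  curve <- 80 / (1 + exp(-1.5 * (tt - 3)))
  expect_equal(max_swing_rate(curve + 30), max_swing_rate(curve),
               tolerance = 1e-10)
  # noiseless logistic: max derivative = A*r/4
  expect_equal(max_swing_rate(curve, window = 5), 80 * 1.5 / 4,
               tolerance = 0.01 * 80 * 1.5 / 4)
  expect_error(max_swing_rate(curve, window = 4), "odd")
  expect_error(max_swing_rate(curve[1:3], window = 5), "shorter")
})

test_that("Pearson matrix matches hand computation and null behaviour", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_matrix(cbind(x = x, y = 2 * x + 1))["x", "y"], 1)

  # 5-row worked table against the explicit covariance formula
  tab <- cbind(a = c(2, 4, 1, 7, 5), b = c(9, 3, 4, 8, 6))
  r_hand <- sum((tab[, 1] - mean(tab[, 1])) * (tab[, 2] - mean(tab[, 2]))) /
    sqrt(sum((tab[, 1] - mean(tab[, 1]))^2) * sum((tab[, 2] - mean(tab[, 2]))^2))
  expect_equal(pearson_matrix(tab)["a", "b"], r_hand, tolerance = 1e-12)

  set.seed(22)
  big <- cbind(u = rnorm(10000), v = rnorm(10000))
  expect_lt(abs(pearson_matrix(big)["u", "v"]), 0.05)

  m <- pearson_matrix(tab)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 1, b = 1))
  expect_warning(pearson_matrix(cbind(a = x, z = rep(1, 5))), "zero-variance")
  expect_error(pearson_matrix(cbind(a = c(1, 2, NA, NA, NA),
                                    b = c(NA, 2, 3, 4, NA))), "fewer than 3")
})

test_that("CCA degenerates to |Pearson r| and detects exact linear maps", {
  set.seed(33)
  x <- matrix(rnorm(60), 60, 1, dimnames = list(NULL, "x"))
  y <- matrix(0.6 * x + rnorm(60, 0, 0.8), 60, 1, dimnames = list(NULL, "y"))
  sol <- cca(x, y)
  expect_equal(sol$correlation, abs(cor(x, y)[1, 1]), tolerance = 1e-10)

  # y a column-permuted copy of x -> perfect canonical correlation
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("t", 1:4)))
  sol2 <- cca(X, X[, c(3, 1, 4, 2)])
  expect_equal(sol2$correlation, 1, tolerance = 1e-8)

  # canonical variates have unit variance; self-consistent correlation
  Y <- matrix(rnorm(250), 50, 5)
  sol3 <- cca(X, Y)
  expect_equal(var(sol3$x_scores), 1, tolerance = 1e-10)
  expect_equal(var(sol3$y_scores), 1, tolerance = 1e-10)
  expect_equal(abs(cor(sol3$x_scores, sol3$y_scores)), sol3$correlation,
               tolerance = 1e-10)

  # matches the independent base-R implementation on z-scored data
  ref <- cancor(scale(X), scale(Y))
  expect_equal(sol3$correlation, ref$cor[1], tolerance = 1e-8)

  # first canonical correlation >= any pairwise cross-correlation
  expect_gte(sol3$correlation + 1e-12, max(abs(cor(X, Y))))

  # invariance to affine rescaling of input columns
  X2 <- X
  X2[, 2] <- 5 - 3 * X2[, 2]
  sol4 <- cca(X2, Y)
  expect_equal(sol4$correlation, sol3$correlation, tolerance = 1e-10)

  # rank-deficient block errors informatively
  Xbad <- cbind(X, t5 = X[, 1] * 2)
  expect_error(cca(Xbad, cbind(Y, rnorm(50))), "rank deficient")
  expect_error(cca(X[1:8, ], Y[1:8, ]), "more rows")
})

test_that("planted canonical correlation is recovered", {
  set.seed(44)
  n <- 5000
  rho <- 0.5
  # independent Gaussian columns except cor(X1, Y1) = rho, so the first
  # canonical correlation of the joint distribution is exactly rho
  X <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  Y <- matrix(rnorm(5 * n), n, 5, dimnames = list(NULL, paste0("y", 1:5)))
  Y[, 1] <- rho * X[, 1] + sqrt(1 - rho^2) * rnorm(n)
  sol <- cca(X, Y)
  expect_equal(sol$correlation, rho, tolerance = 0.05)
})

test_that("CCA permutation threshold is seeded and monotone", {
  set.seed(55)
  X <- matrix(rnorm(160 * 4), 160, 4, dimnames = list(NULL, paste0("x", 1:4)))
  Y <- matrix(rnorm(160 * 5), 160, 5)
  t1 <- cca_permutation_threshold(X, Y, n_perm = 300, seed = 9)
  t2 <- cca_permutation_threshold(X, Y, n_perm = 300, seed = 9)
  expect_equal(as.numeric(t1), as.numeric(t2))
  t80 <- cca_permutation_threshold(X, Y, n_perm = 300, quantile = 0.8, seed = 9)
  expect_lte(as.numeric(t80), as.numeric(t1))
  # permuted null correlations live strictly inside [0, 1]
  nulls <- attr(t1, "null_correlations")
  expect_true(all(nulls > 0 & nulls < 1))
})
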
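# The RDA engine against an independent brute-force oracle, permutation
# tests, variance partitioning and biplot scores.

test_that("simple and partial RDA match the brute-force oracle", {
  set.seed(601)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    m <- sample(3:20, 1)
    p <- sample(1:4, 1)
    Y <- matrix(rnorm(n * m), n, m)
    X <- matrix(rnorm(n * p), n, p)
    Z <- if (rep %% 2 == 0) matrix(rnorm(n * 2), n, 2) else NULL
    f <- fit_rda(Y, X, Z)
    o <- oracle_rda(Y, X, Z)
    expect_equal(f$r2, o$r2, tolerance = 1e-10)
    expect_equal(f$r2_adj, o$r2_adj, tolerance = 1e-10)
    expect_equal(f$eig, o$eig, tolerance = 1e-8)
    expect_equal(f$p, o$p_rank)
  }
})

test_that("degenerate designs behave as contracts require", {
  set.seed(602)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  B <- matrix(rnorm(2 * 5), 2, 5)
  Y <- X %*% B
  f <- fit_rda(Y, X)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_lt(f$ss_residual, 1e-16 * f$ss_total)
  # X orthogonal to Y by construction
  Yc <- scale(matrix(rnorm(n * 4), n, 4), center = TRUE, scale = FALSE)
  Xc <- scale(matrix(rnorm(n * 2), n, 2), center = TRUE, scale = FALSE)
  Yo <- Yc - Xc %*% solve(crossprod(Xc)) %*% crossprod(Xc, Yc)
  expect_lt(fit_rda(Yo, Xc)$r2, 1e-10)
  # Z = X leaves nothing to explain
  fz <- fit_rda(matrix(rnorm(n * 4), n, 4), X, Z = X)
  expect_lt(fz$r2, 1e-10)
  # additivity of sums of squares
  Z <- matrix(rnorm(n * 2), n, 2)
  fp <- fit_rda(matrix(rnorm(n * 4), n, 4), X, Z)
  expect_equal(fp$ss_conditioned + fp$ss_constrained + fp$ss_residual,
               fp$ss_all, tolerance = 1e-8)
  expect_error(fit_rda(matrix(1, n, 3), X), "constant")
  expect_error(fit_rda(matrix(rnorm(8), 4, 2), matrix(rnorm(12), 4, 3)),
               "must exceed")
})

test_that("RDA matches vegan on a shared example", {
  skip_if_not_installed("vegan")
  set.seed(603)
  n <- 35
  Y <- matrix(rnorm(n * 6), n, 6)
  X <- matrix(rnorm(n * 3), n, 3)
  f <- fit_rda(Y, X)
  v <- vegan::rda(Y ~ X)
  expect_equal(f$r2, unname(v$CCA$tot.chi / v$tot.chi), tolerance = 1e-8)
  expect_equal(f$eig / (n - 1), unname(v$CCA$eig), tolerance = 1e-8)
  expect_equal(f$r2_adj, vegan::RsquareAdj(v)$adj.r.squared,
               tolerance = 1e-8)
})

test_that("overall permutation test saturates, is column-symmetric", {
  set.seed(604)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- X %*% matrix(rnorm(2 * 5), 2, 5) + matrix(rnorm(n * 5, sd = 0.01),
                                                 n, 5)
  a <- anova_overall(Y, X, n_perm = 99, seed = 1)
  expect_equal(a$p, 1 / 100)
  # invariant to relabeling of response columns
  a2 <- anova_overall(Y[, c(3, 1, 2, 5, 4)], X, n_perm = 99, seed = 1)
  expect_equal(a$p, a2$p)
  expect_equal(a$F, a2$F, tolerance = 1e-10)
  expect_error(anova_overall(Y, X, n_perm = 0), "n_perm")
})

test_that("marginal tests handle aliasing, orthogonality and the SS inequality", {
  set.seed(605)
  n <- 40
  B <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  x1 <- B[, 1, drop = FALSE]; x2 <- B[, 2, drop = FALSE]
  Y <- matrix(rnorm(n * 5), n, 5)
  # orthogonal single-column terms: marginal SS equals simple SS
  am <- anova_margin(Y, list(a = x1, b = x2), n_perm = 49, seed = 1)
  s_a <- fit_rda(Y, x1)$ss_constrained
  s_b <- fit_rda(Y, x2)$ss_constrained
  expect_equal(am$ss_margin[am$term == "a"], s_a, tolerance = 1e-10)
  expect_equal(am$ss_margin[am$term == "b"], s_b, tolerance = 1e-10)
  # duplicated term: aliased, NA with warning
  # both duplicated terms warn, one warning per term
  expect_warning(expect_warning(
    am2 <- anova_margin(Y, list(a = x1, b = x1), n_perm = 49, seed = 1),
    "aliased"), "aliased")
  expect_true(all(is.na(am2$F)))
  expect_lt(max(abs(am2$ss_margin)), 1e-10)
  # terms sharing their signal: sum of marginal SS <= constrained SS
  x3 <- x1 + 0.2 * matrix(rnorm(n), n, 1)
  Ysig <- (x1 + x3) %*% matrix(rnorm(5), 1, 5) +
    matrix(rnorm(n * 5, sd = 0.3), n, 5)
  am3 <- anova_margin(Ysig, list(a = x1, b = x3), n_perm = 49, seed = 1)
  full <- fit_rda(Ysig, cbind(x1, x3))$ss_constrained
  expect_lte(sum(am3$ss_margin), full + 1e-10)
})

test_that("variance partitioning identities hold and edge cases error", {
  set.seed(606)
  n <- 50
  Y <- matrix(rnorm(n * 8), n, 8)
  X1 <- matrix(rnorm(n * 2), n, 2)
  X2 <- matrix(rnorm(n * 3), n, 3)
  vp <- varpart_rda(Y, X1, X2)
  expect_equal(vp$a + vp$b, vp$r2_adj[["X1"]], tolerance = 1e-10)
  expect_equal(vp$b + vp$c, vp$r2_adj[["X2"]], tolerance = 1e-10)
  expect_equal(vp$a + vp$b + vp$c, vp$r2_adj[["X12"]], tolerance = 1e-10)
  expect_equal(vp$a + vp$b + vp$c + vp$d, 1, tolerance = 1e-10)
  expect_equal(vp$raw_a + vp$raw_b + vp$raw_c + vp$raw_d, 1,
               tolerance = 1e-10)
  # empty X2
  vp0 <- varpart_rda(Y, X1, X1[, 0])
  expect_equal(vp0$a, fit_rda(Y, X1)$r2_adj, tolerance = 1e-12)
  expect_equal(vp0$b, 0); expect_equal(vp0$c, 0)
  # shared column rejected
  expect_error(varpart_rda(Y, X1, cbind(X2, X1[, 1])), "share")
})

test_that("ancestry coefficients work as an RDA response", {
  ad <- simulate_admixture(n_ind = 80, n_snps = 400, K = 3, fst = 0.2,
                           seed = 607)
  Q <- drop_simplex_col(ad$Q)
  X <- matrix(rnorm(80 * 2), 80, 2)
  f <- fit_rda(Q, X)
  expect_true(f$r2 >= 0 && f$r2 <= 1)
  expect_equal(sum(f$eig) / f$ss_total, f$r2, tolerance = 1e-10)
})

test_that("biplot scores are correlations with axes", {
  set.seed(608)
  n <- 40
  x <- matrix(rnorm(n), n, 1)
  Y <- x %*% matrix(rnorm(5), 1, 5) + matrix(rnorm(n * 5, sd = 0.2), n, 5)
  f <- fit_rda(Y, x)
  expect_equal(abs(f$biplot[1, 1]), 1, tolerance = 1e-10,
               ignore_attr = TRUE)
  X <- matrix(rnorm(n * 3), n, 3)
  f2 <- fit_rda(Y, X)
  expect_true(all(abs(f2$biplot) <= 1 + 1e-12))
  # a variable equal to the axis-1 site scores correlates 1 with axis 1
  v <- f2$site_scores[, 1, drop = FALSE]
  expect_equal(abs(biplot_scores(f2, cbind(f2$Xres, v))[4, 1]), 1,
               tolerance = 1e-10)
})

test_that("single-variable scan ranks the driver first and conditions away shared signal", {
  set.seed(609)
  n <- 60
  driver <- rnorm(n)
  other <- rnorm(n)
  Y <- outer(driver, rnorm(6)) + matrix(rnorm(n * 6, sd = 0.5), n, 6)
  env <- cbind(driver = driver, other = other)
  tab <- single_variable_scan(Y, env, n_perm = 99, seed = 1)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$variable[1], "driver")
  tabz <- single_variable_scan(Y, env, Z = cbind(driver), n_perm = 0)
  expect_lt(tabz$r2[tabz$variable == "driver"],
            tab$r2[tab$variable == "driver"])
})
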
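# PCA and projection, K estimation, ALS ancestry factorization, cluster
# assignment, Hudson FST, Nei distance, and neighbor-joining.

test_that("PCA matches an SVD oracle and has the spectral properties", {
  set.seed(101)
  X <- matrix(rnorm(24), 6, 4)
  pca <- run_pca(X, n_axes = 3)
  sv <- svd(sweep(X, 2, colMeans(X)))
  expect_equal(pca$eigenvalues, sv$d^2 / 5, tolerance = 1e-10)
  expect_equal(sum(pca$eigenvalues),
               sum(diag(cov(X))) * 1, tolerance = 1e-10)
  # scores orthogonal
  G <- crossprod(pca$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-10)
  # two separated clouds: PC1 explains nearly everything
  X2 <- cbind(c(rep(0, 10), rep(10, 10)) + rnorm(20, sd = 1e-3),
              rnorm(20, sd = 1e-3))
  p2 <- run_pca(X2, n_axes = 2)
  expect_gt(p2$prop_var[1], 0.99)
  expect_gt(abs(diff(tapply(p2$scores[, 1], rep(1:2, each = 10), mean))), 5)
  expect_warning(run_pca(X, n_axes = 10), "rank")
})

test_that("PC projection is exact for training rows and centers correctly", {
  set.seed(102)
  X <- matrix(rnorm(200), 20, 10)
  pca <- run_pca(X, n_axes = 4)
  expect_equal(project_pca(X, pca), unclass(pca$scores), tolerance = 1e-10)
  expect_equal(as.numeric(project_pca(rbind(colMeans(X)), pca)),
               rep(0, 4), tolerance = 1e-10)
  expect_error(project_pca(X[, 1:5], pca), "site set")
  # held-out individuals project near their own cluster centroid
  ad <- simulate_admixture(n_ind = 80, n_snps = 600, K = 2, fst = 0.3,
                           alpha = 0.05, seed = 103)
  lab <- assign_clusters(ad$Q)$labels
  tr <- seq(1, 80, by = 2); ho <- seq(2, 80, by = 2)
  Xall <- impute_mean(ad$geno)
  ptr <- run_pca(Xall[tr, ], n_axes = 2)
  cen <- rbind(colMeans(ptr$scores[lab[tr] == 1, , drop = FALSE]),
               colMeans(ptr$scores[lab[tr] == 2, , drop = FALSE]))
  sc <- project_pca(Xall[ho, ], ptr)
  d1 <- sqrt(rowSums((sc - cen[rep(1, length(ho)), ])^2))
  d2 <- sqrt(rowSums((sc - cen[rep(2, length(ho)), ])^2))
  nearest <- ifelse(d1 < d2, 1, 2)
  expect_gt(mean(nearest == lab[ho]), 0.9)
})

test_that("latent-dimension estimate is 1 for unstructured data, K for clusters", {
  hits <- 0
  for (s in 1:8) {
    set.seed(400 + s)
    X <- matrix(rbinom(60 * 300, 2, 0.4), 60, 300)
    if (estimate_d(X, n_perm = 15, seed = s) == 1) hits <- hits + 1
  }
  expect_gte(hits, 7)
  ad <- simulate_admixture(n_ind = 120, n_snps = 1500, K = 4, fst = 0.2,
                           alpha = 0.05, seed = 7)
  X <- impute_mean(ad$geno)
  expect_equal(estimate_d(X, n_perm = 15, seed = 1), 4)
})

test_that("ALS ancestry factorization recovers Q and is monotone", {
  ad <- simulate_admixture(n_ind = 100, n_snps = 1000, K = 2, fst = 0.15,
                           seed = 9)
  anc <- estimate_ancestry(impute_mean(ad$geno), 2)
  expect_lt(min_perm_rmse(anc$Q, ad$Q), 0.10)
  expect_true(all(diff(anc$objective) <= 1e-8))
  expect_equal(rowSums(anc$Q), rep(1, 100), tolerance = 1e-6)
  expect_true(all(anc$P >= 0 & anc$P <= 1))
  # K = 1 degenerate case
  a1 <- estimate_ancestry(impute_mean(ad$geno), 1)
  expect_equal(as.numeric(a1$Q), rep(1, 100))
  expect_equal(as.numeric(a1$P), colMeans(pmin(pmax(
    svd(impute_mean(ad$geno) / 2, nu = 1, nv = 1)$u %*%
      t(svd(impute_mean(ad$geno) / 2, nu = 1, nv = 1)$v) *
      svd(impute_mean(ad$geno) / 2)$d[1], 0), 1)), tolerance = 1e-8)
  expect_error(estimate_ancestry(impute_mean(ad$geno), 200), "K exceeds")
})

test_that("cluster assignment uses argmax with lowest-index ties", {
  cl <- assign_clusters(rbind(c(0.5, 0.3, 0.1, 0.1),
                              c(0.5, 0.5, 0, 0),
                              c(0.95, 0.05, 0, 0),
                              c(0.6, 0.4, 0, 0)))
  expect_equal(cl$labels, c(1L, 1L, 1L, 1L))
  expect_equal(cl$frac_admixed, 0.75)
})

test_that("Hudson FST matches hand evaluation and a per-site oracle", {
  # fixed difference -> FST = 1
  d <- cbind(c(rep(2L, 10), rep(0L, 10)))
  G <- geno_matrix(d, sprintf("i%02d", 1:20),
                   data.frame(chrom = "1H", pos = 1L))
  expect_equal(hudson_fst(G, rep(1:2, each = 10))$dist$mat[1, 2], 1)

  # p1 = 0.9, p2 = 0.1, n1 = n2 = 20 alleles:
  # N = 0.64 - 2 * (0.09 / 19), D = 0.82
  d2 <- cbind(c(rep(2L, 9), 0L, rep(0L, 9), 2L))
  G2 <- geno_matrix(d2, sprintf("i%02d", 1:20),
                    data.frame(chrom = "1H", pos = 1L))
  expect_equal(hudson_fst(G2, rep(1:2, each = 10))$dist$mat[1, 2],
               (0.64 - 2 * (0.09 / 19)) / 0.82, tolerance = 1e-12)

  # random toy vs elementwise oracle
  set.seed(55)
  d3 <- matrix(sample(0:2, 30 * 25, TRUE), 30, 25)
  storage.mode(d3) <- "integer"
  d3[sample(length(d3), 40)] <- NA
  G3 <- geno_matrix(d3, sprintf("i%02d", 1:30),
                    data.frame(chrom = "1H", pos = seq_len(25)))
  labs <- rep(1:3, each = 10)
  got <- hudson_fst(G3, labs)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    num <- 0; den <- 0
    for (l in 1:25) {
      x1 <- d3[labs == pair[1], l]; x2 <- d3[labs == pair[2], l]
      n1 <- 2 * sum(!is.na(x1)); n2 <- 2 * sum(!is.na(x2))
      if (n1 < 2 || n2 < 2) next
      p1 <- sum(x1, na.rm = TRUE) / n1; p2 <- sum(x2, na.rm = TRUE) / n2
      D <- p1 * (1 - p2) + p2 * (1 - p1)
      if (D <= 0) next
      num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
        p2 * (1 - p2) / (n2 - 1)
      den <- den + D
    }
    expect_equal(got$dist$mat[pair[1], pair[2]], num / den,
                 tolerance = 1e-12)
  }
})

test_that("island-model FST is recovered within 10%", {
  isl <- island_sim(n_per_pop = 50, n_pops = 2, m = 5000, fst = 0.1,
                    seed = 77)
  est <- hudson_fst(isl$geno, isl$labels)$dist$mat[1, 2]
  expect_lt(abs(est - 0.1) / 0.1, 0.1)
})

test_that("FST profile is flat under uniform divergence, peaks at a planted block", {
  isl <- island_sim(n_per_pop = 40, n_pops = 2, m = 500, fst = 0.05,
                    seed = 78)
  prof <- fst_profile(isl$geno, isl$labels, window_snps = 50)
  expect_lt(sd(prof$track$fst) / mean(prof$track$fst), 1.5)
  # plant a high-divergence block at sites 201-250
  d <- isl$geno$dosage
  d[isl$labels == 1, 201:250] <- 2L
  d[isl$labels == 2, 201:250] <- 0L
  G <- geno_matrix(d, isl$geno$ind_ids, isl$geno$sites)
  prof2 <- fst_profile(G, isl$labels, window_snps = 50)
  expect_equal(which.max(prof2$track$fst), 5L)  # window of sites 201-250
})

test_that("Nei distance matches hand evaluation and is symmetric", {
  # one locus, pop1 fixed (1,0), pop2 (0.5, 0.5): D = -ln(0.5 / sqrt(0.5))
  d <- cbind(c(rep(2L, 10), rep(1L, 10)))
  G <- geno_matrix(d, sprintf("i%02d", 1:20),
                   data.frame(chrom = "1H", pos = 1L))
  nd <- nei_distance(G, rep(1:2, each = 10))
  expect_equal(nd$mat[1, 2], -log(0.5 / sqrt(0.5)), tolerance = 1e-10)
  expect_equal(nd$mat, t(nd$mat))
  expect_equal(nd$mat[1, 1], 0)
  # identical frequency profiles -> 0
  d2 <- cbind(rep(1L, 20), rep(2L, 20))
  G2 <- geno_matrix(d2, sprintf("i%02d", 1:20),
                    data.frame(chrom = "1H", pos = 1:2))
  expect_equal(nei_distance(G2, rep(1:2, each = 10))$mat[1, 2], 0)
})

test_that("neighbor-joining inverts additive distances exactly", {
  skip_if_not_installed("ape")
  # hand-built 4-taxon additive matrix from ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  nwk <- nj_tree(D)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, LETTERS[1:4])
  co <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(co, D, tolerance = 1e-8)
  # equidistant 3 taxa: equal branches
  D3 <- matrix(2, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(D3) <- 0
  tr3 <- ape::read.tree(text = nj_tree(D3))
  expect_equal(unname(tr3$edge.length), rep(1, 3))
  # property: random additive trees up to 8 taxa are inverted exactly
  set.seed(202)
  for (rep in 1:20) {
    nt <- sample(4:8, 1)
    tr0 <- ape::rtree(nt, br = function(n) runif(n, 0.5, 2))
    tr0$tip.label <- paste0("t", seq_len(nt))
    D0 <- ape::cophenetic.phylo(tr0)
    got <- ape::read.tree(text = nj_tree(D0))
    co0 <- ape::cophenetic.phylo(got)[rownames(D0), colnames(D0)]
    expect_equal(co0, D0, tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa|symmetric")
})
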
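# Allele-sharing distances, unPC scores, the Box-Cox/Student-t outlier
# test and the barrier/low-rate rank test.

test_that("Dps matches hand values and a per-site loop oracle", {
  # identical demes -> 0; opposite fixation -> 1
  d <- cbind(rep(c(2L, 2L, 0L, 0L), each = 5))
  G <- geno_matrix(cbind(d, d), sprintf("i%02d", 1:20),
                   data.frame(chrom = "1H", pos = 1:2))
  labs <- rep(c("a", "b", "c", "d"), each = 5)
  M <- dps_distance(G, labs)$mat
  expect_equal(M["a", "b"], 0)
  expect_equal(M["a", "c"], 1)
  # one site, freqs 0.8 vs 0.4: p = min(.8,.4) + min(.2,.6) = 0.6
  d2 <- cbind(c(2L, 2L, 2L, 2L, 0L, 2L, 2L, 0L, 0L, 0L))
  G2 <- geno_matrix(d2, sprintf("i%02d", 1:10),
                    data.frame(chrom = "1H", pos = 1L))
  expect_equal(dps_distance(G2, rep(1:2, each = 5))$mat[1, 2], 0.4,
               tolerance = 1e-12)
  # random toy vs elementwise oracle
  set.seed(801)
  d3 <- matrix(sample(0:2, 24 * 30, TRUE), 24, 30)
  storage.mode(d3) <- "integer"
  d3[sample(length(d3), 60)] <- NA
  G3 <- geno_matrix(d3, sprintf("i%02d", 1:24),
                    data.frame(chrom = "1H", pos = 1:30))
  labs3 <- rep(1:3, each = 8)
  M3 <- dps_distance(G3, labs3)$mat
  for (pr in list(c(1, 2), c(2, 3))) {
    tot <- c(); u <- 0
    for (l in 1:30) {
      x1 <- d3[labs3 == pr[1], l]; x2 <- d3[labs3 == pr[2], l]
      if (all(is.na(x1)) || all(is.na(x2))) next
      f1 <- mean(x1, na.rm = TRUE) / 2; f2 <- mean(x2, na.rm = TRUE) / 2
      tot <- c(tot, min(f1, f2) + min(1 - f1, 1 - f2))
    }
    expect_equal(M3[pr[1], pr[2]], 1 - mean(tot), tolerance = 1e-12)
  }
})

test_that("unPC scores are centroid distance over kilometres", {
  # demes on one meridian: distances exactly proportional to delta-lat
  cfg <- sim_config(n_demes = 4, n_ind = 8, n_snps = 10, seed = 1)
  dm <- simulate_demes(cfg)
  dm$demes$lat <- c(31, 31.2, 31.5, 32); dm$demes$lon <- 35
  dm$individuals <- data.frame(ind_id = sprintf("I%03d", 1:8),
                               deme_id = rep(dm$demes$deme_id, each = 2))
  S <- matrix(0, 8, 3)
  S[, 1] <- rep(c(0, 1, 3, 6), each = 2)       # centroid geometry by hand
  up <- unpc_scores(S, dm, n_pcs = 3)
  km_ab <- greatcircle_km(dm$demes[, c("lat", "lon")])[1, 2]
  expect_equal(up$score[up$deme_i == "D01" & up$deme_j == "D02"],
               1 / km_ab, tolerance = 1e-10)
  # genetic distance proportional to geography -> all scores equal
  kmfac <- 6371.0088 * pi / 180
  S2 <- matrix(0, 8, 3)
  S2[, 1] <- rep((dm$demes$lat - 31) * kmfac * 2, each = 2)
  up2 <- unpc_scores(S2, dm, n_pcs = 3)
  expect_lt(diff(range(up2$score)), 1e-6)
  # doubling the geographic separations halves every score
  dm2 <- dm
  dm2$demes$lat <- 31 + (dm$demes$lat - 31) * 2
  up3 <- unpc_scores(S, dm2, n_pcs = 3)
  expect_equal(up3$score, up$score / 2, tolerance = 1e-6)
})

test_that("Box-Cox exponent recovers the generating transform", {
  set.seed(802)
  ln <- exp(rnorm(500))
  bc <- boxcox_outlier_test(ln)
  expect_gte(bc$lambda, -0.2); expect_lte(bc$lambda, 0.2)
  ga <- rnorm(500, mean = 10, sd = 2)
  bc2 <- boxcox_outlier_test(ga)
  expect_gte(bc2$lambda, 0.7); expect_lte(bc2$lambda, 1.3)
  expect_error(boxcox_outlier_test(c(1, 2, 3)), "5 pairs")
})

test_that("a planted extreme is flagged and its removal un-flags the rest", {
  set.seed(803)
  # a short-tailed base sample: standardized uniform never exceeds ~1.73,
  # below the two-sided t criterion, so only the plant is flagged
  x <- runif(200, 9, 11)
  x[7] <- 10 + 8 * sd(x)
  bc <- boxcox_outlier_test(x)
  expect_true(7 %in% bc$high)
  bc2 <- boxcox_outlier_test(x[-7])
  expect_equal(length(bc2$high), 0)
  # quantile variant flags the top/bottom 2.5%
  bcq <- boxcox_outlier_test(x, method = "quantile")
  expect_true(7 %in% bcq$high)
  expect_lte(length(bcq$high) + length(bcq$low), ceiling(0.05 * 200) + 2)
})

test_that("IBD anomalies: long-range similarity low, cross-barrier isolation high", {
  set.seed(804)
  cfg <- sim_config(n_demes = 20, n_ind = 40, n_snps = 10, seed = 5)
  dm <- simulate_demes(cfg)
  dm$individuals <- data.frame(ind_id = sprintf("I%03d", 1:40),
                               deme_id = rep(dm$demes$deme_id, each = 2))
  # genetic positions proportional to geography plus mild noise = pure IBD
  base <- cbind(dm$demes$x_km, dm$demes$y_km, 0)
  S <- (base + matrix(rnorm(60, sd = 3), 20, 3))[rep(1:20, each = 2), ]
  up <- unpc_scores(S, dm, n_pcs = 3)
  # plant a long-distance migration pair: make the two most distant demes
  # genetically identical
  km <- greatcircle_km(dm$demes[, c("lat", "lon")])
  far <- which(km == max(km), arr.ind = TRUE)[1, ]
  S2 <- S
  S2[rep(1:20, each = 2) == far[2], ] <-
    S[rep(1:20, each = 2) == far[1], , drop = FALSE]
  up_low <- unpc_scores(S2, dm, n_pcs = 3)
  bc_low <- boxcox_outlier_test(up_low)
  pair_idx <- which((up_low$deme_i == dm$demes$deme_id[far[1]] &
                     up_low$deme_j == dm$demes$deme_id[far[2]]) |
                    (up_low$deme_i == dm$demes$deme_id[far[2]] &
                     up_low$deme_j == dm$demes$deme_id[far[1]]))
  expect_true(pair_idx %in% bc_low$low)
  # plant an isolation pair: nearest demes pushed genetically far apart
  km2 <- km; diag(km2) <- Inf
  near <- which(km2 == min(km2), arr.ind = TRUE)[1, ]
  S3 <- S
  S3[rep(1:20, each = 2) == near[2], 3] <-
    S3[rep(1:20, each = 2) == near[2], 3] + 120
  up_high <- unpc_scores(S3, dm, n_pcs = 3)
  bc_high <- boxcox_outlier_test(up_high)
  pair_idx2 <- which((up_high$deme_i == dm$demes$deme_id[near[1]] &
                      up_high$deme_j == dm$demes$deme_id[near[2]]) |
                     (up_high$deme_i == dm$demes$deme_id[near[2]] &
                      up_high$deme_j == dm$demes$deme_id[near[1]]))
  expect_true(pair_idx2 %in% bc_high$high)
})

test_that("rank test behaves at both extremes and under mask complement", {
  m <- matrix(rnorm(400), 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[, 1:8] <- TRUE
  r <- raster_grid(m, 1, c(0, 0), mask = mask)
  # identical distributions: p near 0.5
  expect_gt(barrier_rate_test(r)$p, 0.05)
  # complete separation
  m2 <- m; m2[mask] <- m2[mask] - 100
  r2 <- raster_grid(m2, 1, c(0, 0), mask = mask)
  expect_lt(barrier_rate_test(r2)$p, 1e-6)
  # ties: identical values in both classes
  r3 <- raster_grid(matrix(1, 10, 10), 1, c(0, 0),
                    mask = matrix(rep(c(TRUE, FALSE), 50), 10, 10))
  expect_equal(barrier_rate_test(r3)$p, 0.5, tolerance = 0.05)
  # swapping the mask flips the one-sided p
  r4 <- raster_grid(m2, 1, c(0, 0), mask = !mask)
  expect_gt(barrier_rate_test(r4)$p, 1 - 1e-6)
  expect_error(barrier_rate_test(raster_grid(m, 1, c(0, 0))), "mask")
})
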
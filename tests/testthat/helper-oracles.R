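# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use a different computational route (explicit hat
# matrices, dense eigensolves, elementwise loops) than the package code.

# Brute-force redundancy analysis: explicit hat matrices and dense
# eigendecomposition; pseudo-inverses via MASS::ginv.
oracle_rda <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_all <- sum(Yc^2)
  q <- 0
  Yr <- Yc; Xr <- X
  if (!is.null(Z)) {
    M <- cbind(1, as.matrix(Z))
    Hz <- M %*% MASS::ginv(crossprod(M)) %*% t(M)
    q <- qr(sweep(as.matrix(Z), 2, colMeans(as.matrix(Z))))$rank
    Yr <- Yc - Hz %*% Yc
    Xr <- X - Hz %*% X
  }
  Xrc <- sweep(Xr, 2, colMeans(Xr))
  Hx <- Xrc %*% MASS::ginv(crossprod(Xrc)) %*% t(Xrc)
  fitted <- Hx %*% Yr
  p <- qr(Xrc)$rank
  ss_fit <- sum(fitted^2)
  ss_res <- sum((Yr - fitted)^2)
  r2 <- ss_fit / ss_all
  ev <- eigen(crossprod(fitted), symmetric = TRUE)$values
  list(r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1 - q) / (n - 1 - q - p),
       eig = ev[ev > 1e-8 * max(ev, 1e-300)],
       F = (ss_fit / p) / (ss_res / (n - p - q - 1)),
       p_rank = p)
}

# All permutations of a small vector (for label-switching in Q recovery).
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(perms_of(v[-i]), function(p) c(v[i], p))))
}

min_perm_rmse <- function(Qhat, Qtrue) {
  K <- ncol(Qtrue)
  min(vapply(perms_of(seq_len(K)), function(p)
    sqrt(mean((Qhat[, p, drop = FALSE] - Qtrue)^2)), numeric(1)))
}

# Elementwise greedy LD-prune oracle on a precomputed r^2 matrix.
oracle_greedy_prune <- function(R2, window, r2_max) {
  keep <- logical(nrow(R2))
  retained <- integer(0)
  for (j in seq_len(nrow(R2))) {
    cand <- utils::tail(retained, window)
    drop <- any(R2[cand, j] > r2_max)
    if (!drop) retained <- c(retained, j)
    keep[j] <- !drop
  }
  keep
}

# Island-model genotypes: K populations with Balding-Nichols frequencies at
# a target FST, individuals drawn binomially from their own population.
island_sim <- function(n_per_pop, n_pops, m, fst, seed) {
  set.seed(seed)
  p0 <- runif(m, 0.1, 0.9)
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  P <- sapply(seq_len(m), function(l) rbeta(n_pops, a[l], b[l]))
  G <- do.call(rbind, lapply(seq_len(n_pops), function(k)
    matrix(rbinom(n_per_pop * m, 2, rep(P[k, ], each = n_per_pop)),
           n_per_pop, m)))
  sites <- data.frame(chrom = "1H", pos = seq_len(m) * 10L,
                      ref = "A", alt = "C")
  list(geno = geno_matrix(G, sprintf("i%04d", seq_len(n_per_pop * n_pops)),
                          sites),
       labels = rep(seq_len(n_pops), each = n_per_pop), P = P)
}

# Small standard simulated landscape shared by several tests.
tiny_landscape <- function(seed = 42, n_demes = 15, n_ind = 90,
                           n_snps = 600, ...) {
  cfg <- sim_config(n_demes = n_demes, n_ind = n_ind, n_snps = n_snps,
                    seed = seed, ...)
  dm <- simulate_demes(cfg)
  env <- simulate_env(dm, seed = seed)
  sim <- simulate_genotypes(cfg, dm, env)
  list(cfg = cfg, dm = dm, env = env, geno = sim$geno, truth = sim$truth)
}
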
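# Population-structure inference and genetic differentiation: PCA with
# projection, latent-dimension (K) estimation, ancestry-coefficient
# factorization by alternating constrained least squares, cluster
# assignment, Hudson ratio-of-averages FST, Nei (1972) distance, and
# neighbor-joining trees.

#' Principal component analysis of an imputed dosage matrix
#'
#' Columns are centered (Patterson `p(1-p)` or unit-variance scaling
#' optional, off by default since dosages share a scale); the covariance is
#' eigen-decomposed via SVD. Axis signs are fixed so the largest-magnitude
#' site loading on each axis is positive.
#'
#' @param X Numeric individuals x sites matrix without missing values.
#' @param n_axes Number of axes to retain.
#' @param scaling `"none"` (default), `"sd"` (unit variance), or
#'   `"patterson"` (`sqrt(p(1-p))` with `p` the allele frequency).
#' @return A `pca_result`: `eigenvectors` (site loadings), `eigenvalues`
#'   (covariance eigenvalues, all axes), `scores`, `prop_var`, `center`,
#'   `scale`.
#' @export
run_pca <- function(X, n_axes = 10, scaling = c("none", "sd", "patterson")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (any(is.na(X))) stop("X must be imputed (no missing values)")
  ctr <- colMeans(X)
  scl <- switch(scaling,
                none = rep(1, ncol(X)),
                sd = apply(X, 2, stats::sd),
                patterson = { p <- ctr / 2; sqrt(pmax(p * (1 - p), 1e-12)) })
  if (any(scl == 0)) scl[scl == 0] <- 1
  Xc <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  sv <- svd(Xc)
  eigval <- sv$d^2 / (nrow(X) - 1)
  rank <- sum(sv$d > 1e-10 * sv$d[1])
  if (n_axes > rank) {
    warning("n_axes exceeds rank (", rank, "); truncated")
    n_axes <- rank
  }
  V <- sv$v[, seq_len(n_axes), drop = FALSE]
  # sign convention: largest-|loading| element positive
  for (a in seq_len(n_axes)) {
    i <- which.max(abs(V[, a]))
    if (V[i, a] < 0) V[, a] <- -V[, a]
  }
  scores <- Xc %*% V
  rownames(scores) <- rownames(X)
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(n_axes))
  structure(list(eigenvectors = V, eigenvalues = eigval,
                 scores = scores,
                 prop_var = eigval / sum(eigval),
                 center = ctr, scale = scl, scaling = scaling),
            class = "pca_result")
}

#' Project new individuals onto existing principal axes
#'
#' Scores are inner products of the (centered, optionally scaled) new
#' genotypes with the stored eigenvectors.
#'
#' @param X_new Matrix with the same site set and order as the PCA input.
#' @param pca A `pca_result` from [run_pca()].
#' @return Score matrix for the new rows.
#' @export
project_pca <- function(X_new, pca) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(pca$center))
    stop("site set of X_new disagrees with the fitted PCA")
  Xc <- sweep(sweep(X_new, 2, pca$center), 2, pca$scale, `/`)
  Xc %*% pca$eigenvectors
}

#' Estimate the number of ancestral clusters K
#'
#' Parallel analysis on the standardized genotype matrix: K - 1 structure
#' axes are those whose covariance eigenvalues exceed the maximum eigenvalue
#' observed over `n_perm` replicates in which every column is independently
#' permuted (destroying structure but preserving margins); K adds one for
#' the mean component of the frequency matrix.
#'
#' @param X Imputed dosage matrix.
#' @param n_perm Number of permutation replicates.
#' @param seed Integer seed.
#' @return Integer K >= 1.
#' @export
estimate_d <- function(X, n_perm = 20, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 individuals")
  if (any(is.na(X))) stop("X must be imputed")
  sdv <- apply(X, 2, stats::sd)
  Xs <- sweep(sweep(X[, sdv > 0, drop = FALSE], 2,
                    colMeans(X[, sdv > 0, drop = FALSE])),
              2, sdv[sdv > 0], `/`)
  ev <- svd(Xs, nu = 0, nv = 0)$d^2
  with_seed(derive_seed(seed, "estimate_d"), {
    null_max <- vapply(seq_len(n_perm), function(r) {
      Xp <- apply(Xs, 2, sample)
      svd(Xp, nu = 0, nv = 0)$d[1]^2
    }, numeric(1))
    as.integer(sum(ev > max(null_max)) + 1L)
  })
}

# Exact simplex-constrained least squares, shared design across rows.
# Minimizes ||B - A q||^2 per column of B s.t. q >= 0, sum(q) = 1, by
# enumerating zero-supports (exact for small K).
simplex_ls <- function(AtA, AtB, B2) {
  K <- nrow(AtA); n <- ncol(AtB)
  best_obj <- rep(Inf, n)
  best_q <- matrix(1 / K, K, n)
  supports <- lapply(seq_len(2^K - 1), function(code)
    which(bitwAnd(code, 2^(seq_len(K) - 1)) > 0))
  for (S in supports) {
    k <- length(S)
    A_SS <- AtA[S, S, drop = FALSE] + diag(1e-10, k)
    Ai <- tryCatch(solve(A_SS), error = function(e) NULL)
    if (is.null(Ai)) next
    b_S <- AtB[S, , drop = FALSE]
    u <- Ai %*% b_S                       # k x n
    w <- Ai %*% rep(1, k)                 # k x 1
    mu <- (colSums(u) - 1) / sum(w)
    q_S <- u - w %*% rbind(mu)            # k x n
    feas <- colSums(q_S < -1e-9) == 0
    if (!any(feas)) next
    obj <- B2 - 2 * colSums(q_S * b_S) +
      colSums(q_S * (A_SS %*% q_S))
    upd <- feas & obj < best_obj - 1e-12
    if (any(upd)) {
      best_obj[upd] <- obj[upd]
      best_q[, upd] <- 0
      best_q[S, upd] <- pmax(q_S[, upd, drop = FALSE], 0)
    }
  }
  best_q / rep(colSums(best_q), each = K)
}

#' Ancestry-coefficient factorization by alternating least squares
#'
#' Likelihood-free two-step estimator: (i) the individual-specific frequency
#' matrix `F` is the projection of `X/2` onto its top-K principal subspace,
#' clipped to `[0, 1]`; (ii) `F ~ Q P` is factorized by alternating
#' constrained least squares with `Q` rows on the K-simplex (exact
#' support-enumeration solver) and `P` in `[0, 1]` (clipped coordinate
#' descent), iterated until the relative objective change falls below `tol`.
#' Initialization is deterministic (pivoted anchor rows of `F`), so results
#' are seed-free.
#'
#' @param X Imputed dosage matrix (n x m).
#' @param K Number of ancestral clusters.
#' @param tol Relative objective tolerance.
#' @param max_iter Iteration cap.
#' @return An `ancestry_matrix`: `Q` (n x K, rows sum to 1), `P` (K x m in
#'   `[0, 1]`), `K`, `objective` (trace of `||F - QP||^2`).
#' @export
estimate_ancestry <- function(X, K, tol = 1e-6, max_iter = 1000) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (K < 1) stop("K must be >= 1")
  if (K > min(n, m)) stop("K exceeds min(n, m)")
  if (any(is.na(X))) stop("X must be imputed")
  Fhat <- X / 2
  sv <- svd(Fhat, nu = K, nv = K)
  Fhat <- sv$u %*% (diag(sv$d[seq_len(K)], K) %*% t(sv$v))
  Fhat <- pmin(pmax(Fhat, 0), 1)
  if (K == 1) {
    Q <- matrix(1, n, 1)
    P <- matrix(colMeans(Fhat), 1, m)
    return(structure(list(Q = Q, P = P, K = 1L,
                          objective = sum((Fhat - Q %*% P)^2)),
                     class = "ancestry_matrix"))
  }
  # deterministic anchors: successive rows of F maximizing residual norm
  anchors <- integer(K)
  R <- Fhat
  for (k in seq_len(K)) {
    norms <- rowSums(R^2)
    norms[anchors[seq_len(k - 1)]] <- -Inf
    anchors[k] <- which.max(norms)
    v <- R[anchors[k], ]
    nv <- sum(v^2)
    if (nv > 0) R <- R - (R %*% v) %*% rbind(v) / nv
  }
  P <- Fhat[anchors, , drop = FALSE]
  Q <- matrix(1 / K, n, K)
  obj_trace <- numeric(0)
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    # Q step: exact simplex-constrained LS per row
    AtA <- P %*% t(P)
    AtB <- P %*% t(Fhat)
    Q <- t(simplex_ls(AtA, AtB, rowSums(Fhat^2)))
    # P step: clipped coordinate descent (3 sweeps), monotone
    QtQ <- crossprod(Q)
    QtF <- crossprod(Q, Fhat)
    for (sweep_i in 1:3) {
      for (k in seq_len(K)) {
        resid_k <- QtF[k, ] - QtQ[k, ] %*% P + QtQ[k, k] * P[k, ]
        if (QtQ[k, k] > 1e-12)
          P[k, ] <- pmin(pmax(as.numeric(resid_k) / QtQ[k, k], 0), 1)
      }
    }
    obj <- sum(Fhat^2) - 2 * sum(QtF * P) + sum((QtQ %*% P) * P)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(obj_old, 1e-12))
      break
    obj_old <- obj
  }
  structure(list(Q = Q, P = P, K = as.integer(K), objective = obj_trace),
            class = "ancestry_matrix")
}

#' @export
print.ancestry_matrix <- function(x, ...) {
  cat(sprintf("<ancestry_matrix> %d individuals, K = %d\n",
              nrow(x$Q), x$K))
  invisible(x)
}

#' Assign individuals to clusters by highest ancestry coefficient
#'
#' Ties break toward the lowest cluster index. Also reports the fraction of
#' individuals whose largest coefficient is below `admixed_below` (admixed
#' individuals).
#'
#' @param Q Ancestry matrix (n x K) or an `ancestry_matrix`.
#' @param admixed_below Threshold for the admixture report.
#' @return List: `labels` (integer), `frac_admixed`.
#' @export
assign_clusters <- function(Q, admixed_below = 0.9) {
  if (inherits(Q, "ancestry_matrix")) Q <- Q$Q
  Q <- as.matrix(Q)
  labels <- apply(Q, 1, which.max)   # which.max = first max: lowest index
  list(labels = as.integer(labels),
       frac_admixed = mean(apply(Q, 1, max) < admixed_below))
}

# Per-pair allele frequencies and counts on non-missing calls.
pop_freqs <- function(G, labels) {
  labs <- sort(unique(labels))
  freq <- list(); cnt <- list()
  for (l in labs) {
    sub <- G$dosage[labels == l, , drop = FALSE]
    nall <- 2 * colSums(!is.na(sub))
    freq[[as.character(l)]] <- ifelse(nall > 0,
                                      colSums(sub, na.rm = TRUE) / nall, NA)
    cnt[[as.character(l)]] <- nall
  }
  list(labs = labs, freq = freq, cnt = cnt)
}

hudson_components <- function(p1, p2, n1, n2) {
  ok <- n1 >= 2 & n2 >= 2 & !is.na(p1) & !is.na(p2)
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  N[!ok] <- NA; D[!ok] <- NA
  list(N = N, D = D)
}

#' Hudson-style FST as a ratio of averages
#'
#' Per site, with sample alternate-allele frequencies `p1`, `p2` and allele
#' counts `n1`, `n2`:
#' `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)`. The pairwise estimate is `sum(N)/sum(D)` over
#' sites with `D > 0`; sites with `D = 0` (or fewer than 2 observed alleles
#' in either population) are skipped and counted. Negative estimates are
#' reported as-is.
#'
#' @param G A [geno_matrix()].
#' @param labels Cluster label per individual.
#' @return List: `dist` (a [dist_matrix()] tagged `"fst"`), `per_site`
#'   (list of per-pair `N`, `D` vectors), `n_skipped` (per-pair counts).
#' @export
hudson_fst <- function(G, labels) {
  stopifnot(inherits(G, "geno_matrix"), length(labels) == nrow(G$dosage))
  pf <- pop_freqs(G, labels)
  labs <- pf$labs
  if (length(labs) < 2) stop("need at least 2 clusters")
  for (l in labs) {
    if (all(pf$cnt[[as.character(l)]] < 2))
      stop("cluster ", l, " has fewer than 2 observed alleles at every site")
  }
  k <- length(labs)
  M <- matrix(0, k, k)
  per_site <- list(); n_skipped <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ci <- as.character(labs[i]); cj <- as.character(labs[j])
    hc <- hudson_components(pf$freq[[ci]], pf$freq[[cj]],
                            pf$cnt[[ci]], pf$cnt[[cj]])
    use <- !is.na(hc$D) & hc$D > 0
    M[i, j] <- M[j, i] <- sum(hc$N[use]) / sum(hc$D[use])
    key <- paste(labs[i], labs[j], sep = "-")
    per_site[[key]] <- list(N = hc$N, D = hc$D)
    n_skipped[[key]] <- sum(!use)
  }
  list(dist = dist_matrix(M, as.character(labs), "fst"),
       per_site = per_site, n_skipped = n_skipped)
}

#' Windowed FST genome profile
#'
#' Ratio-of-averages FST within sliding windows along each chromosome, for
#' every pair of clusters. Windows with no usable site are skipped and
#' counted. Output uses 0-based half-open starts (BED-like track
#' convention); site positions remain 1-based elsewhere.
#'
#' @param G A [geno_matrix()].
#' @param labels Cluster label per individual.
#' @param window_bp Window width in bp (used unless `window_snps` given).
#' @param window_snps Optional window width in SNPs.
#' @return List: `track` (data.frame `chrom`, `start`, `end`, `pair`,
#'   `fst`, `n_sites`), `n_empty` windows skipped.
#' @export
fst_profile <- function(G, labels, window_bp = 1e7, window_snps = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  pf <- pop_freqs(G, labels)
  labs <- pf$labs
  pairs <- utils::combn(seq_along(labs), 2)
  rows <- list(); n_empty <- 0L
  for (ch in unique(G$sites$chrom)) {
    idx <- which(G$sites$chrom == ch)
    pos <- G$sites$pos[idx]
    if (!is.null(window_snps)) {
      starts_i <- seq(1, length(idx), by = window_snps)
      bounds <- lapply(starts_i, function(s)
        idx[s:min(s + window_snps - 1, length(idx))])
      lims <- lapply(bounds, function(b)
        c(G$sites$pos[b[1]] - 1L, G$sites$pos[b[length(b)]]))
    } else {
      brk <- seq(0, max(pos), by = window_bp)
      bounds <- lapply(brk, function(s) idx[pos > s & pos <= s + window_bp])
      lims <- lapply(brk, function(s) c(s, s + window_bp))
    }
    for (w in seq_along(bounds)) {
      sites_w <- bounds[[w]]
      if (!length(sites_w)) { n_empty <- n_empty + 1L; next }
      for (pp in seq_len(ncol(pairs))) {
        i <- pairs[1, pp]; j <- pairs[2, pp]
        ci <- as.character(labs[i]); cj <- as.character(labs[j])
        hc <- hudson_components(pf$freq[[ci]][sites_w],
                                pf$freq[[cj]][sites_w],
                                pf$cnt[[ci]][sites_w],
                                pf$cnt[[cj]][sites_w])
        use <- !is.na(hc$D) & hc$D > 0
        if (!any(use)) { n_empty <- n_empty + 1L; next }
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start = lims[[w]][1], end = lims[[w]][2],
          pair = paste(labs[i], labs[j], sep = "-"),
          fst = sum(hc$N[use]) / sum(hc$D[use]),
          n_sites = sum(use), stringsAsFactors = FALSE)
      }
    }
  }
  list(track = do.call(rbind, rows), n_empty = n_empty)
}

#' Nei (1972) standard genetic distance
#'
#' With per-locus allele-frequency vectors `x`, `y` pooled over loci:
#' `D = -ln( sum(x y) / sqrt(sum(x^2) sum(y^2)) )`. Cluster allele
#' frequencies come from non-missing calls; loci monomorphic in both
#' clusters contribute to the sums.
#'
#' @param G A [geno_matrix()].
#' @param labels Cluster label per individual.
#' @return A [dist_matrix()] tagged `"nei"`.
#' @export
nei_distance <- function(G, labels) {
  stopifnot(inherits(G, "geno_matrix"))
  pf <- pop_freqs(G, labels)
  labs <- pf$labs
  k <- length(labs)
  M <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- pf$freq[[as.character(labs[i])]]
    y <- pf$freq[[as.character(labs[j])]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    jxy <- sum(x * y + (1 - x) * (1 - y))
    jx <- sum(x^2 + (1 - x)^2)
    jy <- sum(y^2 + (1 - y)^2)
    ratio <- jxy / sqrt(jx * jy)
    if (ratio <= 0) stop("zero allele identity between clusters ",
                         labs[i], " and ", labs[j], ": infinite distance")
    M[i, j] <- M[j, i] <- -log(ratio)
  }
  dist_matrix(M, as.character(labs), "nei")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q break
#' toward the lowest index pair; negative branch lengths are clamped to zero
#' with the deficit moved to the sister branch. Exact for additive
#' distances.
#'
#' @param D A [dist_matrix()] or symmetric matrix with labels.
#' @return Newick string (unrooted, trifurcating root).
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist_matrix")) { labels <- D$labels; M <- D$mat }
  else { M <- as.matrix(D); labels <- rownames(M) }
  if (is.null(labels)) labels <- as.character(seq_len(nrow(M)))
  if (any(is.na(M))) stop("distance matrix contains NaN/NA")
  if (max(abs(M - t(M))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(M)
  if (n < 3) stop("need at least 3 taxa")
  nodes <- labels                       # newick fragment per active node
  active <- seq_len(n)
  repeat {
    r <- length(active)
    if (r == 3) break
    Dm <- M[active, active, drop = FALSE]
    R <- rowSums(Dm)
    Qm <- (r - 2) * Dm - outer(R, R, `+`)
    diag(Qm) <- Inf
    # lowest-index-pair tie break: scan column-major over i < j
    best <- c(NA, NA); bestq <- Inf
    for (ii in 1:(r - 1)) for (jj in (ii + 1):r) {
      if (Qm[ii, jj] < bestq - 1e-12) { bestq <- Qm[ii, jj]; best <- c(ii, jj) }
    }
    i <- best[1]; j <- best[2]
    dij <- Dm[i, j]
    vi <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    ai <- active[i]; aj <- active[j]
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", nodes[ai], vi, nodes[aj], vj)
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    # replace node i with the merged node, drop j
    M <- rbind(M, 0); M <- cbind(M, 0)
    u <- nrow(M)
    M[u, active] <- dnew; M[active, u] <- dnew
    M[u, u] <- 0
    nodes <- c(nodes, newfrag)
    active <- c(active[-c(i, j)], u)
  }
  # resolve the final three nodes as a star
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (M[a, b] + M[a, c3] - M[b, c3]) / 2
  vb <- (M[a, b] + M[b, c3] - M[a, c3]) / 2
  vc <- (M[a, c3] + M[b, c3] - M[a, b]) / 2
  if (va < 0) { vb <- vb + va / 2; vc <- vc + va / 2; va <- 0 }
  if (vb < 0) { va <- va + vb / 2; vc <- vc + vb / 2; vb <- 0 }
  if (vc < 0) { va <- va + vc / 2; vb <- vb + vc / 2; vc <- 0 }
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
          nodes[a], va, nodes[b], vb, nodes[c3], vc)
}
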
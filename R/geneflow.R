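# Light-weight gene-flow statistics: allele-sharing (Dps) distances, unPC
# scores (PC-space genetic distance over geographic distance) with a
# Box-Cox/Student-t outlier test, and the barrier/low-rate Wilcoxon
# association test.

#' Allele-sharing distance between demes
#'
#' For each deme pair, `p` is the mean over sites of the shared-allele
#' proportion between deme allele-frequency profiles (min-sharing:
#' `sum_alleles min(f1, f2)` per site) and `Dps = 1 - p`. Sites missing in
#' either deme are excluded pairwise.
#'
#' @param G A [geno_matrix()].
#' @param demes A `deme_map` (or a deme label vector per individual).
#' @return A [dist_matrix()] tagged `"dps"`.
#' @export
dps_distance <- function(G, demes) {
  labels <- if (inherits(demes, "deme_map"))
    demes$individuals$deme_id[match(G$ind_ids, demes$individuals$ind_id)]
  else demes
  stopifnot(length(labels) == nrow(G$dosage))
  pf <- pop_freqs(G, labels)
  labs <- pf$labs
  if (length(labs) < 2) stop("need at least 2 demes")
  for (l in labs) {
    if (all(is.na(pf$freq[[as.character(l)]])))
      stop("deme ", l, " has no observed data at any site")
  }
  k <- length(labs)
  M <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- pf$freq[[as.character(labs[i])]]
    y <- pf$freq[[as.character(labs[j])]]
    ok <- !is.na(x) & !is.na(y)
    shared <- pmin(x[ok], y[ok]) + pmin(1 - x[ok], 1 - y[ok])
    M[i, j] <- M[j, i] <- 1 - mean(shared)
  }
  dist_matrix(M, as.character(labs), "dps")
}

#' unPC scores: genetic PC distance over geographic distance
#'
#' Each deme's genetic position is the centroid of its members' scores on
#' the top `n_pcs` axes; the raw score of a deme pair is the Euclidean
#' centroid distance divided by the great-circle distance in km.
#'
#' @param pc_scores Individual score matrix (rows named by individual or
#'   aligned with the deme map's individual table).
#' @param demes A `deme_map`.
#' @param n_pcs Number of leading axes (default 3).
#' @return An `unpc_result` data.frame: `deme_i`, `deme_j`, `km`,
#'   `genetic_dist`, `score`.
#' @export
unpc_scores <- function(pc_scores, demes, n_pcs = 3) {
  stopifnot(inherits(demes, "deme_map"))
  S <- as.matrix(pc_scores)[, seq_len(n_pcs), drop = FALSE]
  stopifnot(nrow(S) == nrow(demes$individuals))
  ids <- demes$demes$deme_id
  if (length(ids) < 3) stop("need at least 3 demes")
  cent <- t(vapply(ids, function(d)
    colMeans(S[demes$individuals$deme_id == d, , drop = FALSE]),
    numeric(n_pcs)))
  D_km <- greatcircle_km(demes$demes[, c("lat", "lon")])
  if (any(D_km[upper.tri(D_km)] == 0)) stop("coincident demes")
  pairs <- utils::combn(seq_along(ids), 2)
  gd <- sqrt(colSums((t(cent)[, pairs[1, ], drop = FALSE] -
                      t(cent)[, pairs[2, ], drop = FALSE])^2))
  km <- D_km[cbind(pairs[1, ], pairs[2, ])]
  out <- data.frame(deme_i = ids[pairs[1, ]], deme_j = ids[pairs[2, ]],
                    km = km, genetic_dist = gd, score = gd / km,
                    stringsAsFactors = FALSE)
  class(out) <- c("unpc_result", class(out))
  out
}

#' Box-Cox transformation and Student-t outlier test of unPC scores
#'
#' The Box-Cox exponent maximizes the profile log-likelihood over the grid
#' `[-2, 2]` (step 0.01). Transformed scores are standardized; a pair is
#' flagged "high" when its standardized value exceeds the two-sided
#' `t_{1-alpha/2, N-1}` critical value, "low" when below its negative.
#' Under isolation by distance the scores are exchangeable, so flagged
#' pairs mark anomalies: "high" = isolation over a short distance, "low" =
#' long-distance genetic similarity. Non-positive scores are shifted by
#' `-min + epsilon` with the shift reported.
#'
#' With `method = "quantile"`, the top and bottom `alpha/2` empirical
#' quantiles are flagged instead.
#'
#' @param scores An `unpc_result` or numeric vector of scores.
#' @param alpha Two-tailed significance level (default 0.05).
#' @param method `"t"` (default) or `"quantile"`.
#' @return List: `table` (input plus `transformed`, `standardized`,
#'   `flag`), `lambda`, `t_crit`, `shift`, `high`, `low` (indices).
#' @export
boxcox_outlier_test <- function(scores, alpha = 0.05,
                                method = c("t", "quantile")) {
  method <- match.arg(method)
  tab <- NULL
  if (inherits(scores, "unpc_result") || is.data.frame(scores)) {
    tab <- as.data.frame(scores)
    x <- tab$score
  } else x <- as.numeric(scores)
  N <- length(x)
  if (N < 5) stop("fewer than 5 pairs; outlier test is meaningless")
  shift <- 0
  if (any(x <= 0)) {
    shift <- -min(x) + 1e-6 * diff(range(x))
    x <- x + shift
  }
  grid <- seq(-2, 2, by = 0.01)
  bc <- MASS::boxcox(x ~ 1, lambda = grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  z <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  zs <- (z - mean(z)) / stats::sd(z)
  if (method == "t") {
    crit <- stats::qt(1 - alpha / 2, df = N - 1)
    high <- which(zs > crit); low <- which(zs < -crit)
  } else {
    crit <- NA_real_
    qs <- stats::quantile(zs, c(alpha / 2, 1 - alpha / 2))
    high <- which(zs > qs[2]); low <- which(zs < qs[1])
  }
  flag <- rep("none", N)
  flag[high] <- "high"; flag[low] <- "low"
  if (!is.null(tab)) {
    tab$transformed <- z; tab$standardized <- zs; tab$flag <- flag
  } else {
    tab <- data.frame(score = x - shift, transformed = z,
                      standardized = zs, flag = flag)
  }
  list(table = tab, lambda = lambda, t_crit = crit, shift = shift,
       high = high, low = low)
}

#' Are barrier cells associated with lower rates?
#'
#' One-sided Mann-Whitney rank-sum test (normal approximation with tie
#' correction) of the hypothesis that masked (barrier) cells of a rate
#' raster have lower values than unmasked cells.
#'
#' @param raster A [raster_grid()] with both mask classes nonempty.
#' @return List: `U` (rank-sum statistic), `p` (one-sided), `n_barrier`,
#'   `n_open`.
#' @export
barrier_rate_test <- function(raster) {
  stopifnot(inherits(raster, "raster_grid"))
  if (is.null(raster$mask)) stop("raster has no barrier mask")
  b <- raster$values[raster$mask]
  o <- raster$values[!raster$mask]
  if (!length(b) || !length(o)) stop("one mask class is empty")
  if (length(unique(c(b, o))) == 1) {
    # fully tied: the rank statistic is degenerate, no evidence either way
    return(list(U = length(b) * length(o) / 2, p = 0.5,
                n_barrier = length(b), n_open = length(o)))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(b, o, alternative = "less", exact = FALSE,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_barrier = length(b), n_open = length(o))
}

#' Write the unPC pair table as CSV
#' @param result Output of [boxcox_outlier_test()] on an `unpc_result`.
#' @param path Output file.
#' @export
write_unpc_table <- function(result, path) {
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}
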
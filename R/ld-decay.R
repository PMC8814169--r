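# Linkage-disequilibrium decay: windowed composite r^2, Hill-Weir expected
# decay curve fitting, loess smoothing, and the half-decay distance.
#
# Because phase is unknown in dosage data, r^2 here is the squared Pearson
# correlation of mean-imputed dosages (composite LD). The Hill-Weir
# expectation concerns gametic r^2, so fitted parameters are interpreted
# comparatively.

#' Windowed pairwise r^2 along the genome
#'
#' For each site, the squared Pearson correlation of mean-imputed dosages
#' against the next `window` sites on the same chromosome; distance is the
#' bp position difference. Pairs involving a monomorphic site are skipped
#' and counted.
#'
#' @param G A [geno_matrix()] (sites sorted by position).
#' @param window Marker lookahead (default 250).
#' @return List: `pairs` (data.frame `chrom`, `pos1`, `pos2`, `dist`,
#'   `r2`), `n_monomorphic_skipped`.
#' @export
pairwise_r2 <- function(G, window = 250) {
  stopifnot(inherits(G, "geno_matrix"), window >= 1)
  X <- impute_mean(G)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ss <- colSums(Xc^2)
  rows <- list(); skipped <- 0L
  for (ch in unique(G$sites$chrom)) {
    idx <- which(G$sites$chrom == ch)
    if (length(idx) < 2) next
    pos <- G$sites$pos[idx]
    for (a in seq_len(length(idx) - 1)) {
      i <- idx[a]
      bs <- idx[(a + 1):min(a + window, length(idx))]
      if (ss[i] == 0) { skipped <- skipped + length(bs); next }
      poly <- ss[bs] > 0
      skipped <- skipped + sum(!poly)
      bs <- bs[poly]
      if (!length(bs)) next
      r2 <- as.numeric(crossprod(Xc[, i], Xc[, bs, drop = FALSE]))^2 /
        (ss[i] * ss[bs])
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, pos1 = pos[a], pos2 = G$sites$pos[bs],
        dist = abs(G$sites$pos[bs] - pos[a]),
        r2 = r2, stringsAsFactors = FALSE)
    }
  }
  list(pairs = do.call(rbind, rows), n_monomorphic_skipped = skipped)
}

#' Hill-Weir expected r^2 at recombination scale C = rho * d
#'
#' `E[r^2](C) = [(10+C) / ((2+C)(11+C))] *
#'   [1 + ((3+C)(12+12C+C^2)) / (n(2+C)(11+C))]` for sample size `n`.
#'
#' @param C Population recombination parameter (`rho * distance`).
#' @param n Sample size (number of individuals).
#' @return Expected r^2.
#' @export
hill_weir_expectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir decay curve
#'
#' Least squares over `rho > 0` (bounded scalar optimization on
#' `[1e-8, 10]` per bp) of the Hill-Weir expectation against bin means of
#' r^2 on log-spaced distance bins (binning stabilizes the heteroscedastic,
#' short-distance-dominated pair cloud; set `bins = 0` to fit raw pairs).
#'
#' @param pairs Data frame with `dist` and `r2` (e.g. from
#'   [pairwise_r2()]`$pairs`).
#' @param n Sample size used in the expectation.
#' @param bins Number of log-spaced distance bins (default 50).
#' @return An `ld_decay_fit`: `rho`, `n`, `curve` (function of distance),
#'   `r2_max`, `half_decay_bp` (NA when right-censored on the grid),
#'   `grid` (data.frame `dist`, `r2`).
#' @export
fit_hill_weir <- function(pairs, n, bins = 50) {
  pairs <- pairs[is.finite(pairs$r2) & pairs$dist > 0, ]
  if (nrow(pairs) < 50)
    warning("fewer than 50 pairs; the decay fit will be unstable")
  if (bins > 0) {
    brk <- exp(seq(log(min(pairs$dist)), log(max(pairs$dist)),
                   length.out = bins + 1))
    brk[1] <- brk[1] * (1 - 1e-9)
    bin <- cut(pairs$dist, brk, include.lowest = TRUE)
    d_fit <- tapply(pairs$dist, bin, mean)
    r_fit <- tapply(pairs$r2, bin, mean)
    keep <- !is.na(d_fit)
    d_fit <- d_fit[keep]; r_fit <- r_fit[keep]
  } else {
    d_fit <- pairs$dist; r_fit <- pairs$r2
  }
  obj <- function(log_rho)
    sum((r_fit - hill_weir_expectation(exp(log_rho) * d_fit, n))^2)
  opt <- stats::optimize(obj, interval = log(c(1e-8, 10)))
  rho <- exp(opt$minimum)
  if (!is.finite(opt$objective))
    stop("Hill-Weir fit failed to converge; objective non-finite ",
         "(rho = ", rho, ")")
  curve_fn <- function(d) hill_weir_expectation(rho * d, n)
  grid_d <- exp(seq(log(max(min(d_fit), 1)), log(max(d_fit)),
                    length.out = 512))
  grid_r <- curve_fn(grid_d)
  structure(list(rho = rho, n = n, curve = curve_fn,
                 r2_max = max(grid_r),
                 half_decay_bp = .half_decay_grid(grid_d, grid_r),
                 grid = data.frame(dist = grid_d, r2 = grid_r)),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<ld_decay_fit> rho = %.3g /bp, n = %d, r2_max = %.3f, half-decay = %s bp\n",
    x$rho, x$n, x$r2_max,
    if (is.na(x$half_decay_bp)) "censored" else
      format(x$half_decay_bp, digits = 4)))
  invisible(x)
}

.half_decay_grid <- function(dist, r2) {
  half <- max(r2) / 2
  i <- which(r2 <= half)
  if (!length(i)) return(NA_real_)
  dist[min(i)]
}

#' Loess smoothing of the r^2 decay cloud
#'
#' Tricube-weighted local linear regression of r^2 on distance with
#' neighborhood fraction `span`, evaluated on a 512-point log-spaced grid.
#'
#' @param pairs Data frame with `dist` and `r2` (>= 100 pairs).
#' @param span Neighborhood fraction (default 0.005).
#' @return List: `grid` (data.frame `dist`, `r2`), `r2_max`,
#'   `half_decay_bp`, `span`.
#' @export
smooth_decay <- function(pairs, span = 0.005) {
  pairs <- pairs[is.finite(pairs$r2) & pairs$dist > 0, ]
  if (nrow(pairs) < 100) stop("need at least 100 pairs for smoothing")
  if (span * nrow(pairs) < 3)
    stop("span so small that neighborhoods have fewer than 3 points")
  fit <- stats::loess(r2 ~ dist, data = pairs, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid_d <- exp(seq(log(min(pairs$dist)), log(max(pairs$dist)),
                    length.out = 512))
  grid_r <- stats::predict(fit, newdata = data.frame(dist = grid_d))
  list(grid = data.frame(dist = grid_d, r2 = grid_r),
       r2_max = max(grid_r, na.rm = TRUE),
       half_decay_bp = .half_decay_grid(grid_d[!is.na(grid_r)],
                                        grid_r[!is.na(grid_r)]),
       span = span)
}

#' Half-decay distance of a decay curve
#'
#' Smallest grid distance at which the curve drops to half its maximum.
#'
#' @param fit An `ld_decay_fit`, the output of [smooth_decay()], or a list
#'   with a `grid` data.frame (`dist`, `r2`).
#' @return List: `half_decay_bp` (NA when the curve never reaches half its
#'   maximum on the grid, i.e. right-censored), `r2_max`, `censored`.
#' @export
half_decay <- function(fit) {
  g <- fit$grid
  hd <- .half_decay_grid(g$dist, g$r2)
  list(half_decay_bp = hd, r2_max = max(g$r2), censored = is.na(hd))
}
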
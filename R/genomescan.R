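# RDA-based genome scan: SNP loadings on the leading constrained axes are
# converted to Mahalanobis distances, recalibrated by the genomic inflation
# factor against a chi-squared null, and thresholded by FDR.

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment with monotonicity enforcement (cumulative minimum
#' from the largest p-value).
#'
#' @param p Vector of p-values in `[0, 1]` (no NaN).
#' @return Vector of q-values.
#' @export
bh_qvalues <- function(p) {
  if (any(is.na(p))) stop("NaN/NA in p-values")
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Mahalanobis genome scan on RDA loadings
#'
#' Takes the m x k response-loading matrix of a fitted RDA; computes
#' `D2_i = (l_i - mu)' Sigma^-1 (l_i - mu)` with `mu`, `Sigma` the loading
#' mean and covariance over all SNPs (optionally trimmed); estimates the
#' genomic inflation factor `lambda = median(D2) / qchisq(0.5, k)`;
#' converts `D2 / lambda` to upper-tail chi-squared(k) p-values, then BH
#' q-values; flags candidates at `q < fdr`.
#'
#' @param result An `rda_result` with at least `k` constrained axes.
#' @param k Number of axes (default 4).
#' @param fdr FDR threshold for candidate flagging.
#' @param trim Fraction of extreme loadings trimmed per axis when
#'   estimating `mu`/`Sigma` (0 = classical estimator, the default; the
#'   lambda step supplies outlier robustness).
#' @return A `scan_result`: data.frame `stats` (`D2`, `p`, `q`,
#'   `candidate`) plus `k`, `lambda`, `fdr`, `loadings`.
#' @export
rda_scan <- function(result, k = 4, fdr = 0.05, trim = 0) {
  stopifnot(inherits(result, "rda_result"))
  have <- sum(result$eig > 1e-12 * max(result$eig, .Machine$double.eps))
  have <- min(have, ncol(result$loadings))
  if (k > have)
    stop("k = ", k, " exceeds the ", have, " available constrained axes")
  L <- result$loadings[, seq_len(k), drop = FALSE]
  if (trim > 0) {
    keep <- rep(TRUE, nrow(L))
    for (a in seq_len(k)) {
      qs <- stats::quantile(L[, a], c(trim / 2, 1 - trim / 2))
      keep <- keep & L[, a] >= qs[1] & L[, a] <= qs[2]
    }
    mu <- colMeans(L[keep, , drop = FALSE])
    Sg <- stats::cov(L[keep, , drop = FALSE])
  } else {
    mu <- colMeans(L)
    Sg <- stats::cov(L)
  }
  if (rcond(Sg) < 1e-12)
    stop("singular loading covariance; try fewer axes (k)")
  D2 <- stats::mahalanobis(L, mu, Sg)
  lambda <- stats::median(D2) / stats::qchisq(0.5, df = k)
  p <- stats::pchisq(D2 / lambda, df = k, lower.tail = FALSE)
  q <- bh_qvalues(p)
  stats_df <- data.frame(D2 = D2, p = p, q = q, candidate = q < fdr)
  rownames(stats_df) <- rownames(L)
  structure(list(stats = stats_df, k = as.integer(k), lambda = lambda,
                 fdr = fdr, loadings = L),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "<scan_result> %d SNPs, k = %d, lambda = %.3f, %d candidates (FDR < %g)\n",
    nrow(x$stats), x$k, x$lambda, sum(x$stats$candidate), x$fdr))
  invisible(x)
}

#' Simple and structure-corrected genome scans
#'
#' Runs the RDA of imputed dosages on the environmental variables without
#' and with ancestry covariates (one ancestry column dropped), then the
#' Mahalanobis scan on each, and reports the candidate-set overlap.
#'
#' SNP columns are standardized (unit variance) before the scan RDA so that
#' loadings of SNPs with different allele frequencies are on a common scale;
#' without this, high-MAF SNPs dominate the Mahalanobis statistic and its
#' chi-squared calibration breaks down.
#'
#' @param G A [geno_matrix()] (or an already-imputed numeric matrix).
#' @param env An [env_table()] or matrix over individuals.
#' @param Q Optional ancestry matrix for the corrected scan.
#' @param k Number of axes.
#' @param fdr FDR threshold.
#' @param scale_response Standardize SNP columns (default TRUE).
#' @return List: `simple` and (when `Q` given) `corrected` `scan_result`s,
#'   and `overlap` (count of shared candidates).
#' @export
scan_pipeline <- function(G, env, Q = NULL, k = 4, fdr = 0.05,
                          scale_response = TRUE) {
  Y <- if (inherits(G, "geno_matrix")) impute_mean(G) else as.matrix(G)
  if (scale_response) {
    sdv <- apply(Y, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Y <- sweep(Y, 2, sdv, `/`)
  }
  X <- env_values(env)
  simple <- rda_scan(fit_rda(Y, X), k = k, fdr = fdr)
  out <- list(simple = simple, corrected = NULL, overlap = NA_integer_)
  if (!is.null(Q)) {
    Zq <- drop_simplex_col(Q)
    corrected <- rda_scan(fit_rda(Y, X, Z = Zq), k = k, fdr = fdr)
    out$corrected <- corrected
    out$overlap <- sum(simple$stats$candidate & corrected$stats$candidate)
  }
  out
}

#' Write per-SNP scan results as a genome table
#'
#' Tab-separated: `chrom`, `pos`, `D2`, `p`, `q`, `candidate`.
#'
#' @param scan A `scan_result`.
#' @param sites Site table (`chrom`, `pos`) aligned with the scanned SNPs.
#' @param path Output file.
#' @export
write_scan_table <- function(scan, sites, path) {
  stopifnot(nrow(sites) == nrow(scan$stats))
  df <- cbind(sites[, c("chrom", "pos")], scan$stats)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
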
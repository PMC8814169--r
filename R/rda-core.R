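# Redundancy analysis engine: simple and partial RDA, permutation tests
# (overall and marginal), Ezekiel-adjusted R^2, two-set variance
# partitioning, biplot scores, and a single-variable scan.
#
# Conventions. The response is centered, never scaled. In partial models the
# R^2 denominator is the TOTAL (pre-residualization) variance, so partial
# components add up with simple ones; the residual-variance denominator is
# available via `denominator = "residual"`. Permutation for partial models
# permutes the residuals of the reduced (covariates-only) model.

# Orthonormal basis of the column space of X at tolerance tol. `ref` anchors
# the rank tolerance to a pre-residualization scale, so a block residualized
# to numerical zero is detected as rank 0 rather than numerical noise.
.basis <- function(X, tol = 1e-10, ref = NULL) {
  if (is.null(X) || ncol(as.matrix(X)) == 0)
    return(matrix(0, nrow(as.matrix(X)), 0))
  X <- as.matrix(X)
  sv <- svd(X)
  thr <- tol * max(sv$d[1], ref, .Machine$double.eps)
  r <- sum(sv$d > thr)
  sv$u[, seq_len(r), drop = FALSE]
}

.scale_ref <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) == 0) return(0)
  svd(scale(X, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d[1]
}

#' Fit a simple or partial redundancy analysis
#'
#' The response matrix is centered. With covariates `Z`, both `Y` and `X`
#' are replaced by their least-squares residuals on `[1, Z]`. The fit is
#' multivariate least squares of the (residualized) response on `X`
#' (pseudo-inverse at tolerance 1e-10); constrained axes are the principal
#' axes of the fitted values.
#'
#' `R^2 = SS(fitted) / SS(total)`, where SS(total) is the sum of squares of
#' the centered but NOT residualized response (unless
#' `denominator = "residual"`), so that partial fractions are additive.
#' `R^2adj` uses the Ezekiel correction with covariate degrees:
#' `1 - (1 - R^2) (n - 1 - q) / (n - 1 - q - p)`.
#'
#' When `Y` is an ancestry-coefficient matrix, drop one column first (see
#' [drop_simplex_col()]) to remove the simplex constraint's collinearity.
#'
#' @param Y Response matrix (n x m), rows aligned with `X`/`Z`.
#' @param X Explanatory matrix (n x p).
#' @param Z Optional covariate matrix (n x q).
#' @param denominator `"total"` (default) or `"residual"`.
#' @param n_axes Number of constrained axes to keep scores/loadings for
#'   (default: all).
#' @return An `rda_result`: `n`, `p`, `q`, `r2`, `r2_adj`, `eig`
#'   (constrained eigenvalues, SS scale), `site_scores`, `loadings`
#'   (response loadings, unit columns), `biplot` (explanatory correlations
#'   with axes), `ss_total`, `ss_constrained`, `ss_residual`,
#'   `ss_conditioned`.
#' @export
fit_rda <- function(Y, X, Z = NULL, denominator = c("total", "residual"),
                    n_axes = NULL) {
  denominator <- match.arg(denominator)
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (!is.null(Z)) Z <- as.matrix(Z)
  n <- nrow(Y)
  stopifnot(nrow(X) == n, is.null(Z) || nrow(Z) == n)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_all <- sum(Yc^2)
  if (ss_all == 0) stop("constant response matrix")
  q <- 0L
  Qz <- NULL
  Xr <- X
  Yr <- Yc
  xref <- .scale_ref(X)
  if (!is.null(Z) && ncol(Z) > 0) {
    Qz <- .basis(scale(Z, center = TRUE, scale = FALSE))
    q <- ncol(Qz)
    Yr <- Yc - Qz %*% crossprod(Qz, Yc)
    Xr <- X - matrix(colMeans(X), n, ncol(X), byrow = TRUE)
    Xr <- Xr - Qz %*% crossprod(Qz, Xr)
  }
  Qx <- .basis(scale(Xr, center = TRUE, scale = FALSE), ref = xref)
  p <- ncol(Qx)
  if (n <= p + q + 1)
    stop("n must exceed rank(X) + rank(Z) + 1 (n = ", n, ", p = ", p,
         ", q = ", q, ")")
  Tm <- crossprod(Qx, Yr)              # p x m
  ss_fit <- sum(Tm^2)
  ss_res <- sum(Yr^2) - ss_fit
  ss_cond <- ss_all - sum(Yr^2)
  ss_tot <- if (denominator == "total") ss_all else sum(Yr^2)
  r2 <- ss_fit / ss_tot
  r2_adj <- 1 - (1 - r2) * (n - 1 - q) / (n - 1 - q - p)
  sv <- if (p > 0) svd(Tm) else list(d = numeric(0),
                                     u = matrix(0, 0, 0),
                                     v = matrix(0, ncol(Y), 0))
  k_all <- sum(sv$d > 1e-12 * max(sv$d, .Machine$double.eps))
  if (is.null(n_axes)) n_axes <- k_all else n_axes <- min(n_axes, k_all)
  ax <- seq_len(n_axes)
  eig <- sv$d[seq_len(k_all)]^2
  site_scores <- if (p > 0)
    Qx %*% sweep(sv$u[, ax, drop = FALSE], 2, sv$d[ax], `*`)
  else matrix(0, n, 0)
  loadings <- sv$v[, ax, drop = FALSE]
  rownames(loadings) <- colnames(Y)
  if (length(ax)) {
    colnames(site_scores) <- colnames(loadings) <- paste0("RDA", ax)
  }
  res <- structure(list(n = n, p = p, q = q,
                        r2 = r2, r2_adj = r2_adj, eig = eig,
                        site_scores = site_scores, loadings = loadings,
                        ss_total = ss_tot, ss_all = ss_all,
                        ss_constrained = ss_fit, ss_residual = ss_res,
                        ss_conditioned = ss_cond,
                        denominator = denominator,
                        Qx = Qx, Qz = Qz, Xres = Xr),
                   class = "rda_result")
  res$biplot <- biplot_scores(res, X)
  res
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "<rda_result> n = %d, rank(X) = %d, rank(Z) = %d\n  R2 = %.4f (adj %.4f)%s\n",
    x$n, x$p, x$q, x$r2, x$r2_adj,
    if (!is.null(x$p_value)) sprintf(", permutation p = %.4g", x$p_value)
    else ""))
  invisible(x)
}

#' Correlations of explanatory variables with constrained axes
#'
#' @param result An `rda_result`.
#' @param X The explanatory matrix used in the fit (residualized internally
#'   when covariates were present).
#' @return Matrix of Pearson correlations, variables x axes; `NA` for
#'   zero-variance axes or variables.
#' @export
biplot_scores <- function(result, X) {
  X <- as.matrix(X)
  Xr <- if (result$q > 0) result$Xres else X
  S <- result$site_scores
  if (!ncol(S)) return(matrix(NA_real_, ncol(X), 0))
  out <- suppressWarnings(stats::cor(Xr, S))
  sds <- apply(S, 2, stats::sd)
  out[, sds == 0] <- NA
  rownames(out) <- colnames(X)
  out
}

# Internal permutation engine shared by anova_overall / anova_margin.
.perm_F <- function(Yc, Qx, Qz, n_perm) {
  n <- nrow(Yc)
  p <- ncol(Qx); q <- if (is.null(Qz)) 0L else ncol(Qz)
  project <- function(Ym) {
    if (!is.null(Qz)) Ym <- Ym - Qz %*% crossprod(Qz, Ym)
    ssf <- sum(crossprod(Qx, Ym)^2)
    ssr <- sum(Ym^2) - ssf
    (ssf / p) / (ssr / (n - p - q - 1))
  }
  Yres <- if (!is.null(Qz)) Yc - Qz %*% crossprod(Qz, Yc) else Yc
  F_obs <- project(Yres)
  F_perm <- vapply(seq_len(n_perm), function(b)
    project(Yres[sample.int(n), , drop = FALSE]), numeric(1))
  list(F_obs = F_obs,
       p = (1 + sum(F_perm >= F_obs)) / (1 + n_perm))
}

#' Overall permutation test of an RDA model
#'
#' Pseudo-F is `(SS_constrained / p) / (SS_residual / (n - p - q - 1))`.
#' The null distribution permutes rows of the residualized response
#' (reduced-model residual permutation when covariates are present; free row
#' permutation otherwise); `p = (1 + #{F* >= F}) / (1 + n_perm)`.
#'
#' @param Y,X,Z As in [fit_rda()].
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return List: `F` (observed pseudo-F), `p`, `n_perm`.
#' @export
anova_overall <- function(Y, X, Z = NULL, n_perm = 5000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  Y <- as.matrix(Y); X <- as.matrix(X)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Yc)
  Qz <- NULL
  Xr <- X
  xref <- .scale_ref(X)
  if (!is.null(Z) && ncol(as.matrix(Z)) > 0) {
    Z <- as.matrix(Z)
    Qz <- .basis(scale(Z, center = TRUE, scale = FALSE))
    Xr <- scale(X, center = TRUE, scale = FALSE)
    Xr <- Xr - Qz %*% crossprod(Qz, Xr)
  }
  Qx <- .basis(scale(Xr, center = TRUE, scale = FALSE), ref = xref)
  if (n <= ncol(Qx) + (if (is.null(Qz)) 0 else ncol(Qz)) + 1)
    stop("too few observations for the requested model")
  out <- with_seed(derive_seed(seed, "anova_overall"),
                   .perm_F(Yc, Qx, Qz, n_perm))
  list(F = out$F_obs, p = out$p, n_perm = n_perm)
}

#' Marginal (type III) permutation tests of explanatory blocks
#'
#' For each term, the marginal contribution is tested with all other terms
#' (and `Z`) as conditions: the reduced-model residuals are permuted and the
#' partial pseudo-F of the term recomputed. Aliased terms (zero marginal
#' rank) are reported `NA` with a warning.
#'
#' @param Y Response matrix.
#' @param terms Named list of explanatory blocks (each n x p_t).
#' @param Z Optional covariates applying to every model.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Data frame: `term`, `df`, `ss_margin`, `F`, `p`.
#' @export
anova_margin <- function(Y, terms, Z = NULL, n_perm = 999, seed = 1) {
  if (length(terms) < 2) stop("need at least 2 terms")
  if (is.null(names(terms)))
    names(terms) <- paste0("term", seq_along(terms))
  Y <- as.matrix(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Yc)
  Xall <- do.call(cbind, lapply(terms, as.matrix))
  full <- fit_rda(Y, Xall, Z)
  rows <- list()
  for (t in names(terms)) {
    others <- do.call(cbind, lapply(terms[setdiff(names(terms), t)],
                                    as.matrix))
    Zt <- if (is.null(Z)) others else cbind(as.matrix(Z), others)
    Qz <- .basis(scale(Zt, center = TRUE, scale = FALSE))
    Xt <- scale(as.matrix(terms[[t]]), center = TRUE, scale = FALSE)
    xref <- svd(Xt, nu = 0, nv = 0)$d[1]
    Xt <- Xt - Qz %*% crossprod(Qz, Xt)
    Qx <- .basis(Xt, ref = xref)
    if (ncol(Qx) == 0) {
      warning("term '", t, "' is aliased (zero marginal rank)")
      rows[[t]] <- data.frame(term = t, df = 0L, ss_margin = 0,
                              F = NA_real_, p = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    without <- fit_rda(Y, others, Z)
    ss_margin <- full$ss_constrained - without$ss_constrained
    out <- with_seed(derive_seed(seed, paste0("margin_", t)),
                     .perm_F(Yc, Qx, Qz, n_perm))
    rows[[t]] <- data.frame(term = t, df = ncol(Qx),
                            ss_margin = ss_margin,
                            F = out$F_obs, p = out$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-set variance partitioning
#'
#' Adjusted fractions from the three models `X1`, `X2`, `X1 u X2`:
#' `a = R2adj(X1 u X2) - R2adj(X2)` (X1 alone),
#' `c = R2adj(X1 u X2) - R2adj(X1)` (X2 alone),
#' `b = R2adj(X1) - a` (joint), `d = 1 - R2adj(X1 u X2)` (residual).
#' Raw (unadjusted) analogues are reported alongside, since observed
#' percentage decompositions are usually quoted raw.
#'
#' @param Y Response matrix.
#' @param X1,X2 Explanatory sets (no shared columns).
#' @return A `variance_partition`: `a`, `b`, `c`, `d`, the underlying
#'   `r2_adj` and `r2` of the three models, and raw fractions
#'   `raw_a`, `raw_b`, `raw_c`, `raw_d`.
#' @export
varpart_rda <- function(Y, X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X2) == 0) {
    f1 <- fit_rda(Y, X1)
    return(structure(list(a = f1$r2_adj, b = 0, c = 0, d = 1 - f1$r2_adj,
                          r2_adj = c(X1 = f1$r2_adj, X2 = 0,
                                     X12 = f1$r2_adj),
                          r2 = c(X1 = f1$r2, X2 = 0, X12 = f1$r2),
                          raw_a = f1$r2, raw_b = 0, raw_c = 0,
                          raw_d = 1 - f1$r2),
                     class = "variance_partition"))
  }
  for (j in seq_len(ncol(X1))) for (k in seq_len(ncol(X2))) {
    if (isTRUE(all.equal(as.numeric(X1[, j]), as.numeric(X2[, k]),
                         tolerance = 1e-12)))
      stop("X1 and X2 share a column (", j, ", ", k,
           "); fractions would be ill-defined")
  }
  f1 <- fit_rda(Y, X1)
  f2 <- fit_rda(Y, X2)
  f12 <- fit_rda(Y, cbind(X1, X2))
  a <- f12$r2_adj - f2$r2_adj
  c_ <- f12$r2_adj - f1$r2_adj
  b <- f1$r2_adj - a
  d <- 1 - f12$r2_adj
  raw_a <- f12$r2 - f2$r2
  raw_c <- f12$r2 - f1$r2
  raw_b <- f1$r2 - raw_a
  structure(list(a = a, b = b, c = c_, d = d,
                 r2_adj = c(X1 = f1$r2_adj, X2 = f2$r2_adj,
                            X12 = f12$r2_adj),
                 r2 = c(X1 = f1$r2, X2 = f2$r2, X12 = f12$r2),
                 raw_a = raw_a, raw_b = raw_b, raw_c = raw_c,
                 raw_d = 1 - f12$r2),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("<variance_partition> adjusted fractions\n")
  cat(sprintf("  a (X1 alone) = %.4f\n  b (joint)    = %.4f\n", x$a, x$b))
  cat(sprintf("  c (X2 alone) = %.4f\n  d (residual) = %.4f\n", x$c, x$d))
  invisible(x)
}

#' Per-variable RDA scan
#'
#' Fits one simple (or partial, with `Z`) RDA per environmental variable
#' and returns the table ranked by explained variance.
#'
#' @param Y Response matrix.
#' @param env An [env_table()] or matrix of variables.
#' @param Z Optional covariates.
#' @param n_perm Permutations per variable (0 skips testing).
#' @param seed Integer seed.
#' @return Data frame: `variable`, `r2`, `r2_adj`, `p`, ranked by `r2`.
#' @export
single_variable_scan <- function(Y, env, Z = NULL, n_perm = 999, seed = 1) {
  X <- env_values(env)
  if (ncol(X) == 0) stop("env is empty")
  rows <- lapply(colnames(X), function(v) {
    f <- fit_rda(Y, X[, v, drop = FALSE], Z)
    p <- if (n_perm > 0)
      anova_overall(Y, X[, v, drop = FALSE], Z, n_perm = n_perm,
                    seed = derive_seed(seed, v))$p
    else NA_real_
    data.frame(variable = v, r2 = f$r2, r2_adj = f$r2_adj, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2), ]
  rownames(out) <- NULL
  out
}

#' Drop one ancestry column before using Q as response or covariate
#'
#' Ancestry rows sum to one, so the K columns are exactly collinear; the
#' last column is dropped.
#'
#' @param Q Ancestry matrix or `ancestry_matrix`.
#' @return Matrix with K - 1 columns.
#' @export
drop_simplex_col <- function(Q) {
  if (inherits(Q, "ancestry_matrix")) Q <- Q$Q
  Q <- as.matrix(Q)
  Q[, -ncol(Q), drop = FALSE]
}
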
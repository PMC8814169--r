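# Reduce a collinear environmental table to an analysis-ready set: group
# collinear variables, collapse each group to a synthetic PC1 variable, and
# select variables by variance inflation factor.

env_values <- function(env) {
  if (inherits(env, "env_table")) env$values else as.matrix(env)
}

#' Group collinear environmental variables
#'
#' Agglomerative (average-linkage) clustering with dissimilarity
#' `1 - |Pearson r|`, cut at height `cut`. Singleton groups are allowed.
#'
#' @param env An [env_table()] or numeric matrix.
#' @param cut Tree cut height (default 0.3, i.e. group when `|r| > 0.7` on
#'   average).
#' @return Integer group label per column, named.
#' @export
cluster_collinear <- function(env, cut = 0.3) {
  X <- env_values(env)
  if (ncol(X) < 2) stop("need at least 2 columns")
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0))
    stop("constant column: ", paste(colnames(X)[sdv == 0], collapse = ", "))
  d <- stats::as.dist(1 - abs(stats::cor(X)))
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, h = cut)
}

#' Collapse collinear groups to synthetic variables
#'
#' Each multi-member group is replaced by the first principal-component
#' score vector of its standardized members, re-standardized, signed so its
#' correlation with the group's first member is positive, and named by
#' concatenating the member names with `+`. Singletons pass through
#' standardized.
#'
#' @param env An [env_table()] or matrix.
#' @param groups Output of [cluster_collinear()].
#' @return An [env_table()] with one column per group and synthetic flags.
#' @export
make_synthetic_vars <- function(env, groups) {
  X <- env_values(env)
  stopifnot(length(groups) == ncol(X))
  Xs <- standardize_cols(X)
  cols <- list(); nm <- character(0); synth <- logical(0)
  grp_out <- integer(0)
  for (g in sort(unique(groups))) {
    members <- which(groups == g)
    if (length(members) == 1) {
      v <- Xs[, members]
      nm <- c(nm, colnames(X)[members]); synth <- c(synth, FALSE)
    } else {
      pc <- stats::prcomp(Xs[, members, drop = FALSE], center = FALSE,
                          scale. = FALSE)
      v <- pc$x[, 1]
      if (stats::cor(v, Xs[, members[1]]) < 0) v <- -v
      v <- as.numeric(scale(v))
      nm <- c(nm, paste(colnames(X)[members], collapse = "+"))
      synth <- c(synth, TRUE)
    }
    cols <- c(cols, list(v)); grp_out <- c(grp_out, g)
  }
  out <- do.call(cbind, cols)
  colnames(out) <- nm
  rownames(out) <- rownames(X)
  env_table(out, group = grp_out, synthetic = synth)
}

vif_values <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative variable selection by variance inflation factor
#'
#' While any VIF is `>= vif_max`, the largest-VIF column is dropped
#' (perfectly collinear columns, VIF infinite, go first). Every removal is
#' logged with its VIF.
#'
#' @param env An [env_table()] or matrix.
#' @param vif_max Acceptance threshold; all remaining VIFs are `< vif_max`.
#' @return List: `env` (an [env_table()] of the retained columns),
#'   `removed` (data.frame `variable`, `vif`), `vif` (final VIFs).
#' @export
vif_select <- function(env, vif_max = 5) {
  X <- env_values(env)
  et <- if (inherits(env, "env_table")) env else env_table(X)
  removed <- data.frame(variable = character(0), vif = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    if (ncol(X) < 2) break
    if (nrow(X) <= ncol(X))
      stop("fewer rows than columns; VIF regression is underdetermined")
    v <- vif_values(X)
    if (all(v < vif_max)) break
    worst <- which.max(v)
    removed <- rbind(removed,
                     data.frame(variable = colnames(X)[worst],
                                vif = v[worst], stringsAsFactors = FALSE))
    X <- X[, -worst, drop = FALSE]
  }
  keep <- colnames(X)
  out <- env_table(X,
                   group = et$group[keep],
                   synthetic = et$synthetic[keep],
                   center = et$center[keep], scale = et$scale[keep])
  final_vif <- if (ncol(X) >= 2) vif_values(X) else rep(1, ncol(X))
  list(env = out, removed = removed,
       vif = stats::setNames(final_vif, keep))
}

#' Write a VIF removal log as JSON
#' @param removed `removed` element from [vif_select()].
#' @param path Output path.
#' @export
write_vif_log <- function(removed, path) {
  jsonlite::write_json(removed, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
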
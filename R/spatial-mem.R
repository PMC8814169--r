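# Spatial eigenfunction machinery: great-circle distances, Gabriel graph,
# inverse-distance spatial weights, distance-based Moran's eigenvector maps
# (dbMEM), Moran's I, and forward selection with the double stopping rule.

#' Great-circle distance matrix (haversine, km)
#'
#' Earth radius 6371.0088 km.
#'
#' @param coords Matrix or data.frame with columns `lat`, `lon` (decimal
#'   degrees) in that order, or named.
#' @return Symmetric distance matrix in km with zero diagonal.
#' @export
greatcircle_km <- function(coords) {
  cdf <- as.data.frame(coords)
  if (all(c("lat", "lon") %in% colnames(cdf)))
    cdf <- cdf[, c("lat", "lon"), drop = FALSE]
  coords <- as.matrix(cdf)
  if (!is.numeric(coords)) stop("coordinates must be numeric lat/lon")
  lat <- coords[, 1]; lon <- coords[, 2]
  if (any(abs(lat) > 90)) stop("latitude out of range [-90, 90]")
  if (any(abs(lon) > 180)) stop("longitude out of range [-180, 180]")
  p <- cbind(lon, lat)
  D <- geosphere::distm(p, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371008.8)) / 1000
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' Gabriel graph over demes
#'
#' Edge (i, j) is present iff for every other point k:
#' `d(i,j)^2 <= d(i,k)^2 + d(k,j)^2` (boundary ties keep the edge), with
#' great-circle distances.
#'
#' @param coords Deme coordinates (`lat`, `lon` degrees); rownames or a
#'   `deme_id` column give node ids.
#' @return A `spatial_graph`: `nodes`, `coords`, `edges` (data.frame
#'   `from`, `to`, `dist_km`, `weight` = 1/km), and the full distance
#'   matrix.
#' @export
gabriel_graph <- function(coords) {
  cdf <- as.data.frame(coords)
  ids <- if ("deme_id" %in% names(cdf)) as.character(cdf$deme_id)
         else if (!is.null(rownames(cdf))) rownames(cdf)
         else as.character(seq_len(nrow(cdf)))
  D <- greatcircle_km(cdf)
  dimnames(D) <- list(ids, ids)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 demes")
  if (any(D[upper.tri(D)] == 0)) stop("coincident demes (zero distance)")
  D2 <- D^2
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    others <- setdiff(seq_len(n), c(i, j))
    if (all(D2[i, j] <= D2[i, others] + D2[others, j] + 1e-12)) {
      from <- c(from, i); to <- c(to, j)
    }
  }
  edges <- data.frame(from = ids[from], to = ids[to],
                      dist_km = D[cbind(from, to)],
                      weight = 1 / D[cbind(from, to)],
                      stringsAsFactors = FALSE)
  structure(list(nodes = ids, coords = cdf, edges = edges, dist_km = D),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d Gabriel edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Inverse-distance spatial weighting matrix
#'
#' `W[i, j] = 1 / d_km(i, j)` on Gabriel edges, 0 elsewhere. Errors if the
#' graph is disconnected (listing the components).
#'
#' @param graph A `spatial_graph` from [gabriel_graph()].
#' @return Symmetric weight matrix (km^-1) with zero diagonal.
#' @export
build_weights <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  n <- length(graph$nodes)
  W <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  fi <- match(graph$edges$from, graph$nodes)
  ti <- match(graph$edges$to, graph$nodes)
  W[cbind(fi, ti)] <- graph$edges$weight
  W[cbind(ti, fi)] <- graph$edges$weight
  g <- igraph::graph_from_edgelist(cbind(fi, ti), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    parts <- split(graph$nodes, comp$membership)
    stop("spatial graph is disconnected; components: ",
         paste(vapply(parts, function(p) paste(p, collapse = ","), ""),
               collapse = " | "))
  }
  W
}

#' Distance-based Moran's eigenvector maps
#'
#' Eigen-decomposition of the doubly centered weighting matrix
#' `Omega = H W H`, `H = I - 11'/n`. Eigenvectors with eigenvalues of
#' magnitude above `1e-8 * max|lambda|` are returned, sorted by descending
#' eigenvalue; the sign of each eigenvalue classifies the MEM as
#' broad-scale (positive, positive spatial autocorrelation) or fine-scale
#' (negative). Each eigenvector's largest-magnitude entry is made positive.
#'
#' @param W Symmetric spatial weight matrix with zero diagonal.
#' @param membership Optional deme assignment per individual (values in
#'   `rownames(W)` or indices); when given, `$vectors_ind` replicates each
#'   deme's value across its members.
#' @return A `mem_set`: `vectors` (demes x MEMs, mean-zero orthonormal),
#'   `values`, `sign_class` (`"positive"`/`"negative"`), optionally
#'   `vectors_ind`.
#' @export
compute_dbmem <- function(W, membership = NULL) {
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  n <- nrow(W)
  H <- diag(n) - matrix(1 / n, n, n)
  Om <- H %*% W %*% H
  Om <- (Om + t(Om)) / 2
  eg <- eigen(Om, symmetric = TRUE)
  keep <- abs(eg$values) > 1e-8 * max(abs(eg$values))
  vals <- eg$values[keep]
  V <- eg$vectors[, keep, drop = FALSE]
  for (a in seq_len(ncol(V))) {
    i <- which.max(abs(V[, a]))
    if (V[i, a] < 0) V[, a] <- -V[, a]
  }
  colnames(V) <- paste0("MEM", seq_len(ncol(V)))
  rownames(V) <- rownames(W)
  out <- list(vectors = V, values = vals,
              sign_class = ifelse(vals > 0, "positive", "negative"),
              omega = Om)
  if (!is.null(membership)) {
    idx <- if (is.numeric(membership)) membership
           else match(membership, rownames(W))
    if (any(is.na(idx))) stop("membership values not found among demes")
    Vi <- V[idx, , drop = FALSE]
    rownames(Vi) <- names(membership)
    out$vectors_ind <- Vi
    out$membership <- idx
  }
  structure(out, class = "mem_set")
}

#' @export
print.mem_set <- function(x, ...) {
  cat(sprintf("<mem_set> %d MEMs (%d broad-scale, %d fine-scale)\n",
              length(x$values), sum(x$values > 0), sum(x$values < 0)))
  invisible(x)
}

#' Moran's I of a variable under a spatial weight matrix
#'
#' @param x Numeric vector over demes.
#' @param W Spatial weight matrix.
#' @return Moran's I.
#' @export
moran_i <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

# R^2 of multivariate Y (centered) on design X via QR basis.
.r2_of <- function(Yc, X, ss_tot) {
  qx <- qr(cbind(1, X))
  Qb <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  sum((crossprod(Qb, Yc))^2) / ss_tot
}

.adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - 1 - p)

#' Forward selection of MEMs with the double stopping rule
#'
#' Selection runs separately within the positive- and negative-eigenvalue
#' classes, then takes the union. Within a class, a global permutation test
#' of all the class's MEMs against `Y` gates entry; if significant, MEMs
#' are added greedily by largest R-squared increase, stopping when a
#' candidate's permutation p-value exceeds `alpha` or the cumulative
#' adjusted R-squared exceeds the class's global adjusted R-squared.
#'
#' @param Y Response matrix (rows = observations); centered internally.
#' @param mems A `mem_set`; individual-level vectors are used when present.
#' @param alpha Entry significance level.
#' @param n_perm Permutations for each test (a warning below 99).
#' @param seed Integer seed.
#' @return List: `selected` (column names), `vectors` (selected columns),
#'   `trace` (data.frame of steps), `global` (per-class global test).
#' @export
forward_select <- function(Y, mems, alpha = 0.05, n_perm = 999, seed = 1) {
  stopifnot(inherits(mems, "mem_set"))
  if (n_perm < 99) warning("n_perm < 99 gives coarse p-values")
  V <- if (!is.null(mems$vectors_ind)) mems$vectors_ind else mems$vectors
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(V))
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stop("Y has zero variance")
  n <- nrow(Yc)
  trace <- list(); global <- list(); selected <- character(0)
  with_seed(derive_seed(seed, "forward_select"), {
    for (cls in c("positive", "negative")) {
      cols <- which(mems$sign_class == cls)
      if (!length(cols)) next
      Xcls <- V[, cols, drop = FALSE]
      r2_glob <- .r2_of(Yc, Xcls, ss_tot)
      r2adj_glob <- .adj_r2(r2_glob, n, ncol(Xcls))
      perm_glob <- vapply(seq_len(n_perm), function(b)
        .r2_of(Yc[sample.int(n), , drop = FALSE], Xcls, ss_tot),
        numeric(1))
      p_glob <- (1 + sum(perm_glob >= r2_glob)) / (1 + n_perm)
      global[[cls]] <- list(r2 = r2_glob, r2adj = r2adj_glob, p = p_glob)
      if (p_glob > alpha) next
      chosen <- integer(0)
      r2_cur <- 0
      repeat {
        remaining <- setdiff(seq_len(ncol(Xcls)), chosen)
        if (!length(remaining)) break
        r2_new <- vapply(remaining, function(j)
          .r2_of(Yc, Xcls[, c(chosen, j), drop = FALSE], ss_tot),
          numeric(1))
        best <- remaining[which.max(r2_new)]
        r2_best <- max(r2_new)
        # permutation test of the candidate's partial contribution
        stat_obs <- r2_best - r2_cur
        stat_perm <- vapply(seq_len(n_perm), function(b) {
          Yp <- Yc[sample.int(n), , drop = FALSE]
          .r2_of(Yp, Xcls[, c(chosen, best), drop = FALSE], ss_tot) -
            .r2_of(Yp, Xcls[, chosen, drop = FALSE], ss_tot)
        }, numeric(1))
        p_cand <- (1 + sum(stat_perm >= stat_obs)) / (1 + n_perm)
        r2adj_best <- .adj_r2(r2_best, n, length(chosen) + 1)
        stop_p <- p_cand > alpha
        stop_r2 <- r2adj_best > r2adj_glob
        trace[[length(trace) + 1]] <- data.frame(
          class = cls, candidate = colnames(Xcls)[best],
          r2 = r2_best, r2adj = r2adj_best, p = p_cand,
          accepted = !(stop_p || stop_r2), stringsAsFactors = FALSE)
        if (stop_p || stop_r2) break
        chosen <- c(chosen, best)
        r2_cur <- r2_best
      }
      selected <- c(selected, colnames(Xcls)[chosen])
    }
  })
  sel_cols <- V[, selected, drop = FALSE]
  list(selected = selected, vectors = sel_cols,
       trace = if (length(trace)) do.call(rbind, trace) else NULL,
       global = global)
}
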
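# Synthetic landscape-genomic data with known ground truth.
#
# The generator emulates the sampling design the downstream analysis assumes:
# a few hundred highly selfing individuals clustered into demes over a small
# geographic extent, isolation by distance produced by a Gaussian random
# field on deme allele-frequency logits, a linear dispersal barrier acting as
# a multiplicative effective-distance penalty, collinear environmental
# gradients confounded with latitude, and a minority of loci whose
# frequencies respond to one environmental gradient.

# Evaluate expr with a local RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults mirror the study design the package is built around: 244 selfing
#' individuals in 58 demes over a ~200 km extent, 20,000 biallelic SNPs with
#' 3% missingness, four spatially arranged ancestry clusters, a Gaussian
#' random field on allele-frequency logits producing isolation by distance,
#' a linear barrier penalizing crossing dispersal, and 2% of loci with an
#' environmental effect of 0.8 logit units per environmental SD. The selfing
#' inbreeding coefficient 0.96 corresponds to an equilibrium outcrossing rate
#' of about 2%.
#'
#' @param n_demes Number of demes (>= 4).
#' @param n_ind Number of individuals.
#' @param n_snps Number of biallelic SNPs.
#' @param extent_km Side length of the square study extent (km).
#' @param barrier `NULL`, or a list with `p1`, `p2` (km coordinates of the
#'   segment endpoints within the extent) and `penalty` (>= 1), the
#'   multiplicative factor applied to effective distances of deme pairs whose
#'   connecting segment crosses the barrier.
#' @param gp_sigma2 Variance of the spatial Gaussian field (logit^2 units).
#' @param gp_range_km Correlation range of the field (km).
#' @param adaptive_frac Fraction of loci with an environmental effect.
#' @param effect_size Effect on the frequency logit per environmental SD.
#' @param selfing_F Inbreeding coefficient in `[0, 1]`.
#' @param missing_rate Missing-call rate (MCAR).
#' @param k_clusters Number of spatial ancestry clusters recorded in truth.
#' @param seed Integer seed; fully determines all outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_demes = 58, n_ind = 244, n_snps = 20000,
                       extent_km = 200,
                       barrier = list(p1 = c(100, 0), p2 = c(100, 120),
                                      penalty = 3),
                       gp_sigma2 = 0.25, gp_range_km = extent_km / 4,
                       adaptive_frac = 0.02, effect_size = 0.8,
                       selfing_F = 0.96, missing_rate = 0.03,
                       k_clusters = 4, seed = 1) {
  stopifnot(n_demes >= 4, n_ind >= 1, n_snps >= 1, extent_km > 0,
            gp_sigma2 >= 0, gp_range_km > 0,
            adaptive_frac >= 0, adaptive_frac <= 1,
            selfing_F >= 0, selfing_F <= 1,
            missing_rate >= 0, missing_rate <= 1,
            k_clusters >= 1)
  if (!is.null(barrier)) {
    stopifnot(is.list(barrier), length(barrier$p1) == 2,
              length(barrier$p2) == 2, barrier$penalty >= 1)
  }
  structure(list(n_demes = n_demes, n_ind = n_ind, n_snps = n_snps,
                 extent_km = extent_km, barrier = barrier,
                 gp_sigma2 = gp_sigma2, gp_range_km = gp_range_km,
                 adaptive_frac = adaptive_frac, effect_size = effect_size,
                 selfing_F = selfing_F, missing_rate = missing_rate,
                 k_clusters = k_clusters, seed = as.integer(seed)),
            class = "sim_config")
}

# Reference point for the synthetic landscape (decimal degrees).
.SIM_LAT0 <- 31.5
.SIM_LON0 <- 35.0
.KM_PER_DEG <- 6371.0088 * pi / 180

# km offsets within the extent -> lat/lon around the reference point
km_to_lonlat <- function(x_km, y_km) {
  cbind(lon = .SIM_LON0 + x_km / (.KM_PER_DEG * cos(.SIM_LAT0 * pi / 180)),
        lat = .SIM_LAT0 + y_km / .KM_PER_DEG)
}

lonlat_to_km <- function(lon, lat) {
  cbind(x = (lon - .SIM_LON0) * .KM_PER_DEG * cos(.SIM_LAT0 * pi / 180),
        y = (lat - .SIM_LAT0) * .KM_PER_DEG)
}

# Do segments (a1,a2) and (b1,b2) intersect (2-D, closed)?
segments_intersect <- function(a1, a2, b1, b2) {
  orient <- function(p, q, r)
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  on_seg <- function(p, q, r)
    min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
    min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  o1 <- orient(a1, a2, b1); o2 <- orient(a1, a2, b2)
  o3 <- orient(b1, b2, a1); o4 <- orient(b1, b2, a2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(a1, a2, b1)) || (o2 == 0 && on_seg(a1, a2, b2)) ||
  (o3 == 0 && on_seg(b1, b2, a1)) || (o4 == 0 && on_seg(b1, b2, a2))
}

#' Simulate deme locations, individual membership and the barrier raster
#'
#' Demes are placed uniformly at random in the square extent; individuals are
#' allocated one per deme first (so no deme is empty) and the remainder
#' multinomially. The barrier raster flags grid cells intersected by the
#' barrier segment.
#'
#' @param cfg A [sim_config()].
#' @param raster_cells Grid resolution of the barrier raster per side.
#' @return A `deme_map`: list with `demes` (data.frame `deme_id`, `lat`,
#'   `lon`, `x_km`, `y_km`), `individuals` (data.frame `ind_id`, `deme_id`),
#'   `barrier` (a [raster_grid()] with mask, or `NULL`), `extent_km`, and the
#'   barrier specification.
#' @export
simulate_demes <- function(cfg, raster_cells = 50) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_demes < 4)
    stop("n_demes must be >= 4: the Gabriel graph and MEMs degenerate")
  with_seed(derive_seed(cfg$seed, "demes"), {
    repeat {
      x <- stats::runif(cfg$n_demes, 0, cfg$extent_km)
      y <- stats::runif(cfg$n_demes, 0, cfg$extent_km)
      if (!any(duplicated(cbind(x, y)))) break
    }
    ll <- km_to_lonlat(x, y)
    demes <- data.frame(deme_id = sprintf("D%02d", seq_len(cfg$n_demes)),
                        lat = ll[, "lat"], lon = ll[, "lon"],
                        x_km = x, y_km = y, stringsAsFactors = FALSE)
    extra <- cfg$n_ind - cfg$n_demes
    if (extra < 0) stop("n_ind must be >= n_demes")
    counts <- rep(1L, cfg$n_demes) +
      as.integer(stats::rmultinom(1, extra, rep(1, cfg$n_demes)))
    individuals <- data.frame(
      ind_id = sprintf("I%03d", seq_len(cfg$n_ind)),
      deme_id = rep(demes$deme_id, counts), stringsAsFactors = FALSE)

    barrier <- NULL
    if (!is.null(cfg$barrier)) {
      cs <- cfg$extent_km / raster_cells
      mask <- matrix(FALSE, raster_cells, raster_cells)
      for (i in seq_len(raster_cells)) {     # i = row from top
        for (j in seq_len(raster_cells)) {   # j = column
          x0 <- (j - 1) * cs; x1 <- j * cs
          y1 <- cfg$extent_km - (i - 1) * cs; y0 <- y1 - cs
          corners <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
          edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
          hit <- any(vapply(edges, function(e) segments_intersect(
            cfg$barrier$p1, cfg$barrier$p2, corners[[e[1]]], corners[[e[2]]]),
            logical(1)))
          # also catch a segment fully inside the cell
          bp <- cfg$barrier$p1
          if (!hit && bp[1] >= x0 && bp[1] <= x1 && bp[2] >= y0 && bp[2] <= y1)
            hit <- TRUE
          mask[i, j] <- hit
        }
      }
      barrier <- raster_grid(matrix(0, raster_cells, raster_cells),
                             cellsize = cs, origin = c(0, 0), mask = mask)
    }
    structure(list(demes = demes, individuals = individuals,
                   barrier = barrier, extent_km = cfg$extent_km,
                   barrier_spec = cfg$barrier),
              class = "deme_map")
  })
}

#' @export
print.deme_map <- function(x, ...) {
  cat(sprintf("<deme_map> %d demes, %d individuals, extent %.0f km%s\n",
              nrow(x$demes), nrow(x$individuals), x$extent_km,
              if (is.null(x$barrier)) "" else ", with barrier"))
  invisible(x)
}

#' Environmental variable table
#'
#' @param values Numeric matrix, rows = demes or individuals (rownames are
#'   ids), columns named.
#' @param group Optional per-column collinear-group labels.
#' @param synthetic Optional per-column logical flags.
#' @param center,scale Standardization record per column.
#' @return An `env_table` object.
#' @export
env_table <- function(values, group = NULL, synthetic = NULL,
                      center = NULL, scale = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (any(is.na(values))) stop("env_table values must not contain NA")
  if (is.null(group)) group <- seq_len(ncol(values))
  if (is.null(synthetic)) synthetic <- rep(FALSE, ncol(values))
  structure(list(values = values,
                 group = stats::setNames(group, colnames(values)),
                 synthetic = stats::setNames(synthetic, colnames(values)),
                 center = center, scale = scale),
            class = "env_table")
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("<env_table> %d rows x %d variables (%d synthetic)\n",
              nrow(x$values), ncol(x$values), sum(x$synthetic)))
  invisible(x)
}

#' Simulate collinear environmental gradients over demes
#'
#' Each group of variables shares a latent gradient: the first group follows
#' latitude, the second longitude, and further groups follow independent
#' random fields over demes. Member variables are the latent plus independent
#' Gaussian noise, standardized; within-group correlations therefore exceed
#' between-group correlations in expectation.
#'
#' @param demes A `deme_map`.
#' @param n_groups Number of collinear groups.
#' @param group_sizes Integer vector of member counts (length `n_groups`).
#' @param noise_sd Noise SD relative to the unit-variance latent.
#' @param seed Integer seed.
#' @return An [env_table()] over demes, with true group labels in `$group`
#'   and the latent gradients in `attr(, "latents")`.
#' @export
simulate_env <- function(demes, n_groups = 3, group_sizes = c(3, 2, 2),
                         noise_sd = 0.2, seed = 1) {
  stopifnot(inherits(demes, "deme_map"), length(group_sizes) == n_groups)
  if (sum(group_sizes) == 0) stop("group_sizes must sum to a positive count")
  n <- nrow(demes$demes)
  with_seed(derive_seed(seed, "env"), {
    latents <- matrix(0, n, n_groups)
    for (g in seq_len(n_groups)) {
      latents[, g] <- if (g == 1) demes$demes$lat
                      else if (g == 2) demes$demes$lon
                      else stats::rnorm(n)
      latents[, g] <- as.numeric(scale(latents[, g]))
    }
    cols <- list(); grp <- integer(0); nm <- character(0)
    base_names <- c("lat_grad", "lon_grad", paste0("field", seq_len(n_groups)))
    for (g in seq_len(n_groups)) {
      for (k in seq_len(group_sizes[g])) {
        v <- latents[, g] + stats::rnorm(n, sd = noise_sd)
        cols <- c(cols, list(v)); grp <- c(grp, g)
        nm <- c(nm, sprintf("%s_%d", base_names[g], k))
      }
    }
    vals <- do.call(cbind, cols)
    colnames(vals) <- nm
    rownames(vals) <- demes$demes$deme_id
    vals <- standardize_cols(vals)
    out <- env_table(vals, group = grp,
                     center = attr(vals, "center"),
                     scale = attr(vals, "scale"))
    attr(out, "latents") <- latents
    out
  })
}

# Effective distance matrix between demes: great-circle km, multiplied by the
# barrier penalty for pairs whose connecting segment crosses the barrier.
effective_distances <- function(demes, barrier_spec) {
  D <- greatcircle_km(demes$demes[, c("lat", "lon")])
  if (!is.null(barrier_spec)) {
    xy <- cbind(demes$demes$x_km, demes$demes$y_km)
    n <- nrow(xy)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (segments_intersect(xy[i, ], xy[j, ],
                             barrier_spec$p1, barrier_spec$p2)) {
        D[i, j] <- D[j, i] <- D[i, j] * barrier_spec$penalty
      }
    }
  }
  D
}

#' Simulate genotypes over the landscape
#'
#' For each site, an ancestral frequency is drawn uniformly on (0.05, 0.95);
#' deme frequencies follow `logit(p_ld) = logit(p0_l) + u_l(d) + b_l E*(d)`,
#' where `u_l` is a zero-mean Gaussian field over demes with covariance
#' `gp_sigma2 * exp(-d_eff / gp_range_km)` on effective distances (great
#' circle times the barrier crossing penalty), and `b_l = effect_size` for
#' the adaptive fraction of sites (0 otherwise). Frequencies are clipped to
#' `[0.001, 0.999]`. Genotypes are drawn with inbreeding:
#' `P(2) = p^2 + Fpq`, `P(1) = 2pq(1-F)`, `P(0) = q^2 + Fpq`; missing calls
#' are MCAR.
#'
#' @param cfg A [sim_config()].
#' @param demes A `deme_map` from [simulate_demes()].
#' @param env Optional [env_table()] over demes; required when
#'   `adaptive_frac > 0`.
#' @param env_column Which environmental column is the selective gradient.
#' @return A list: `geno` (a [geno_matrix()]) and `truth` (`sim_truth` list
#'   with `adaptive_idx`, `b`, `deme_freq`, `Q`, `P`, `cluster`,
#'   `env_column`, `gp` parameters, and the barrier mask).
#' @export
simulate_genotypes <- function(cfg, demes, env = NULL, env_column = 1) {
  stopifnot(inherits(cfg, "sim_config"), inherits(demes, "deme_map"))
  n_d <- nrow(demes$demes); m <- cfg$n_snps
  if (cfg$adaptive_frac > 0 && is.null(env))
    stop("env is required when adaptive_frac > 0")
  if (!is.null(env)) stopifnot(inherits(env, "env_table"),
                               nrow(env$values) == n_d)
  with_seed(derive_seed(cfg$seed, "genotypes"), {
    p0 <- stats::runif(m, 0.05, 0.95)
    U <- matrix(0, n_d, m)
    if (cfg$gp_sigma2 > 0) {
      Deff <- effective_distances(demes, cfg$barrier)
      S <- cfg$gp_sigma2 * exp(-Deff / cfg$gp_range_km) +
        diag(1e-8 * cfg$gp_sigma2, n_d)
      # the barrier penalty deforms the exponential kernel, so S can pick
      # up small negative eigenvalues; clip them (standard PSD repair), but
      # refuse a covariance that is substantially indefinite
      eg <- eigen(S, symmetric = TRUE)
      if (min(eg$values) < -0.05 * max(eg$values))
        stop("spatial covariance not positive semi-definite after jitter")
      L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n_d)
      U <- L %*% matrix(stats::rnorm(n_d * m), n_d, m)
    }
    b <- numeric(m); adaptive_idx <- integer(0)
    eta <- matrix(logit(p0), n_d, m, byrow = TRUE) + U
    if (cfg$adaptive_frac > 0) {
      n_adap <- max(1L, floor(cfg$adaptive_frac * m))
      adaptive_idx <- sort(sample.int(m, n_adap))
      b[adaptive_idx] <- cfg$effect_size
      Estar <- env$values[, env_column]
      eta[, adaptive_idx] <- eta[, adaptive_idx] +
        outer(Estar, b[adaptive_idx])
    }
    P_deme <- pmin(pmax(inv_logit(eta), 0.001), 0.999)

    # genotypes with inbreeding, deme by deme
    deme_of <- match(demes$individuals$deme_id, demes$demes$deme_id)
    n <- nrow(demes$individuals)
    G <- matrix(0L, n, m)
    Fco <- cfg$selfing_F
    for (d in seq_len(n_d)) {
      rows <- which(deme_of == d)
      if (!length(rows)) next
      p <- P_deme[d, ]; q <- 1 - p
      p2 <- p^2 + Fco * p * q
      p1 <- 2 * p * q * (1 - Fco)
      u <- matrix(stats::runif(length(rows) * m), length(rows), m)
      thr2 <- matrix(p2, length(rows), m, byrow = TRUE)
      thr1 <- matrix(p2 + p1, length(rows), m, byrow = TRUE)
      G[rows, ] <- 2L * (u < thr2) + 1L * (u >= thr2 & u < thr1)
    }
    if (cfg$missing_rate > 0) {
      G[matrix(stats::runif(n * m), n, m) < cfg$missing_rate] <- NA_integer_
    }

    # site metadata: 7 chromosomes, sorted positions
    chrom <- paste0(rep(1:7, length.out = m), "H")
    ord <- order(chrom)
    pos <- integer(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(5e8, length(idx)))
    }
    sites <- data.frame(chrom = chrom, pos = pos,
                        ref = "A", alt = "C", stringsAsFactors = FALSE)
    keep <- order(sites$chrom, sites$pos)
    sites <- sites[keep, , drop = FALSE]
    G <- G[, keep, drop = FALSE]
    P_deme <- P_deme[, keep, drop = FALSE]
    b <- b[keep]
    adaptive_idx <- sort(match(adaptive_idx, keep))
    geno <- geno_matrix(G, ind_ids = demes$individuals$ind_id, sites = sites)

    # ancestry truth: spatial k-means clusters softened by Dirichlet(0.3)
    km <- stats::kmeans(cbind(demes$demes$x_km, demes$demes$y_km),
                        centers = cfg$k_clusters, nstart = 10)
    K <- cfg$k_clusters
    dirich <- matrix(stats::rgamma(n * K, shape = 0.3), n, K)
    dirich <- dirich / rowSums(dirich)
    Q <- matrix(0, n, K)
    Q[cbind(seq_len(n), km$cluster[deme_of])] <- 1
    Q <- 0.6 * Q + 0.4 * dirich
    Pclust <- t(vapply(seq_len(K), function(k)
      colMeans(P_deme[km$cluster == k, , drop = FALSE]), numeric(ncol(G))))

    truth <- structure(list(
      adaptive_idx = adaptive_idx, b = b, deme_freq = P_deme,
      Q = Q, P = Pclust, cluster = km$cluster, env_column = env_column,
      gp = list(sigma2 = cfg$gp_sigma2, range_km = cfg$gp_range_km),
      barrier_mask = if (!is.null(demes$barrier)) demes$barrier$mask),
      class = "sim_truth")
    list(geno = geno, truth = truth)
  })
}

#' Simulate a log migration-rate surface over the barrier raster
#'
#' Barrier cells have their mean log-rate lowered by `contrast`; independent
#' Gaussian noise is added everywhere. Stands in for an effective-migration
#' surface so the barrier association test is exercisable.
#'
#' @param barrier A [raster_grid()] with a barrier mask.
#' @param contrast Drop in mean log-rate at barrier cells.
#' @param noise_sd Noise SD.
#' @param seed Integer seed.
#' @return A [raster_grid()] of log migration rates carrying the same mask.
#' @export
simulate_rate_surface <- function(barrier, contrast = 2, noise_sd = 0.5,
                                  seed = 1) {
  stopifnot(inherits(barrier, "raster_grid"))
  if (is.null(barrier$mask)) stop("barrier raster has no mask")
  with_seed(derive_seed(seed, "rates"), {
    v <- matrix(stats::rnorm(length(barrier$mask), sd = noise_sd),
                nrow(barrier$mask), ncol(barrier$mask))
    v[barrier$mask] <- v[barrier$mask] - contrast
    raster_grid(v, barrier$cellsize, barrier$origin, mask = barrier$mask)
  })
}

#' Simulate genotypes under an admixture model
#'
#' Benchmark generator for ancestry-coefficient factorization: cluster
#' allele frequencies follow the Balding-Nichols model at a target FST,
#' ancestry rows are Dirichlet, and genotypes are binomial draws from the
#' individual-specific frequencies `Q %*% P`.
#'
#' @param n_ind,n_snps Dimensions.
#' @param K Number of ancestral clusters.
#' @param fst Target differentiation of cluster frequencies.
#' @param alpha Dirichlet concentration of ancestry rows.
#' @param seed Integer seed.
#' @return A list: `geno` ([geno_matrix()]), `Q` (n x K), `P` (K x m).
#' @export
simulate_admixture <- function(n_ind = 100, n_snps = 1000, K = 3,
                               fst = 0.15, alpha = 0.3, seed = 1) {
  stopifnot(K >= 1, fst > 0, fst < 1)
  with_seed(derive_seed(seed, "admixture"), {
    p0 <- stats::runif(n_snps, 0.1, 0.9)
    a <- p0 * (1 - fst) / fst
    bb <- (1 - p0) * (1 - fst) / fst
    P <- t(vapply(seq_len(K), function(k) stats::rbeta(n_snps, a, bb),
                  numeric(n_snps)))
    Q <- matrix(stats::rgamma(n_ind * K, shape = alpha), n_ind, K)
    Q <- Q / rowSums(Q)
    Fmat <- Q %*% P
    G <- matrix(stats::rbinom(n_ind * n_snps, 2, as.numeric(Fmat)),
                n_ind, n_snps)
    sites <- data.frame(chrom = "1H", pos = seq_len(n_snps) * 100L,
                        ref = "A", alt = "C", stringsAsFactors = FALSE)
    list(geno = geno_matrix(G, ind_ids = sprintf("I%03d", seq_len(n_ind)),
                            sites = sites),
         Q = Q, P = P)
  })
}

#' Write all synthetic-data artifacts to a directory
#'
#' Emits the dosage matrix (VCF and CSV), deme and individual tables, the
#' environmental table, the ground-truth record (JSON) and the barrier
#' raster.
#'
#' @param sim Output of [simulate_genotypes()].
#' @param demes A `deme_map`.
#' @param env An [env_table()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, demes, env, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    csv = file.path(dir, "genotypes.csv"),
    demes = file.path(dir, "demes.csv"),
    individuals = file.path(dir, "individuals.csv"),
    env = file.path(dir, "env.csv"),
    truth = file.path(dir, "truth.json"))
  write_genotypes(sim$geno, paths["vcf"], format = "vcf")
  write_genotypes(sim$geno, paths["csv"], format = "csv")
  utils::write.csv(demes$demes[, c("deme_id", "lat", "lon")],
                   paths["demes"], row.names = FALSE)
  utils::write.csv(demes$individuals, paths["individuals"],
                   row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(env$values), env$values,
                              check.names = FALSE),
                   paths["env"], row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(
    list(adaptive_idx = tr$adaptive_idx, b = tr$b,
         cluster = tr$cluster, env_column = tr$env_column, gp = tr$gp),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(demes$barrier)) {
    paths <- c(paths, barrier = file.path(dir, "barrier.grid"))
    bar <- demes$barrier
    bar$values <- bar$mask * 1
    write_raster(bar, paths["barrier"])
  }
  invisible(paths)
}
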
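# Pipeline orchestration: a single configuration object holding every
# threshold in one auditable place, per-stage runners writing plain-text
# artifacts plus a provenance record, and change detection so re-runs only
# re-execute stages whose configuration or inputs changed.

.STAGES <- c("simulate", "filter", "structure", "env", "spatial",
             "varpart", "scan", "geneflow", "ld")

#' Default pipeline configuration
#'
#' Nested per-stage settings; every stage draws its randomness from the
#' single global `seed` through [derive_seed()].
#'
#' @param outdir Output directory.
#' @param seed Global integer seed.
#' @param ... Named per-stage overrides (lists merged over the defaults).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = "pipeline_out", seed = 1, ...) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    simulate = list(n_demes = 58, n_ind = 244, n_snps = 5000,
                    extent_km = 200, gp_sigma2 = 0.25, gp_range_km = 50,
                    adaptive_frac = 0.02, effect_size = 0.8,
                    selfing_F = 0.96, missing_rate = 0.03, k_clusters = 4,
                    barrier = TRUE, env_groups = 3,
                    env_group_sizes = c(3, 2, 2), env_noise_sd = 0.2),
    filter = list(maf_min = 0.05, max_missing_site = 0.2,
                  max_missing_ind = 0.2, prune_r2 = NA),
    structure = list(n_axes = 10, K = NA, n_perm_d = 20),
    env = list(cut = 0.3, vif_max = 5),
    spatial = list(alpha = 0.05, n_perm_select = 999),
    varpart = list(n_perm = 5000),
    scan = list(k = 4, fdr = 0.05),
    geneflow = list(n_pcs = 3, alpha = 0.05, rate_contrast = 2,
                    rate_noise_sd = 0.5),
    ld = list(window = 250, span = 0.005, max_sites = 2000))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return [read_pipeline_config()]: a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(raw[c("outdir", "seed")],
            raw[setdiff(names(raw), c("outdir", "seed"))]))
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_dir <- function(config, stage) file.path(config$outdir, stage)

stage_inputs <- function(config, stage) {
  d <- function(s, f) file.path(stage_dir(config, s), f)
  switch(stage,
    simulate = character(0),
    filter = d("simulate", "genotypes.csv"),
    structure = d("filter", "genotypes.csv"),
    env = d("simulate", "env.csv"),
    spatial = c(d("simulate", "demes.csv"), d("simulate", "individuals.csv"),
                d("filter", "genotypes.csv")),
    varpart = c(d("filter", "genotypes.csv"), d("env", "env_selected.csv"),
                d("spatial", "mems_selected.csv"), d("structure", "Q.csv"),
                d("simulate", "individuals.csv")),
    scan = c(d("filter", "genotypes.csv"), d("env", "env_selected.csv"),
             d("structure", "Q.csv"), d("simulate", "individuals.csv")),
    geneflow = c(d("filter", "genotypes.csv"), d("simulate", "demes.csv"),
                 d("simulate", "individuals.csv"),
                 d("simulate", "barrier.grid")),
    ld = d("filter", "genotypes.csv"))
}

check_inputs <- function(config, stage) {
  ins <- stage_inputs(config, stage)
  missing <- ins[!file.exists(ins)]
  if (length(missing)) {
    owner <- basename(dirname(missing[1]))
    stop("stage '", stage, "' needs ", basename(missing[1]),
         "; run stage '", owner, "' first")
  }
  ins
}

write_provenance <- function(config, stage, inputs) {
  prov <- list(stage = stage,
               config = config[[stage]],
               seed = derive_seed(config$seed, stage),
               inputs = as.list(if (length(inputs))
                 tools::md5sum(inputs) else character(0)),
               version = as.character(utils::packageVersion("rdascape")),
               time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(prov, file.path(stage_dir(config, stage),
                                       "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  prov
}

stage_unchanged <- function(config, stage) {
  pfile <- file.path(stage_dir(config, stage), "provenance.json")
  if (!file.exists(pfile)) return(FALSE)
  prov <- tryCatch(jsonlite::read_json(pfile), error = function(e) NULL)
  if (is.null(prov)) return(FALSE)
  # round-trip the live config slice through JSON so both sides share one
  # canonical form (NA serializes as null, integers as numbers, ...)
  now_cfg <- jsonlite::toJSON(
    jsonlite::parse_json(jsonlite::toJSON(config[[stage]],
                                          auto_unbox = TRUE, digits = NA)),
    auto_unbox = TRUE, digits = NA)
  old_cfg <- jsonlite::toJSON(prov$config, auto_unbox = TRUE, digits = NA)
  if (!identical(as.character(now_cfg), as.character(old_cfg)))
    return(FALSE)
  ins <- stage_inputs(config, stage)
  if (!all(file.exists(ins))) return(FALSE)
  sums <- as.list(if (length(ins)) tools::md5sum(ins) else character(0))
  identical(unname(unlist(sums)), unname(unlist(prov$inputs))) &&
    identical(names(unlist(sums)), names(unlist(prov$inputs)))
}

read_deme_map <- function(config) {
  demes <- utils::read.csv(file.path(stage_dir(config, "simulate"),
                                     "demes.csv"),
                           stringsAsFactors = FALSE)
  km <- lonlat_to_km(demes$lon, demes$lat)
  demes$x_km <- km[, "x"]; demes$y_km <- km[, "y"]
  individuals <- utils::read.csv(file.path(stage_dir(config, "simulate"),
                                           "individuals.csv"),
                                 stringsAsFactors = FALSE)
  structure(list(demes = demes, individuals = individuals, barrier = NULL,
                 extent_km = NA, barrier_spec = NULL), class = "deme_map")
}

read_env_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  env_table(vals)
}

# Align a deme-level matrix to individuals through the deme map.
expand_to_individuals <- function(values, dm, ind_ids) {
  deme_of <- dm$individuals$deme_id[match(ind_ids, dm$individuals$ind_id)]
  out <- values[match(deme_of, rownames(values)), , drop = FALSE]
  rownames(out) <- ind_ids
  out
}

#' Run a single pipeline stage
#'
#' Stages: `simulate`, `filter`, `structure`, `env`, `spatial`, `varpart`,
#' `scan`, `geneflow`, `ld`. Each reads its upstream artifacts (erroring
#' with the name of the stage to run first when absent), writes plain-text
#' outputs under `outdir/<stage>/`, and records provenance (config slice,
#' input checksums, derived seed, package version).
#'
#' @param name Stage name.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the stage's in-memory results.
#' @export
run_stage <- function(name, config) {
  name <- match.arg(name, .STAGES)
  dir.create(stage_dir(config, name), recursive = TRUE,
             showWarnings = FALSE)
  inputs <- check_inputs(config, name)
  seed <- derive_seed(config$seed, name)
  sd <- stage_dir(config, name)
  res <- switch(name,
    simulate = {
      sc <- config$simulate
      cfg <- sim_config(
        n_demes = sc$n_demes, n_ind = sc$n_ind, n_snps = sc$n_snps,
        extent_km = sc$extent_km,
        barrier = if (isTRUE(sc$barrier))
          list(p1 = c(sc$extent_km / 2, 0),
               p2 = c(sc$extent_km / 2, 0.6 * sc$extent_km), penalty = 3)
          else NULL,
        gp_sigma2 = sc$gp_sigma2, gp_range_km = sc$gp_range_km,
        adaptive_frac = sc$adaptive_frac, effect_size = sc$effect_size,
        selfing_F = sc$selfing_F, missing_rate = sc$missing_rate,
        k_clusters = sc$k_clusters, seed = seed)
      dm <- simulate_demes(cfg)
      env <- simulate_env(dm, n_groups = sc$env_groups,
                          group_sizes = sc$env_group_sizes,
                          noise_sd = sc$env_noise_sd, seed = seed)
      sim <- simulate_genotypes(cfg, dm, env)
      write_simulation(sim, dm, env, sd)
      list(geno = sim$geno, truth = sim$truth, demes = dm, env = env)
    },
    filter = {
      G <- read_genotypes(inputs[1], format = "csv")
      fs <- filter_sites(G, config$filter$maf_min,
                         config$filter$max_missing_site)
      fi <- filter_individuals(fs$geno, config$filter$max_missing_ind)
      G2 <- fi$geno
      reports <- list(sites = fs$report, individuals = fi$report)
      if (!is.na(config$filter$prune_r2)) {
        pr <- ld_prune(G2, r2_max = config$filter$prune_r2)
        G2 <- pr$geno
        reports$prune <- pr$report
      }
      write_genotypes(G2, file.path(sd, "genotypes.csv"), format = "csv")
      write_filter_report(reports, file.path(sd, "filter_report.json"))
      list(geno = G2, reports = reports)
    },
    structure = {
      G <- read_genotypes(inputs[1], format = "csv")
      X <- impute_mean(G)
      pca <- run_pca(X, n_axes = config$structure$n_axes)
      K <- config$structure$K
      if (is.na(K)) K <- estimate_d(X, n_perm = config$structure$n_perm_d,
                                    seed = seed)
      anc <- estimate_ancestry(X, K)
      cl <- assign_clusters(anc)
      fst <- NULL; nei <- NULL; nwk <- NULL
      if (length(unique(cl$labels)) >= 2) {
        fst <- hudson_fst(G, cl$labels)
        nei <- nei_distance(G, cl$labels)
        if (length(unique(cl$labels)) >= 3) nwk <- nj_tree(nei)
      }
      utils::write.csv(data.frame(ind_id = G$ind_ids, pca$scores),
                       file.path(sd, "pca_scores.csv"), row.names = FALSE)
      utils::write.csv(data.frame(ind_id = G$ind_ids, anc$Q),
                       file.path(sd, "Q.csv"), row.names = FALSE)
      if (!is.null(fst)) {
        utils::write.csv(data.frame(cluster = rownames(fst$dist$mat),
                                    fst$dist$mat),
                         file.path(sd, "fst.csv"), row.names = FALSE)
        utils::write.csv(data.frame(cluster = rownames(nei$mat), nei$mat),
                         file.path(sd, "nei.csv"), row.names = FALSE)
      }
      if (!is.null(nwk)) writeLines(nwk, file.path(sd, "nj.nwk"))
      jsonlite::write_json(
        list(K = K, frac_admixed = cl$frac_admixed,
             prop_var = pca$prop_var[seq_len(min(10, length(pca$prop_var)))]),
        file.path(sd, "structure_summary.json"),
        auto_unbox = TRUE, digits = NA)
      list(pca = pca, K = K, ancestry = anc, clusters = cl, fst = fst,
           nei = nei, newick = nwk)
    },
    env = {
      env <- read_env_csv(inputs[1])
      groups <- cluster_collinear(env, cut = config$env$cut)
      synth <- make_synthetic_vars(env, groups)
      sel <- vif_select(synth, vif_max = config$env$vif_max)
      utils::write.csv(data.frame(id = rownames(sel$env$values),
                                  sel$env$values, check.names = FALSE),
                       file.path(sd, "env_selected.csv"), row.names = FALSE)
      utils::write.csv(data.frame(variable = names(groups),
                                  group = as.integer(groups)),
                       file.path(sd, "groups.csv"), row.names = FALSE)
      write_vif_log(sel$removed, file.path(sd, "vif_removed.json"))
      list(groups = groups, env = sel$env, removed = sel$removed)
    },
    spatial = {
      dm <- read_deme_map(config)
      G <- read_genotypes(inputs[3], format = "csv")
      graph <- gabriel_graph(dm$demes)
      W <- build_weights(graph)
      deme_of <- dm$individuals$deme_id[match(G$ind_ids,
                                              dm$individuals$ind_id)]
      mems <- compute_dbmem(W, membership = deme_of)
      Y <- impute_mean(G)
      fsel <- forward_select(Y, mems, alpha = config$spatial$alpha,
                             n_perm = config$spatial$n_perm_select,
                             seed = seed)
      utils::write.csv(graph$edges, file.path(sd, "gabriel_edges.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(deme_id = rownames(mems$vectors),
                                  mems$vectors),
                       file.path(sd, "mems_deme.csv"), row.names = FALSE)
      sel_ind <- fsel$vectors
      utils::write.csv(data.frame(ind_id = G$ind_ids, sel_ind,
                                  check.names = FALSE),
                       file.path(sd, "mems_selected.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(selected = fsel$selected,
             eigenvalues = mems$values,
             n_positive = sum(mems$values > 0),
             n_negative = sum(mems$values < 0)),
        file.path(sd, "spatial_summary.json"), auto_unbox = TRUE,
        digits = NA)
      list(graph = graph, W = W, mems = mems, selection = fsel)
    },
    varpart = {
      G <- read_genotypes(inputs[1], format = "csv")
      Y <- impute_mean(G)
      dm <- read_deme_map(config)
      env <- read_env_csv(inputs[2])
      Xenv <- expand_to_individuals(env$values, dm, G$ind_ids)
      mems_df <- utils::read.csv(inputs[3], check.names = FALSE,
                                 stringsAsFactors = FALSE)
      Xmem <- as.matrix(mems_df[match(G$ind_ids, mems_df[[1]]), -1,
                                drop = FALSE])
      qdf <- utils::read.csv(inputs[4], stringsAsFactors = FALSE)
      Q <- as.matrix(qdf[match(G$ind_ids, qdf[[1]]), -1, drop = FALSE])
      vp_env_space <- varpart_rda(Y, Xenv, Xmem)
      p_env <- anova_overall(Y, Xenv, n_perm = config$varpart$n_perm,
                             seed = seed)
      have_mem <- ncol(Xmem) > 0
      p_space <- if (have_mem)
        anova_overall(Y, Xmem, n_perm = config$varpart$n_perm,
                      seed = seed + 1) else NULL
      p_env_cond <- if (have_mem)
        anova_overall(Y, Xenv, Z = Xmem, n_perm = config$varpart$n_perm,
                      seed = seed + 2) else NULL
      fit_struct <- fit_rda(Y, drop_simplex_col(Q))
      fit_env_structcond <- fit_rda(Y, Xenv, Z = drop_simplex_col(Q))
      vp_Q <- varpart_rda(drop_simplex_col(Q), Xenv, Xmem)
      out <- list(
        env_space = vp_env_space[c("a", "b", "c", "d", "raw_a", "raw_b",
                                   "raw_c", "raw_d", "r2", "r2_adj")],
        p_env = p_env, p_space = p_space, p_env_cond = p_env_cond,
        structure_r2 = fit_struct$r2,
        env_given_structure_r2 = fit_env_structcond$r2,
        ancestry_response = vp_Q[c("a", "b", "c", "d")])
      jsonlite::write_json(out, file.path(sd, "varpart.json"),
                           auto_unbox = TRUE, digits = NA)
      c(out, list(vp = vp_env_space))
    },
    scan = {
      G <- read_genotypes(inputs[1], format = "csv")
      dm <- read_deme_map(config)
      env <- read_env_csv(inputs[2])
      Xenv <- expand_to_individuals(env$values, dm, G$ind_ids)
      qdf <- utils::read.csv(inputs[3], stringsAsFactors = FALSE)
      Q <- as.matrix(qdf[match(G$ind_ids, qdf[[1]]), -1, drop = FALSE])
      k_eff <- min(config$scan$k, qr(scale(Xenv, scale = FALSE))$rank)
      sc <- scan_pipeline(G, Xenv, Q = Q, k = k_eff,
                          fdr = config$scan$fdr)
      write_scan_table(sc$simple, G$sites, file.path(sd, "scan_simple.tsv"))
      write_scan_table(sc$corrected, G$sites,
                       file.path(sd, "scan_corrected.tsv"))
      cand <- G$sites[sc$simple$stats$candidate, c("chrom", "pos")]
      utils::write.csv(cand, file.path(sd, "candidates_simple.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(n_candidates_simple = sum(sc$simple$stats$candidate),
             n_candidates_corrected = sum(sc$corrected$stats$candidate),
             overlap = sc$overlap,
             lambda_simple = sc$simple$lambda,
             lambda_corrected = sc$corrected$lambda),
        file.path(sd, "scan_summary.json"), auto_unbox = TRUE, digits = NA)
      sc
    },
    geneflow = {
      G <- read_genotypes(inputs[1], format = "csv")
      dm <- read_deme_map(config)
      dm$individuals <- dm$individuals[
        dm$individuals$ind_id %in% G$ind_ids, , drop = FALSE]
      keep_demes <- unique(dm$individuals$deme_id)
      dm$demes <- dm$demes[dm$demes$deme_id %in% keep_demes, , drop = FALSE]
      dps <- dps_distance(G, dm)
      X <- impute_mean(G)
      pca <- run_pca(X, n_axes = config$geneflow$n_pcs)
      up <- unpc_scores(pca$scores, dm, n_pcs = config$geneflow$n_pcs)
      flags <- boxcox_outlier_test(up, alpha = config$geneflow$alpha)
      bar <- read_raster(inputs[4])
      bar$mask <- bar$values > 0
      rates <- simulate_rate_surface(bar,
                                     contrast = config$geneflow$rate_contrast,
                                     noise_sd = config$geneflow$rate_noise_sd,
                                     seed = seed)
      bt <- barrier_rate_test(rates)
      write_unpc_table(flags, file.path(sd, "unpc_pairs.csv"))
      utils::write.csv(data.frame(deme = rownames(dps$mat), dps$mat),
                       file.path(sd, "dps.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(lambda = flags$lambda, n_high = length(flags$high),
             n_low = length(flags$low),
             barrier_U = bt$U, barrier_p = bt$p),
        file.path(sd, "geneflow_summary.json"), auto_unbox = TRUE,
        digits = NA)
      list(dps = dps, unpc = flags, barrier_test = bt)
    },
    ld = {
      G <- read_genotypes(inputs[1], format = "csv")
      if (ncol(G$dosage) > config$ld$max_sites) {
        keep <- sort(with_seed(seed, sample.int(ncol(G$dosage),
                                                config$ld$max_sites)))
        G <- geno_matrix(G$dosage[, keep, drop = FALSE], G$ind_ids,
                         G$sites[keep, , drop = FALSE])
      }
      pr <- pairwise_r2(G, window = config$ld$window)
      fit <- fit_hill_weir(pr$pairs, n = nrow(G$dosage))
      sm <- tryCatch(smooth_decay(pr$pairs, span = config$ld$span),
                     error = function(e)
                       smooth_decay(pr$pairs, span = max(
                         config$ld$span, 5 / nrow(pr$pairs))))
      utils::write.csv(pr$pairs, file.path(sd, "ld_pairs.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(rho = fit$rho, r2_max_fit = fit$r2_max,
             half_decay_fit_bp = fit$half_decay_bp,
             r2_max_smooth = sm$r2_max,
             half_decay_smooth_bp = sm$half_decay_bp,
             n_pairs = nrow(pr$pairs)),
        file.path(sd, "ld_summary.json"), auto_unbox = TRUE, digits = NA)
      list(pairs = pr, fit = fit, smooth = sm)
    })
  write_provenance(config, name, inputs)
  invisible(res)
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order, skipping stages whose
#' configuration slice and input checksums are unchanged since their
#' recorded provenance (so changing, say, the scan FDR re-executes only the
#' scan stage).
#'
#' @param config A [pipeline_config()].
#' @param force Re-run every stage regardless of provenance.
#' @return Invisibly, a named list of stage results (NULL for skipped
#'   stages).
#' @export
run_pipeline <- function(config, force = FALSE) {
  results <- list()
  for (stage in .STAGES) {
    if (!force && stage_unchanged(config, stage)) {
      message("stage '", stage, "' unchanged; skipping")
      results[[stage]] <- NULL
      next
    }
    message("running stage '", stage, "'")
    results[[stage]] <- run_stage(stage, config)
  }
  invisible(results)
}
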
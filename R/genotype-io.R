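# Genotype containers, VCF/CSV I/O, site and individual filters, mean
# imputation and greedy LD pruning.

#' Genotype dosage matrix
#'
#' @param dosage Integer matrix, individuals x sites, entries in
#'   `{0, 1, 2, NA}` (NA = missing call).
#' @param ind_ids Unique individual identifiers.
#' @param sites Data frame with at least `chrom` and `pos` (1-based bp,
#'   strictly increasing within chromosome); optional `ref`, `alt`.
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(dosage, ind_ids, sites) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (length(ind_ids) != nrow(dosage))
    stop("ind_ids length disagrees with dosage rows")
  if (anyDuplicated(ind_ids))
    stop("duplicated individual IDs: ",
         paste(unique(ind_ids[duplicated(ind_ids)]), collapse = ", "))
  if (nrow(sites) != ncol(dosage))
    stop("sites rows disagree with dosage columns")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or missing")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch,
           " (first offence near pos ", p[which(diff(p) <= 0)[1] + 1], ")")
  }
  rownames(dosage) <- ind_ids
  colnames(dosage) <- paste(sites$chrom, sites$pos, sep = "_")
  rownames(sites) <- NULL
  structure(list(dosage = dosage, ind_ids = as.character(ind_ids),
                 sites = sites),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf("<geno_matrix> %d individuals x %d sites (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

new_filter_report <- function(step, n_sites_in, n_sites_out,
                              n_ind_in, n_ind_out, thresholds, removed) {
  structure(list(step = step,
                 n_sites_in = n_sites_in, n_sites_out = n_sites_out,
                 n_ind_in = n_ind_in, n_ind_out = n_ind_out,
                 thresholds = thresholds, removed = removed),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: sites %d -> %d, individuals %d -> %d\n",
              x$step, x$n_sites_in, x$n_sites_out, x$n_ind_in, x$n_ind_out))
  for (nm in names(x$removed))
    cat(sprintf("  %s: %d removed\n", nm, x$removed[[nm]]))
  invisible(x)
}

#' Write a filter report as JSON
#' @param report A `filter_report` (or list of them).
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Read genotypes from VCF or dosage CSV
#'
#' VCF records must be biallelic SNPs; multiallelic or non-SNP records are
#' excluded and counted. GT fields are converted to alternate-allele counts;
#' `./.` and `.` become missing.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"csv"`. Guessed from the extension by default.
#' @return A [geno_matrix()]; the number of excluded records is attached as
#'   `attr(, "report")`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    M <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(M) <- "integer"
    parts <- strsplit(colnames(M), "_")
    sites <- data.frame(
      chrom = vapply(parts, function(p)
        paste(p[-length(p)], collapse = "_"), ""),
      pos = as.integer(vapply(parts, function(p) p[length(p)], "")),
      stringsAsFactors = FALSE)
    return(geno_matrix(M, ids, sites))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_excluded <- sum(!snp)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  ids <- colnames(gt)
  if (anyDuplicated(ids))
    stop("duplicated sample IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  code <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1", "1")] <- 2L
    out
  }
  M <- t(apply(gt, 1, code))   # sites x individuals
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("unsorted or duplicated positions on chromosome ", ch, " in ",
           path, " (first offence near pos ",
           p[which(diff(p) <= 0)[1] + 1], ")")
  }
  g <- geno_matrix(t(M), ids, sites)
  attr(g, "report") <- list(n_records_excluded = n_excluded)
  g
}

#' Write genotypes as minimal VCF or dosage CSV
#'
#' The VCF is a v4.2 subset: CHROM, POS, ID, REF, ALT, QUAL '.', FILTER '.',
#' INFO '.', FORMAT GT; missing calls are `./.`.
#'
#' @param G A [geno_matrix()].
#' @param path Output file.
#' @param format `"vcf"` or `"csv"`.
#' @export
write_genotypes <- function(G, path, format = c("vcf", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(ind_id = G$ind_ids,
                     G$dosage, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  ref <- rep(if ("ref" %in% names(G$sites)) G$sites$ref else "A",
             length.out = ncol(G$dosage))
  alt <- rep(if ("alt" %in% names(G$sites)) G$sites$alt else "C",
             length.out = ncol(G$dosage))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", G$ind_ids), collapse = "\t"))
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(ncol(G$dosage)), function(j) {
    d <- G$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gtcode[as.character(d)])
    paste(c(G$sites$chrom[j], G$sites$pos[j], ".", ref[j], alt[j],
            ".", ".", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

site_maf <- function(G) {
  alt <- colSums(G$dosage, na.rm = TRUE)
  nobs <- 2 * colSums(!is.na(G$dosage))
  p <- ifelse(nobs > 0, alt / nobs, NA_real_)
  pmin(p, 1 - p)
}

#' Filter sites on minor allele frequency and missingness
#'
#' MAF is computed on non-missing alleles; a site is kept when
#' `MAF >= maf_min` (boundary kept) and its missing fraction is
#' `<= max_missing`.
#'
#' @param G A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency in `[0, 0.5]`.
#' @param max_missing Maximum per-site missing fraction.
#' @return List: `geno` (filtered) and `report` (a `filter_report`).
#' @export
filter_sites <- function(G, maf_min = 0.05, max_missing = 1) {
  stopifnot(inherits(G, "geno_matrix"), maf_min >= 0, maf_min <= 0.5)
  maf <- site_maf(G)
  missfrac <- colMeans(is.na(G$dosage))
  drop_maf <- is.na(maf) | maf < maf_min
  drop_miss <- missfrac > max_missing
  keep <- !(drop_maf | drop_miss)
  if (!any(keep)) stop("all sites removed by filters")
  out <- geno_matrix(G$dosage[, keep, drop = FALSE], G$ind_ids,
                     G$sites[keep, , drop = FALSE])
  rep <- new_filter_report("filter_sites",
                           ncol(G$dosage), sum(keep),
                           nrow(G$dosage), nrow(G$dosage),
                           list(maf_min = maf_min, max_missing = max_missing),
                           list(low_maf = sum(drop_maf),
                                high_missing = sum(drop_miss & !drop_maf)))
  list(geno = out, report = rep)
}

#' Filter individuals on missingness
#'
#' @param G A [geno_matrix()].
#' @param max_missing Maximum per-individual missing fraction.
#' @return List: `geno` and `report`.
#' @export
filter_individuals <- function(G, max_missing = 0.059) {
  stopifnot(inherits(G, "geno_matrix"))
  missfrac <- rowMeans(is.na(G$dosage))
  keep <- missfrac <= max_missing
  if (!any(keep)) stop("all individuals removed by filter")
  out <- geno_matrix(G$dosage[keep, , drop = FALSE], G$ind_ids[keep],
                     G$sites)
  rep <- new_filter_report("filter_individuals",
                           ncol(G$dosage), ncol(G$dosage),
                           nrow(G$dosage), sum(keep),
                           list(max_missing = max_missing),
                           list(high_missing = sum(!keep)))
  list(geno = out, report = rep)
}

#' Mean-impute missing dosages
#'
#' Missing entries at a site become the mean dosage of the site's observed
#' entries; observed entries are unchanged.
#'
#' @param G A [geno_matrix()].
#' @return A numeric individuals x sites matrix.
#' @export
impute_mean <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  X <- G$dosage
  storage.mode(X) <- "double"
  nobs <- colSums(!is.na(X))
  if (any(nobs == 0))
    stop("site(s) with all calls missing; run filter_sites first: ",
         paste(utils::head(colnames(X)[nobs == 0], 3), collapse = ", "))
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X
}

#' Greedy LD pruning
#'
#' Left-to-right scan within each chromosome: each retained site is compared
#' (squared Pearson correlation of mean-imputed dosages) against up to
#' `window` subsequent retained sites; the later member of a pair with
#' `r^2 > r2_max` is dropped. The window counts retained SNPs, not kb. The
#' first site of a chromosome is never dropped.
#'
#' @param G A [geno_matrix()].
#' @param r2_max Squared-correlation threshold.
#' @param window Retained-site lookahead (>= 1).
#' @return List: `geno` and `report`.
#' @export
ld_prune <- function(G, r2_max = 0.1, window = 50) {
  stopifnot(inherits(G, "geno_matrix"))
  if (window < 1) stop("window must be >= 1")
  X <- impute_mean(G)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ss <- colSums(Xc^2)
  keep <- rep(TRUE, ncol(X))
  for (ch in unique(G$sites$chrom)) {
    idx <- which(G$sites$chrom == ch)
    retained <- integer(0)
    for (j in idx) {
      cand <- utils::tail(retained, window)
      drop <- FALSE
      for (i in cand) {
        if (ss[i] == 0 || ss[j] == 0) next  # monomorphic: r^2 undefined
        r2 <- (sum(Xc[, i] * Xc[, j]))^2 / (ss[i] * ss[j])
        if (r2 > r2_max) { drop <- TRUE; break }
      }
      if (drop) keep[j] <- FALSE else retained <- c(retained, j)
    }
  }
  out <- geno_matrix(G$dosage[, keep, drop = FALSE], G$ind_ids,
                     G$sites[keep, , drop = FALSE])
  rep <- new_filter_report("ld_prune",
                           ncol(G$dosage), sum(keep),
                           nrow(G$dosage), nrow(G$dosage),
                           list(r2_max = r2_max, window = window,
                                window_unit = "retained SNPs"),
                           list(pruned = sum(!keep)))
  list(geno = out, report = rep)
}
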
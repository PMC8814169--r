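#' @keywords internal
"_PACKAGE"

# Missing dosage sentinel used internally; never written to disk.
.MISSING <- -1L

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Derive a stage-specific random seed from a global seed
#'
#' Deterministic substream derivation: each pipeline stage draws its
#' randomness from `seed * 31 + offset` (mod 2^31 - 1), where the offset is a
#' fixed per-stage constant. Keeps partial re-runs reproducible.
#'
#' @param seed Integer global seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, filter = 2L, structure = 3L, env = 4L,
               spatial = 5L, varpart = 6L, scan = 7L, geneflow = 8L,
               ld = 9L)
  off <- unname(offsets[match(stage, names(offsets))])
  if (is.na(off)) off <- sum(utf8ToInt(stage)) %% 997L
  as.integer((as.numeric(seed) * 31 + off) %% (2^31 - 1))
}

#' Construct a symmetric distance matrix object
#'
#' @param mat Symmetric numeric matrix with zero diagonal.
#' @param labels Row/column labels.
#' @param statistic Tag: "fst", "nei", "dps" or "custom".
#' @return A `dist_matrix` object.
#' @export
dist_matrix <- function(mat, labels = rownames(mat), statistic = "custom") {
  mat <- as.matrix(mat)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(mat)))
  stopifnot(nrow(mat) == ncol(mat), length(labels) == nrow(mat))
  if (any(is.na(mat))) stop("distance matrix contains NA")
  if (max(abs(mat - t(mat))) > 1e-8) stop("distance matrix is not symmetric")
  diag(mat) <- 0
  dimnames(mat) <- list(labels, labels)
  structure(list(labels = labels, mat = mat, statistic = statistic),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %s, %d labels\n", x$statistic, length(x$labels)))
  print(round(x$mat, 4))
  invisible(x)
}

# ---- plain-text raster grid ------------------------------------------------

#' Construct a raster grid
#'
#' A minimal in-memory raster: a numeric value matrix (rows = grid rows from
#' the top), cell size in km, an origin (x, y of the lower-left corner in km),
#' and an optional logical mask of the same shape (used to flag barrier cells).
#'
#' @param values Numeric matrix.
#' @param cellsize Cell edge length (km).
#' @param origin Numeric length-2 vector, lower-left corner (km).
#' @param mask Optional logical matrix, same shape as `values`.
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(values, cellsize, origin = c(0, 0), mask = NULL) {
  values <- as.matrix(values)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(values))) stop("mask shape differs from values")
    storage.mode(mask) <- "logical"
  }
  structure(list(values = values, cellsize = cellsize,
                 origin = as.numeric(origin), mask = mask),
            class = "raster_grid")
}

#' Write a raster grid as plain text
#'
#' Format: a 4-line header (`ncols`, `nrows`, `cellsize`, `origin x y`)
#' followed by `nrows` whitespace-separated data rows (top row first).
#'
#' @param r A `raster_grid`.
#' @param path Output file.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "raster_grid"))
  hdr <- c(sprintf("ncols %d", ncol(r$values)),
           sprintf("nrows %d", nrow(r$values)),
           sprintf("cellsize %.10g", r$cellsize),
           sprintf("origin %.10g %.10g", r$origin[1], r$origin[2]))
  rows <- apply(r$values, 1, function(v) paste(format(v, digits = 10),
                                               collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a plain-text raster grid
#'
#' @param path File written by [write_raster()].
#' @return A `raster_grid` (without mask).
#' @export
read_raster <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(ln[1:4], "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  if (!identical(key, c("ncols", "nrows", "cellsize", "origin")))
    stop("malformed raster header in ", path)
  nc <- as.integer(hdr[[1]][2]); nr <- as.integer(hdr[[2]][2])
  cs <- as.numeric(hdr[[3]][2])
  org <- as.numeric(hdr[[4]][2:3])
  vals <- do.call(rbind, lapply(ln[5:(4 + nr)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  if (ncol(vals) != nc) stop("raster data width disagrees with header")
  raster_grid(vals, cs, org)
}

# Standardize columns of a matrix to mean 0, sd 1.
standardize_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0)) stop("constant column cannot be standardized: ",
                          paste(colnames(x)[sdv == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  attr(xs, "center") <- mu
  attr(xs, "scale") <- sdv
  xs
}
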
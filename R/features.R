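# Expression-derived node features: normalization, principal-component
# projection with genes as observations and samples as variables, and
# per-component minimum-maximum scaling.  The fitted transform is a plain
# affine map, so genes unseen at fit time are projected inductively with the
# train-time loadings; their scaled coordinates may fall outside [0, 1] and
# are deliberately not clamped (linearity preserved).

#' Read an expression matrix
#'
#' Delimited text, genes in rows, samples in columns, header row of sample
#' ids, first column gene symbols.  Values are FPKM-like: nonnegative.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma).
#' @return Numeric matrix genes x samples with dimnames.
#' @export
read_expression <- function(path, sep = ",") {
  assert_that(file.exists(path), "expression file not found: %s", path)
  df <- read.table(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  assert_that(all(is.finite(m)), "expression matrix has non-finite entries")
  assert_that(all(m >= 0), "expression matrix has negative entries")
  m
}

#' Write an expression matrix in the dialect [read_expression()] consumes
#' @param expr Numeric matrix genes x samples.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, sep = ",") {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize an expression matrix
#'
#' Default is the standard `log2(x + 1)` variance-stabilizing transform for
#' FPKM-like data; `"zscore"` additionally centers and scales each gene;
#' `"none"` passes through.
#'
#' @param expr Nonnegative numeric matrix genes x samples.
#' @param method `"log2"` (default), `"zscore"`, or `"none"`.
#' @return Transformed matrix, same shape.
#' @export
normalize_expression <- function(expr, method = c("log2", "zscore", "none")) {
  method <- match.arg(method)
  assert_that(all(expr >= 0), "normalize_expression requires nonnegative input")
  switch(method,
    none = expr,
    log2 = log2(expr + 1),
    zscore = {
      lg <- log2(expr + 1)
      mu <- rowMeans(lg)
      sd <- apply(lg, 1, stats::sd)
      sd[sd == 0] <- 1
      (lg - mu) / sd
    })
}

#' Fit the node-feature transform (PCA + min-max scaling)
#'
#' Principal components are fitted on the rows of `fit_genes` only (genes are
#' observations, samples are variables), enabling the unseen-gene scenarios
#' where the transform must never see test genes.  Loadings carry a
#' deterministic sign convention (largest-magnitude entry positive) and
#' min-max bounds are taken from the fit genes' projected coordinates, so
#' projecting the fit set itself yields every component spanning exactly
#' `[0, 1]`.
#'
#' @param expr Normalized expression matrix genes x samples (apply
#'   [normalize_expression()] first; the transform stores no normalization).
#' @param n_components Number of principal components (default 50).
#' @param fit_genes Genes to fit on (default all rows of `expr`).
#' @return A `feature_transform`: sample `center`, `loadings`
#'   (samples x d), `minmax` bounds, `explained_variance` shares, `fitted_on`
#'   gene set.
#' @export
fit_feature_transform <- function(expr, n_components = 50,
                                  fit_genes = rownames(expr)) {
  missing <- setdiff(fit_genes, rownames(expr))
  if (length(missing) > 0L) {
    stopf("fit gene missing from expression matrix: %s", missing[1L])
  }
  x <- expr[fit_genes, , drop = FALSE]
  max_d <- min(nrow(x) - 1L, ncol(x))
  assert_that(n_components >= 1 && n_components <= max_d,
              "n_components (%d) exceeds min(n_genes - 1, n_samples) = %d",
              n_components, max_d)
  if (all(apply(x, 2, stats::sd) == 0)) stopf("zero-variance expression data")
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|entry| of each loading vector made positive
  flip <- vapply(seq_len(ncol(loadings)), function(j) {
    v <- loadings[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- sweep(x, 2, pc$center) %*% loadings
  mins <- apply(scores, 2, min)
  maxs <- apply(scores, 2, max)
  if (any(maxs - mins <= 0)) {
    stopf("degenerate component with zero spread in fit set")
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(center = pc$center, loadings = loadings,
                 minmax = cbind(min = mins, max = maxs),
                 explained_variance = ev[seq_len(n_components)],
                 fitted_on = fit_genes),
            class = "feature_transform")
}

#' @export
print.feature_transform <- function(x, ...) {
  cat(sprintf("feature_transform: %d components over %d samples, fitted on %d genes\n",
              ncol(x$loadings), length(x$center), length(x$fitted_on)))
  invisible(x)
}

#' Project genes through a fitted feature transform
#'
#' Centers by the fit-time sample means, projects onto the stored loadings,
#' and applies the stored min-max affine map.  Genes absent at fit time are
#' projected with the same map; coordinates outside `[0, 1]` are kept as-is.
#'
#' @param transform A `feature_transform`.
#' @param expr Normalized expression matrix containing rows for `genes`,
#'   with the same sample columns as at fit time.
#' @param genes Genes to project (default all rows of `expr`).
#' @return A `feature_matrix`: list with `vectors` (genes x d matrix) and
#'   `genes`.
#' @export
apply_feature_transform <- function(transform, expr, genes = rownames(expr)) {
  if (ncol(expr) != length(transform$center) ||
      !identical(colnames(expr), names(transform$center))) {
    stopf("sample columns do not match the fitted transform")
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L) {
    stopf("gene missing from expression matrix: %s", missing[1L])
  }
  x <- expr[genes, , drop = FALSE]
  scores <- sweep(x, 2, transform$center) %*% transform$loadings
  rng <- transform$minmax[, "max"] - transform$minmax[, "min"]
  scaled <- sweep(sweep(scores, 2, transform$minmax[, "min"]), 2, rng, `/`)
  colnames(scaled) <- paste0("PC", seq_len(ncol(scaled)))
  structure(list(vectors = scaled, genes = genes), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d genes x %d components\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Persist / restore a feature transform
#'
#' Single-file plain-text (JSON) serialization so a train-time transform can
#' be reapplied at test time.
#'
#' @param transform A `feature_transform`.
#' @param path File path.
#' @return `write_feature_transform`: invisibly `path`;
#'   `read_feature_transform`: the restored `feature_transform`.
#' @export
write_feature_transform <- function(transform, path) {
  obj <- list(center = as.list(transform$center),
              loadings = transform$loadings,
              minmax = transform$minmax,
              explained_variance = transform$explained_variance,
              fitted_on = transform$fitted_on)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_feature_transform
#' @export
read_feature_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  center <- unlist(obj$center)
  loadings <- obj$loadings
  rownames(loadings) <- names(center)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  minmax <- obj$minmax
  colnames(minmax) <- c("min", "max")
  rownames(minmax) <- colnames(loadings)
  structure(list(center = center, loadings = loadings, minmax = minmax,
                 explained_variance = as.numeric(obj$explained_variance),
                 fitted_on = as.character(obj$fitted_on)),
            class = "feature_transform")
}

#' Write a feature matrix as gene + numeric columns TSV
#' @param features A `feature_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(gene = features$genes, features$vectors,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path File path.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  structure(list(vectors = m, genes = df$gene), class = "feature_matrix")
}
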
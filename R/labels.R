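# Essential / nonessential / unlabeled label construction from
# knockout-screen gene-effect matrices.
#
# The labeling recipe: within each cell line, genes are percentile-ranked by
# viability effect (most negative = most depleted = rank 1); per gene, a high
# quantile of its ranks across lines summarizes whether the gene is strongly
# depleted in most lines; the summary distribution is bimodal and a Gaussian
# KDE valley between the two modes separates the common-essential mode from
# the rest.

#' Read a gene-effect matrix
#'
#' Reads DepMap-style CSV exports of per-gene, per-cell-line viability effect
#' scores (more negative = stronger depletion).  Orientation is auto-detected
#' from the header: if the first column holds cell-line style ids and the
#' header holds gene symbols (lines-by-genes, the DepMap download
#' orientation), the matrix is transposed to genes-by-lines.
#'
#' @param path CSV file with a leading id column and a header row.
#' @param genes_in_rows Force orientation; `NA` (default) auto-detects by
#'   matching row/column counts: the larger dimension is taken as genes.
#' @return Numeric matrix, genes in rows (rownames), cell lines in columns.
#' @export
read_gene_effect <- function(path, genes_in_rows = NA) {
  assert_that(file.exists(path), "gene-effect file not found: %s", path)
  df <- read.table(path, sep = ",", header = TRUE, row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (is.na(genes_in_rows)) genes_in_rows <- nrow(m) >= ncol(m)
  if (!genes_in_rows) m <- t(m)
  assert_that(nrow(m) >= 2 && ncol(m) >= 1,
              "gene-effect matrix needs >= 2 genes and >= 1 line")
  m
}

#' Per-line percentile ranks of gene effects
#'
#' Within each cell line, genes are ranked ascending by effect score (the
#' most negative, i.e. most depleting, gene gets rank 1), ties receive the
#' average rank, and ranks are normalized by the number of scored genes so
#' percentiles lie in `(0, 1]`.  Missing entries (gene unscreened in a line)
#' stay `NA` and are excluded from that line's denominator.
#'
#' @param effects Numeric matrix, genes x cell lines (rownames = genes).
#' @return Matrix of the same shape with percentile ranks in `(0, 1]`.
#' @export
percentile_ranks <- function(effects) {
  assert_that(is.matrix(effects) && nrow(effects) >= 2,
              "effects must be a matrix with >= 2 genes")
  out <- apply(effects, 2, function(col) {
    ok <- !is.na(col)
    if (sum(ok) == 0L) stopf("cell line with no scored genes")
    r <- rep(NA_real_, length(col))
    r[ok] <- rank(col[ok], ties.method = "average") / sum(ok)
    r
  })
  dimnames(out) <- dimnames(effects)
  out
}

#' Summarize per-gene rank distributions at a coverage quantile
#'
#' A common-essential gene should produce a significant growth phenotype in
#' most cell lines; "most" is operationalized as a coverage fraction
#' (default 0.90).  The summary is the coverage-quantile (type 7, linear
#' interpolation) of a gene's percentile ranks across lines: it is small iff
#' the gene ranks among the most depleted genes in at least `coverage` of
#' its lines.
#'
#' @param ranks Matrix from [percentile_ranks()].
#' @param coverage Quantile level in `(0, 1]`.
#' @return Named numeric vector, one summary in `[0, 1]` per gene.
#' @export
rank_summary <- function(ranks, coverage = 0.90) {
  assert_that(coverage > 0 && coverage <= 1, "coverage must lie in (0, 1]")
  apply(ranks, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    unname(quantile(x, probs = coverage, type = 7))
  })
}

#' Valley threshold of a bimodal distribution by Gaussian KDE
#'
#' Smooths the values with a Gaussian kernel density estimate on a uniform
#' grid over `[0, 1]`, locates the two highest-density modes (strict local
#' maxima of the gridded density), and returns the grid location of minimum
#' density strictly between them.  On DepMap-style rank summaries this valley
#' falls around 0.3 and separates the common-essential mode from the rest.
#'
#' @param values Numeric vector in `[0, 1]`, at least 50 values.
#' @param grid_points Number of evaluation grid points (default 512).
#' @param bandwidth Either a positive number or a rule name understood by
#'   [stats::density()] (`"nrd"` = Scott's rule, the default; `"nrd0"`,
#'   `"SJ"`, ...).
#' @param prominence_ratio Two neighboring density maxima count as distinct
#'   modes only when the dip between them falls below this fraction of the
#'   lower maximum (default 0.8); shallower dips are sampling bumpiness on
#'   one mode and are merged.
#' @return The valley location (scalar).  If several grid points tie at the
#'   minimum density the midpoint of the tied run is returned.  Errors with
#'   "no valley found" when the smoothed density has fewer than two modes.
#' @export
kde_valley_threshold <- function(values, grid_points = 512, bandwidth = "nrd",
                                 prominence_ratio = 0.8) {
  values <- values[!is.na(values)]
  assert_that(length(values) >= 50,
              "kde_valley_threshold needs >= 50 values, got %d", length(values))
  d <- density(values, bw = bandwidth, kernel = "gaussian",
               from = 0, to = 1, n = grid_points)
  y <- d$y
  x <- d$x
  n <- length(y)
  peaks <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  # ignore numerically negligible ripples in the density tails
  peaks <- peaks[y[peaks] > 1e-3 * max(y)]
  # merge neighboring maxima not separated by a pronounced dip: keep the
  # higher of the pair until all surviving modes are well separated
  while (length(peaks) >= 2L) {
    dips <- vapply(seq_len(length(peaks) - 1L), function(i) {
      between <- (peaks[i] + 1L):(peaks[i + 1L] - 1L)
      min(y[between]) / min(y[peaks[i]], y[peaks[i + 1L]])
    }, numeric(1))
    worst <- which.max(dips)
    if (dips[worst] < prominence_ratio) break
    drop <- if (y[peaks[worst]] < y[peaks[worst + 1L]]) worst else worst + 1L
    peaks <- peaks[-drop]
  }
  if (length(peaks) < 2L) stop("no valley found", call. = FALSE)
  top2 <- peaks[order(y[peaks], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  between <- (lo + 1L):(hi - 1L)
  ymin <- min(y[between])
  tied <- between[y[between] == ymin]
  mean(range(x[tied]))
}

#' Call common-essential genes below a summary threshold
#'
#' @param summary Named numeric vector from [rank_summary()].
#' @param threshold Valley threshold in `(0, 1)`.
#' @return Character vector of genes with summary strictly below threshold.
#' @export
call_common_essential <- function(summary, threshold) {
  assert_that(threshold > 0 && threshold < 1, "threshold must lie in (0, 1)")
  names(summary)[!is.na(summary) & summary < threshold]
}

#' Intersect essential calls from two screening technologies
#'
#' @param set_a,set_b Character gene sets (e.g. CRISPR and RNAi calls).
#' @return Their intersection.
#' @export
intersect_screens <- function(set_a, set_b) intersect(set_a, set_b)

#' Partition a gene universe into essential / nonessential / unlabeled
#'
#' Essential genes are the common-essential calls; conditionally essential
#' genes (essential only in some cell lines) are set aside as unlabeled
#' rather than forced into either class; everything else is nonessential.
#' Essential takes precedence over conditional on overlap.
#'
#' @param universe All gene symbols under consideration.
#' @param common Common-essential gene set (must be within `universe`).
#' @param conditional Conditionally essential gene set (may overlap anything).
#' @return A `label_set`: disjoint character vectors `essential`,
#'   `nonessential`, `unlabeled` whose union is `universe`.
#' @export
assign_labels <- function(universe, common, conditional = character()) {
  universe <- unique(as.character(universe))
  common <- unique(as.character(common))
  conditional <- unique(as.character(conditional))
  outside <- setdiff(common, universe)
  if (length(outside) > 0L) {
    stopf("common-essential gene outside universe: %s", outside[1L])
  }
  essential <- sort(common)
  unlabeled <- sort(setdiff(intersect(conditional, universe), common))
  nonessential <- sort(setdiff(universe, union(common, conditional)))
  structure(list(essential = essential, nonessential = nonessential,
                 unlabeled = unlabeled),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: %d essential, %d nonessential, %d unlabeled\n",
              length(x$essential), length(x$nonessential),
              length(x$unlabeled)))
  invisible(x)
}

restrict_labels <- function(labels, nodes) {
  structure(list(essential = intersect(labels$essential, nodes),
                 nonessential = intersect(labels$nonessential, nodes),
                 unlabeled = sort(union(intersect(labels$unlabeled, nodes),
                                        setdiff(nodes, c(labels$essential,
                                                         labels$nonessential,
                                                         labels$unlabeled))))),
            class = "label_set")
}

#' Full labeling pipeline for one screening technology
#'
#' Chains [percentile_ranks()], [rank_summary()], [kde_valley_threshold()]
#' and [call_common_essential()] on one gene-effect matrix.
#'
#' @param effects Gene-effect matrix (genes x lines).
#' @param coverage Coverage quantile for [rank_summary()].
#' @param grid_points,bandwidth Passed to [kde_valley_threshold()].
#' @return List with `summary`, `threshold`, and `essential` (the called
#'   gene set).
#' @export
label_screen <- function(effects, coverage = 0.90, grid_points = 512,
                         bandwidth = "nrd") {
  ranks <- percentile_ranks(effects)
  summ <- rank_summary(ranks, coverage = coverage)
  thr <- kde_valley_threshold(summ, grid_points = grid_points,
                              bandwidth = bandwidth)
  list(summary = summ, threshold = thr,
       essential = call_common_essential(summ, thr))
}

#' Write a label set as plain-text lists plus a combined TSV
#'
#' @param labels A `label_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_label_set <- function(labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("essential.txt", "nonessential.txt",
                            "unlabeled.txt", "labels.tsv"))
  writeLines(labels$essential, paths[1])
  writeLines(labels$nonessential, paths[2])
  writeLines(labels$unlabeled, paths[3])
  tab <- data.frame(
    gene = c(labels$essential, labels$nonessential, labels$unlabeled),
    label = rep(c("essential", "nonessential", "unlabeled"),
                c(length(labels$essential), length(labels$nonessential),
                  length(labels$unlabeled))))
  tab <- tab[order(tab$gene), ]
  write.table(tab, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a label set written by [write_label_set()]
#' @param path Path to the combined `labels.tsv`.
#' @return A `label_set`.
#' @export
read_label_set <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character"))
  assign_labels(universe = tab$gene,
                common = tab$gene[tab$label == "essential"],
                conditional = tab$gene[tab$label == "unlabeled"])
}
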
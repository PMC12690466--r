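# Reading, filtering and canonicalizing PPI edge lists.
#
# Gene identity throughout the package is the raw symbol string,
# case-sensitive; identifier mapping (aliases, orthologs) is the caller's
# responsibility.  Node order is fixed to lexicographic at graph
# construction so seeded runs are reproducible across platforms.

#' Read a PPI edge list
#'
#' Reads confidence-scored protein-protein interaction edge lists in the
#' common two-column (gene pair) or three-column (gene pair + numeric
#' confidence) dialects used by STRING-, CPDB- and BioGRID-style exports.
#' A header row is detected automatically: a first row whose score field is
#' non-numeric (or, for two-column files, that exactly repeats common header
#' tokens) is skipped.  STRING detailed-links files carry combined scores in
#' 0--1000; scores above 1 are rescaled by 1/1000 so confidences always live
#' in `[0, 1]`.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"two-column"` (no confidence) or `"three-column"`.
#' @param delimiter Field delimiter, default tab.
#' @return A `data.frame` with columns `gene_a`, `gene_b` and (for the
#'   three-column dialect) `confidence`.
#' @export
read_edge_list <- function(path, dialect = c("three-column", "two-column"),
                           delimiter = "\t") {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "edge list file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_fields <- if (dialect == "three-column") 3L else 2L
  if (length(lines) == 0L) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE)
    if (dialect == "three-column") out$confidence <- numeric()
    return(out)
  }
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  start <- 1L
  first <- parts[[1L]]
  if (length(first) >= n_fields) {
    if (dialect == "three-column") {
      if (is.na(suppressWarnings(as.numeric(first[3L])))) start <- 2L
    } else {
      header_tokens <- c("gene_a", "gene_b", "protein1", "protein2",
                         "gene1", "gene2", "source", "target",
                         "genea", "geneb")
      if (all(tolower(first[1:2]) %in% header_tokens)) start <- 2L
    }
  }
  if (start > length(lines)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE)
    if (dialect == "three-column") out$confidence <- numeric()
    return(out)
  }
  parts <- parts[start:length(parts)]
  line_no <- seq(start, length(lines))
  bad <- which(vapply(parts, length, integer(1)) < n_fields)
  if (length(bad) > 0L) {
    stopf("malformed row at line %d: expected %d fields", line_no[bad[1L]],
          n_fields)
  }
  gene_a <- vapply(parts, `[[`, character(1), 1L)
  gene_b <- vapply(parts, `[[`, character(1), 2L)
  blank <- which(!nzchar(gene_a) | !nzchar(gene_b))
  if (length(blank) > 0L) {
    stopf("malformed row at line %d: empty gene symbol", line_no[blank[1L]])
  }
  out <- data.frame(gene_a = gene_a, gene_b = gene_b,
                    stringsAsFactors = FALSE)
  if (dialect == "three-column") {
    score <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
    if (anyNA(score)) {
      stopf("malformed row at line %d: unparsable confidence score",
            line_no[which(is.na(score))[1L]])
    }
    if (any(score > 1)) score <- score / 1000
    out$confidence <- score
  }
  out
}

#' Filter an edge list by interaction confidence
#'
#' High-confidence filtering as applied to public PPI databases, e.g. keeping
#' CPDB interactions with score strictly above 0.5 and STRING interactions at
#' or above 0.85.  The comparator is explicit per call because database
#' conventions read either way.
#'
#' @param edges Edge list from [read_edge_list()]; every record must carry a
#'   confidence.
#' @param threshold Confidence threshold in `[0, 1]`.
#' @param comparator `"strict"` keeps `confidence > threshold`; `"inclusive"`
#'   keeps `confidence >= threshold`.
#' @return The retained records, input order preserved.
#' @export
filter_by_confidence <- function(edges, threshold,
                                 comparator = c("strict", "inclusive")) {
  comparator <- match.arg(comparator)
  assert_that(!is.null(edges$confidence) && !anyNA(edges$confidence),
              "filter_by_confidence requires a confidence for every record")
  keep <- if (comparator == "strict") edges$confidence > threshold
          else edges$confidence >= threshold
  edges[keep, , drop = FALSE]
}

#' Build an undirected simple gene graph from an edge list
#'
#' Self-loops are dropped (a node's own representation enters the model
#' through the self/neighbor concatenation, not through an adjacency
#' self-edge), reversed and duplicate pairs are collapsed with the maximum
#' confidence kept, and nodes are ordered lexicographically.
#'
#' @param edges Edge list (`gene_a`, `gene_b`, optional `confidence`).
#' @param nodes Optional character vector of extra node symbols to include
#'   even if isolated (e.g. genes named only by self-loop rows are retained
#'   automatically).
#' @return A `gene_graph` object: ordered node symbols, a 2-column integer
#'   edge matrix (`i < j`), per-edge confidences (or `NULL`), and an
#'   adjacency list of integer neighbor indices.
#' @export
build_graph <- function(edges, nodes = NULL) {
  gene_a <- as.character(edges$gene_a)
  gene_b <- as.character(edges$gene_b)
  conf <- edges$confidence
  node_names <- sort(unique(c(gene_a, gene_b, nodes)))
  ia <- match(gene_a, node_names)
  ib <- match(gene_b, node_names)
  keep <- ia != ib
  ia <- ia[keep]
  ib <- ib[keep]
  if (!is.null(conf)) conf <- conf[keep]
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  key <- (lo - 1) * length(node_names) + hi
  if (!is.null(conf)) {
    o <- order(key, -conf)
    dup <- duplicated(key[o])
    lo <- lo[o][!dup]; hi <- hi[o][!dup]; conf <- conf[o][!dup]
  } else {
    dup <- duplicated(key)
    ord <- order(key[!dup])
    lo <- lo[!dup][ord]; hi <- hi[!dup][ord]
  }
  if (!is.null(conf)) {
    ord <- order(lo, hi)
    lo <- lo[ord]; hi <- hi[ord]; conf <- conf[ord]
  }
  new_gene_graph(node_names, cbind(lo, hi), conf)
}

new_gene_graph <- function(node_names, edge_mat, conf = NULL) {
  n <- length(node_names)
  edge_mat <- matrix(as.integer(edge_mat), ncol = 2)
  colnames(edge_mat) <- c("i", "j")
  adj <- build_adjacency(n, edge_mat)
  structure(list(nodes = node_names, edges = edge_mat,
                 confidence = conf, adj = adj),
            class = "gene_graph")
}

build_adjacency <- function(n, edge_mat) {
  adj <- vector("list", n)
  if (nrow(edge_mat) > 0) {
    ends <- c(edge_mat[, 1], edge_mat[, 2])
    nbrs <- c(edge_mat[, 2], edge_mat[, 1])
    adj_split <- split(nbrs, factor(ends, levels = seq_len(n)))
    adj <- lapply(adj_split, as.integer)
  } else {
    adj <- replicate(n, integer(0), simplify = FALSE)
  }
  unname(adj)
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$confidence)) "" else " (confidence-weighted)"))
  invisible(x)
}

#' Number of nodes / edges of a gene graph
#' @param graph A `gene_graph`.
#' @return Integer count.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Node degrees
#' @param graph A `gene_graph`.
#' @return Named integer vector of degrees, in node order.
#' @export
node_degrees <- function(graph) {
  setNames(vapply(graph$adj, length, integer(1)), graph$nodes)
}

#' Degree histogram of a gene graph
#'
#' Tabulates node degrees; counts sum to the node count and
#' `sum(degree * count)` equals twice the edge count.  Used to check the
#' heavy-tailed (scale-free-like) degree structure of PPI networks and its
#' loss under edge randomization.
#'
#' @param graph A `gene_graph`.
#' @return A `data.frame` with columns `degree` and `count`.
#' @export
degree_histogram <- function(graph) {
  deg <- vapply(graph$adj, length, integer(1))
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' Dump a gene graph as a sorted edge-list table
#'
#' Inverse of [build_graph()]: emits one row per edge with endpoints in
#' lexicographic order, suitable for [read_edge_list()] round-trips.
#'
#' @param graph A `gene_graph`.
#' @param path Optional file path; when given the table is written as TSV
#'   without header.
#' @return The edge `data.frame`, invisibly when `path` is given.
#' @export
graph_to_edge_list <- function(graph, path = NULL) {
  a <- graph$nodes[graph$edges[, 1]]
  b <- graph$nodes[graph$edges[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  if (!is.null(graph$confidence)) out$confidence <- graph$confidence
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Induce a subgraph on a node subset
#'
#' @param graph A `gene_graph`.
#' @param keep_nodes Character vector of node symbols to retain.
#' @return The induced `gene_graph` (edges with both endpoints retained).
#' @export
induce_subgraph <- function(graph, keep_nodes) {
  keep <- graph$nodes %in% keep_nodes
  new_names <- graph$nodes[keep]
  idx_map <- match(graph$nodes, new_names)
  e <- graph$edges
  ek <- keep[e[, 1]] & keep[e[, 2]]
  e2 <- cbind(idx_map[e[ek, 1]], idx_map[e[ek, 2]])
  conf <- if (is.null(graph$confidence)) NULL else graph$confidence[ek]
  lo <- pmin(e2[, 1], e2[, 2]); hi <- pmax(e2[, 1], e2[, 2])
  ord <- order(lo, hi)
  new_gene_graph(new_names, cbind(lo[ord], hi[ord]),
                 if (is.null(conf)) NULL else conf[ord])
}

#' Align graph, node features and labels into one dataset
#'
#' Restricts the analysis to in-network genes that carry feature rows: the
#' graph is induced on nodes having features, labels are restricted to the
#' surviving nodes, and genes without a label become unlabeled.  A short
#' report of counts dropped at each step is attached and printed.
#'
#' @param graph A `gene_graph`.
#' @param features A `feature_matrix` (see [apply_feature_transform()]) or a
#'   plain numeric matrix with gene rownames.
#' @param labels A `label_set` (see [assign_labels()]).
#' @param expression Optional raw expression matrix (genes x samples) kept
#'   alongside for scenarios that refit the feature transform.
#' @return An `aligned_dataset`: `graph`, `features` (matrix, rows in graph
#'   node order), `labels` (restricted `label_set`), optional `expression`,
#'   and a `report` of dropped counts.
#' @export
align_dataset <- function(graph, features, labels, expression = NULL) {
  fmat <- as_feature_rows(features)
  common <- intersect(graph$nodes, rownames(fmat))
  if (length(common) == 0L) {
    stopf("no overlap between graph nodes and feature genes")
  }
  dropped_features <- length(graph$nodes) - length(common)
  g2 <- induce_subgraph(graph, common)
  fmat <- fmat[g2$nodes, , drop = FALSE]
  lab2 <- restrict_labels(labels, g2$nodes)
  report <- c(
    sprintf("dropped %d genes lacking features", dropped_features),
    sprintf("dropped %d labeled genes outside the network",
            length(setdiff(c(labels$essential, labels$nonessential), g2$nodes)))
  )
  structure(list(graph = g2, features = fmat, labels = lab2,
                 expression = expression, report = report),
            class = "aligned_dataset")
}

as_feature_rows <- function(features) {
  if (inherits(features, "feature_matrix")) features <- features$vectors
  assert_that(is.matrix(features) && !is.null(rownames(features)),
              "features must be a matrix with gene rownames")
  features
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("aligned_dataset: %d nodes, %d edges, %d features/node\n",
              length(x$graph$nodes), nrow(x$graph$edges), ncol(x$features)))
  cat(sprintf("  labels: %d essential, %d nonessential, %d unlabeled\n",
              length(x$labels$essential), length(x$labels$nonessential),
              length(x$labels$unlabeled)))
  for (line in x$report) cat(" ", line, "\n")
  invisible(x)
}
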
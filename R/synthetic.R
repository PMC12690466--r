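# Synthetic data generators.
#
# Every other module is testable without downloads: these generators emit
# scale-free-like interaction networks (preferential attachment, mimicking
# PPI degree distributions), planted essential-gene labels optionally biased
# toward hubs, expression matrices with a class mean-shift plus one pass of
# neighbor smoothing (so both features and topology carry signal), and
# bimodal gene-effect screen matrices.  All outputs use the same file
# dialects the I/O modules read, and every generator is a pure function of
# its parameters + seed.

#' Synthetic study configuration
#'
#' Bundles the generator parameters of the reference experiment: a
#' 2,000-node, 10,000-edge scale-free network with 10% essential genes
#' preferentially placed on hubs (`hub_bias = 1`), a 100-sample expression
#' matrix with a 1.5-sd class mean shift and 0.3 neighbor-correlation
#' smoothing, and a 100-line gene-effect screen with unit class separation.
#'
#' @param n_nodes,n_edges Network size.
#' @param essential_fraction Fraction of nodes planted essential.
#' @param hub_bias Exponent of the degree bias when drawing essential genes.
#' @param n_samples Expression samples.
#' @param feature_effect_size Class mean shift in noise-sd units.
#' @param neighbor_correlation Weight of the neighbor-mean smoothing pass,
#'   in `[0, 1)`.
#' @param n_lines Cell lines in the gene-effect screen.
#' @param effect_separation Gap between essential and nonessential effect
#'   means (sd of both classes is 0.2).
#' @param seed Master seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_nodes = 2000L, n_edges = 10000L,
                             essential_fraction = 0.1, hub_bias = 1,
                             n_samples = 100L, feature_effect_size = 1.5,
                             neighbor_correlation = 0.3, n_lines = 100L,
                             effect_separation = 1.0, seed = 1L) {
  assert_that(essential_fraction > 0 && essential_fraction < 1,
              "essential_fraction must lie in (0, 1)")
  assert_that(neighbor_correlation >= 0 && neighbor_correlation < 1,
              "neighbor_correlation must lie in [0, 1)")
  assert_that(effect_separation > 0, "effect_separation must be positive")
  structure(list(n_nodes = as.integer(n_nodes),
                 n_edges = as.integer(n_edges),
                 essential_fraction = essential_fraction,
                 hub_bias = hub_bias, n_samples = as.integer(n_samples),
                 feature_effect_size = feature_effect_size,
                 neighbor_correlation = neighbor_correlation,
                 n_lines = as.integer(n_lines),
                 effect_separation = effect_separation,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

gene_names <- function(n) sprintf("G%06d", seq_len(n))

#' Generate a scale-free-like gene graph
#'
#' Preferential-attachment growth targeting `n_edges` edges in total: each
#' new node attaches to `m = round(n_edges / n_nodes)` distinct existing
#' nodes with probability proportional to degree; remaining edges are added
#' (or surplus edges removed) afterwards by degree-proportional endpoint
#' sampling, so the realized edge count equals the request exactly.
#'
#' @param n_nodes,n_edges Requested sizes; a simple graph of this size must
#'   be feasible and `n_edges >= n_nodes - 1`.
#' @param seed RNG seed.
#' @return A `gene_graph` with synthetic symbols `G000001`, ...
#' @export
generate_graph <- function(n_nodes, n_edges, seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  assert_that(n_edges >= n_nodes - 1,
              "n_edges must be at least n_nodes - 1 for connected growth")
  assert_that(n_edges <= n_nodes * (n_nodes - 1) / 2,
              "n_edges exceeds the simple-graph maximum")
  m <- max(1L, as.integer(round(n_edges / n_nodes)))
  m0 <- m + 1L
  assert_that(n_nodes > m0, "n_nodes too small for attachment count %d", m)
  with_seed(seed, {
    # endpoint multiset: sampling uniformly from it is degree-proportional
    ends <- integer(2L * (n_edges + m * m0))
    e_i <- integer(n_edges + m * m0)
    e_j <- integer(n_edges + m * m0)
    n_end <- 0L
    n_e <- 0L
    push_edge <- function(a, b) {
      n_e <<- n_e + 1L
      e_i[n_e] <<- min(a, b); e_j[n_e] <<- max(a, b)
      ends[n_end + 1L] <<- a; ends[n_end + 2L] <<- b
      n_end <<- n_end + 2L
    }
    for (v in seq_len(m0 - 1L)) push_edge(v, v + 1L)  # seed path
    for (v in seq(m0 + 1L, n_nodes)) {
      targets <- unique(ends[sample.int(n_end, min(3L * m, n_end),
                                        replace = TRUE)])
      while (length(targets) < m) {
        targets <- unique(c(targets, ends[sample.int(n_end, m,
                                                     replace = TRUE)]))
      }
      for (t in targets[seq_len(m)]) push_edge(v, t)
    }
    e_i <- e_i[seq_len(n_e)]; e_j <- e_j[seq_len(n_e)]
    key <- (e_i - 1) * n_nodes + e_j
    seen <- new.env(hash = TRUE, size = n_e * 2L)
    for (k in key) assign(as.character(k), TRUE, envir = seen)
    ends <- ends[seq_len(n_end)]
    # top up (or trim) to the exact edge count
    while (n_e < n_edges) {
      a <- ends[sample.int(length(ends), 1L)]
      b <- ends[sample.int(length(ends), 1L)]
      if (a == b) next
      kk <- as.character((min(a, b) - 1) * n_nodes + max(a, b))
      if (exists(kk, envir = seen, inherits = FALSE)) next
      assign(kk, TRUE, envir = seen)
      n_e <- n_e + 1L
      e_i <- c(e_i, min(a, b)); e_j <- c(e_j, max(a, b))
      ends <- c(ends, a, b)
    }
    if (n_e > n_edges) {
      drop <- sample.int(n_e, n_e - n_edges)
      e_i <- e_i[-drop]; e_j <- e_j[-drop]
    }
    ord <- order(e_i, e_j)
    new_gene_graph(gene_names(n_nodes), cbind(e_i[ord], e_j[ord]))
  })
}

#' Plant essential-gene labels on a graph
#'
#' Draws exactly `round(essential_fraction * n_nodes)` essential genes
#' without replacement with probability proportional to `degree^hub_bias`
#' (`hub_bias = 0` gives uniform sampling; positive values bias toward
#' hubs, echoing the enrichment of essential genes among highly connected
#' proteins).  The remainder is nonessential; no genes are left unlabeled.
#'
#' @param graph A `gene_graph`.
#' @param essential_fraction Fraction in `(0, 1)`.
#' @param hub_bias Nonnegative degree-bias exponent.
#' @param seed RNG seed.
#' @return A `label_set`.
#' @export
plant_labels <- function(graph, essential_fraction, hub_bias = 0,
                         seed = 1L) {
  assert_that(essential_fraction > 0 && essential_fraction < 1,
              "essential_fraction must lie in (0, 1)")
  n <- length(graph$nodes)
  n_ess <- round(essential_fraction * n)
  deg <- vapply(graph$adj, length, integer(1))
  w <- pmax(deg, 0)^hub_bias
  if (hub_bias == 0) w <- rep(1, n)
  ess_idx <- with_seed(seed, sample.int(n, n_ess, prob = w))
  assign_labels(universe = graph$nodes,
                common = graph$nodes[ess_idx])
}

#' Generate an expression matrix with planted class signal
#'
#' Per gene and sample, a latent signal equal to the class mean shift
#' (essential genes shifted by `feature_effect_size` noise-sd units) plus
#' standard normal noise; one neighbor-averaging pass blends each gene's
#' signal with the mean of its neighbors' (weight `neighbor_correlation`),
#' so network structure leaks into the features; the result is mapped to
#' nonnegative FPKM-like values as `2^(signal + 5)`.
#'
#' @param graph A `gene_graph`.
#' @param labels A `label_set` over the graph's nodes.
#' @param n_samples Number of samples (columns).
#' @param feature_effect_size Class mean shift in sd units.
#' @param neighbor_correlation Smoothing weight in `[0, 1)`.
#' @param seed RNG seed.
#' @return Nonnegative numeric matrix genes x samples.
#' @export
generate_expression <- function(graph, labels, n_samples = 100L,
                                feature_effect_size = 1.5,
                                neighbor_correlation = 0.3, seed = 1L) {
  n <- length(graph$nodes)
  mu <- ifelse(graph$nodes %in% labels$essential, feature_effect_size, 0)
  with_seed(seed, {
    S <- matrix(rnorm(n * n_samples), n, n_samples) + mu
    if (neighbor_correlation > 0 && nrow(graph$edges) > 0) {
      A <- Matrix::sparseMatrix(i = c(graph$edges[, 1], graph$edges[, 2]),
                                j = c(graph$edges[, 2], graph$edges[, 1]),
                                x = 1, dims = c(n, n))
      deg <- vapply(graph$adj, length, integer(1))
      nbr_mean <- as.matrix(A %*% S) / pmax(deg, 1L)
      has_nbr <- deg > 0
      S[has_nbr, ] <- (1 - neighbor_correlation) * S[has_nbr, ] +
        neighbor_correlation * nbr_mean[has_nbr, ]
    }
    expr <- 2^(S + 5)
    dimnames(expr) <- list(graph$nodes,
                           sprintf("S%04d", seq_len(n_samples)))
    expr
  })
}

#' Generate a bimodal gene-effect screen matrix
#'
#' Essential genes draw viability effects from
#' `N(-effect_separation, 0.2^2)` and all others from `N(0, 0.2^2)`,
#' independently per cell line, yielding the bimodal rank-summary
#' distribution the KDE-valley labeler expects.
#'
#' @param labels A `label_set` defining the gene universe and classes.
#' @param n_lines Number of cell lines.
#' @param effect_separation Gap between class means (> 0).
#' @param seed RNG seed.
#' @return Numeric matrix genes x lines (rownames = genes, sorted).
#' @export
generate_gene_effects <- function(labels, n_lines = 100L,
                                  effect_separation = 1.0, seed = 1L) {
  assert_that(effect_separation > 0, "effect_separation must be positive")
  genes <- sort(c(labels$essential, labels$nonessential, labels$unlabeled))
  mu <- ifelse(genes %in% labels$essential, -effect_separation, 0)
  with_seed(seed, {
    eff <- matrix(rnorm(length(genes) * n_lines, sd = 0.2),
                  length(genes), n_lines) + mu
    dimnames(eff) <- list(genes, sprintf("L%04d", seq_len(n_lines)))
    eff
  })
}

#' Generate the network scaling grid
#'
#' The full grid of preferential-attachment networks across the requested
#' node and edge counts (default: 5 node counts x 9 edge counts = 45
#' networks), written as edge-list TSVs in the dialect [read_edge_list()]
#' consumes, with a manifest of requested versus realized sizes.
#' Infeasible pairs are skipped with a warning.
#'
#' @param node_counts Node counts (default 10,000 to 30,000 by 5,000).
#' @param edge_counts Edge counts (default 200,000 to 1,800,000 by
#'   200,000).
#' @param dir Output directory for the edge-list files (default: no files
#'   written).
#' @param seed Master seed.
#' @return Manifest data.frame: requested/realized node and edge counts,
#'   file path (NA when not written).
#' @export
generate_scaling_suite <- function(node_counts = seq(10000L, 30000L, 5000L),
                                   edge_counts = seq(200000L, 1800000L,
                                                     200000L),
                                   dir = NULL, seed = 1L) {
  grid <- expand.grid(n_nodes = node_counts, n_edges = edge_counts)
  seeds <- seed_stream(seed, nrow(grid))
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    nn <- grid$n_nodes[i]
    ne <- grid$n_edges[i]
    feasible <- ne >= nn - 1 && ne <= nn * (nn - 1) / 2 &&
      nn > round(ne / nn) + 1
    if (!feasible) {
      warning(sprintf("skipping infeasible grid point (%d nodes, %d edges)",
                      nn, ne), call. = FALSE)
      next
    }
    g <- generate_graph(nn, ne, seed = seeds[i])
    path <- NA_character_
    if (!is.null(dir)) {
      path <- file.path(dir, sprintf("net_n%d_e%d.tsv", nn, ne))
      graph_to_edge_list(g, path)
    }
    rows[[i]] <- data.frame(n_nodes_requested = nn, n_edges_requested = ne,
                            n_nodes = length(g$nodes),
                            n_edges = nrow(g$edges), path = path)
  }
  do.call(rbind, rows)
}

#' Generate the full reference dataset
#'
#' Chains the generators into one aligned dataset at the configured study
#' conditions: graph, planted labels, expression with class signal,
#' log2-normalized PCA min-max features, and the raw expression matrix kept
#' for transform-refitting scenarios.
#'
#' @param config A `synthetic_config`.
#' @param n_components Principal components for the node features (default
#'   50, capped at the sample count).
#' @return An `aligned_dataset` with attached `expression`; the planted
#'   `label_set` is in `$labels`.
#' @export
make_reference_dataset <- function(config = synthetic_config(),
                                   n_components = 50L) {
  seeds <- seed_stream(config$seed, 3L)
  graph <- generate_graph(config$n_nodes, config$n_edges, seed = seeds[1])
  labels <- plant_labels(graph, config$essential_fraction,
                         hub_bias = config$hub_bias, seed = seeds[2])
  expr <- generate_expression(graph, labels, config$n_samples,
                              config$feature_effect_size,
                              config$neighbor_correlation, seed = seeds[3])
  n_components <- min(n_components, config$n_samples)
  norm <- normalize_expression(expr)
  transform <- fit_feature_transform(norm, n_components = n_components)
  feats <- apply_feature_transform(transform, norm)
  align_dataset(graph, feats, labels, expression = expr)
}
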
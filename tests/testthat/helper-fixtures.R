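# Shared fixture builders: everything is generated in code at test time.

# Graph from a plain character edge matrix/pairs, e.g. g(c("A","B", "B","C")).
tiny_graph <- function(pairs, confidence = NULL, nodes = NULL) {
  m <- matrix(pairs, ncol = 2, byrow = TRUE)
  el <- data.frame(gene_a = m[, 1], gene_b = m[, 2],
                   stringsAsFactors = FALSE)
  if (!is.null(confidence)) el$confidence <- confidence
  build_graph(el, nodes = nodes)
}

# Random simple graph on n nodes with ~p edge density (Erdos-Renyi style),
# used where any small graph will do.
random_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  names <- sprintf("N%03d", seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  el <- data.frame(gene_a = names[pairs[keep, 1]],
                   gene_b = names[pairs[keep, 2]])
  build_graph(el, nodes = names)
}

# Feature matrix with given dimension for a graph's nodes.
random_features <- function(graph, d = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(length(graph$nodes) * d), length(graph$nodes), d)
  rownames(X) <- graph$nodes
  X
}

# A small aligned dataset with planted feature signal for fast training
# tests: essential nodes get a mean shift on every feature.
small_signal_dataset <- function(n = 120, d = 4, frac = 0.25,
                                 effect = 3, seed = 1) {
  g <- random_graph(n, p = 0.05, seed = seed)
  set.seed(seed + 1)
  ess <- sort(sample(g$nodes, round(frac * n)))
  labels <- assign_labels(g$nodes, ess)
  X <- random_features(g, d = d, seed = seed + 2)
  X[labels$essential, ] <- X[labels$essential, ] + effect
  align_dataset(g, X, labels)
}

# Independent brute-force metric oracles (kept deliberately naive).
brute_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  rec <- 0
  area <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    r <- tp / sum(labels == 1)
    area <- area + (r - rec) * prec
    rec <- r
  }
  area
}

brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

brute_youden <- function(scores, labels) {
  thr <- sort(unique(scores))
  best <- -Inf
  best_t <- NA
  for (t in thr) {
    tpr <- sum(scores >= t & labels == 1) / sum(labels == 1)
    fpr <- sum(scores >= t & labels == 0) / sum(labels == 0)
    if (tpr - fpr > best + 1e-12) {
      best <- tpr - fpr
      best_t <- t
    }
  }
  list(threshold = best_t, J = best)
}

# Dense, sampling-free evaluation of the aggregation recursion: for every
# node, h^k = relu(W_k [h^{k-1}; mean of ALL neighbors' h^{k-1}]), then the
# linear output head.  Independent of the package's batched/sampled path.
dense_forward <- function(params, graph, X, targets) {
  n <- length(graph$nodes)
  H <- X[graph$nodes, , drop = FALSE]
  for (k in seq_along(params$layer_weights)) {
    W <- params$layer_weights[[k]]
    Hnew <- matrix(0, n, ncol(W))
    for (v in seq_len(n)) {
      nb <- graph$adj[[v]]
      nbr <- if (length(nb) > 0) colMeans(H[nb, , drop = FALSE])
             else numeric(ncol(H))
      Hnew[v, ] <- pmax(as.vector(c(H[v, ], nbr) %*% W), 0)
    }
    H <- Hnew
  }
  idx <- match(targets, graph$nodes)
  as.vector(H[idx, , drop = FALSE] %*% params$output_weight) +
    params$output_bias
}
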
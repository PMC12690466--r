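# Controlled corruption of network structure and node features, used to ask
# how much of the classifier's performance rests on topology versus
# expression signal.  Edge perturbation replaces a chosen fraction of edges
# with uniform random vertex pairs (driving the degree distribution away
# from scale-free); feature perturbation swaps feature vectors between
# random node pairs (preserving the row multiset while destroying the
# feature-label association).

#' Randomly replace a fraction of graph edges
#'
#' Selects `round(fraction * n_edges)` edges uniformly and replaces each
#' with an edge between two vertices drawn uniformly from the node set,
#' rejecting self-loops and duplicate edges.  Node and edge counts are
#' preserved exactly.
#'
#' @param graph A `gene_graph`.
#' @param fraction Fraction of edges to replace, in `[0, 1]`.
#' @param seed RNG seed.
#' @param rewire_one_endpoint Replace only one endpoint of each selected
#'   edge instead of redrawing both (default `FALSE`; the full-replacement
#'   reading).
#' @param max_attempts Rejection-sampling cap per replacement edge.
#' @return The perturbed `gene_graph` (confidences dropped).
#' @export
perturb_edges <- function(graph, fraction, seed = 1L,
                          rewire_one_endpoint = FALSE,
                          max_attempts = 1000L) {
  assert_that(fraction >= 0 && fraction <= 1, "fraction must lie in [0, 1]")
  m <- nrow(graph$edges)
  n <- length(graph$nodes)
  n_swap <- round(fraction * m)
  if (n_swap == 0L) return(graph)
  with_seed(seed, {
    e <- graph$edges
    key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
    existing <- new.env(hash = TRUE, size = m * 2L)
    for (k in seq_len(m)) assign(as.character(key(e[k, 1], e[k, 2])), TRUE,
                                 envir = existing)
    chosen <- sample.int(m, n_swap)
    for (k in chosen) {
      rm(list = as.character(key(e[k, 1], e[k, 2])), envir = existing)
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        if (rewire_one_endpoint) {
          keep_end <- if (runif(1) < 0.5) e[k, 1] else e[k, 2]
          cand <- c(keep_end, sample.int(n, 1L))
        } else {
          cand <- sample.int(n, 2L, replace = TRUE)
        }
        if (cand[1] == cand[2]) next
        ck <- as.character(key(cand[1], cand[2]))
        if (exists(ck, envir = existing, inherits = FALSE)) next
        e[k, ] <- c(min(cand), max(cand))
        assign(ck, TRUE, envir = existing)
        placed <- TRUE
        break
      }
      if (!placed) {
        stopf("could not place a replacement edge after %d attempts",
              max_attempts)
      }
    }
    ord <- order(e[, 1], e[, 2])
    new_gene_graph(graph$nodes, e[ord, , drop = FALSE])
  })
}

#' Swap feature vectors between random node pairs
#'
#' Selects `round(fraction * n_nodes)` nodes (rounded down to an even
#' count), pairs them at random, and exchanges the feature vectors within
#' each pair.  The multiset of feature rows is preserved exactly.
#'
#' @param features Numeric matrix with gene rownames, or a
#'   `feature_matrix`.
#' @param fraction Fraction of nodes involved in swaps, in `[0, 1]`.
#' @param seed RNG seed.
#' @return Matrix of the same shape and rownames with rows swapped.
#' @export
perturb_features <- function(features, fraction, seed = 1L) {
  assert_that(fraction >= 0 && fraction <= 1, "fraction must lie in [0, 1]")
  fmat <- as_feature_rows(features)
  n <- nrow(fmat)
  n_pick <- round(fraction * n)
  n_pick <- n_pick - (n_pick %% 2L)
  if (n_pick < 2L) return(fmat)
  with_seed(seed, {
    picked <- sample.int(n, n_pick)
    a <- picked[seq_len(n_pick / 2L)]
    b <- picked[n_pick / 2L + seq_len(n_pick / 2L)]
    out <- fmat
    out[a, ] <- fmat[b, , drop = FALSE]
    out[b, ] <- fmat[a, , drop = FALSE]
    rownames(out) <- rownames(fmat)
    out
  })
}

#' Perturb both edges and features of a dataset
#'
#' Composition of [perturb_edges()] and [perturb_features()] with
#' independent random substreams derived from one seed.
#'
#' @param dataset An `aligned_dataset`.
#' @param edge_fraction,feature_fraction Fractions in `[0, 1]`.
#' @param seed Master seed.
#' @return The perturbed `aligned_dataset`.
#' @export
perturb_both <- function(dataset, edge_fraction, feature_fraction,
                         seed = 1L) {
  subseeds <- seed_stream(seed, 2L)
  g <- perturb_edges(dataset$graph, edge_fraction, seed = subseeds[1])
  f <- perturb_features(dataset$features, feature_fraction,
                        seed = subseeds[2])
  out <- dataset
  out$graph <- g
  out$features <- f
  out
}

#' Perturbation scan harness
#'
#' For every mode x fraction x repeat, perturbs the dataset and runs
#' cross-validated evaluation, emitting long-format results for degradation
#' curves.  The perturbation is applied once per repeat, before the CV
#' split.
#'
#' @param dataset An `aligned_dataset`.
#' @param config A `model_config`.
#' @param fractions Perturbation fractions (default 0, 0.25, 0.5, 0.75, 1).
#' @param modes Subset of `c("edges", "features", "both")`.
#' @param repeats Repeats per mode x fraction (default 10).
#' @param k CV folds per repeat (default 5).
#' @param ratio Negative subsampling ratio.
#' @param seed Master seed.
#' @param scorer Scoring backend, see [run_cross_validation()].
#' @return Long-format data.frame: mode, fraction, repeat_index, fold,
#'   auprc, auroc, seed.
#' @export
perturbation_scan <- function(dataset, config,
                              fractions = c(0, 0.25, 0.5, 0.75, 1),
                              modes = c("edges", "features", "both"),
                              repeats = 10L, k = 5L, ratio = 4, seed = 1L,
                              scorer = sage_scorer) {
  modes <- match.arg(modes, several.ok = TRUE)
  grid <- expand.grid(mode = modes, fraction = fractions,
                      repeat_index = seq_len(repeats),
                      stringsAsFactors = FALSE)
  seeds <- seed_stream(seed, nrow(grid))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mode <- grid$mode[i]
    fr <- grid$fraction[i]
    pert <- switch(mode,
      edges = {
        d <- dataset
        d$graph <- perturb_edges(dataset$graph, fr, seed = seeds[i])
        d
      },
      features = {
        d <- dataset
        d$features <- perturb_features(dataset$features, fr,
                                       seed = seeds[i])
        d
      },
      both = perturb_both(dataset, fr, fr, seed = seeds[i]))
    res <- run_cross_validation(pert, config, k = k, repeats = 1L,
                                ratio = ratio,
                                seed = (seeds[i] + 1) %% 2147483647,
                                scorer = scorer)
    f <- res$folds
    out[[i]] <- data.frame(mode = mode, fraction = fr,
                           repeat_index = grid$repeat_index[i],
                           fold = f$fold, auprc = f$auprc,
                           auroc = f$auroc, seed = seeds[i])
  }
  do.call(rbind, out)
}
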
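# Class-imbalance-aware benchmarking.
#
# Essential genes are rare, so the candidate pool is rebalanced to a fixed
# nonessential:essential ratio (default 4:1) before cross-validation and the
# ratio is enforced in training, validation and test alike.  A random
# classifier therefore has AUPRC equal to the pooled prevalence, 1/5 = 0.2 --
# keep that baseline in mind when reading AUPRC values.

#' Subsample nonessential genes to a fixed class ratio
#'
#' Keeps every essential gene and draws `round(ratio * n_essential)`
#' nonessential genes uniformly without replacement; when fewer are
#' available all are taken with a warning.
#'
#' @param labels A `label_set`.
#' @param ratio Nonessential:essential ratio (default 4).
#' @param seed RNG seed.
#' @return List with `nodes` (the pooled gene symbols), `positive` and
#'   `negative` subsets.
#' @export
subsample_negatives <- function(labels, ratio = 4, seed = 1L) {
  pos <- labels$essential
  if (length(pos) == 0L) stopf("no essential genes to anchor the pool")
  n_neg <- round(ratio * length(pos))
  neg_all <- labels$nonessential
  if (length(neg_all) < n_neg) {
    warning(sprintf("only %d nonessential genes available for a %d:1 pool",
                    length(neg_all), ratio), call. = FALSE)
    neg <- neg_all
  } else {
    neg <- with_seed(seed, sort(sample(neg_all, n_neg)))
  }
  list(nodes = c(pos, neg), positive = pos, negative = neg)
}

#' Stratified repeated cross-validation splits
#'
#' Stratified k-fold test partition of the pool; within each fold a
#' stratified `val_fraction` of the non-test remainder is held out for
#' validation (the 80/20 train/test split with 10% of the training side for
#' validation).
#'
#' @param pool List from [subsample_negatives()] (or any list with
#'   `positive`/`negative` character vectors).
#' @param k Number of folds (default 5).
#' @param val_fraction Fraction of the non-test pool held out for
#'   validation (default 0.1).
#' @param seed RNG seed.
#' @return A `split_spec`: list of `k` folds, each with disjoint `train`,
#'   `val`, `test` character vectors; test sets partition the pool.
#' @export
make_cv_splits <- function(pool, k = 5L, val_fraction = 0.1, seed = 1L) {
  pos <- pool$positive
  neg <- pool$negative
  if (length(pos) < k || length(neg) < k) {
    stopf("each class needs at least k = %d members", k)
  }
  with_seed(seed, {
    fold_of <- function(x) {
      x <- sample(x)
      split(x, rep_len(seq_len(k), length(x)))
    }
    pos_folds <- fold_of(pos)
    neg_folds <- fold_of(neg)
    folds <- lapply(seq_len(k), function(i) {
      test <- c(pos_folds[[i]], neg_folds[[i]])
      rest_pos <- unlist(pos_folds[-i], use.names = FALSE)
      rest_neg <- unlist(neg_folds[-i], use.names = FALSE)
      n_vp <- max(if (length(rest_pos) > 1) 1L else 0L,
                  round(val_fraction * length(rest_pos)))
      n_vn <- max(if (length(rest_neg) > 1) 1L else 0L,
                  round(val_fraction * length(rest_neg)))
      val <- c(sample(rest_pos, n_vp), sample(rest_neg, n_vn))
      train <- setdiff(c(rest_pos, rest_neg), val)
      list(train = train, val = val, test = test)
    })
    structure(list(folds = folds, k = k, val_fraction = val_fraction,
                   seed = seed),
              class = "split_spec")
  })
}

check_two_class <- function(labels) {
  if (length(unique(labels)) < 2L) {
    stopf("both classes must be present")
  }
}

# Precision-recall coordinates at every distinct-score threshold, scores
# descending; tied scores form one threshold group.
pr_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- which(grp != c(grp[-1], -1))
  tp <- tp[last]; fp <- fp[last]
  P <- sum(labels)
  data.frame(threshold = s[last], recall = tp / P,
             precision = tp / (tp + fp))
}

#' Area under the precision-recall curve
#'
#' Step-area convention: the sum over descending-score threshold groups of
#' (increase in recall) x (precision at that threshold), with no linear
#' interpolation between PR points (interpolated PR overestimates the
#' area).  The baseline for a random ranking equals the positive prevalence.
#'
#' @param scores Numeric scores, higher = more essential.
#' @param labels 0/1 labels.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  check_two_class(labels)
  pts <- pr_points(scores, labels)
  drecall <- diff(c(0, pts$recall))
  sum(drecall * pts$precision)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic with midrank tie
#' handling: the probability that a random positive outscores a random
#' negative (ties count one half).
#'
#' @inheritParams auprc
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_two_class(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#' @inheritParams auprc
#' @return data.frame with `threshold`, `tpr`, `fpr` at every distinct score
#'   (classification rule: positive when `score >= threshold`).
#' @export
roc_points <- function(scores, labels) {
  check_two_class(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(labels == 1 & scores >= t) / P,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(labels == 0 & scores >= t) / N,
                numeric(1))
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

#' Youden's J optimal cutoff
#'
#' Scans every distinct score value as a candidate threshold (positive call
#' when `score >= threshold`) and returns the threshold maximizing
#' J = TPR - FPR, the balanced sensitivity/specificity trade-off point of
#' the ROC curve.  Among tied maximizers the smallest threshold is returned.
#'
#' @inheritParams auprc
#' @return List with `threshold` and `J`.
#' @export
youden_cutoff <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  J <- pts$tpr - pts$fpr
  best <- which(J >= max(J) - 1e-12)   # numerical ties count as ties
  pick <- best[which.min(pts$threshold[best])]
  list(threshold = pts$threshold[pick], J = max(J))
}

# Default scorer: train the sample-and-aggregate model on the fold and
# score its test nodes.  A scorer is any function with this signature, so
# oracle or baseline scorers can be dropped into the same CV harness.
sage_scorer <- function(dataset, train_nodes, val_nodes, test_nodes,
                        config, seed, track_nodes = FALSE) {
  cfg <- config
  cfg$seed <- seed
  fit <- train_model(dataset, train_nodes, val_nodes, cfg,
                     track_nodes = track_nodes)
  scores <- predict_scores(fit$params, dataset$graph, dataset$features,
                           test_nodes, cfg, seed = seed)
  list(scores = scores, touched_nodes = fit$touched_nodes)
}

#' Repeated stratified cross-validation of the classifier
#'
#' For each repeat: rebuild the 4:1 candidate pool, split it into stratified
#' folds, train per fold with the test labels masked, and score the test
#' fold.  Fold-level AUPRC/AUROC are aggregated as mean and sd.
#'
#' @param dataset An `aligned_dataset`.
#' @param config A `model_config`.
#' @param k Folds per repeat (default 5).
#' @param repeats Number of repeats (default 10).
#' @param ratio Negative subsampling ratio (default 4).
#' @param seed Master seed; all repeats derive sub-seeds from it.
#' @param scorer Scoring backend (default: train the model); signature
#'   `(dataset, train_nodes, val_nodes, test_nodes, config, seed)`
#'   returning `list(scores = named numeric)`.
#' @return An `eval_result`: `folds` data.frame (repeat, fold, auprc,
#'   auroc), `summary` (means and sds), and `scores` (pooled per-gene test
#'   scores with labels).
#' @export
run_cross_validation <- function(dataset, config, k = 5L, repeats = 10L,
                                 ratio = 4, seed = 1L, scorer = sage_scorer) {
  seeds <- seed_stream(seed, 2L * repeats)
  rows <- list()
  score_tab <- list()
  for (r in seq_len(repeats)) {
    pool <- subsample_negatives(dataset$labels, ratio = ratio,
                                seed = seeds[2L * r - 1L])
    splits <- make_cv_splits(pool, k = k, seed = seeds[2L * r])
    for (f in seq_len(k)) {
      fold <- splits$folds[[f]]
      fold_seed <- (seeds[2L * r] + f) %% 2147483647
      sc <- scorer(dataset, fold$train, fold$val, fold$test, config,
                   seed = fold_seed)
      y <- as.numeric(fold$test %in% dataset$labels$essential)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_index = r, fold = f,
                   auprc = auprc(sc$scores, y), auroc = auroc(sc$scores, y))
      score_tab[[length(score_tab) + 1L]] <-
        data.frame(gene = fold$test, score = unname(sc$scores), label = y,
                   repeat_index = r, fold = f)
    }
  }
  folds <- do.call(rbind, rows)
  new_eval_result(folds, do.call(rbind, score_tab),
                  config = config, seed = seed)
}

new_eval_result <- function(folds, scores, config, seed, extra = list()) {
  res <- c(list(folds = folds,
                summary = data.frame(
                  metric = c("auprc", "auroc"),
                  mean = c(mean(folds$auprc), mean(folds$auroc)),
                  sd = c(stats::sd(folds$auprc), stats::sd(folds$auroc))),
                scores = scores, config = config, seed = seed),
           extra)
  structure(res, class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result over %d fold evaluations:\n", nrow(x$folds)))
  cat(sprintf("  AUPRC %.3f +/- %.3f   AUROC %.3f +/- %.3f\n",
              x$summary$mean[1], x$summary$sd[1],
              x$summary$mean[2], x$summary$sd[2]))
  if (!is.null(x$scenario)) cat("  scenario:", x$scenario, "\n")
  invisible(x)
}

#' Unseen-gene evaluation scenarios
#'
#' Four feature-exposure regimes quantifying how much test-gene information
#' the training stage may use:
#' * `mask-labels-only` -- standard CV: full graph and features, only the
#'   test labels hidden (the transductive upper bound).
#' * `drop-test-from-graph` -- test nodes deleted from the training graph;
#'   the feature transform still fitted on all genes.
#' * `pca-train-only` -- full graph, but the PCA transform fitted only on
#'   non-test genes and then used to project everyone.
#' * `drop-test-completely` -- both restrictions: the model never sees test
#'   nodes in any form; they re-enter only at scoring time, projected with
#'   the train-fitted transform on the full graph.
#'
#' Scenarios other than `mask-labels-only` refit the feature transform per
#' fold from the dataset's raw expression matrix.
#'
#' @inheritParams run_cross_validation
#' @param scenario One of the four scenario names above.
#' @param normalize Normalization passed to [normalize_expression()] before
#'   the per-fold PCA refit.
#' @param track_nodes Record, per fold, which node symbols entered any
#'   training computation graph (isolation proof for the drop scenarios).
#' @return An `eval_result` with extra fields `scenario` and (when tracked)
#'   `isolation` (per-fold count of test nodes that leaked into training
#'   computation graphs; all zero in the drop scenarios).
#' @export
run_unseen_scenarios <- function(dataset, config, scenario, k = 5L,
                                 repeats = 10L, ratio = 4, seed = 1L,
                                 normalize = "log2", track_nodes = FALSE) {
  scenarios <- c("mask-labels-only", "drop-test-from-graph",
                 "pca-train-only", "drop-test-completely")
  if (!scenario %in% scenarios) {
    stopf("unknown scenario '%s'; choose one of: %s", scenario,
          paste(scenarios, collapse = ", "))
  }
  if (scenario == "mask-labels-only") {
    res <- run_cross_validation(dataset, config, k = k, repeats = repeats,
                                ratio = ratio, seed = seed)
    res$scenario <- scenario
    return(res)
  }
  assert_that(!is.null(dataset$expression),
              "scenario '%s' needs the raw expression matrix in the dataset",
              scenario)
  expr <- normalize_expression(dataset$expression, method = normalize)
  graph <- dataset$graph
  n_comp <- config$input_dim
  drop_graph <- scenario %in% c("drop-test-from-graph",
                                "drop-test-completely")
  fit_train_only <- scenario %in% c("pca-train-only",
                                    "drop-test-completely")

  seeds <- seed_stream(seed, 2L * repeats)
  rows <- list()
  score_tab <- list()
  leaks <- integer(0)
  for (r in seq_len(repeats)) {
    pool <- subsample_negatives(dataset$labels, ratio = ratio,
                                seed = seeds[2L * r - 1L])
    splits <- make_cv_splits(pool, k = k, seed = seeds[2L * r])
    for (f in seq_len(k)) {
      fold <- splits$folds[[f]]
      fold_seed <- (seeds[2L * r] + f) %% 2147483647
      train_graph <- if (drop_graph) {
        induce_subgraph(graph, setdiff(graph$nodes, fold$test))
      } else graph
      fit_genes <- if (fit_train_only) {
        setdiff(graph$nodes, fold$test)
      } else graph$nodes
      transform <- fit_feature_transform(expr, n_components = n_comp,
                                         fit_genes = fit_genes)
      train_feats <- apply_feature_transform(transform, expr,
                                             train_graph$nodes)
      train_ds <- structure(list(graph = train_graph,
                                 features = train_feats$vectors,
                                 labels = dataset$labels),
                            class = "aligned_dataset")
      cfg <- config
      cfg$seed <- fold_seed
      fit <- train_model(train_ds, fold$train, fold$val, cfg,
                         track_nodes = track_nodes)
      # scoring always on the full graph with everyone projected
      full_feats <- apply_feature_transform(transform, expr, graph$nodes)
      scores <- predict_scores(fit$params, graph, full_feats$vectors,
                               fold$test, cfg, seed = fold_seed)
      if (track_nodes) {
        leaks <- c(leaks, length(intersect(fit$touched_nodes, fold$test)))
      }
      y <- as.numeric(fold$test %in% dataset$labels$essential)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_index = r, fold = f,
                   auprc = auprc(scores, y), auroc = auroc(scores, y))
      score_tab[[length(score_tab) + 1L]] <-
        data.frame(gene = fold$test, score = unname(scores), label = y,
                   repeat_index = r, fold = f)
    }
  }
  folds <- do.call(rbind, rows)
  new_eval_result(folds, do.call(rbind, score_tab), config = config,
                  seed = seed,
                  extra = list(scenario = scenario,
                               isolation = if (track_nodes) leaks else NULL))
}

#' Write an evaluation result to disk
#'
#' JSON with per-fold metrics, summary, config echo and seed, plus a
#' per-gene score TSV and ROC/PR coordinate CSVs for plotting.
#'
#' @param result An `eval_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_eval_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(summary = result$summary, folds = result$folds,
               scenario = result$scenario %||% "standard-cv",
               seed = result$seed, config = unclass(result$config))
  p_json <- file.path(dir, "metrics.json")
  jsonlite::write_json(meta, p_json, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  p_scores <- file.path(dir, "scores.tsv")
  write.table(result$scores, p_scores, sep = "\t", quote = FALSE,
              row.names = FALSE)
  y <- result$scores$label
  s <- result$scores$score
  p_roc <- file.path(dir, "roc_curve.csv")
  p_pr <- file.path(dir, "pr_curve.csv")
  write.table(roc_points(s, y), p_roc, sep = ",", quote = FALSE,
              row.names = FALSE)
  write.table(pr_points(s, y), p_pr, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(c(p_json, p_scores, p_roc, p_pr))
}
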
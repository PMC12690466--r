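# An oracle scorer that never trains: scores are the true labels plus tiny
# jitter, giving perfect ranking cheaply.  Used for harness bookkeeping
# tests where model quality is irrelevant.
label_oracle_scorer <- function(dataset, train_nodes, val_nodes, test_nodes,
                                config, seed, ...) {
  y <- as.numeric(test_nodes %in% dataset$labels$essential)
  set.seed(seed)
  list(scores = setNames(y + runif(length(y), 0, 1e-6), test_nodes))
}

test_that("negative subsampling builds an exact 4:1 pool", {
  labels <- assign_labels(sprintf("G%04d", 1:10100),
                          common = sprintf("G%04d", 1:100))
  pool <- subsample_negatives(labels, ratio = 4, seed = 1)
  expect_length(pool$positive, 100)
  expect_length(pool$negative, 400)
  expect_length(pool$nodes, 500)
  expect_identical(pool, subsample_negatives(labels, ratio = 4, seed = 1))
  expect_false(identical(pool$negative,
                         subsample_negatives(labels, 4, seed = 2)$negative))

  # insufficiency: take all with a warning
  small <- assign_labels(sprintf("G%03d", 1:400),
                         common = sprintf("G%03d", 1:100))
  expect_warning(p2 <- subsample_negatives(small, ratio = 4, seed = 1),
                 "only 300")
  expect_length(p2$negative, 300)

  none <- assign_labels(c("A", "B"), common = character(0))
  expect_error(subsample_negatives(none), "no essential")
})

test_that("CV splits are stratified partitions with validation held out", {
  labels <- assign_labels(sprintf("G%04d", 1:2100),
                          common = sprintf("G%04d", 1:100))
  pool <- subsample_negatives(labels, ratio = 4, seed = 3)
  sp <- make_cv_splits(pool, k = 5, seed = 4)
  test_sets <- lapply(sp$folds, `[[`, "test")
  expect_setequal(unlist(test_sets), pool$nodes)
  expect_equal(sum(lengths(test_sets)), length(pool$nodes))
  for (f in sp$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_length(intersect(f$train, f$val), 0)
    # stratification: each test fold holds ~1/5 of each class
    expect_equal(sum(f$test %in% pool$positive), 20)
    expect_equal(sum(f$test %in% pool$negative), 80)
    # validation is ~10% of the non-test pool
    expect_equal(length(f$val), round(0.1 * 320) + round(0.1 * 80))
  }
  expect_error(make_cv_splits(list(positive = c("A", "B"),
                                   negative = sprintf("N%d", 1:10)),
                              k = 5), "at least k")
})

test_that("ranking metrics match brute-force oracles on random draws", {
  # hand cases first
  expect_equal(auprc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auroc(c(0.1, 0.9), c(1, 0)), 0.0)
  yd <- youden_cutoff(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(yd$J, 1)
  expect_equal(yd$threshold, 0.8)
  expect_error(auprc(c(0.2, 0.3), c(1, 1)), "both classes")
  expect_error(youden_cutoff(c(0.2, 0.3), c(1, 1)), "both classes")

  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    s <- if (runif(1) < 0.5) runif(n) else sample(seq(0, 1, 0.1), n, TRUE)
    expect_equal(auprc(s, y), brute_auprc(s, y), tolerance = 1e-12)
    expect_equal(auroc(s, y), brute_auroc(s, y), tolerance = 1e-12)
    bj <- brute_youden(s, y)
    j <- youden_cutoff(s, y)
    expect_equal(j$J, bj$J, tolerance = 1e-12)
    # tie-break: smallest threshold attaining the maximum
    cand <- sort(unique(s))
    Js <- vapply(cand, function(t) {
      sum(s >= t & y == 1) / sum(y) - sum(s >= t & y == 0) / sum(1 - y)
    }, numeric(1))
    expect_equal(j$threshold, min(cand[abs(Js - max(Js)) < 1e-12]))
  }
})

test_that("null metrics sit at prevalence and one half", {
  set.seed(15)
  y <- rbinom(2000, 1, 0.3)
  reps <- replicate(20, {
    s <- runif(2000)
    c(auprc(s, y), auroc(s, y))
  })
  expect_equal(mean(reps[1, ]), mean(y), tolerance = 0.05)
  expect_equal(mean(reps[2, ]), 0.5, tolerance = 0.03)
})

test_that("metrics are invariant under strictly monotone score transforms", {
  set.seed(16)
  s <- runif(300)
  y <- rbinom(300, 1, 0.25)
  for (f in list(function(x) 3 * x - 1, function(x) x^3, plogis)) {
    expect_equal(auprc(f(s), y), auprc(s, y), tolerance = 1e-12)
    expect_equal(auroc(f(s), y), auroc(s, y), tolerance = 1e-12)
  }
})

test_that("auroc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:20) {
    y <- c(0, 1, rbinom(48, 1, 0.4))
    s <- round(runif(50), 2)   # ties included
    ref <- suppressMessages(as.numeric(pROC::auc(y, s,
                                                 direction = "<")))
    expect_equal(auroc(s, y), ref, tolerance = 1e-10)
  }
})

test_that("cross-validation bookkeeping: fold counts, oracle bound, seed", {
  ds <- small_signal_dataset(n = 150, seed = 30)
  cfg <- model_config(input_dim = ncol(ds$features), depth = 2,
                      sample_sizes = c(5, 5), hidden_dims = c(8, 8))
  res <- run_cross_validation(ds, cfg, k = 3, repeats = 2, ratio = 2,
                              seed = 7, scorer = label_oracle_scorer)
  expect_equal(nrow(res$folds), 6)      # k x repeats entries
  expect_equal(res$summary$mean[1], 1)  # true labels as scores: AUPRC 1
  expect_equal(res$summary$mean[2], 1)
  res2 <- run_cross_validation(ds, cfg, k = 3, repeats = 2, ratio = 2,
                               seed = 7, scorer = label_oracle_scorer)
  expect_identical(res$folds, res2$folds)
  expect_identical(res$scores, res2$scores)
})

test_that("unseen-gene scenarios respect their information contracts", {
  cfg_syn <- synthetic_config(n_nodes = 300, n_edges = 900, n_samples = 30,
                              seed = 41)
  ds <- make_reference_dataset(cfg_syn, n_components = 10)
  cfg <- model_config(input_dim = 10, depth = 2, sample_sizes = c(5, 5),
                      hidden_dims = c(8, 8), max_epochs = 8,
                      batch_size = 128)

  expect_error(run_unseen_scenarios(ds, cfg, scenario = "bogus"),
               "unknown scenario")

  # mask-labels-only is exactly standard CV under the same seed
  r1 <- run_unseen_scenarios(ds, cfg, "mask-labels-only", k = 2,
                             repeats = 1, ratio = 2, seed = 5)
  r2 <- run_cross_validation(ds, cfg, k = 2, repeats = 1, ratio = 2,
                             seed = 5)
  expect_identical(r1$folds[c("auprc", "auroc")],
                   r2$folds[c("auprc", "auroc")])

  # drop-test-completely: no test node id in any training computation graph
  r3 <- run_unseen_scenarios(ds, cfg, "drop-test-completely", k = 2,
                             repeats = 1, ratio = 2, seed = 5,
                             track_nodes = TRUE)
  expect_true(all(r3$isolation == 0))
  expect_true(all(r3$folds$auprc >= 0 & r3$folds$auprc <= 1))

  # a dataset without raw expression cannot refit the transform
  ds2 <- ds
  ds2$expression <- NULL
  expect_error(run_unseen_scenarios(ds2, cfg, "pca-train-only"),
               "expression")
})

test_that("evaluation results serialize with curves and metadata", {
  ds <- small_signal_dataset(n = 120, seed = 50)
  cfg <- model_config(input_dim = ncol(ds$features), depth = 2,
                      sample_sizes = c(4, 4), hidden_dims = c(8, 8))
  res <- run_cross_validation(ds, cfg, k = 2, repeats = 1, ratio = 2,
                              seed = 3, scorer = label_oracle_scorer)
  dir <- withr::local_tempdir()
  write_eval_result(res, dir)
  expect_true(all(file.exists(file.path(dir, c("metrics.json",
                                               "scores.tsv",
                                               "roc_curve.csv",
                                               "pr_curve.csv")))))
  meta <- jsonlite::read_json(file.path(dir, "metrics.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$summary$mean[1], res$summary$mean[1])
  expect_equal(meta$seed, 3)
})
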
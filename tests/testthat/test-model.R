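zero_params <- function(config, bias = 0) {
  p <- init_params(config)
  p$layer_weights <- lapply(p$layer_weights, function(W) W * 0)
  p$output_weight <- p$output_weight * 0
  p$output_bias <- bias
  p
}

test_that("neighborhood sampling obeys size, membership and determinism", {
  g <- random_graph(60, p = 0.4, seed = 3)
  deg <- vapply(g$adj, length, integer(1))
  targets <- g$nodes[order(-deg)[1:5]]
  comp <- sample_neighborhood(g, targets, sizes = c(7, 3), seed = 42)

  expect_identical(g$nodes[comp$levels[[1]]], targets)
  for (j in 1:2) {
    size <- c(7, 3)[j]
    for (i in seq_along(comp$levels[[j]])) {
      v <- comp$levels[[j]][i]
      s <- comp$samples[[j]][[i]]
      expect_lte(length(s), size)
      expect_equal(length(s), min(length(g$adj[[v]]), size))
      expect_equal(anyDuplicated(s), 0)
      expect_true(all(s %in% g$adj[[v]]))   # every sample is a neighbor
    }
  }

  # take-all when degree below the size budget
  low <- g$nodes[which.min(deg)]
  comp2 <- sample_neighborhood(g, low, sizes = max(deg) + 1L, seed = 1)
  expect_setequal(comp2$samples[[1]][[1]], g$adj[[match(low, g$nodes)]])

  # same seed, same draw; different seed, (almost surely) different draw
  compa <- sample_neighborhood(g, targets, c(7, 3), seed = 42)
  expect_identical(comp, compa)
  expect_error(sample_neighborhood(g, "ABSENT", c(7, 3)), "not in graph")

  # isolated nodes get empty samples
  gi <- build_graph(data.frame(gene_a = "A", gene_b = "B"),
                    nodes = c("A", "B", "LONE"))
  ci <- sample_neighborhood(gi, "LONE", sizes = c(5, 5), seed = 1)
  expect_length(ci$samples[[1]][[1]], 0)
})

test_that("a single aggregation step is concat -> mean -> linear -> relu", {
  # h_self (1,0), one neighbor (0,1), W = [I2; I2] adds self and mean
  W <- rbind(diag(2), diag(2))
  expect_equal(aggregate_step(c(1, 0), list(c(0, 1)), W), c(1, 1))

  # all neighbors equal: mean is that constant regardless of count
  expect_equal(aggregate_step(c(1, 0), list(c(2, 2), c(2, 2), c(2, 2)), W),
               aggregate_step(c(1, 0), list(c(2, 2)), W))

  # zero weights annihilate; negative pre-activations rectify to zero
  expect_equal(aggregate_step(c(1, 1), list(c(1, 1)), W * 0), c(0, 0))
  expect_equal(aggregate_step(c(-1, 0), list(), W), c(0, 0))
  expect_error(aggregate_step(c(1, 0), list(c(1, 2, 3)), W), "mismatch")
})

test_that("forward on a 3-node path matches the hand-derived logits", {
  g <- tiny_graph(c("a", "b", "b", "c"))
  X <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  cfg <- model_config(input_dim = 2, depth = 2, sample_sizes = c(5, 5),
                      hidden_dims = c(2, 2))
  p <- init_params(cfg)
  p$layer_weights[[1]] <- rbind(diag(2), diag(2))    # self + neighbor mean
  p$layer_weights[[2]] <- rbind(diag(2), -diag(2))   # self - neighbor mean
  p$output_weight <- c(2, 3)
  p$output_bias <- 0.25
  # frozen manual computation:
  #   h1: a=(1,1), b=(1,1.5), c=(1,2)
  #   h2: a=relu(0,-0.5)=(0,0), b=(0,0), c=(0,0.5)
  #   logits = 2*x + 3*y + 0.25  ->  a 0.25, b 0.25, c 1.75
  logits <- forward(p, g, X, c("a", "b", "c"), cfg, seed = 1)
  expect_equal(logits, c(0.25, 0.25, 1.75))
})

test_that("zero layer weights propagate only the output bias", {
  g <- build_graph(data.frame(gene_a = "A", gene_b = "B"),
                   nodes = c("A", "B", "LONE"))
  X <- random_features(g, d = 3)
  cfg <- model_config(input_dim = 3, depth = 2, sample_sizes = c(4, 4),
                      hidden_dims = c(4, 4))
  p <- zero_params(cfg, bias = 1.7)
  expect_equal(forward(p, g, X, g$nodes, cfg, seed = 5), rep(1.7, 3))
  # and sigmoid maps logit 0 to probability 0.5
  expect_equal(unname(predict_scores(zero_params(cfg), g, X, "LONE", cfg)),
               0.5)
})

test_that("saturated sampling equals dense brute-force aggregation", {
  for (seed in 1:10) {
    g <- random_graph(sample(5:20, 1), p = 0.35, seed = seed)
    X <- random_features(g, d = 2, seed = seed + 100)
    cfg <- model_config(input_dim = 2, depth = 3,
                        sample_sizes = rep(length(g$nodes), 3),
                        hidden_dims = c(3, 3, 3), seed = seed)
    p <- init_params(cfg)
    expect_equal(forward(p, g, X, g$nodes, cfg, seed = seed),
                 dense_forward(p, g, X, g$nodes), tolerance = 1e-6)
  }
})

test_that("forward is deterministic and local to the K-hop neighborhood", {
  # long path: the far end is > K hops from the target
  n <- 10
  pairs <- as.vector(rbind(sprintf("n%02d", 1:(n - 1)),
                           sprintf("n%02d", 2:n)))
  g <- tiny_graph(pairs)
  X <- random_features(g, d = 2, seed = 1)
  cfg <- model_config(input_dim = 2, depth = 3, sample_sizes = c(5, 5, 5),
                      hidden_dims = c(4, 4, 4))
  p <- init_params(cfg)
  base <- forward(p, g, X, "n01", cfg, seed = 7)
  expect_identical(base, forward(p, g, X, "n01", cfg, seed = 7))

  # editing features beyond 3 hops leaves the logit unchanged
  X2 <- X
  X2[sprintf("n%02d", 5:10), ] <- 99
  expect_equal(forward(p, g, X2, "n01", cfg, seed = 7), base)

  # editing the graph beyond 3 hops leaves the logit unchanged
  g2 <- tiny_graph(c(pairs, "n07", "n10"))
  expect_equal(forward(p, g2, X, "n01", cfg, seed = 7), base)
})

test_that("weighted cross-entropy has its closed forms", {
  expect_equal(weighted_bce_loss(0.5, 1, c(4, 1)), 4 * log(2))
  expect_equal(weighted_bce_loss(c(1 - 1e-12, 1e-12), c(1, 0)), 0,
               tolerance = 1e-9)
  set.seed(8)
  h <- runif(20, 0.05, 0.95)
  y <- rbinom(20, 1, 0.5)
  expect_equal(weighted_bce_loss(h, y, c(1, 1)),
               mean(-(y * log(h) + (1 - y) * log(1 - h))))
  expect_error(weighted_bce_loss(c(0.5, 0.5), 1), "length")
})

test_that("backpropagated gradients match finite differences", {
  g <- tiny_graph(c("a", "b", "b", "c", "c", "d", "a", "c"))
  X <- random_features(g, d = 2, seed = 5)
  cfg <- model_config(input_dim = 2, depth = 2, sample_sizes = c(2, 2),
                      hidden_dims = c(3, 3), seed = 2)
  p <- init_params(cfg)
  y <- c(1, 0, 1, 0)
  w <- c(4, 1)
  comp <- sample_neighborhood(g, g$nodes, cfg$sample_sizes, seed = 9)

  loss_at <- function(params) {
    fwd <- essnet:::forward_pass(params, comp, X)
    essnet:::bce_logits(fwd$logits, y, w)$loss
  }
  fwd <- essnet:::forward_pass(p, comp, X, keep_cache = TRUE)
  lg <- essnet:::bce_logits(fwd$logits, y, w)
  an <- essnet:::backward_pass(p, fwd, lg$dlogits)

  eps <- 1e-6
  for (k in 1:2) {
    W <- p$layer_weights[[k]]
    num <- W * 0
    for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
      up <- p; up$layer_weights[[k]][i, j] <- W[i, j] + eps
      dn <- p; dn$layer_weights[[k]][i, j] <- W[i, j] - eps
      num[i, j] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    }
    expect_equal(an$layer_weights[[k]], num, tolerance = 1e-4)
  }
  num_out <- vapply(seq_along(p$output_weight), function(i) {
    up <- p; up$output_weight[i] <- p$output_weight[i] + eps
    dn <- p; dn$output_weight[i] <- p$output_weight[i] - eps
    (loss_at(up) - loss_at(dn)) / (2 * eps)
  }, numeric(1))
  expect_equal(an$output_weight, num_out, tolerance = 1e-4)
  up <- p; up$output_bias <- p$output_bias + eps
  dn <- p; dn$output_bias <- p$output_bias - eps
  expect_equal(an$output_bias, (loss_at(up) - loss_at(dn)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("training is seeded, early-stops, and learns separable data", {
  ds <- small_signal_dataset(n = 120, seed = 10)
  pool <- subsample_negatives(ds$labels, ratio = 2, seed = 1)
  sp <- make_cv_splits(pool, k = 3, seed = 2)
  f <- sp$folds[[1]]
  cfg <- model_config(input_dim = ncol(ds$features), depth = 2,
                      sample_sizes = c(5, 5), hidden_dims = c(16, 16),
                      max_epochs = 60, batch_size = 64, seed = 99)

  # no-op contract
  cfg0 <- cfg; cfg0$max_epochs <- 0L
  fit0 <- train_model(ds, f$train, f$val, cfg0)
  expect_equal(nrow(fit0$history), 0)
  expect_equal(attr(fit0$history, "stopped_epoch"), 0L)

  fit1 <- train_model(ds, f$train, f$val, cfg)
  fit2 <- train_model(ds, f$train, f$val, cfg)
  expect_identical(fit1$history$val_loss, fit2$history$val_loss)
  stopped <- attr(fit1$history, "stopped_epoch")
  expect_lte(stopped, cfg$max_epochs)
  expect_equal(nrow(fit1$history), stopped)
  # early stopping fired within patience of the best epoch
  expect_lte(stopped, attr(fit1$history, "best_epoch") + cfg$patience)

  # strong planted signal: training-set ranking is nearly perfect
  sc <- predict_scores(fit1$params, ds$graph, ds$features, f$train, cfg,
                       seed = 3)
  y <- as.numeric(f$train %in% ds$labels$essential)
  expect_gt(auprc(sc, y), 0.95)

  # error cases
  no_pos <- setdiff(f$train, ds$labels$essential)
  expect_error(train_model(ds, no_pos, f$val, cfg), "no essential")
  expect_error(train_model(ds, f$train, f$train[1], cfg), "overlap")
})

test_that("a trained model scores supergraph nodes inductively", {
  ds <- small_signal_dataset(n = 100, seed = 21)
  pool <- subsample_negatives(ds$labels, ratio = 2, seed = 1)
  sp <- make_cv_splits(pool, k = 3, seed = 2)
  f <- sp$folds[[1]]
  cfg <- model_config(input_dim = ncol(ds$features), depth = 2,
                      sample_sizes = c(5, 5), hidden_dims = c(8, 8),
                      max_epochs = 15, batch_size = 64, seed = 5)
  fit <- train_model(ds, f$train, f$val, cfg)

  # supergraph: new nodes wired into the old graph
  dump <- graph_to_edge_list(ds$graph)
  extra <- data.frame(gene_a = c("NEW1", "NEW2", "NEW1"),
                      gene_b = c(ds$graph$nodes[1], ds$graph$nodes[2],
                                 "NEW2"))
  g_big <- build_graph(rbind(dump, extra))
  X_big <- rbind(ds$features,
                 matrix(rnorm(2 * ncol(ds$features)), 2,
                        dimnames = list(c("NEW1", "NEW2"), NULL)))
  sc <- predict_scores(fit$params, g_big, X_big, c("NEW1", "NEW2"), cfg,
                       seed = 11)
  expect_true(all(sc > 0 & sc < 1))
  expect_identical(sc, predict_scores(fit$params, g_big, X_big,
                                      c("NEW1", "NEW2"), cfg, seed = 11))
})

test_that("checkpoints round-trip parameters and configuration", {
  cfg <- model_config(input_dim = 3, depth = 2, sample_sizes = c(4, 2),
                      hidden_dims = c(5, 4), seed = 12)
  p <- init_params(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(list(params = p, config = cfg, transform_id = "t1"), f)
  back <- read_checkpoint(f)
  expect_equal(back$params$layer_weights, p$layer_weights)
  expect_equal(back$params$output_weight, p$output_weight)
  expect_equal(back$config$sample_sizes, cfg$sample_sizes)
  expect_equal(back$config$class_weights, cfg$class_weights)
  expect_equal(back$transform_id, "t1")

  g <- random_graph(10, p = 0.4, seed = 1)
  X <- random_features(g, d = 3)
  expect_equal(forward(back$params, g, X, g$nodes, back$config, seed = 2),
               forward(p, g, X, g$nodes, cfg, seed = 2))
})
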
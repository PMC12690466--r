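# The inductive sample-and-aggregate classifier.
#
# A target node's prediction depends only on its K-hop sampled neighborhood
# ("computation graph"): at each hop a fixed-size uniform sample of
# neighbors is drawn, neighbor representations are mean-aggregated,
# concatenated with the node's own representation, passed through a learned
# linear map with ReLU, and the depth-K representation is reduced to a logit
# by a learned linear output layer.  Training minimizes class-weighted
# binary cross-entropy (computed in logit space for stability) with Adam.
#
# Everything here is plain matrix algebra: per minibatch the layered node
# sets are flattened into matrices and the per-node neighbor means become a
# single sparse row-stochastic matrix multiply, so both the forward pass and
# the (hand-derived) backward pass are a handful of dense/sparse products.

#' Model configuration
#'
#' @param input_dim Node feature dimensionality (e.g. 50 principal
#'   components).
#' @param depth Number of aggregation hops K (default 3).
#' @param sample_sizes Neighbors sampled per hop, length-`depth`, ordered
#'   from the first hop (direct neighbors of a target) outward; default
#'   `c(30, 25, 10)`.
#' @param hidden_dims Width of each aggregation layer, length `depth`
#'   (default 128 each).
#' @param learning_rate Adam step size (default 0.01).
#' @param max_epochs Training epoch cap (default 200).
#' @param patience Early-stopping patience in epochs without validation-loss
#'   improvement (default 10).
#' @param min_delta Smallest validation-loss decrease counted as an
#'   improvement by early stopping (default 1e-3).
#' @param batch_size Target nodes per minibatch (default 512).
#' @param class_weights Named loss weights `c(essential =, nonessential =)`,
#'   default 4 and 1, matching the 4:1 negative subsampling.
#' @param seed Master seed controlling initialization and neighbor sampling.
#' @return A `model_config` list.
#' @export
model_config <- function(input_dim, depth = 3L,
                         sample_sizes = c(30L, 25L, 10L),
                         hidden_dims = rep(128L, depth),
                         learning_rate = 0.01, max_epochs = 200L,
                         patience = 10L, min_delta = 1e-3,
                         batch_size = 512L,
                         class_weights = c(essential = 4, nonessential = 1),
                         seed = 1L) {
  assert_that(depth >= 1, "depth must be >= 1")
  assert_that(length(sample_sizes) == depth,
              "sample_sizes must have length depth (%d)", depth)
  assert_that(all(sample_sizes >= 1), "sample_sizes must be positive")
  assert_that(length(hidden_dims) == depth,
              "hidden_dims must have length depth (%d)", depth)
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(all(class_weights > 0), "class weights must be positive")
  class_weights <- setNames(as.numeric(class_weights),
                            c("essential", "nonessential"))
  structure(list(input_dim = as.integer(input_dim), depth = as.integer(depth),
                 sample_sizes = as.integer(sample_sizes),
                 hidden_dims = as.integer(hidden_dims),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_delta = min_delta,
                 batch_size = as.integer(batch_size),
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize model parameters
#'
#' Uniform Glorot initialization for the K layer weights (each mapping the
#' concatenated self+neighbor vector of length `2 * d_in` to `d_out`) and the
#' output projection; output bias starts at 0.
#'
#' @param config A `model_config`.
#' @param seed RNG seed (default `config$seed`).
#' @return A `model_params` list: `layer_weights` (list of K matrices),
#'   `output_weight`, `output_bias`.
#' @export
init_params <- function(config, seed = config$seed) {
  dims <- c(config$input_dim, config$hidden_dims)
  with_seed(seed, {
    lw <- lapply(seq_len(config$depth), function(k) {
      fan_in <- 2L * dims[k]
      fan_out <- dims[k + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    })
    d_out <- dims[length(dims)]
    lim <- sqrt(6 / (d_out + 1))
    structure(list(layer_weights = lw,
                   output_weight = runif(d_out, -lim, lim),
                   output_bias = 0),
              class = "model_params")
  })
}

#' Sample a layered neighborhood computation graph
#'
#' For a batch of target nodes, draws the K-hop neighbor samples that a
#' forward pass consumes: level 1 is the targets; at each level every node's
#' neighbor set is subsampled uniformly without replacement to at most
#' `sizes[level]` (all neighbors kept when the degree is smaller; isolated
#' nodes get an empty sample), and the next level is the union of the
#' current level and everything sampled.
#'
#' @param graph A `gene_graph`.
#' @param targets Character vector of target node symbols.
#' @param sizes Integer vector of per-hop sample sizes, hop 1 first.
#' @param seed RNG seed making the draw reproducible.
#' @return A `computation_graph`: `levels` (list of K+1 integer node-index
#'   vectors, level 1 = targets) and `samples` (per level, a list of sampled
#'   neighbor index vectors aligned with the level's nodes).
#' @export
sample_neighborhood <- function(graph, targets, sizes, seed = 1L) {
  idx <- match(targets, graph$nodes)
  if (anyNA(idx)) {
    stopf("target not in graph: %s", targets[which(is.na(idx))[1L]])
  }
  K <- length(sizes)
  adj <- graph$adj
  with_seed(seed, {
    levels <- vector("list", K + 1L)
    samples <- vector("list", K)
    levels[[1L]] <- idx
    for (j in seq_len(K)) {
      cur <- levels[[j]]
      size <- sizes[j]
      samp <- lapply(adj[cur], function(nb) {
        if (length(nb) <= size) nb
        else nb[sample.int(length(nb), size)]
      })
      samples[[j]] <- samp
      levels[[j + 1L]] <- unique(c(cur, unlist(samp, use.names = FALSE)))
    }
    structure(list(levels = levels, samples = samples, sizes = sizes),
              class = "computation_graph")
  })
}

#' All node indices touched by a computation graph
#' @param comp A `computation_graph`.
#' @return Sorted integer vector of node indices.
#' @export
computation_nodes <- function(comp) {
  sort(unique(unlist(comp$levels, use.names = FALSE)))
}

#' One sample-and-aggregate step for a single node
#'
#' Mean of the sampled neighbor vectors (the zero vector when there are
#' none), concatenated after the node's own vector, multiplied by the layer
#' weight and rectified.  This is the per-node scalar form of the batched
#' layer used inside [forward()].
#'
#' @param h_self Numeric vector of length d.
#' @param neighbor_vectors List of numeric length-d vectors (possibly empty).
#' @param W Weight matrix with `2 * d` rows.
#' @return Rectified output vector of length `ncol(W)`.
#' @export
aggregate_step <- function(h_self, neighbor_vectors, W) {
  d <- length(h_self)
  assert_that(nrow(W) == 2L * d, "W must have 2 * length(h_self) rows")
  if (length(neighbor_vectors) > 0L) {
    lens <- vapply(neighbor_vectors, length, integer(1))
    assert_that(all(lens == d), "neighbor vector dimension mismatch")
    nbr <- Reduce(`+`, neighbor_vectors) / length(neighbor_vectors)
  } else {
    nbr <- numeric(d)
  }
  pmax(as.vector(c(h_self, nbr) %*% W), 0)
}

# Build the per-level mean-aggregation operator: a sparse row-stochastic
# matrix mapping representations on `next_level` to neighbor means on
# `level` (zero rows for isolated nodes).
mean_operator <- function(samples, level_len, next_level) {
  lens <- vapply(samples, length, integer(1))
  rows <- rep.int(seq_len(level_len), lens)
  cols <- match(unlist(samples, use.names = FALSE), next_level)
  vals <- rep.int(ifelse(lens > 0, 1 / pmax(lens, 1L), 0), lens)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(level_len, length(next_level)))
}

# Forward pass over a sampled computation graph.  X is the full feature
# matrix in graph-node order.  Returns logits plus the caches needed by
# backward_pass.
forward_pass <- function(params, comp, X, keep_cache = FALSE) {
  K <- length(comp$samples)
  H <- X[comp$levels[[K + 1L]], , drop = FALSE]
  cache <- if (keep_cache) vector("list", K) else NULL
  for (t in seq_len(K)) {
    j <- K - t + 1L
    level <- comp$levels[[j]]
    next_level <- comp$levels[[j + 1L]]
    idx <- match(level, next_level)
    M <- mean_operator(comp$samples[[j]], length(level), next_level)
    # W acts on the concatenation [h_self, h_nbr]; applying its two halves
    # separately avoids materializing the concatenated matrix
    W <- params$layer_weights[[t]]
    d <- ncol(H)
    Hs <- H[idx, , drop = FALSE]
    Hn <- as.matrix(M %*% H)
    Z <- Hs %*% W[seq_len(d), , drop = FALSE] +
      Hn %*% W[d + seq_len(d), , drop = FALSE]
    Hnew <- Z
    Hnew[Hnew < 0] <- 0
    if (keep_cache) {
      cache[[t]] <- list(idx = idx, M = M, Hs = Hs, Hn = Hn, mask = Z > 0)
    }
    H <- Hnew
  }
  logits <- as.vector(H %*% params$output_weight) + params$output_bias
  list(logits = logits, H_final = H, cache = cache)
}

# Hand-derived backward pass: gradients of mean(weighted BCE-with-logits)
# with respect to every parameter.  `dlogits` is dLoss/dlogit per target.
backward_pass <- function(params, fwd, dlogits) {
  K <- length(params$layer_weights)
  g_out_w <- as.vector(crossprod(fwd$H_final, dlogits))
  g_out_b <- sum(dlogits)
  G <- tcrossprod(matrix(dlogits, ncol = 1), matrix(params$output_weight,
                                                   ncol = 1))
  g_layers <- vector("list", K)
  for (t in rev(seq_len(K))) {
    cc <- fwd$cache[[t]]
    G <- G * cc$mask
    g_layers[[t]] <- rbind(crossprod(cc$Hs, G), crossprod(cc$Hn, G))
    if (t > 1L) {
      d_in <- ncol(cc$Hs)
      W <- params$layer_weights[[t]]
      d_self <- tcrossprod(G, W[seq_len(d_in), , drop = FALSE])
      d_nbr <- tcrossprod(G, W[d_in + seq_len(d_in), , drop = FALSE])
      dH <- as.matrix(Matrix::crossprod(cc$M, d_nbr))
      dH[cc$idx, ] <- dH[cc$idx, , drop = FALSE] + d_self
      G <- dH
    }
  }
  list(layer_weights = g_layers, output_weight = g_out_w,
       output_bias = g_out_b)
}

#' Forward pass: logits for target nodes
#'
#' Samples a fresh computation graph (seeded) and evaluates the K nested
#' aggregation steps from the raw node features, then the linear output
#' projection.  With `sample_sizes >= max degree` this equals the dense,
#' sampling-free evaluation of the aggregation recursion.
#'
#' @param params A `model_params`.
#' @param graph A `gene_graph`.
#' @param features Numeric matrix with one row per graph node (graph node
#'   order, rownames = node symbols) or a `feature_matrix` covering all
#'   graph nodes.
#' @param targets Character vector of target node symbols.
#' @param config A `model_config`.
#' @param seed Sampling seed.
#' @return Numeric vector of logits, one per target.
#' @export
forward <- function(params, graph, features, targets, config, seed = 1L) {
  X <- feature_rows_for_graph(features, graph)
  comp <- sample_neighborhood(graph, targets, config$sample_sizes, seed)
  forward_pass(params, comp, X)$logits
}

feature_rows_for_graph <- function(features, graph) {
  fmat <- as_feature_rows(features)
  missing <- setdiff(graph$nodes, rownames(fmat))
  if (length(missing) > 0L) {
    stopf("missing feature row for graph node: %s", missing[1L])
  }
  fmat[graph$nodes, , drop = FALSE]
}

#' Class-weighted binary cross-entropy
#'
#' Mean over nodes of `-w(y) * (y * log(h) + (1 - y) * log(1 - h))` with
#' per-class weights; with unit weights this is plain binary cross-entropy.
#' Training uses the numerically equivalent logit-space form.
#'
#' @param probabilities Predicted probabilities in `(0, 1)`.
#' @param labels 0/1 labels.
#' @param weights Length-2 numeric `c(w_pos, w_neg)`, default `c(4, 1)`.
#' @return Scalar loss.
#' @export
weighted_bce_loss <- function(probabilities, labels, weights = c(4, 1)) {
  assert_that(length(probabilities) == length(labels),
              "probabilities and labels differ in length")
  w <- ifelse(labels == 1, weights[1], weights[2])
  mean(-w * (labels * log(probabilities) +
               (1 - labels) * log(1 - probabilities)))
}

# Loss and dLoss/dlogit in logit space: softplus(z) - y*z, class-weighted,
# averaged over the batch.
bce_logits <- function(logits, labels, weights) {
  w <- ifelse(labels == 1, weights[1], weights[2])
  sp <- pmax(logits, 0) + log1p(exp(-abs(logits)))
  loss <- mean(w * (sp - labels * logits))
  dlogits <- w * (plogis(logits) - labels) / length(logits)
  list(loss = loss, dlogits = dlogits)
}

adam_init <- function(params) {
  flat <- c(params$layer_weights, list(params$output_weight,
                                       params$output_bias))
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  flat_p <- c(params$layer_weights, list(params$output_weight,
                                         params$output_bias))
  flat_g <- c(grads$layer_weights, list(grads$output_weight,
                                        grads$output_bias))
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (i in seq_along(flat_p)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * flat_g[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * flat_g[[i]]^2
    mhat <- state$m[[i]] / corr1
    vhat <- state$v[[i]] / corr2
    flat_p[[i]] <- flat_p[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  K <- length(params$layer_weights)
  params$layer_weights <- flat_p[seq_len(K)]
  params$output_weight <- flat_p[[K + 1L]]
  params$output_bias <- flat_p[[K + 2L]]
  list(params = params, state = state)
}

#' Train the classifier
#'
#' Adam optimization of the class-weighted cross-entropy over minibatched
#' computation graphs, with neighborhoods resampled every epoch.  Stops when
#' validation loss has not improved for `patience` epochs or at
#' `max_epochs`, returning the parameters of the best validation epoch.
#' Unlabeled genes participate in message passing as sampled neighbors but
#' never contribute loss terms.
#'
#' @param dataset An `aligned_dataset` (graph + features + labels).
#' @param train_nodes,val_nodes Disjoint character vectors of labeled node
#'   symbols.
#' @param config A `model_config`.
#' @param track_nodes When `TRUE`, records the set of node symbols that
#'   appeared in any training computation graph (isolation instrumentation
#'   for unseen-gene experiments).
#' @return List with `params` (`model_params`), `history` (data.frame of
#'   per-epoch train/validation loss, plus attributes `stopped_epoch`,
#'   `best_epoch`), and `touched_nodes` (when tracked).
#' @export
train_model <- function(dataset, train_nodes, val_nodes, config,
                        track_nodes = FALSE) {
  graph <- dataset$graph
  X <- feature_rows_for_graph(dataset$features, graph)
  lab <- dataset$labels
  y_of <- function(nodes) as.numeric(nodes %in% lab$essential)
  known <- c(lab$essential, lab$nonessential)
  assert_that(all(train_nodes %in% known) && all(val_nodes %in% known),
              "train/val nodes must be labeled")
  assert_that(length(intersect(train_nodes, val_nodes)) == 0L,
              "train and validation nodes overlap")
  y_train <- y_of(train_nodes)
  if (sum(y_train) == 0) stopf("no essential genes in the training set")
  y_val <- y_of(val_nodes)
  w <- unname(config$class_weights)

  params <- init_params(config)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  if (config$max_epochs == 0L) {
    attr(history, "stopped_epoch") <- 0L
    attr(history, "best_epoch") <- 0L
    return(list(params = params, history = history,
                touched_nodes = if (track_nodes) character() else NULL))
  }

  state <- adam_init(params)
  seeds <- seed_stream(config$seed, 3L * config$max_epochs + 1L)
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  touched <- integer(0)
  stopped <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(seeds[3L * epoch - 2L],
                     sample.int(length(train_nodes)))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    n_seen <- 0L
    for (b in seq_along(batches)) {
      ids <- batches[[b]]
      batch_seed <- (seeds[3L * epoch - 1L] + b) %% 2147483647
      comp <- sample_neighborhood(graph, train_nodes[ids],
                                  config$sample_sizes, seed = batch_seed)
      if (track_nodes) touched <- union(touched, computation_nodes(comp))
      fwd <- forward_pass(params, comp, X, keep_cache = TRUE)
      lg <- bce_logits(fwd$logits, y_train[ids], w)
      grads <- backward_pass(params, fwd, lg$dlogits)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + lg$loss * length(ids)
      n_seen <- n_seen + length(ids)
    }
    train_loss <- epoch_loss / n_seen
    val_comp <- sample_neighborhood(graph, val_nodes, config$sample_sizes,
                                    seed = seeds[3L * epoch])
    val_logits <- forward_pass(params, val_comp, X)$logits
    val_loss <- bce_logits(val_logits, y_val, w)$loss
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (val_loss < best_val - config$min_delta) {
      best_val <- val_loss
      best_params <- params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) {
        stopped <- epoch
        break
      }
    }
  }
  attr(history, "stopped_epoch") <- stopped
  attr(history, "best_epoch") <- best_epoch
  list(params = best_params, history = history,
       touched_nodes = if (track_nodes) graph$nodes[sort(touched)] else NULL)
}

#' Inductive scoring of target nodes
#'
#' Sigmoid of the forward logits under a single seeded neighborhood sample.
#' The supplied graph and features may be a strict supergraph of what the
#' model was trained on: new nodes and edges are consumed without
#' retraining (the inductive contract).
#'
#' @inheritParams forward
#' @return Named numeric vector of probabilities in `(0, 1)`.
#' @export
predict_scores <- function(params, graph, features, targets, config,
                           seed = 1L) {
  setNames(plogis(forward(params, graph, features, targets, config, seed)),
           targets)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON serialization of parameters + configuration (+ an
#' optional identifier of the feature transform the model was trained
#' with).
#'
#' @param fit List with `params` and `config` (as from [train_model()] plus
#'   its config), optionally `transform_id`.
#' @param path File path.
#' @return `write_checkpoint`: invisibly `path`; `read_checkpoint`: the
#'   restored list.
#' @export
write_checkpoint <- function(fit, path) {
  obj <- list(config = unclass(fit$config),
              layer_weights = fit$params$layer_weights,
              output_weight = fit$params$output_weight,
              output_bias = fit$params$output_bias,
              transform_id = fit$transform_id %||% NA)
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor",
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_in <- obj$config[c("input_dim", "depth", "sample_sizes",
                         "hidden_dims", "learning_rate", "max_epochs",
                         "patience", "min_delta", "batch_size",
                         "class_weights", "seed")]
  cfg_in$class_weights <- unlist(cfg_in$class_weights)
  cfg <- do.call(model_config, cfg_in)
  params <- structure(list(layer_weights = obj$layer_weights,
                           output_weight = as.numeric(obj$output_weight),
                           output_bias = as.numeric(obj$output_bias)),
                      class = "model_params")
  list(params = params, config = cfg, transform_id = obj$transform_id)
}
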
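#' @title Local model architectures
#'
#' @description
#' Three architectures are registered.  `"logistic"` (8 weights + 1 bias)
#' and `"tabular_mlp"` (8 -> 16 hidden ReLU -> 2 softmax) consume the
#' 8-feature clinical rows and are the trained backends.  `"paper_cnn"` is
#' a 28x28x1 image network -- conv 5x5/32 (same padding), 2x2 max-pool,
#' conv 5x5/64 (same padding), 2x2 max-pool, dense 512, dense 10 softmax --
#' kept for its exact trainable-parameter count (1,663,370) and
#' initialization contract; it cannot consume tabular rows and is not part
#' of the training path.
#'
#' Parameters are carried as a single flat numeric vector, all weights
#' first (layer by layer, column-major) then all biases (layer by layer),
#' so updates can flow through clipping, noising, verification and
#' aggregation as plain vectors.
#'
#' @param arch_id one of `"logistic"`, `"tabular_mlp"`, `"paper_cnn"`.
#' @return `count_params()` returns the exact number of trainable
#'   parameters.
#' @examples
#' count_params("paper_cnn")  # 1663370
#' @export
count_params <- function(arch_id) {
  sum(arch_shapes(arch_id)$sizes)
}

# Layer shape table: weight and bias sizes in flattening order.
arch_shapes <- function(arch_id) {
  switch(arch_id,
    logistic = list(
      weights = list(c(8, 1)), biases = list(1L),
      sizes = c(8L, 1L)),
    tabular_mlp = list(
      weights = list(c(8, 16), c(16, 2)), biases = list(16L, 2L),
      sizes = c(8L * 16L, 16L * 2L, 16L, 2L)),
    paper_cnn = list(
      weights = list(c(5, 5, 1, 32), c(5, 5, 32, 64), c(3136, 512),
                     c(512, 10)),
      biases = list(32L, 64L, 512L, 10L),
      sizes = c(800L, 51200L, 1605632L, 5120L, 32L, 64L, 512L, 10L)),
    stop_param("unknown arch_id: ", arch_id)
  )
}

n_weights <- function(arch_id) {
  sh <- arch_shapes(arch_id)
  sum(vapply(sh$weights, prod, 0))
}

#' Initialize model parameters
#'
#' Weights are drawn i.i.d. from N(0, 0.02^2) and all biases start at 0;
#' the draw is deterministic under `seed`.
#'
#' @inheritParams count_params
#' @param seed integer seed.
#' @param init_sd standard deviation of the weight initialization.
#' @return an object of class `model_params`: list with `values` (flat
#'   numeric vector, weights then biases) and `arch_id`.
#' @export
init_params <- function(arch_id, seed, init_sd = 0.02) {
  nw <- n_weights(arch_id)
  ntotal <- count_params(arch_id)
  w <- with_seed(derive_seed(seed, "init_params", arch_id),
                 rnorm(nw, 0, init_sd))
  structure(list(values = c(w, rep(0, ntotal - nw)), arch_id = arch_id),
            class = "model_params")
}

# Split a flat vector into per-layer weight matrices / bias vectors.
unflatten <- function(params) {
  sh <- arch_shapes(params$arch_id)
  v <- params$values
  out <- list(W = list(), b = list())
  pos <- 0
  for (i in seq_along(sh$weights)) {
    d <- sh$weights[[i]]
    len <- prod(d)
    out$W[[i]] <- array(v[pos + seq_len(len)], dim = d)
    pos <- pos + len
  }
  for (i in seq_along(sh$biases)) {
    len <- sh$biases[[i]]
    out$b[[i]] <- v[pos + seq_len(len)]
    pos <- pos + len
  }
  out
}

flatten_layers <- function(arch_id, layers) {
  c(unlist(lapply(layers$W, as.numeric)),
    unlist(lapply(layers$b, as.numeric)))
}

#' Standardization spec for the tabular backends
#'
#' Returns the per-column centers and scales applied to the features
#' before any model sees them.  Synthetic data carries its nominal
#' centers/scales in provenance (public generator constants, so no
#' per-dataset statistic leaks); externally loaded data falls back to
#' column statistics.
#'
#' @param ds a `clinical_dataset`.
#' @return list with `centers` and `scales` (length-8 numeric vectors).
#' @export
feature_prep <- function(ds) {
  pv <- ds$provenance
  if (!is.null(pv$centers))
    return(list(centers = pv$centers, scales = pv$scales))
  list(centers = colMeans(ds$features),
       scales = pmax(apply(ds$features, 2, sd), 1e-8))
}

std_features <- function(features, prep) {
  scale(features, center = prep$centers, scale = prep$scales)
}

# Class-1 probability under the current parameters.
predict_prob <- function(params, features, prep) {
  xs <- std_features(features, prep)
  if (params$arch_id == "logistic") {
    ly <- unflatten(params)
    plogis(drop(xs %*% ly$W[[1]]) + ly$b[[1]])
  } else if (params$arch_id == "tabular_mlp") {
    ly <- unflatten(params)
    h <- pmax(sweep(xs %*% ly$W[[1]], 2, ly$b[[1]], "+"), 0)
    z <- sweep(h %*% ly$W[[2]], 2, ly$b[[2]], "+")
    1 / (1 + exp(pmin(pmax(z[, 1] - z[, 2], -700), 700)))
  } else stop_param("arch '", params$arch_id,
                    "' cannot consume tabular features")
}

# Mean cross-entropy and flat gradient for one mini-batch.
batch_grad <- function(params, xs, y) {
  m <- nrow(xs)
  if (params$arch_id == "logistic") {
    ly <- unflatten(params)
    eta <- drop(xs %*% ly$W[[1]]) + ly$b[[1]]
    p <- plogis(eta)
    loss <- mean(pmax(eta, 0) - y * eta + log1p(exp(-abs(eta))))
    r <- p - y
    g <- c(drop(crossprod(xs, r)) / m, mean(r))
    list(grad = g, loss = loss)
  } else if (params$arch_id == "tabular_mlp") {
    ly <- unflatten(params)
    a1 <- sweep(xs %*% ly$W[[1]], 2, ly$b[[1]], "+")
    h <- pmax(a1, 0)
    z <- sweep(h %*% ly$W[[2]], 2, ly$b[[2]], "+")
    zmax <- pmax(z[, 1], z[, 2])
    lse <- zmax + log(exp(z[, 1] - zmax) + exp(z[, 2] - zmax))
    # one-hot targets: column 2 is the positive class
    loss <- mean(lse - ifelse(y == 1, z[, 2], z[, 1]))
    pz <- exp(z - lse)              # softmax probabilities
    dz <- pz
    dz[, 1] <- dz[, 1] - (y == 0)
    dz[, 2] <- dz[, 2] - (y == 1)
    dz <- dz / m
    dW2 <- crossprod(h, dz)
    db2 <- colSums(dz)
    dh <- dz %*% t(ly$W[[2]])
    da1 <- dh * (a1 > 0)
    dW1 <- crossprod(xs, da1)
    db1 <- colSums(da1)
    list(grad = flatten_layers(params$arch_id,
                               list(W = list(dW1, dW2),
                                    b = list(db1, db2))),
         loss = loss)
  } else stop_param("arch '", params$arch_id, "' has no tabular gradient")
}

#' Train locally for one round and return the parameter delta
#'
#' Runs `iterations` mini-batch SGD steps of the cross-entropy loss on one
#' device's shard.  The batch size is silently reduced to the shard size
#' when the shard is smaller than `batch_size`; batches are sampled
#' without replacement within an epoch and the shard is reshuffled when an
#' epoch is exhausted.  The returned "local gradient" is the raw parameter
#' delta `w_in - w_out` accumulated over all iterations -- the single
#' per-round quantity a device uploads -- so that the server update
#' `w - mean(deltas)` reproduces federated averaging.
#'
#' @param params a `model_params` (the current global model).
#' @param shard a `clinical_dataset` (this device's local data).
#' @param batch_size,iterations,lr mini-batch SGD settings.
#' @param seed integer seed for the batch-sampling stream.
#' @param prep standardization (centers/scales); defaults to the shard's
#'   provenance.
#' @param device_id,round identifiers stored on the update.
#' @return an object of class `local_update`: list with `gradient` (flat
#'   delta, same length as `params$values`), `loss` (mean loss over the
#'   processed batches), `device_id`, `round`.
#' @export
local_train <- function(params, shard, batch_size = 64, iterations = 20,
                        lr = 0.1, seed = 1, prep = NULL,
                        device_id = NA_integer_, round = NA_integer_) {
  stopifnot(inherits(params, "model_params"),
            inherits(shard, "clinical_dataset"))
  n <- nrow(shard$features)
  if (n == 0) stop_param("empty shard")
  if (iterations < 1) stop_param("'iterations' must be >= 1")
  prep <- prep %||% feature_prep(shard)
  xs <- std_features(shard$features, prep)
  y <- shard$labels
  b <- min(batch_size, n)
  w0 <- params$values
  cur <- params
  losses <- numeric(iterations)
  with_seed(seed, {
    order <- sample.int(n)
    pos <- 0
    for (it in seq_len(iterations)) {
      if (pos + b > n) { order <- sample.int(n); pos <- 0 }
      idx <- order[pos + seq_len(b)]
      pos <- pos + b
      bg <- batch_grad(cur, xs[idx, , drop = FALSE], y[idx])
      cur$values <- cur$values - lr * bg$grad
      losses[it] <- bg$loss
    }
  })
  structure(list(gradient = w0 - cur$values, loss = mean(losses),
                 device_id = device_id, round = round),
            class = "local_update")
}

#' Evaluate a model on a test set
#'
#' @param params a `model_params`.
#' @param test a non-empty `clinical_dataset`.
#' @param prep standardization; defaults to the test set's provenance.
#' @return list with `accuracy` (fraction correctly classified) and
#'   `attack_success_rate` (= 1 - accuracy: the fraction of test samples
#'   the model misclassifies, the metric used to quantify poisoning
#'   damage).
#' @export
evaluate_model <- function(params, test, prep = NULL) {
  stopifnot(inherits(test, "clinical_dataset"))
  if (nrow(test$features) == 0) stop_param("empty test set")
  prep <- prep %||% feature_prep(test)
  p <- predict_prob(params, test$features, prep)
  pred <- as.integer(p > 0.5)
  acc <- mean(pred == test$labels)
  list(accuracy = acc, attack_success_rate = 1 - acc)
}

# Mean training loss of `params` on a dataset (used for the convergence
# stopping rule).
dataset_loss <- function(params, ds, prep) {
  xs <- std_features(ds$features, prep)
  batch_grad(params, xs, ds$labels)$loss
}

#' Plain federated averaging reference
#'
#' The undefended baseline: per round every device runs [local_train()],
#' updates are clipped at the same adaptive threshold schedule as the full
#' pipeline (pass `clipper = NULL` to disable clipping), averaged, and
#' applied with server step 1 -- no noise, no verification, no chain.
#' Uses the same per-(round, device) batch substreams as the full
#' pipeline, so with the noise multiplier at 0, no attack, and
#' verification disabled the pipeline must reproduce this trajectory
#' bit for bit.
#'
#' @param params initial `model_params`.
#' @param shards list of `clinical_dataset` shards.
#' @param rounds number of rounds.
#' @param batch_size,iterations,lr SGD settings per [local_train()].
#' @param seed master seed (batch substreams are derived per round and
#'   device).
#' @param prep standardization applied on all shards.
#' @param clipper optional [clipper_state()] applied to each update.
#' @return list with final `params` and the per-round matrix `trace` of
#'   flattened parameters.
#' @export
fedavg_reference <- function(params, shards, rounds, batch_size = 64,
                             iterations = 20, lr = 0.1, seed = 1,
                             prep = NULL, clipper = NULL) {
  prep <- prep %||% feature_prep(shards[[1]])
  trace <- matrix(NA_real_, rounds, length(params$values))
  for (t in seq_len(rounds)) {
    C_t <- if (is.null(clipper)) Inf else clipping_threshold(clipper)
    deltas <- lapply(seq_along(shards), function(i) {
      u <- local_train(params, shards[[i]], batch_size, iterations, lr,
                       seed = derive_seed(seed, "batch", t, i), prep = prep,
                       device_id = i, round = t)
      if (is.finite(C_t)) clip_gradient(u$gradient, C_t) else u$gradient
    })
    gbar <- Reduce(`+`, deltas) / length(deltas)
    params$values <- params$values - gbar
    if (!is.null(clipper)) clipper <- update_prior(clipper, gbar)
    trace[t, ] <- params$values
  }
  list(params = params, trace = trace)
}
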
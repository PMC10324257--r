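# Contrastive pair training. Positive pairs (same class, y = 1) are
# pulled together, negative pairs (y = 0) pushed beyond a margin:
#   L = (1 / 2N) * sum_n [ y d^2 + (1 - y) max(margin - d, 0)^2 ]
# with d the Euclidean distance between the two embeddings of a pair
# under the shared branch parameters.

#' Contrastive loss configuration
#'
#' @param margin Positive threshold beyond which negative pairs stop
#'   contributing; default 1 (suits unnormalized embeddings).
#' @export
loss_config <- function(margin = 1.0) {
  osm_check(margin > 0, "margin must be > 0")
  structure(list(margin = margin), class = "osm_loss_config")
}

#' Training configuration
#'
#' Defaults are the reference protocol: Adam at learning rate 1e-5,
#' batches of 50 pairs, 50 epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Pairs per optimization step.
#' @param epochs Number of epochs; fresh pairs are sampled each epoch.
#' @param pairs_per_epoch `NULL` = one pair per training image.
#' @param positive_fraction Fraction of same-class pairs per epoch.
#' @param seed Master seed; per-epoch sampling seeds derive from it.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 50, epochs = 50,
                         pairs_per_epoch = NULL, positive_fraction = 0.5,
                         seed = 1) {
  osm_check(learning_rate > 0 && batch_size >= 1 && epochs >= 0,
            "learning_rate and batch_size must be positive, epochs >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 pairs_per_epoch = pairs_per_epoch,
                 positive_fraction = positive_fraction,
                 seed = as.integer(seed)),
            class = "osm_train_config")
}

#' Sample labeled image pairs
#'
#' Draws exactly `round(positive_fraction * n_pairs)` positive
#' (same-class) pairs and the rest negative (different-class), with no
#' self-pairs; the result is a pure function of the seed.
#'
#' @param m An `osm_manifest`, `osm_dataset`, or bare label vector.
#' @param n_pairs Number of pairs.
#' @param positive_fraction Fraction of positive pairs, in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame with columns `first`, `second` (indices into the
#'   manifest) and `y` (1 = same class, 0 = different).
#' @export
sample_pairs <- function(m, n_pairs, positive_fraction = 0.5, seed = 1) {
  labels <- if (inherits(m, "osm_dataset")) m$labels
            else if (is.data.frame(m)) m$label
            else as.character(m)
  osm_check(n_pairs >= 1, "n_pairs must be >= 1")
  osm_check(positive_fraction >= 0 && positive_fraction <= 1,
            "positive_fraction must be in [0, 1]")
  classes <- unique(labels)
  osm_check(length(classes) == 2, "pair sampling needs exactly two classes")
  by_class <- split(seq_along(labels), labels)
  n_pos <- round(positive_fraction * n_pairs)
  n_neg <- n_pairs - n_pos
  pos_ok <- names(by_class)[vapply(by_class, length, 1L) >= 2]
  if (n_pos > 0 && length(pos_ok) == 0) {
    osm_stop("positive pairs requested but no class has at least 2 images")
  }
  with_seed(seed, {
    first <- integer(n_pairs); second <- integer(n_pairs); y <- integer(n_pairs)
    for (i in seq_len(n_pos)) {
      cl <- if (length(pos_ok) == 1) pos_ok else sample(pos_ok, 1)
      ij <- sample(by_class[[cl]], 2)
      first[i] <- ij[1]; second[i] <- ij[2]; y[i] <- 1L
    }
    for (i in seq_len(n_neg)) {
      a <- by_class[[classes[1]]]; b <- by_class[[classes[2]]]
      first[n_pos + i] <- if (length(a) == 1) a else sample(a, 1)
      second[n_pos + i] <- if (length(b) == 1) b else sample(b, 1)
      y[n_pos + i] <- 0L
    }
    ord <- sample.int(n_pairs)
  })
  data.frame(first = first[ord], second = second[ord], y = y[ord])
}

#' Contrastive loss of a batch
#'
#' @param y Match labels, 1 = same class, 0 = different class.
#' @param d Nonnegative embedding distances, one per pair.
#' @param config A [loss_config()].
#' @return The scalar loss `(1/2N) sum(y d^2 + (1-y) max(margin-d,0)^2)`.
#' @export
contrastive_loss <- function(y, d, config = loss_config()) {
  osm_check(length(y) == length(d) && length(y) >= 1,
            "y and d must be nonempty vectors of equal length")
  osm_check(all(y %in% c(0, 1)), "y must be 0/1")
  osm_check(all(d >= 0), "distances must be nonnegative")
  margin <- config$margin
  sum(y * d^2 + (1 - y) * pmax(margin - d, 0)^2) / (2 * length(y))
}

# dL/dd per pair (same 1/2N scaling as the loss).
contrastive_loss_ddist <- function(y, d, margin) {
  (y * d - (1 - y) * pmax(margin - d, 0)) / length(y)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (key in names(grads)) {
    if (grepl("run_(mean|var)$", key)) next  # batch-norm statistics
    g <- grads[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    params[[key]] <- params[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Forward/backward of one batch of pairs; returns the loss and the flat
# gradient accumulated over both arms of every pair (shared weights).
pair_batch_grad <- function(net, tensors, batch, margin, training = TRUE) {
  n <- nrow(batch)
  e1 <- vector("list", n); e2 <- vector("list", n)
  c1 <- vector("list", n); c2 <- vector("list", n)
  run_updates <- list()
  for (i in seq_len(n)) {
    f1 <- forward_net(net, tensors[[batch$first[i]]], training = training, keep = TRUE)
    f2 <- forward_net(net, tensors[[batch$second[i]]], training = training, keep = TRUE)
    e1[[i]] <- f1$out; e2[[i]] <- f2$out
    c1[[i]] <- f1$caches; c2[[i]] <- f2$caches
    run_updates <- modifyList(run_updates, f1$run_updates)
    run_updates <- modifyList(run_updates, f2$run_updates)
  }
  d <- vapply(seq_len(n), function(i) sqrt(sum((e1[[i]] - e2[[i]])^2)), 0)
  loss <- contrastive_loss(batch$y, d, loss_config(margin))
  gd <- contrastive_loss_ddist(batch$y, d, margin)
  total <- NULL
  for (i in seq_len(n)) {
    if (d[i] > 0) {
      de1 <- gd[i] * (e1[[i]] - e2[[i]]) / d[i]
    } else {
      de1 <- 0 * e1[[i]]  # subgradient at coincident embeddings
    }
    g1 <- backward_net(net, c1[[i]], de1)
    g2 <- backward_net(net, c2[[i]], -de1)
    add <- function(tot, g) {
      if (is.null(tot)) return(g)
      for (k in names(g)) tot[[k]] <- tot[[k]] + g[[k]]
      tot
    }
    total <- add(add(total, g1), g2)
  }
  list(loss = loss, grads = total, d = d, run_updates = run_updates)
}

apply_run_updates <- function(net, run_updates) {
  for (key in names(run_updates)) {
    i <- as.integer(key)
    net$layers[[i]]$params$run_mean <- run_updates[[key]]$run_mean
    net$layers[[i]]$params$run_var <- run_updates[[key]]$run_var
  }
  net
}

#' Train a branch network with contrastive pairs
#'
#' Each epoch samples fresh pairs (seed derived from `tcfg$seed` and the
#' epoch number), steps Adam on mini-batches of `batch_size` pairs, and
#' records the epoch mean loss. Fully reproducible: the same
#' (net, data, configs) produce identical histories and parameters.
#'
#' @param net An `osm_branch` (modified copy is returned).
#' @param data An `osm_dataset` from [load_dataset()], or an
#'   `osm_manifest` (then `pre` is used to load it).
#' @param tcfg A [train_config()].
#' @param lcfg A [loss_config()].
#' @param pre A [preprocess_spec()] when `data` is a manifest.
#' @param checkpoint Optional path; if given, a checkpoint plus JSON
#'   sidecar (seeds, epochs, loss curve) is written at the end.
#' @return List with `net` (trained branch) and `history` (data frame
#'   `epoch, mean_loss`).
#' @export
train_model <- function(net, data, tcfg = train_config(),
                        lcfg = loss_config(), pre = NULL, checkpoint = NULL) {
  if (inherits(data, "osm_manifest")) {
    data <- load_dataset(data, pre %||% preprocess_spec(side = net$config$input_size))
  }
  osm_check(inherits(data, "osm_dataset"), "data must be a dataset or manifest")
  n_imgs <- length(data$tensors)
  n_pairs <- tcfg$pairs_per_epoch %||% n_imgs
  params <- collect_params(net$layers)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0))
  for (epoch in seq_len(tcfg$epochs)) {
    pairs <- sample_pairs(data$labels, n_pairs, tcfg$positive_fraction,
                          seed = derive_seed(tcfg$seed, epoch))
    losses <- numeric(0); sizes <- integer(0)
    starts <- seq(1, n_pairs, by = tcfg$batch_size)
    for (bi in seq_along(starts)) {
      rows <- starts[bi]:min(starts[bi] + tcfg$batch_size - 1L, n_pairs)
      batch <- pairs[rows, , drop = FALSE]
      res <- pair_batch_grad(net, data$tensors, batch, lcfg$margin)
      if (!is.finite(res$loss)) {
        osm_stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi))
      }
      upd <- adam_step(params, res$grads, state, tcfg$learning_rate)
      params <- upd$params; state <- upd$state
      net$layers <- assign_params(net$layers, params)
      net <- apply_run_updates(net, res$run_updates)
      losses <- c(losses, res$loss); sizes <- c(sizes, length(rows))
    }
    history <- rbind(history, data.frame(
      epoch = epoch, mean_loss = sum(losses * sizes) / sum(sizes)))
  }
  if (!is.null(checkpoint)) {
    save_checkpoint(net, checkpoint,
                    provenance = list(seed = tcfg$seed, epochs = tcfg$epochs,
                                      learning_rate = tcfg$learning_rate,
                                      batch_size = tcfg$batch_size,
                                      loss_history = history$mean_loss))
  }
  list(net = net, history = history)
}

#' Write a loss history as CSV
#'
#' @param history Data frame `epoch, mean_loss` from [train_model()].
#' @param path Output CSV path.
#' @export
write_loss_history <- function(history, path) {
  write.csv(history, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
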
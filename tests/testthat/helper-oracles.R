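# Independent brute-force oracles. These are written as plain loops over
# definitions, deliberately sharing no code with the package internals,
# so that agreement is evidence of correctness rather than tautology.

# Channel attention by direct pooling + matrix arithmetic.
oracle_channel_attention <- function(F, block) {
  C <- dim(F)[1]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    plane <- F[c, , ]
    avg[c] <- mean(plane)
    mx[c] <- max(plane)
  }
  p <- block$params
  mlp <- function(v) {
    h <- as.vector(p$W1 %*% v + p$b1)
    h[h < 0] <- 0
    as.vector(p$W2 %*% h + p$b2)
  }
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

# Spatial attention by per-pixel channel pooling and a naive convolution
# triple loop with zero padding.
oracle_spatial_attention <- function(F, block) {
  d <- dim(F); C <- d[1]; H <- d[2]; W <- d[3]
  avg <- matrix(0, H, W); mx <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- F[, i, j]
    avg[i, j] <- mean(v)
    mx[i, j] <- max(v)
  }
  k <- block$kernel
  half <- (k - 1) / 2
  wts <- block$params$Ws  # 1 x (2*k*k), channel fastest, then ki, then kj
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- block$params$bs
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- i + ki - 1 - half; jj <- j + kj - 1 - half
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        w_avg <- wts[1, 1 + 2 * (ki - 1) + 2 * k * (kj - 1)]
        w_max <- wts[1, 2 + 2 * (ki - 1) + 2 * k * (kj - 1)]
        acc <- acc + w_avg * avg[ii, jj] + w_max * mx[ii, jj]
      }
    }
    out[i, j] <- 1 / (1 + exp(-acc))
  }
  out
}

# Exhaustive KNN with the same published decision rule: sort by
# (distance, insertion order), majority vote, nearest wins a vote tie.
oracle_knn <- function(emb, labels, query, k) {
  n <- nrow(emb)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sqrt(sum((emb[i, ] - query)^2))
  ord <- order(d, seq_len(n))
  sel <- ord[1:k]
  tab <- table(labels[sel])
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1) winners else labels[sel[1]]
}

# Naive per-pair contrastive loss loop.
oracle_contrastive <- function(y, d, margin) {
  tot <- 0
  for (i in seq_along(y)) {
    tot <- tot + y[i] * d[i]^2 + (1 - y[i]) * max(margin - d[i], 0)^2
  }
  tot / (2 * length(y))
}

random_feature_map <- function(C = NULL, H = NULL, W = NULL) {
  C <- C %||% sample(1:6, 1)
  H <- H %||% sample(2:7, 1)
  W <- W %||% sample(2:7, 1)
  array(rnorm(C * H * W), dim = c(C, H, W))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
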
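# Minimal CPU tensor-layer library used by the siamese branch networks.
# Tensors are numeric arrays in channels-first C x H x W layout. Forward
# passes optionally keep caches; backward passes consume them and return
# parameter gradients plus the gradient w.r.t. the layer input. The
# convolution uses im2col: patches are gathered with a precomputed linear
# index matrix so that conv forward is a single matrix product.

pad_chw <- function(x, p, value = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(value, dim = c(d[1], d[2] + 2 * p, d[3] + 2 * p))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3])] <- x
  out
}

# Linear indices into a padded C x Hp x Wp array for im2col: rows index
# (channel, kernel row, kernel col) with channel fastest, columns index
# output positions (oh fastest, then ow).
im2col_index <- function(C, Hp, Wp, k, stride) {
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  cv <- rep(seq_len(C), times = k * k)
  iv <- rep(rep(seq_len(k), each = C), times = k)
  jv <- rep(seq_len(k), each = C * k)
  rowbase <- cv + C * (iv - 1L) + C * Hp * (jv - 1L)
  oh <- rep(seq_len(Ho), times = Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  colbase <- C * (oh - 1L) * stride + C * Hp * (ow - 1L) * stride
  list(lin = outer(rowbase, colbase, "+"), Ho = Ho, Wo = Wo)
}

conv_forward <- function(x, W, b, k, stride = 1L, pad = 0L, keep = FALSE) {
  d <- dim(x)
  xp <- pad_chw(x, pad)
  ix <- im2col_index(d[1], dim(xp)[2], dim(xp)[3], k, stride)
  patches <- matrix(xp[ix$lin], nrow = nrow(ix$lin))
  out <- W %*% patches + b
  res <- list(out = array(out, dim = c(nrow(W), ix$Ho, ix$Wo)))
  if (keep) {
    res$cache <- list(patches = patches, lin = ix$lin, dims = d,
                      pdims = dim(xp), k = k, stride = stride, pad = pad)
  }
  res
}

conv_backward <- function(dout, W, cache) {
  co <- dim(dout)[1]
  dm <- matrix(dout, nrow = co)
  dW <- dm %*% t(cache$patches)
  db <- rowSums(dm)
  dpatch <- crossprod(W, dm)
  dxp <- numeric(prod(cache$pdims))
  idx <- as.vector(cache$lin)
  acc <- rowsum(as.vector(dpatch), idx)
  dxp[as.integer(rownames(acc))] <- acc
  dxp <- array(dxp, dim = cache$pdims)
  p <- cache$pad
  d <- cache$dims
  dx <- if (p > 0) dxp[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), drop = FALSE] else dxp
  list(dW = dW, db = db, dx = dx)
}

maxpool_forward <- function(x, k, stride, pad = 0L, keep = FALSE) {
  d <- dim(x)
  xp <- pad_chw(x, pad, value = -Inf)
  C <- d[1]; Hp <- dim(xp)[2]; Wp <- dim(xp)[3]
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  iv <- rep(seq_len(k), times = k)
  jv <- rep(seq_len(k), each = k)
  rowbase <- C * (iv - 1L) + C * Hp * (jv - 1L)
  cv <- rep(seq_len(C), times = Ho * Wo)
  ohv <- rep(rep(seq_len(Ho), each = C), times = Wo)
  owv <- rep(seq_len(Wo), each = C * Ho)
  colbase <- cv + C * (ohv - 1L) * stride + C * Hp * (owv - 1L) * stride
  lin <- outer(rowbase, colbase, "+")
  vals <- matrix(xp[lin], nrow = k * k)
  amax <- max.col(t(vals), ties.method = "first")
  sel <- cbind(amax, seq_along(amax))
  out <- array(vals[sel], dim = c(C, Ho, Wo))
  res <- list(out = out)
  if (keep) {
    res$cache <- list(srcidx = lin[sel], pdims = dim(xp), dims = d, pad = pad)
  }
  res
}

maxpool_backward <- function(dout, cache) {
  dxp <- numeric(prod(cache$pdims))
  acc <- rowsum(as.vector(dout), cache$srcidx)
  dxp[as.integer(rownames(acc))] <- acc
  dxp <- array(dxp, dim = cache$pdims)
  p <- cache$pad
  d <- cache$dims
  if (p > 0) dxp[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), drop = FALSE] else dxp
}

bn_forward <- function(x, layer, training = FALSE, keep = FALSE) {
  C <- dim(x)[1]
  xm <- matrix(x, nrow = C)
  eps <- layer$eps
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
  } else {
    mu <- layer$params$run_mean
    v <- layer$params$run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  out <- array(xhat * layer$params$gamma + layer$params$beta, dim = dim(x))
  res <- list(out = out)
  if (training) {
    res$new_run <- list(
      run_mean = (1 - layer$momentum) * layer$params$run_mean + layer$momentum * mu,
      run_var = (1 - layer$momentum) * layer$params$run_var + layer$momentum * v)
  }
  if (keep) res$cache <- list(xhat = xhat, inv = inv, xm = xm, mu = mu, dims = dim(x))
  res
}

bn_backward <- function(dout, layer, cache) {
  C <- dim(dout)[1]
  dm <- matrix(dout, nrow = C)
  n <- ncol(dm)
  dgamma <- rowSums(dm * cache$xhat)
  dbeta <- rowSums(dm)
  dxhat <- dm * layer$params$gamma
  # standard normalization backward over the per-channel spatial sample
  dx <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$inv
  list(dgamma = dgamma, dbeta = dbeta, dx = array(dx, dim = cache$dims))
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# ------------------------------------------------------ layer constructors

layer_conv <- function(cin, cout, k, stride = 1L, pad = 0L) {
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), cin = cin, cout = cout,
       params = list(W = he_init(cout, cin * k * k, cin * k * k),
                     b = numeric(cout)))
}

layer_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", eps = eps, momentum = momentum,
       params = list(gamma = rep(1, c), beta = numeric(c),
                     run_mean = numeric(c), run_var = rep(1, c)))
}

layer_relu <- function() list(type = "relu", params = list())

layer_maxpool <- function(k, stride = k, pad = 0L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), params = list())
}

layer_flatten <- function() list(type = "flatten", params = list())

layer_gap <- function() list(type = "gap", params = list())

layer_fc <- function(nin, nout) {
  list(type = "fc", params = list(W = he_init(nout, nin, nin),
                                  b = numeric(nout)))
}

layer_attention <- function(c, config) {
  hidden <- max(floor(c / config$reduction), 1L)
  k <- config$kernel
  list(type = "attention", channel = config$channel, spatial = config$spatial,
       kernel = k, C = c, hidden = hidden,
       params = list(
         W1 = he_init(hidden, c, c), b1 = numeric(hidden),
         W2 = he_init(c, hidden, hidden), b2 = numeric(c),
         Ws = he_init(1, 2 * k * k, 2 * k * k), bs = numeric(1)))
}

layer_resblock <- function(cin, cout, stride = 1L) {
  down <- if (stride != 1L || cin != cout) {
    list(conv = layer_conv(cin, cout, 1L, stride = stride, pad = 0L),
         bn = layer_bn(cout))
  }
  list(type = "resblock",
       sub = list(conv1 = layer_conv(cin, cout, 3L, stride = stride, pad = 1L),
                  bn1 = layer_bn(cout),
                  conv2 = layer_conv(cout, cout, 3L, stride = 1L, pad = 1L),
                  bn2 = layer_bn(cout)),
       down = down, params = list())
}

# -------------------------------------------------- forward / backward

# Attention forward: channel gate first (sigmoid over the shared-MLP sum
# of spatially average- and max-pooled descriptors), then spatial gate
# (sigmoid over a kxk convolution of the channel-wise average/max planes).
attention_forward <- function(layer, x, keep = FALSE) {
  d <- dim(x)
  C <- d[1]; HW <- d[2] * d[3]
  p <- layer$params
  cache <- list(dims = d)
  xm <- matrix(x, nrow = C)
  if (layer$channel) {
    a <- rowMeans(xm)
    amax_ch <- max.col(xm, ties.method = "first")
    m <- xm[cbind(seq_len(C), amax_ch)]
    pre_a <- p$W1 %*% a + p$b1
    pre_m <- p$W1 %*% m + p$b1
    h_a <- pmax(pre_a, 0); h_m <- pmax(pre_m, 0)
    z <- p$W2 %*% h_a + p$b2 + p$W2 %*% h_m + p$b2
    mc <- as.vector(sigmoid(z))
    x1m <- xm * mc
    if (keep) {
      cache <- c(cache, list(xm = xm, a = a, m = m, amax_ch = amax_ch,
                             pre_a = pre_a, pre_m = pre_m, h_a = h_a,
                             h_m = h_m, mc = mc))
    }
  } else {
    mc <- rep(1, C)
    x1m <- xm
  }
  if (layer$spatial) {
    avg_s <- colMeans(x1m)
    amax_sp <- max.col(t(x1m), ties.method = "first")
    max_s <- x1m[cbind(amax_sp, seq_len(HW))]
    desc <- array(rbind(avg_s, max_s), dim = c(2L, d[2], d[3]))
    k <- layer$kernel
    cf <- conv_forward(desc, p$Ws, p$bs, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       keep = keep)
    ms <- as.vector(sigmoid(cf$out))
    outm <- x1m * rep(ms, each = C)
    if (keep) {
      cache <- c(cache, list(x1m = x1m, amax_sp = amax_sp, ms = ms,
                             conv_cache = cf$cache))
    }
  } else {
    ms <- rep(1, HW)
    outm <- x1m
  }
  list(out = array(outm, dim = d), mc = mc, ms = ms,
       cache = if (keep) cache else NULL)
}

attention_backward <- function(layer, dout, cache) {
  d <- cache$dims
  C <- d[1]; HW <- d[2] * d[3]
  p <- layer$params
  dm <- matrix(dout, nrow = C)
  g <- list(W1 = 0 * p$W1, b1 = 0 * p$b1, W2 = 0 * p$W2, b2 = 0 * p$b2,
            Ws = 0 * p$Ws, bs = 0 * p$bs)
  if (layer$spatial) {
    x1m <- cache$x1m
    dx1 <- dm * rep(cache$ms, each = C)
    dms <- colSums(dm * x1m)
    dzs <- dms * cache$ms * (1 - cache$ms)
    cb <- conv_backward(array(dzs, dim = c(1L, d[2], d[3])), p$Ws,
                        cache$conv_cache)
    g$Ws <- cb$dW; g$bs <- cb$db
    ddesc <- matrix(cb$dx, nrow = 2)
    dx1 <- dx1 + matrix(rep(ddesc[1, ] / C, each = C), nrow = C)
    idx <- cbind(cache$amax_sp, seq_len(HW))
    dx1[idx] <- dx1[idx] + ddesc[2, ]
  } else {
    dx1 <- dm
  }
  if (layer$channel) {
    xm <- cache$xm
    dx <- dx1 * cache$mc
    dmc <- rowSums(dx1 * xm)
    dz <- dmc * cache$mc * (1 - cache$mc)
    g$W2 <- dz %*% t(cache$h_a) + dz %*% t(cache$h_m)
    g$b2 <- 2 * dz
    dh_a <- crossprod(p$W2, dz)
    dh_m <- crossprod(p$W2, dz)
    dpre_a <- dh_a * (cache$pre_a > 0)
    dpre_m <- dh_m * (cache$pre_m > 0)
    g$W1 <- dpre_a %*% t(cache$a) + dpre_m %*% t(cache$m)
    g$b1 <- as.vector(dpre_a + dpre_m)
    da <- as.vector(crossprod(p$W1, dpre_a))
    dmv <- as.vector(crossprod(p$W1, dpre_m))
    dx <- dx + da / HW
    idx <- cbind(seq_len(C), cache$amax_ch)
    dx[idx] <- dx[idx] + dmv
  } else {
    dx <- dx1
  }
  list(dx = array(dx, dim = d), grads = g)
}

layer_forward <- function(layer, x, training = FALSE, keep = FALSE) {
  switch(layer$type,
    conv = conv_forward(x, layer$params$W, layer$params$b, layer$k,
                        layer$stride, layer$pad, keep = keep),
    bn = bn_forward(x, layer, training = training, keep = keep),
    relu = {
      out <- pmax(x, 0)
      list(out = if (is.array(x)) array(out, dim = dim(x)) else out,
           cache = if (keep) list(mask = x > 0) else NULL)
    },
    maxpool = maxpool_forward(x, layer$k, layer$stride, layer$pad, keep = keep),
    flatten = list(out = as.vector(x),
                   cache = if (keep) list(dims = dim(x)) else NULL),
    gap = {
      C <- dim(x)[1]
      list(out = rowMeans(matrix(x, nrow = C)),
           cache = if (keep) list(dims = dim(x)) else NULL)
    },
    fc = list(out = as.vector(layer$params$W %*% x + layer$params$b),
              cache = if (keep) list(x = x) else NULL),
    attention = attention_forward(layer, x, keep = keep),
    resblock = {
      cc <- list()
      f1 <- layer_forward(layer$sub$conv1, x, training, keep); cc$conv1 <- f1$cache
      f2 <- layer_forward(layer$sub$bn1, f1$out, training, keep); cc$bn1 <- f2$cache
      h <- pmax(f2$out, 0)
      if (keep) cc$relu1 <- list(mask = f2$out > 0)
      f3 <- layer_forward(layer$sub$conv2, h, training, keep); cc$conv2 <- f3$cache
      f4 <- layer_forward(layer$sub$bn2, f3$out, training, keep); cc$bn2 <- f4$cache
      if (!is.null(layer$down)) {
        s1 <- layer_forward(layer$down$conv, x, training, keep); cc$dconv <- s1$cache
        s2 <- layer_forward(layer$down$bn, s1$out, training, keep); cc$dbn <- s2$cache
        sc <- s2$out
      } else sc <- x
      pre <- f4$out + sc
      if (keep) cc$relu2 <- list(mask = pre > 0)
      list(out = array(pmax(pre, 0), dim = dim(pre)), cache = if (keep) cc else NULL)
    },
    osm_stop(sprintf("unknown layer type '%s'", layer$type))
  )
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      cb <- conv_backward(dout, layer$params$W, cache)
      list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db))
    },
    bn = {
      bb <- bn_backward(dout, layer, cache)
      list(dx = bb$dx, grads = list(gamma = bb$dgamma, beta = bb$dbeta,
                                    run_mean = 0 * layer$params$run_mean,
                                    run_var = 0 * layer$params$run_var))
    },
    relu = list(dx = dout * cache$mask, grads = list()),
    maxpool = list(dx = maxpool_backward(dout, cache), grads = list()),
    flatten = list(dx = array(dout, dim = cache$dims), grads = list()),
    gap = {
      d <- cache$dims
      list(dx = array(rep(dout, times = d[2] * d[3]) / (d[2] * d[3]), dim = d),
           grads = list())
    },
    fc = list(dx = as.vector(crossprod(layer$params$W, dout)),
              grads = list(W = dout %*% t(cache$x), b = as.vector(dout))),
    attention = attention_backward(layer, dout, cache),
    resblock = {
      dpre <- dout * cache$relu2$mask
      b4 <- layer_backward(layer$sub$bn2, dpre, cache$bn2)
      b3 <- layer_backward(layer$sub$conv2, b4$dx, cache$conv2)
      dh <- b3$dx * cache$relu1$mask
      b2 <- layer_backward(layer$sub$bn1, dh, cache$bn1)
      b1 <- layer_backward(layer$sub$conv1, b2$dx, cache$conv1)
      grads <- list(conv1 = b1$grads, bn1 = b2$grads,
                    conv2 = b3$grads, bn2 = b4$grads)
      if (!is.null(layer$down)) {
        s2 <- layer_backward(layer$down$bn, dpre, cache$dbn)
        s1 <- layer_backward(layer$down$conv, s2$dx, cache$dconv)
        grads$dconv <- s1$grads
        grads$dbn <- s2$grads
        dx <- b1$dx + s1$dx
      } else {
        dx <- b1$dx + dpre
      }
      list(dx = dx, grads = grads)
    }
  )
}

# ----------------------------------------------- parameter (de)flattening

# Collect every trainable array of a layer list into one flat named list
# ("L3.W", "L9.conv1.b", ...). Used by the optimizer, checkpointing and
# the finite-difference tests. BatchNorm running statistics are carried
# as parameters (so checkpoints round-trip) but the optimizer skips them.

collect_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    tag <- paste0("L", i)
    if (ly$type == "resblock") {
      for (nm in names(ly$sub)) {
        for (pn in names(ly$sub[[nm]]$params)) {
          out[[paste(tag, nm, pn, sep = ".")]] <- ly$sub[[nm]]$params[[pn]]
        }
      }
      if (!is.null(ly$down)) {
        for (pn in names(ly$down$conv$params)) {
          out[[paste(tag, "dconv", pn, sep = ".")]] <- ly$down$conv$params[[pn]]
        }
        for (pn in names(ly$down$bn$params)) {
          out[[paste(tag, "dbn", pn, sep = ".")]] <- ly$down$bn$params[[pn]]
        }
      }
    } else if (length(ly$params)) {
      for (pn in names(ly$params)) {
        out[[paste(tag, pn, sep = ".")]] <- ly$params[[pn]]
      }
    }
  }
  out
}

assign_params <- function(layers, flat) {
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    i <- as.integer(sub("^L", "", parts[1]))
    if (length(parts) == 2) {
      layers[[i]]$params[[parts[2]]] <- flat[[key]]
    } else if (parts[2] == "dconv") {
      layers[[i]]$down$conv$params[[parts[3]]] <- flat[[key]]
    } else if (parts[2] == "dbn") {
      layers[[i]]$down$bn$params[[parts[3]]] <- flat[[key]]
    } else {
      layers[[i]]$sub[[parts[2]]]$params[[parts[3]]] <- flat[[key]]
    }
  }
  layers
}

# Flatten per-layer gradient lists into the same naming scheme.
collect_grads <- function(layers, grads_by_layer) {
  out <- list()
  for (i in seq_along(layers)) {
    g <- grads_by_layer[[i]]
    if (is.null(g) || !length(g)) next
    tag <- paste0("L", i)
    if (layers[[i]]$type == "resblock") {
      for (nm in names(g)) {
        for (pn in names(g[[nm]])) {
          out[[paste(tag, nm, pn, sep = ".")]] <- g[[nm]][[pn]]
        }
      }
    } else {
      for (pn in names(g)) out[[paste(tag, pn, sep = ".")]] <- g[[pn]]
    }
  }
  out
}
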
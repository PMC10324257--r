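layer_types <- function(net) vapply(net$layers, `[[`, "", "type")

test_that("the vgg16 branch has 13 3x3 convs, 5 pools, attention, 3-layer head", {
  net <- build_branch(branch_config("vgg16"), seed = 1)
  tt <- layer_types(net)
  convs <- net$layers[tt == "conv"]
  expect_length(convs, 13)
  expect_true(all(vapply(convs, `[[`, 0L, "k") == 3L))
  expect_equal(sum(tt == "maxpool"), 5)
  expect_equal(sum(tt == "attention"), 1)
  fcs <- net$layers[tt == "fc"]
  expect_length(fcs, 3)
  expect_equal(vapply(fcs, function(l) nrow(l$params$W), 0L), c(4096L, 512L, 100L))
  # attention sits after the last convolutional stage, before the head
  expect_gt(which(tt == "attention"), max(which(tt == "maxpool")))
  expect_lt(which(tt == "attention"), min(which(tt == "fc")))
})

test_that("alexnet and resnet18 branches build with their published stages", {
  a <- build_branch(branch_config("alexnet"), seed = 1)
  ta <- layer_types(a)
  expect_equal(sum(ta == "conv"), 5)
  expect_equal(a$layers[[1]]$k, 11L)
  expect_equal(sum(ta == "maxpool"), 3)
  fcs <- a$layers[ta == "fc"]
  expect_equal(vapply(fcs, function(l) nrow(l$params$W), 0L), c(4096L, 512L, 100L))

  r <- build_branch(branch_config("resnet18"), seed = 1)
  tr <- layer_types(r)
  expect_equal(sum(tr == "resblock"), 8)
  expect_equal(sum(tr == "attention"), 1)
  downs <- vapply(r$layers[tr == "resblock"], function(l) !is.null(l$down), TRUE)
  expect_equal(sum(downs), 3)  # one per width transition
})

test_that("builds are deterministic under the seed and pretrained mode guards", {
  n1 <- build_branch(branch_config("tiny"), seed = 4)
  n2 <- build_branch(branch_config("tiny"), seed = 4)
  expect_identical(ocusiam:::collect_params(n1$layers),
                   ocusiam:::collect_params(n2$layers))
  n3 <- build_branch(branch_config("tiny"), seed = 5)
  expect_false(identical(ocusiam:::collect_params(n1$layers),
                         ocusiam:::collect_params(n3$layers)))
  expect_error(branch_config("tiny", pretrained = TRUE), "pretrained")
  expect_error(build_branch(branch_config("vgg16", pretrained = TRUE), seed = 1),
               "random initialization")
})

test_that("the tiny branch propagates a 64x64 image to the embedding", {
  net <- build_branch(branch_config("tiny"), seed = 2)
  x <- array(rnorm(3 * 64 * 64), dim = c(3, 64, 64))
  e <- embed_image(net, x)
  expect_length(e, 16)
  expect_true(all(is.finite(e)))
  expect_error(embed_image(net, array(0, dim = c(3, 32, 32))), "shape")
})

test_that("inference is deterministic and pairs share one parameter set", {
  net <- build_branch(branch_config("tiny"), seed = 8)
  x <- array(rnorm(3 * 64 * 64), dim = c(3, 64, 64))
  y <- array(rnorm(3 * 64 * 64), dim = c(3, 64, 64))
  expect_identical(embed_image(net, x), embed_image(net, x))

  fp <- forward_pair(net, x, y)
  expect_equal(fp$d, sqrt(sum((fp$e1 - fp$e2)^2)), tolerance = 1e-6)
  expect_equal(fp$d, forward_pair(net, y, x)$d)
  expect_equal(forward_pair(net, x, x)$d, 0)

  # weight sharing is exact: perturbing the branch moves both arms
  net$layers[[1]]$params$b <- net$layers[[1]]$params$b + 0.1
  fp2 <- forward_pair(net, x, x)
  expect_equal(fp2$d, 0)
  expect_false(identical(fp2$e1, fp$e1))
})

test_that("checkpoints round-trip embeddings within 1e-6", {
  net <- tiny_trained()$net
  x <- tiny_synth()$train$tensors[[1]]
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, p, provenance = list(seed = 5, epochs = 3))
  expect_true(file.exists(paste0(p, ".json")))
  back <- load_checkpoint(p)
  expect_equal(embed_image(back, x), embed_image(net, x), tolerance = 1e-6)
  expect_error(load_checkpoint(file.path(tempdir(), "none.rds")),
               class = "osm_io_error")
})

test_that("analytic gradients match finite differences on a 2-pair batch", {
  net <- build_branch(branch_config("tiny"), seed = 3)
  withr::local_seed(31)
  tensors <- lapply(1:4, function(i) array(rnorm(3 * 64 * 64, sd = 0.5),
                                           dim = c(3, 64, 64)))
  batch <- data.frame(first = c(1, 3), second = c(2, 4), y = c(1L, 0L))
  res <- ocusiam:::pair_batch_grad(net, tensors, batch, margin = 1,
                                   training = FALSE)
  params <- ocusiam:::collect_params(net$layers)
  loss_at <- function(p) {
    net$layers <- ocusiam:::assign_params(net$layers, p)
    e <- lapply(tensors, function(x) embed_image(net, x))
    d <- c(sqrt(sum((e[[1]] - e[[2]])^2)), sqrt(sum((e[[3]] - e[[4]])^2)))
    contrastive_loss(batch$y, d, loss_config(1))
  }
  eps <- 1e-5
  # every parameter tensor is probed at sampled coordinates
  for (key in names(params)) {
    if (grepl("run_", key)) next
    n <- length(params[[key]])
    idx <- if (n <= 4) seq_len(n) else sample.int(n, 4)
    for (j in idx) {
      p2 <- params
      p2[[key]][j] <- p2[[key]][j] + eps
      lp <- loss_at(p2)
      p2[[key]][j] <- p2[[key]][j] - 2 * eps
      lm <- loss_at(p2)
      fd <- (lp - lm) / (2 * eps)
      an <- res$grads[[key]][j]
      if (abs(fd) < 1e-9 && abs(an) < 1e-9) next
      expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-3,
                label = sprintf("relative gradient error at %s[%d]", key, j))
    }
  }
})
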
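# Siamese branch networks. A "branch" is the single parameter set shared
# by both arms of the siamese pair: embedding two images and taking the
# Euclidean distance between the results IS the paired forward pass, so
# weight sharing is exact by construction rather than enforced by copying.

#' Attention block configuration
#'
#' @param channel,spatial Enable the channel and/or spatial gate.
#' @param reduction Channel-MLP reduction ratio r (hidden width
#'   `max(floor(C / r), 1)`).
#' @param kernel Spatial-attention convolution kernel size (odd; default 7).
#' @export
attention_config <- function(channel = TRUE, spatial = TRUE,
                             reduction = 16, kernel = 7) {
  osm_check(kernel %% 2 == 1, "spatial attention kernel size must be odd")
  osm_check(reduction >= 1, "reduction ratio must be >= 1")
  structure(list(channel = isTRUE(channel), spatial = isTRUE(spatial),
                 reduction = reduction, kernel = as.integer(kernel)),
            class = "osm_attention_config")
}

#' Branch network configuration
#'
#' Four architectures are available. `vgg16`, `alexnet` and `resnet18`
#' follow the published stage layouts at 224 x 224 input with the
#' attention block inserted after the last convolutional stage and a
#' fully-connected embedding head (4096 -> 512 -> 100 for vgg16/alexnet;
#' 512 -> 100 after global average pooling for resnet18). `tiny` is a
#' deliberately small 3-stage variant (widths 8/16/32, 64 x 64 input,
#' head 128 -> 32 -> 16) for CPU-scale experiments and tests.
#'
#' @param architecture One of `"tiny"`, `"vgg16"`, `"alexnet"`,
#'   `"resnet18"`.
#' @param pretrained Load externally supplied weights instead of random
#'   initialization; requires `weights_file`. Never available for
#'   `tiny`.
#' @param weights_file Optional checkpoint path whose parameters are
#'   copied onto matching tensors.
#' @param attention An [attention_config()].
#' @param embedding_dim Output embedding width; `NULL` = architecture
#'   default (100, or 16 for tiny).
#' @param input_size Input side in pixels; `NULL` = architecture default
#'   (224, or 64 for tiny).
#' @export
branch_config <- function(architecture = c("tiny", "vgg16", "alexnet", "resnet18"),
                          pretrained = FALSE, weights_file = NULL,
                          attention = attention_config(),
                          embedding_dim = NULL, input_size = NULL) {
  architecture <- match.arg(architecture)
  if (architecture == "tiny" && pretrained) {
    osm_stop("the tiny architecture has no pretrained weights")
  }
  embedding_dim <- embedding_dim %||% (if (architecture == "tiny") 16L else 100L)
  input_size <- input_size %||% (if (architecture == "tiny") 64L else 224L)
  osm_check(embedding_dim >= 2, "embedding_dim must be >= 2")
  structure(list(architecture = architecture, pretrained = isTRUE(pretrained),
                 weights_file = weights_file, attention = attention,
                 embedding_dim = as.integer(embedding_dim),
                 input_size = as.integer(input_size)),
            class = "osm_branch_config")
}

conv_bundle <- function(cin, cout, k, stride = 1L, pad = 1L) {
  list(layer_conv(cin, cout, k, stride, pad), layer_relu())
}

branch_layers <- function(config) {
  att <- config$attention
  s <- config$input_size
  if (config$architecture == "tiny") {
    layers <- c(
      conv_bundle(3L, 8L, 3L), list(layer_maxpool(2L)),
      conv_bundle(8L, 16L, 3L), list(layer_maxpool(2L)),
      conv_bundle(16L, 32L, 3L), list(layer_maxpool(2L)),
      list(layer_attention(32L, att), layer_flatten(),
           layer_fc(32L * (s %/% 8L)^2, 128L), layer_relu(),
           layer_fc(128L, 32L), layer_relu(),
           layer_fc(32L, config$embedding_dim)))
  } else if (config$architecture == "vgg16") {
    widths <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                   c(512, 512, 512), c(512, 512, 512))
    layers <- list()
    cin <- 3L
    for (stage in widths) {
      for (w in stage) {
        layers <- c(layers, conv_bundle(cin, w, 3L))
        cin <- w
      }
      layers <- c(layers, list(layer_maxpool(2L)))
    }
    side <- s %/% 32L
    layers <- c(layers, list(
      layer_attention(512L, att), layer_flatten(),
      layer_fc(512L * side^2, 4096L), layer_relu(),
      layer_fc(4096L, 512L), layer_relu(),
      layer_fc(512L, config$embedding_dim)))
  } else if (config$architecture == "alexnet") {
    layers <- c(
      conv_bundle(3L, 64L, 11L, stride = 4L, pad = 2L),
      list(layer_maxpool(3L, 2L)),
      conv_bundle(64L, 192L, 5L, pad = 2L),
      list(layer_maxpool(3L, 2L)),
      conv_bundle(192L, 384L, 3L),
      conv_bundle(384L, 256L, 3L),
      conv_bundle(256L, 256L, 3L),
      list(layer_maxpool(3L, 2L)))
    side <- if (s == 224L) 6L else osm_stop("alexnet requires 224 input")
    layers <- c(layers, list(
      layer_attention(256L, att), layer_flatten(),
      layer_fc(256L * side^2, 4096L), layer_relu(),
      layer_fc(4096L, 512L), layer_relu(),
      layer_fc(512L, config$embedding_dim)))
  } else {  # resnet18
    layers <- list(layer_conv(3L, 64L, 7L, stride = 2L, pad = 3L),
                   layer_bn(64L), layer_relu(),
                   layer_maxpool(3L, 2L, pad = 1L),
                   layer_resblock(64L, 64L), layer_resblock(64L, 64L),
                   layer_resblock(64L, 128L, stride = 2L), layer_resblock(128L, 128L),
                   layer_resblock(128L, 256L, stride = 2L), layer_resblock(256L, 256L),
                   layer_resblock(256L, 512L, stride = 2L), layer_resblock(512L, 512L),
                   layer_attention(512L, att),
                   layer_gap(),
                   layer_fc(512L, 512L), layer_relu(),
                   layer_fc(512L, config$embedding_dim))
  }
  layers
}

#' Build a branch network
#'
#' Constructs the configured architecture with seeded random
#' initialization (He-scaled normal weights, zero biases). Pretrained
#' mode copies parameters from a previously saved checkpoint supplied via
#' `config$weights_file`; attention and head parameters stay freshly
#' initialized if absent from the source.
#'
#' @param config A [branch_config()].
#' @param seed Integer seed; two builds with the same (config, seed) have
#'   identical parameters.
#' @return An `osm_branch` (shared parameter set of the siamese pair).
#' @export
build_branch <- function(config, seed = 1) {
  layers <- with_seed(seed, branch_layers(config))
  if (config$pretrained) {
    if (is.null(config$weights_file) || !file.exists(config$weights_file %||% "")) {
      osm_stop(paste("pretrained weights are unavailable: supply weights_file",
                     "or build with pretrained = FALSE for random initialization"))
    }
    src <- readRDS(config$weights_file)$params
    flat <- collect_params(layers)
    for (nm in intersect(names(src), names(flat))) {
      if (identical(dim(src[[nm]]), dim(flat[[nm]])) &&
          length(src[[nm]]) == length(flat[[nm]])) {
        flat[[nm]] <- src[[nm]]
      }
    }
    layers <- assign_params(layers, flat)
  }
  structure(list(config = config, layers = layers, seed = as.integer(seed)),
            class = "osm_branch")
}

# Full forward pass. Returns the embedding, per-layer caches when
# requested, and any batch-norm running-statistic updates accumulated in
# training mode (applied by the caller so that forward stays pure).
forward_net <- function(net, x, training = FALSE, keep = FALSE) {
  caches <- vector("list", length(net$layers))
  run_updates <- list()
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x, training = training, keep = keep)
    x <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$new_run)) run_updates[[as.character(i)]] <- r$new_run
  }
  list(out = x, caches = caches, run_updates = run_updates)
}

backward_net <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    b <- layer_backward(net$layers[[i]], dout, caches[[i]])
    grads[[i]] <- b$grads
    dout <- b$dx
  }
  collect_grads(net$layers, grads)
}

check_input <- function(net, x) {
  osm_check(is.array(x) && length(dim(x)) == 3,
            "network input must be a C x H x W array")
  d <- dim(x)
  s <- net$config$input_size
  if (d[1] != 3L || d[2] != s || d[3] != s) {
    osm_stop(sprintf("input shape %dx%dx%d does not match expected 3x%dx%d",
                     d[1], d[2], d[3], s, s))
  }
  invisible(TRUE)
}

#' Embed one preprocessed image
#'
#' Deterministic inference pass through the shared branch; the result is
#' the feature vector used for distances, the contrastive loss and KNN.
#'
#' @param net An `osm_branch`.
#' @param x A C x H x W tensor from [preprocess_image()].
#' @return Numeric vector of length `embedding_dim`.
#' @export
embed_image <- function(net, x) {
  check_input(net, x)
  forward_net(net, x, training = FALSE, keep = FALSE)$out
}

#' Paired forward pass
#'
#' Both images pass through the same parameter set; `d` is the Euclidean
#' distance between the two embeddings.
#'
#' @param net An `osm_branch`.
#' @param a,b Preprocessed C x H x W tensors.
#' @return List with `e1`, `e2` (embeddings) and `d` (distance).
#' @export
forward_pair <- function(net, a, b) {
  e1 <- embed_image(net, a)
  e2 <- embed_image(net, b)
  list(e1 = e1, e2 = e2, d = sqrt(sum((e1 - e2)^2)))
}

#' Save a branch checkpoint
#'
#' Writes a single binary blob (architecture tag, config, flattened
#' parameters) plus a JSON sidecar recording config and training
#' provenance.
#'
#' @param net An `osm_branch`.
#' @param path Checkpoint path (`.rds`).
#' @param provenance Optional list (seeds, epochs, loss history) recorded
#'   in the sidecar.
#' @export
save_checkpoint <- function(net, path, provenance = NULL) {
  obj <- list(architecture = net$config$architecture,
              config = net$config,
              params = collect_params(net$layers))
  saveRDS(obj, path)
  side <- list(architecture = net$config$architecture,
               embedding_dim = net$config$embedding_dim,
               input_size = net$config$input_size,
               attention = unclass(net$config$attention),
               provenance = provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a branch checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return An `osm_branch` with the saved parameters.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    osm_stop(sprintf("checkpoint '%s' does not exist", path),
             class = "osm_io_error")
  }
  obj <- readRDS(path)
  obj$config$pretrained <- FALSE  # parameters come from the blob itself
  net <- build_branch(obj$config, seed = 1)
  net$layers <- assign_params(net$layers, obj$params)
  net
}
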
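# Sequential channel + spatial attention over a C x H x W feature map.
# Channel gate: sigmoid(MLP(avgpool(F)) + MLP(maxpool(F))) with one MLP
# shared by both pooled descriptors. Spatial gate: sigmoid of a kxk
# convolution over the channel-wise average and maximum planes. Applied
# sequentially, channel first, each gate multiplying the feature map.

#' Construct an attention block with its parameters
#'
#' @param C Number of feature channels the block expects.
#' @param config An [attention_config()].
#' @param seed Seed for parameter initialization.
#' @return An attention block usable with [channel_attention()],
#'   [spatial_attention()] and [cbam_apply()].
#' @export
attention_block <- function(C, config = attention_config(), seed = 1) {
  with_seed(seed, layer_attention(as.integer(C), config))
}

check_feature_map <- function(F) {
  osm_check(is.array(F) && length(dim(F)) == 3 && all(is.finite(F)),
            "feature map must be a finite C x H x W array")
}

#' Channel attention map
#'
#' Spatial average- and max-pooled descriptors of the feature map pass
#' through the block's shared two-layer MLP; the two outputs are added
#' element-wise and squashed by a sigmoid, yielding one weight per
#' channel.
#'
#' @param F A C x H x W feature map.
#' @param block An [attention_block()] built for `C` channels.
#' @return A C x 1 x 1 array of weights strictly inside (0, 1).
#' @export
channel_attention <- function(F, block) {
  check_feature_map(F)
  C <- dim(F)[1]
  osm_check(ncol(block$params$W1) == C,
            sprintf("attention block expects %d channels, feature map has %d",
                    ncol(block$params$W1), C))
  p <- block$params
  xm <- matrix(F, nrow = C)
  a <- rowMeans(xm)
  m <- apply(xm, 1, max)
  mlp <- function(v) p$W2 %*% pmax(p$W1 %*% v + p$b1, 0) + p$b2
  array(sigmoid(as.vector(mlp(a) + mlp(m))), dim = c(C, 1L, 1L))
}

#' Spatial attention map
#'
#' The channel-wise average and maximum planes of the feature map are
#' stacked into a 2-channel descriptor and convolved with a single
#' odd-sized kernel (default 7 x 7, symmetric padding), then squashed by
#' a sigmoid, yielding one weight per spatial position.
#'
#' @param F A C x H x W feature map.
#' @param block An [attention_block()].
#' @return A 1 x H x W array of weights strictly inside (0, 1).
#' @export
spatial_attention <- function(F, block) {
  check_feature_map(F)
  d <- dim(F)
  k <- block$kernel
  osm_check(k %% 2 == 1, "spatial attention kernel size must be odd")
  xm <- matrix(F, nrow = d[1])
  desc <- array(rbind(colMeans(xm), apply(xm, 2, max)), dim = c(2L, d[2], d[3]))
  z <- conv_forward(desc, block$params$Ws, block$params$bs, k,
                    stride = 1L, pad = (k - 1L) %/% 2L)$out
  array(sigmoid(z), dim = c(1L, d[2], d[3]))
}

#' Apply the sequential attention block to a feature map
#'
#' `F` is first scaled channel-wise by the channel attention map
#' (broadcast over space), then position-wise by the spatial attention
#' map of the intermediate result (broadcast over channels). Disabled
#' gates are the identity; the output shape always equals the input
#' shape.
#'
#' @param F A C x H x W feature map.
#' @param block An [attention_block()].
#' @return The reweighted feature map, same shape as `F`.
#' @export
cbam_apply <- function(F, block) {
  check_feature_map(F)
  attention_forward(block, F, keep = FALSE)$out
}

#' Export a spatial-attention overlay image
#'
#' Upsamples the spatial attention map to the image size (bilinear) and
#' alpha-blends a false-color heat rendering onto the grayscale image, so
#' that the regions the network attends to are visible.
#'
#' @param img An `osm_image`, H x W x C array, or a normalized tensor
#'   from [normalize_image()] (de-normalized automatically).
#' @param ms A 1 x h x w spatial attention map.
#' @param path Output PNG path.
#' @param alpha Blend weight of the heat layer in `[0, 1]`.
#' @return The decoded overlay (invisibly), after writing `path`.
#' @export
export_attention_overlay <- function(img, ms, path, alpha = 0.45) {
  if (is.array(img) && length(dim(img)) == 3 && !inherits(img, "osm_image") &&
      !is.null(attr(img, "norm"))) {
    img <- denormalize_tensor(img)
  }
  img <- as_osm_image(img)
  h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
  osm_check(is.array(ms) && length(dim(ms)) == 3 && dim(ms)[1] == 1,
            "ms must be a 1 x h x w spatial attention map")
  mhw <- matrix(ms[1, , ], nrow = dim(ms)[2])
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(t(mhw)), w = w, h = h,
                                           filter = "bilinear"))
  up <- t(up)
  rng <- range(up)
  heat <- if (diff(rng) > 0) (up - rng[1]) / diff(rng) else up * 0 + 0.5
  gray <- if (dim(img$pixels)[3] == 3) {
    0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] + 0.114 * img$pixels[, , 3]
  } else img$pixels[, , 1]
  # red-yellow heat ramp over the grayscale base
  overlay <- array(0, dim = c(h, w, 3))
  overlay[, , 1] <- clamp01((1 - alpha) * gray + alpha * heat)
  overlay[, , 2] <- clamp01((1 - alpha) * gray + alpha * heat^2)
  overlay[, , 3] <- clamp01((1 - alpha) * gray)
  out <- tryCatch(png::writePNG(overlay, path), error = function(e) e)
  if (inherits(out, "error")) {
    osm_stop(sprintf("cannot write overlay '%s': %s", path,
                     conditionMessage(out)), class = "osm_io_error")
  }
  invisible(new_osm_image(overlay))
}
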
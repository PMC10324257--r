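# Image loading, geometry, normalization, manifests, splits and
# traditional augmentation. Internal raster convention: numeric array
# H x W x C with intensities in [0,1], origin top-left, y downward.
# EBImage stores x (width) first, so the two helpers below transpose.

eb_to_hwc <- function(eb) {
  x <- EBImage::imageData(eb)
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1L))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]  # drop alpha
  aperm(x, c(2, 1, 3))
}

hwc_to_eb <- function(pixels) {
  cm <- if (dim(pixels)[3] == 1) "Grayscale" else "Color"
  x <- aperm(pixels, c(2, 1, 3))
  if (cm == "Grayscale") x <- x[, , 1]
  EBImage::Image(x, colormode = cm)
}

new_osm_image <- function(pixels, source_path = NA_character_) {
  osm_check(is.array(pixels) && length(dim(pixels)) == 3,
            "image pixels must be an H x W x C array")
  osm_check(dim(pixels)[3] %in% c(1L, 3L), "channel count must be 1 or 3")
  osm_check(all(is.finite(pixels)) && min(pixels) >= 0 && max(pixels) <= 1,
            "pixel values must be finite and in [0,1]")
  structure(list(pixels = pixels, source_path = source_path),
            class = "osm_image")
}

as_osm_image <- function(x) {
  if (inherits(x, "osm_image")) return(x)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  new_osm_image(x)
}

#' Load a PNG or JPEG image
#'
#' Decodes an image file to a height x width x channels array of
#' intensities in `[0, 1]` (8-bit value 255 maps to 1). Single-channel
#' images can be replicated to three channels so that they feed
#' three-channel backbones.
#'
#' @param path Path to a PNG or JPEG file.
#' @param expand_gray Replicate a single grayscale channel to 3 channels.
#' @return An `osm_image`: list with `pixels` (H x W x C array) and
#'   `source_path`.
#' @export
load_image <- function(path, expand_gray = FALSE) {
  if (!file.exists(path)) {
    osm_stop(sprintf("cannot read image '%s': file does not exist", path),
             class = "osm_io_error")
  }
  eb <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) {
      osm_stop(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)),
               class = "osm_io_error")
    }
  )
  px <- clamp01(eb_to_hwc(eb))
  if (expand_gray && dim(px)[3] == 1) {
    px <- array(rep(px, 3), dim = c(dim(px)[1:2], 3L))
  }
  new_osm_image(px, source_path = path)
}

#' Write an image to a PNG file
#'
#' @param img An `osm_image` or H x W x C array in `[0, 1]`.
#' @param path Output path; parent directory must exist and be writable.
#' @export
write_image <- function(img, path) {
  img <- as_osm_image(img)
  ok <- tryCatch({
    EBImage::writeImage(hwc_to_eb(img$pixels), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    osm_stop(sprintf("cannot write image '%s': %s", path, conditionMessage(ok)),
             class = "osm_io_error")
  }
  invisible(path)
}

#' Crop rectangle specification
#'
#' Pixel coordinates with the origin at the top-left corner, x growing
#' rightward and y downward; the rectangle is half-open,
#' `[x1, x2) x [y1, y2)`, so its size is `(x2 - x1) x (y2 - y1)` with no
#' off-by-one ambiguity.
#'
#' @param x1,y1 Top-left corner (0-based).
#' @param x2,y2 Exclusive bottom-right corner.
#' @export
crop_spec <- function(x1, y1, x2, y2) {
  osm_check(x1 >= 0 && y1 >= 0 && x1 < x2 && y1 < y2,
            "crop rectangle requires 0 <= x1 < x2 and 0 <= y1 < y2")
  structure(list(x1 = as.integer(x1), y1 = as.integer(y1),
                 x2 = as.integer(x2), y2 = as.integer(y2)),
            class = "osm_crop_spec")
}

#' Default fundus window
#'
#' The fixed acquisition geometry of the ultrasound device places the
#' fundus in the same region of every scan; this 300 x 250 window
#' (x in `[100, 400)`, y in `[50, 300)`) keeps the fundus and discards
#' the dark surround.
#'
#' @export
fundus_crop_spec <- function() crop_spec(100, 50, 400, 300)

#' Crop an image to a rectangle
#'
#' @param img An `osm_image` or H x W x C array.
#' @param spec An [crop_spec()].
#' @return The cropped `osm_image`; output pixel `(i, j)` equals input
#'   pixel `(y1 + i, x1 + j)`.
#' @export
crop_fundus <- function(img, spec = fundus_crop_spec()) {
  img <- as_osm_image(img)
  d <- dim(img$pixels)
  if (spec$x2 > d[2] || spec$y2 > d[1]) {
    osm_stop(sprintf(
      "crop rectangle [%d,%d)x[%d,%d) exceeds image bounds %dx%d (WxH)",
      spec$x1, spec$x2, spec$y1, spec$y2, d[2], d[1]))
  }
  out <- img$pixels[(spec$y1 + 1):spec$y2, (spec$x1 + 1):spec$x2, , drop = FALSE]
  new_osm_image(out, source_path = img$source_path)
}

#' Resize an image to the network input size
#'
#' Bilinear interpolation to a square `side x side` raster; values are
#' clamped to `[0, 1]`.
#'
#' @param img An `osm_image` or H x W x C array.
#' @param side Output side length in pixels (network default 224).
#' @export
resize_image <- function(img, side = 224) {
  osm_check(length(side) == 1 && side >= 1, "side must be >= 1")
  img <- as_osm_image(img)
  d <- dim(img$pixels)
  if (d[1] == side && d[2] == side) return(img)
  eb <- EBImage::resize(hwc_to_eb(img$pixels), w = side, h = side,
                        filter = "bilinear")
  px <- clamp01(eb_to_hwc(eb))
  new_osm_image(px, source_path = img$source_path)
}

#' Per-channel normalization specification
#'
#' Each pixel is transformed as `(x - mean) / sd`, channel-wise. The
#' `"fixed"` mode uses a constant mean and standard deviation of 0.5 per
#' channel — the training shortcut that maps `[0, 1]` intensities onto
#' `[-1, 1]` without re-estimating statistics — while
#' `"dataset-estimated"` standardizes with the statistics of the image at
#' hand.
#'
#' @param mean,sd Per-channel constants, recycled across channels.
#' @param mode `"fixed"` or `"dataset-estimated"`.
#' @export
norm_spec <- function(mean = 0.5, sd = 0.5,
                      mode = c("fixed", "dataset-estimated")) {
  mode <- match.arg(mode)
  osm_check(all(sd > 0), "normalization sd must be > 0")
  structure(list(mean = mean, sd = sd, mode = mode), class = "osm_norm_spec")
}

#' Normalize an image into a network input tensor
#'
#' Applies channel-wise standardization and permutes the raster into the
#' channels x H x W layout consumed by the branch network.
#'
#' @param img An `osm_image` or H x W x C array (typically already cropped
#'   and resized).
#' @param spec A [norm_spec()].
#' @param label Optional class label carried on the tensor.
#' @return A C x H x W numeric array with attribute `label`.
#' @export
normalize_image <- function(img, spec = norm_spec(), label = NULL) {
  img <- as_osm_image(img)
  px <- img$pixels
  nc <- dim(px)[3]
  if (spec$mode == "fixed") {
    mu <- rep_len(spec$mean, nc)
    sd <- rep_len(spec$sd, nc)
  } else {
    mu <- apply(px, 3, mean)
    sd <- apply(px, 3, stats::sd)
    if (any(sd <= 0)) {
      osm_stop("dataset-estimated normalization: constant channel has zero sd")
    }
  }
  for (k in seq_len(nc)) px[, , k] <- (px[, , k] - mu[k]) / sd[k]
  out <- aperm(px, c(3, 1, 2))
  attr(out, "label") <- label
  attr(out, "norm") <- list(mean = mu, sd = sd)
  out
}

#' Invert the normalization of a tensor
#'
#' Maps a C x H x W normalized tensor back to an H x W x C raster in
#' `[0, 1]`, using the statistics recorded by [normalize_image()].
#'
#' @param x A tensor produced by [normalize_image()].
#' @export
denormalize_tensor <- function(x) {
  nrm <- attr(x, "norm") %||% list(mean = 0.5, sd = 0.5)
  px <- aperm(x, c(2, 3, 1))
  nc <- dim(px)[3]
  mu <- rep_len(nrm$mean, nc)
  sd <- rep_len(nrm$sd, nc)
  for (k in seq_len(nc)) px[, , k] <- px[, , k] * sd[k] + mu[k]
  new_osm_image(clamp01(px))
}

# ---------------------------------------------------------------- manifests

#' Build a dataset manifest
#'
#' A manifest is a data frame of `(path, label)` records with a split tag
#' (`train`, `test` or `unsplit`). Paths must be unique and labels must
#' come from exactly two classes.
#'
#' @param path Character vector of image paths.
#' @param label Character vector of class labels, same length.
#' @param split One of `"unsplit"`, `"train"`, `"test"`.
#' @export
manifest <- function(path, label, split = "unsplit") {
  osm_check(length(path) == length(label) && length(path) >= 1,
            "path and label must be nonempty vectors of equal length")
  osm_check(!anyDuplicated(path), "manifest paths must be unique")
  osm_check(length(unique(label)) == 2L,
            "manifest labels must come from exactly two classes")
  osm_check(split %in% c("unsplit", "train", "test"), "invalid split tag")
  structure(data.frame(path = as.character(path), label = as.character(label),
                       stringsAsFactors = FALSE),
            split = split, class = c("osm_manifest", "data.frame"))
}

#' Read a manifest from CSV or JSON
#'
#' CSV dialect: UTF-8, comma-separated with header `path,label`. JSON
#' dialect: array of objects with fields `path` and `label`.
#'
#' @param path File path; the format is chosen by extension
#'   (`.json` vs anything else = CSV).
#' @param split Split tag to attach.
#' @export
read_manifest <- function(path, split = "unsplit") {
  if (!file.exists(path)) {
    osm_stop(sprintf("manifest '%s' does not exist", path), class = "osm_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  osm_check(all(c("path", "label") %in% names(df)),
            "manifest must have columns 'path' and 'label'")
  manifest(df$path, df$label, split = split)
}

#' Write a manifest to CSV or JSON
#'
#' @param m An `osm_manifest`.
#' @param path Output path; `.json` selects the JSON dialect.
#' @export
write_manifest <- function(m, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(data.frame(path = m$path, label = m$label),
                         path, auto_unbox = FALSE)
  } else {
    write.csv(data.frame(path = m$path, label = m$label), path,
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits a two-class manifest so that each class contributes
#' `floor(train_fraction * n_class)` images to the training set and the
#' remainder to the test set. Reproducible: the permutation is a pure
#' function of the seed.
#'
#' @param m An `osm_manifest`.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.7 for the 7:3 protocol).
#' @param seed Integer seed.
#' @param allow_empty_test Permit a split whose test set is empty
#'   (e.g. `train_fraction = 1`).
#' @return List with elements `train`, `test` (manifests) and
#'   `provenance` (seed, fraction, per-class counts).
#' @export
stratified_split <- function(m, train_fraction = 0.7, seed = 1,
                             allow_empty_test = FALSE) {
  osm_check(train_fraction > 0 && train_fraction <= 1,
            "train_fraction must be in (0, 1]")
  counts <- table(m$label)
  osm_check(all(counts >= 2), "each class needs at least 2 images to split")
  idx_train <- integer(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      rows <- which(m$label == cl)
      n_tr <- floor(train_fraction * length(rows))
      idx_train <- c(idx_train, sample(rows, n_tr))
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(nrow(m)), idx_train)
  if (length(idx_test) == 0 && !allow_empty_test) {
    osm_stop("split produced an empty test set; pass allow_empty_test = TRUE to permit")
  }
  mk <- function(rows, tag) {
    if (length(rows) == 0) {
      return(structure(data.frame(path = character(0), label = character(0)),
                       split = tag, class = c("osm_manifest", "data.frame")))
    }
    manifest(m$path[rows], m$label[rows], split = tag)
  }
  list(train = mk(idx_train, "train"),
       test = mk(idx_test, "test"),
       provenance = list(seed = as.integer(seed),
                         train_fraction = train_fraction,
                         counts = list(
                           train = as.list(table(m$label[idx_train])),
                           test = as.list(table(m$label[idx_test])))))
}

#' Write split provenance as JSON
#'
#' @param split_result Value of [stratified_split()].
#' @param path Output JSON path.
#' @export
write_split_provenance <- function(split_result, path) {
  jsonlite::write_json(split_result$provenance, path, auto_unbox = TRUE)
  invisible(path)
}

# ------------------------------------------------------------- augmentation

#' Traditional augmentation specification
#'
#' Enabled transforms are applied in a fixed order: random-crop, rotation,
#' vertical-flip, horizontal-flip, color-jitter. Flips are deterministic
#' (always applied when enabled, so applying a flip-only spec twice
#' recovers the original); crop, rotation and jitter draw their parameters
#' from the configured ranges under the seed given to [augment_image()].
#'
#' @param transforms Character subset of `"random-crop"`,
#'   `"vertical-flip"`, `"horizontal-flip"`, `"rotation"`,
#'   `"color-jitter"`; at least one.
#' @param crop_scale Range of the retained side fraction for random-crop.
#' @param rotation Angle range in degrees.
#' @param brightness Additive intensity offset range.
#' @param contrast Multiplicative contrast factor range.
#' @export
augment_spec <- function(transforms = c("random-crop", "vertical-flip",
                                        "horizontal-flip", "rotation",
                                        "color-jitter"),
                         crop_scale = c(0.7, 1.0),
                         rotation = c(-15, 15),
                         brightness = c(-0.1, 0.1),
                         contrast = c(0.9, 1.1)) {
  known <- c("random-crop", "vertical-flip", "horizontal-flip", "rotation",
             "color-jitter")
  osm_check(length(transforms) >= 1 && all(transforms %in% known),
            "transforms must be a nonempty subset of the known transforms")
  osm_check(length(crop_scale) == 2 && all(crop_scale > 0 & crop_scale <= 1) &&
              crop_scale[1] <= crop_scale[2], "invalid crop_scale range")
  osm_check(length(rotation) == 2 && rotation[1] <= rotation[2],
            "invalid rotation range")
  structure(list(transforms = transforms, crop_scale = crop_scale,
                 rotation = rotation, brightness = brightness,
                 contrast = contrast),
            class = "osm_augment_spec")
}

#' Apply traditional augmentation to an image
#'
#' @param img An `osm_image` or H x W x C array.
#' @param spec An [augment_spec()].
#' @param seed Integer seed; output is a pure function of (img, spec, seed).
#' @return Augmented `osm_image` of the same size as the input.
#' @export
augment_image <- function(img, spec = augment_spec(), seed = 1) {
  osm_check(inherits(spec, "osm_augment_spec"), "spec must be an augment_spec")
  img <- as_osm_image(img)
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  with_seed(seed, {
    if ("random-crop" %in% spec$transforms) {
      s <- runif(1, spec$crop_scale[1], spec$crop_scale[2])
      ch <- max(1L, round(s * h)); cw <- max(1L, round(s * w))
      y0 <- if (h > ch) sample.int(h - ch + 1L, 1L) - 1L else 0L
      x0 <- if (w > cw) sample.int(w - cw + 1L, 1L) - 1L else 0L
      if (ch < h || cw < w) {
        px <- px[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), , drop = FALSE]
        eb <- EBImage::resize(hwc_to_eb(px), w = w, h = h, filter = "bilinear")
        px <- clamp01(eb_to_hwc(eb))
      }
    }
    if ("rotation" %in% spec$transforms) {
      ang <- runif(1, spec$rotation[1], spec$rotation[2])
      if (abs(ang) > 1e-12) {
        eb <- EBImage::rotate(hwc_to_eb(px), ang, output.dim = c(w, h),
                              bg.col = "black")
        px <- clamp01(eb_to_hwc(eb))
      }
    }
    if ("vertical-flip" %in% spec$transforms) {
      px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    }
    if ("horizontal-flip" %in% spec$transforms) {
      px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
    }
    if ("color-jitter" %in% spec$transforms) {
      b <- runif(1, spec$brightness[1], spec$brightness[2])
      k <- runif(1, spec$contrast[1], spec$contrast[2])
      px <- clamp01((px - 0.5) * k + 0.5 + b)
    }
  })
  new_osm_image(px, source_path = img$source_path)
}

# ----------------------------------------------------- preprocessing chain

#' Preprocessing pipeline specification
#'
#' The fixed pipeline order is crop, then resize, then normalize.
#'
#' @param crop A [crop_spec()] or `NULL` to skip cropping.
#' @param side Resize target (network input side).
#' @param norm A [norm_spec()].
#' @param expand_gray Replicate grayscale to 3 channels on load.
#' @export
preprocess_spec <- function(crop = NULL, side = 224, norm = norm_spec(),
                            expand_gray = TRUE) {
  structure(list(crop = crop, side = side, norm = norm,
                 expand_gray = expand_gray),
            class = "osm_preprocess_spec")
}

#' Preprocess one image into a network input tensor
#'
#' @param img An `osm_image`, array, or a file path.
#' @param pre A [preprocess_spec()].
#' @param label Optional class label carried on the tensor.
#' @export
preprocess_image <- function(img, pre = preprocess_spec(), label = NULL) {
  if (is.character(img)) img <- load_image(img, expand_gray = pre$expand_gray)
  img <- as_osm_image(img)
  if (pre$expand_gray && dim(img$pixels)[3] == 1) {
    img <- new_osm_image(array(rep(img$pixels, 3),
                               dim = c(dim(img$pixels)[1:2], 3L)),
                         img$source_path)
  }
  if (!is.null(pre$crop)) img <- crop_fundus(img, pre$crop)
  img <- resize_image(img, side = pre$side)
  normalize_image(img, pre$norm, label = label)
}

#' Preprocess every image of a manifest
#'
#' @param m An `osm_manifest`.
#' @param pre A [preprocess_spec()].
#' @return List with `tensors` (list of C x H x W arrays), `labels`
#'   (character) and `paths`.
#' @export
load_dataset <- function(m, pre = preprocess_spec()) {
  osm_check(nrow(m) >= 1, "manifest is empty")
  tensors <- lapply(seq_len(nrow(m)), function(i) {
    preprocess_image(m$path[i], pre, label = m$label[i])
  })
  structure(list(tensors = tensors, labels = m$label, paths = m$path),
            class = "osm_dataset")
}
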
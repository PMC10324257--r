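# KNN classification over the learned embedding space. The gallery holds
# one embedding per training image; a query is classified by majority
# vote among its k nearest gallery entries under Euclidean distance.

#' Build the embedding gallery from training images
#'
#' @param net A trained `osm_branch`.
#' @param data An `osm_dataset` or `osm_manifest` (then `pre` applies).
#' @param pre A [preprocess_spec()] when `data` is a manifest.
#' @return An `osm_gallery`: list with `embeddings` (n x dim matrix),
#'   `labels`, `paths` and `provenance`.
#' @export
build_gallery <- function(net, data, pre = NULL) {
  if (inherits(data, "osm_manifest")) {
    osm_check(nrow(data) >= 1, "manifest is empty")
    data <- load_dataset(data, pre %||% preprocess_spec(side = net$config$input_size))
  }
  osm_check(inherits(data, "osm_dataset") && length(data$tensors) >= 1,
            "gallery needs a nonempty dataset")
  emb <- t(vapply(data$tensors, function(x) embed_image(net, x),
                  numeric(net$config$embedding_dim)))
  structure(list(embeddings = emb, labels = data$labels,
                 paths = data$paths %||% rep(NA_character_, nrow(emb)),
                 provenance = list(architecture = net$config$architecture,
                                   embedding_dim = net$config$embedding_dim,
                                   n = nrow(emb))),
            class = "osm_gallery")
}

#' Classify an embedding by k-nearest-neighbour vote
#'
#' The k smallest Euclidean distances are selected (distance ties broken
#' by gallery insertion order, so permuting the gallery never changes the
#' decision) and the majority label returned. On a vote tie — inevitable
#' at even k in a two-class problem — the label of the single nearest
#' neighbour wins, which makes k = 2 decide exactly like k = 1 whenever
#' its two neighbours disagree.
#'
#' @param gallery An `osm_gallery`.
#' @param query Numeric embedding vector.
#' @param k Number of neighbours (default 2).
#' @return List with `label`, `confidence` (vote fraction) and
#'   `neighbors` (data frame `index, distance, label` for audit).
#' @export
knn_classify <- function(gallery, query, k = 2) {
  n <- nrow(gallery$embeddings)
  osm_check(k >= 1 && k <= n,
            sprintf("k = %s must be between 1 and the gallery size %d", k, n))
  osm_check(length(query) == ncol(gallery$embeddings),
            "query dimension does not match gallery")
  d2 <- colSums((t(gallery$embeddings) - query)^2)
  ord <- order(d2, seq_len(n))  # stable: insertion order breaks ties
  sel <- ord[seq_len(k)]
  votes <- table(gallery$labels[sel])
  top <- names(votes)[votes == max(votes)]
  label <- if (length(top) == 1) top else gallery$labels[sel[1]]
  list(label = label,
       confidence = as.numeric(max(votes)) / k,
       neighbors = data.frame(index = sel, distance = sqrt(d2[sel]),
                              label = gallery$labels[sel]))
}

#' Classify a raw image end-to-end
#'
#' Composition preprocess -> embed -> KNN vote; deterministic.
#'
#' @param net A trained `osm_branch`.
#' @param gallery An `osm_gallery` built with the same network.
#' @param img An `osm_image`, array or file path.
#' @param pre A [preprocess_spec()] (crop + resize + normalization).
#' @param k Number of neighbours.
#' @return The predicted label (attributes `confidence`, `neighbors`).
#' @export
predict_image <- function(net, gallery, img, pre = NULL, k = 2) {
  pre <- pre %||% preprocess_spec(side = net$config$input_size)
  x <- preprocess_image(img, pre)
  res <- knn_classify(gallery, embed_image(net, x), k = k)
  structure(res$label, confidence = res$confidence, neighbors = res$neighbors)
}

#' Embed every image of a dataset
#'
#' @param net A trained `osm_branch`.
#' @param data An `osm_dataset` or `osm_manifest`.
#' @param pre A [preprocess_spec()] when `data` is a manifest.
#' @return List with `embeddings` (n x dim) and `labels`.
#' @export
embed_dataset <- function(net, data, pre = NULL) {
  g <- build_gallery(net, data, pre = pre)
  list(embeddings = g$embeddings, labels = g$labels, paths = g$paths)
}

#' Predict labels for a set of embeddings
#'
#' @param gallery An `osm_gallery`.
#' @param embeddings n x dim matrix of query embeddings.
#' @param k Number of neighbours.
#' @return Data frame `predicted, confidence`.
#' @export
knn_predict_all <- function(gallery, embeddings, k = 2) {
  res <- lapply(seq_len(nrow(embeddings)), function(i) {
    knn_classify(gallery, embeddings[i, ], k = k)
  })
  data.frame(predicted = vapply(res, `[[`, "", "label"),
             confidence = vapply(res, `[[`, 0, "confidence"))
}

#' Save / load an embedding gallery
#'
#' The array goes into a single binary blob; a JSON sidecar records
#' dimension, labels and provenance.
#'
#' @param gallery An `osm_gallery`.
#' @param path Output path (`.rds`).
#' @export
save_gallery <- function(gallery, path) {
  saveRDS(unclass(gallery), path)
  jsonlite::write_json(list(dim = ncol(gallery$embeddings),
                            n = nrow(gallery$embeddings),
                            labels = gallery$labels,
                            provenance = gallery$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gallery
#' @export
load_gallery <- function(path) {
  if (!file.exists(path)) {
    osm_stop(sprintf("gallery '%s' does not exist", path), class = "osm_io_error")
  }
  structure(readRDS(path), class = "osm_gallery")
}

#' Write predictions as CSV
#'
#' Dialect: `path,predicted,confidence` with confidence the vote
#' fraction.
#'
#' @param paths Image paths (or identifiers).
#' @param preds Data frame from [knn_predict_all()].
#' @param path Output CSV path.
#' @export
write_predictions <- function(paths, preds, path) {
  write.csv(data.frame(path = paths, predicted = preds$predicted,
                       confidence = preds$confidence),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
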
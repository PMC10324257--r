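# Metrics and experiment harnesses: confusion tallies, accuracy /
# precision / recall / F1, the attention ablation, the neighbourhood-size
# sweep and the classifier-head comparison.

#' Tally a 2x2 confusion matrix
#'
#' @param truth,predicted Label vectors of equal length, drawn from the
#'   two known classes.
#' @param positive The designated positive class (default `"PVD"`).
#' @return An `osm_confusion`: list `TP, FP, TN, FN, positive, classes`.
#' @export
confusion_counts <- function(truth, predicted, positive = "PVD") {
  osm_check(length(truth) == length(predicted) && length(truth) > 0,
            "truth and predicted must be nonempty and of equal length")
  classes <- sort(unique(truth))
  osm_check(length(classes) <= 2 && positive %in% c(classes, positive),
            "labels must come from two classes")
  bad <- setdiff(unique(c(truth, predicted)), c(classes, positive))
  if (length(bad)) {
    osm_stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 positive = positive, classes = classes),
            class = "osm_confusion")
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP + TN) / total, precision = TP / (TP + FP), recall =
#' TP / (TP + FN), F1 = 2 P R / (P + R). Division-by-zero cases return 0
#' with `degenerate = TRUE` so harness tables stay rectangular. A
#' macro-averaged precision / recall / F1 over the two classes is also
#' reported.
#'
#' @param counts An `osm_confusion` (or list with `TP, FP, TN, FN`).
#' @return An `osm_metrics` list: `accuracy, precision, recall, f1`,
#'   `macro_precision, macro_recall, macro_f1`, `counts`, `degenerate`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  osm_check(total > 0, "confusion counts sum to zero")
  one_class <- function(tp, fp, fn) {
    p <- safe_div(tp, tp + fp)
    r <- safe_div(tp, tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f)
  }
  pos <- one_class(tp, fp, fn)
  neg <- one_class(tn, fn, fp)  # other class as positive
  degenerate <- (tp + fp == 0) || (tp + fn == 0)
  structure(list(accuracy = (tp + tn) / total,
                 precision = unname(pos["p"]), recall = unname(pos["r"]),
                 f1 = unname(pos["f"]),
                 macro_precision = unname((pos["p"] + neg["p"]) / 2),
                 macro_recall = unname((pos["r"] + neg["r"]) / 2),
                 macro_f1 = unname((pos["f"] + neg["f"]) / 2),
                 counts = counts, degenerate = degenerate),
            class = "osm_metrics")
}

metrics_row <- function(metrics, ...) {
  data.frame(..., accuracy = metrics$accuracy, precision = metrics$precision,
             recall = metrics$recall, f1 = metrics$f1,
             macro_f1 = metrics$macro_f1,
             TP = metrics$counts$TP, FP = metrics$counts$FP,
             TN = metrics$counts$TN, FN = metrics$counts$FN,
             degenerate = metrics$degenerate)
}

#' Evaluate a trained network on a test dataset
#'
#' @param net A trained `osm_branch`.
#' @param gallery An `osm_gallery` of training embeddings.
#' @param test An `osm_dataset` (or manifest with `pre`).
#' @param k Number of neighbours.
#' @param positive The positive class for the metrics.
#' @param pre A [preprocess_spec()] when `test` is a manifest.
#' @return An `osm_metrics` with an added `predictions` data frame.
#' @export
evaluate_model <- function(net, gallery, test, k = 2, positive = "PVD",
                           pre = NULL) {
  te <- embed_dataset(net, test, pre = pre)
  preds <- knn_predict_all(gallery, te$embeddings, k = k)
  m <- compute_metrics(confusion_counts(te$labels, preds$predicted, positive))
  m$predictions <- data.frame(path = te$paths, truth = te$labels,
                              predicted = preds$predicted,
                              confidence = preds$confidence)
  m
}

#' Attention ablation harness
#'
#' Trains one model per attention variant (`none`, `channel`, `spatial`,
#' `both`) from the same seed, builds the gallery, classifies the test
#' split and reports one metrics row per variant together with the first
#' and final epoch losses. A variant that fails is recorded as a failed
#' row, never silently dropped.
#'
#' @param train,test `osm_dataset` objects (preprocessed splits).
#' @param config A [branch_config()] template; its attention settings are
#'   overridden per variant.
#' @param tcfg A [train_config()].
#' @param lcfg A [loss_config()].
#' @param variants Subset of `c("none", "channel", "spatial", "both")`.
#' @param k Number of neighbours for classification.
#' @param positive Positive class for the metrics.
#' @param seed Shared build seed.
#' @param out_dir Optional directory for the CSV table, loss curves and
#'   JSON provenance sidecar.
#' @return Data frame, one row per variant; attribute `histories` holds
#'   the loss curves.
#' @export
run_ablation <- function(train, test, config, tcfg = train_config(),
                         lcfg = loss_config(),
                         variants = c("none", "channel", "spatial", "both"),
                         k = 2, positive = "PVD", seed = 1, out_dir = NULL) {
  known <- c("none", "channel", "spatial", "both")
  osm_check(length(variants) >= 1 && all(variants %in% known) &&
              !anyDuplicated(variants),
            "variants must be a nonempty, distinct subset of none/channel/spatial/both")
  rows <- list(); histories <- list()
  for (v in variants) {
    res <- tryCatch({
      att <- attention_config(channel = v %in% c("channel", "both"),
                              spatial = v %in% c("spatial", "both"),
                              reduction = config$attention$reduction,
                              kernel = config$attention$kernel)
      cfg <- config; cfg$attention <- att
      net <- build_branch(cfg, seed = seed)
      tr <- train_model(net, train, tcfg, lcfg)
      gal <- build_gallery(tr$net, train)
      m <- evaluate_model(tr$net, gal, test, k = k, positive = positive)
      histories[[v]] <- tr$history
      metrics_row(m, variant = v,
                  first_loss = if (nrow(tr$history)) tr$history$mean_loss[1] else NA,
                  final_loss = if (nrow(tr$history))
                    tr$history$mean_loss[nrow(tr$history)] else NA,
                  failed = FALSE)
    }, error = function(e) {
      data.frame(variant = v, first_loss = NA, final_loss = NA,
                 accuracy = NA, precision = NA, recall = NA, f1 = NA,
                 macro_f1 = NA, TP = NA, FP = NA, TN = NA, FN = NA,
                 degenerate = NA, failed = TRUE)
    })
    rows[[v]] <- res
  }
  tab <- rbind_pad(rows)
  attr(tab, "histories") <- histories
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "ablation.csv"), row.names = FALSE)
    for (v in names(histories)) {
      write_loss_history(histories[[v]],
                         file.path(out_dir, sprintf("loss_%s.csv", v)))
    }
    jsonlite::write_json(list(seed = seed, variants = variants, k = k,
                              positive = positive,
                              epochs = tcfg$epochs,
                              learning_rate = tcfg$learning_rate),
                         file.path(out_dir, "ablation_provenance.json"),
                         auto_unbox = TRUE)
  }
  tab
}

#' Neighbourhood-size sweep
#'
#' Re-scores one fixed gallery at several k values (no retraining).
#' Duplicate k values are deduplicated with a warning.
#'
#' @param gallery An `osm_gallery`.
#' @param test List with `embeddings` and `labels` ([embed_dataset()]).
#' @param ks Integer vector of neighbourhood sizes.
#' @param positive Positive class for the metrics.
#' @param out_csv Optional CSV output path.
#' @return Data frame, one row per unique k.
#' @export
run_k_sweep <- function(gallery, test, ks = c(2, 4, 8, 10),
                        positive = "PVD", out_csv = NULL) {
  osm_check(length(ks) >= 1 && all(ks >= 1),
            "ks must be a nonempty vector of positive integers")
  osm_check(max(ks) <= nrow(gallery$embeddings),
            "max(ks) exceeds the gallery size")
  if (anyDuplicated(ks)) {
    warning("duplicate k values deduplicated")
    ks <- unique(ks)
  }
  rows <- lapply(ks, function(k) {
    preds <- knn_predict_all(gallery, test$embeddings, k = k)
    m <- compute_metrics(confusion_counts(test$labels, preds$predicted, positive))
    metrics_row(m, k = k)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out_csv)) write.csv(tab, out_csv, row.names = FALSE)
  tab
}

# Pluggable classifier heads over gallery embeddings. Each entry fits on
# the gallery and predicts labels for a query matrix.
classifier_heads <- function(k = 2) {
  list(
    knn = function(gallery, queries) {
      knn_predict_all(gallery, queries, k = k)$predicted
    },
    svm = function(gallery, queries) {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        osm_stop("package 'e1071' is required for the svm head")
      }
      fit <- e1071::svm(x = gallery$embeddings, y = factor(gallery$labels))
      as.character(predict(fit, queries))
    },
    `random-forest` = function(gallery, queries) {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        osm_stop("package 'randomForest' is required for the random-forest head")
      }
      fit <- randomForest::randomForest(x = gallery$embeddings,
                                        y = factor(gallery$labels))
      as.character(predict(fit, queries))
    },
    `gradient-boosting` = function(gallery, queries) {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        osm_stop("package 'xgboost' is required for the gradient-boosting head")
      }
      fit <- xgboost::xgboost(gallery$embeddings, factor(gallery$labels),
                              nrounds = 30, nthreads = 1, verbosity = 0)
      as.character(predict(fit, queries, type = "class"))
    })
}

#' Classifier-head comparison
#'
#' Fits each requested head on the gallery embeddings and scores it on
#' the test embeddings with the same metrics. The KNN head reproduces
#' [knn_predict_all()] exactly; a failing head yields a failed row
#' without affecting the others.
#'
#' @param gallery An `osm_gallery`.
#' @param test List with `embeddings` and `labels`.
#' @param heads Subset of `"knn"`, `"svm"`, `"random-forest"`,
#'   `"gradient-boosting"`.
#' @param k Neighbours for the KNN head.
#' @param positive Positive class for the metrics.
#' @param out_csv Optional CSV output path.
#' @return Data frame, one row per head.
#' @export
run_classifier_comparison <- function(gallery, test,
                                      heads = c("knn", "svm", "random-forest",
                                                "gradient-boosting"),
                                      k = 2, positive = "PVD", out_csv = NULL) {
  registry <- classifier_heads(k = k)
  bad <- setdiff(heads, names(registry))
  if (length(bad)) {
    osm_stop(sprintf("unknown classifier head(s): %s", paste(bad, collapse = ", ")))
  }
  rows <- lapply(heads, function(h) {
    tryCatch({
      pred <- registry[[h]](gallery, test$embeddings)
      m <- compute_metrics(confusion_counts(test$labels, pred, positive))
      metrics_row(m, head = h, failed = FALSE)
    }, error = function(e) {
      data.frame(head = h, accuracy = NA, precision = NA, recall = NA,
                 f1 = NA, macro_f1 = NA, TP = NA, FP = NA, TN = NA, FN = NA,
                 degenerate = NA, failed = TRUE)
    })
  })
  tab <- rbind_pad(rows)
  if (!is.null(out_csv)) write.csv(tab, out_csv, row.names = FALSE)
  tab
}

# rbind data frames whose column sets may differ (failed harness rows),
# padding absences with NA and keeping the first row's column order first.
rbind_pad <- function(rows) {
  cols <- Reduce(union, lapply(rows, names))
  tab <- do.call(rbind, lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[, cols]
  }))
  rownames(tab) <- NULL
  tab
}
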
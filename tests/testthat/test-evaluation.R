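test_that("confusion tallies follow the designated positive class", {
  truth <- c(rep("PVD", 12), rep("VO", 8))
  perfect <- confusion_counts(truth, truth, positive = "PVD")
  expect_equal(unlist(perfect[c("TP", "TN", "FP", "FN")]),
               c(TP = 12, TN = 8, FP = 0, FN = 0))

  allneg <- confusion_counts(truth, rep("VO", 20), positive = "PVD")
  expect_equal(allneg$FN, 12)
  expect_equal(allneg$TN, 8)

  # 10 positives with 1 missed, 10 negatives with 2 flipped
  pred <- c(rep("PVD", 9), "VO", "PVD", "PVD", rep("VO", 8))
  truth2 <- c(rep("PVD", 10), rep("VO", 10))
  cc <- confusion_counts(truth2, pred, positive = "PVD")
  expect_equal(unlist(cc[c("TP", "FN", "FP", "TN")]),
               c(TP = 9, FN = 1, FP = 2, TN = 8))
  expect_error(confusion_counts(truth2, c(pred[-1], "weird")), "unknown label")
})

test_that("metrics evaluate their formulas exactly on the hand tally", {
  m <- compute_metrics(list(TP = 9, FN = 1, FP = 2, TN = 8))
  expect_equal(m$accuracy, 0.85, tolerance = 1e-4)
  expect_equal(m$precision, 9 / 11, tolerance = 1e-4)
  expect_equal(m$recall, 0.9, tolerance = 1e-4)
  expect_equal(m$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9), tolerance = 1e-4)
  expect_equal(m$f1, 0.8571, tolerance = 1e-4)

  perfect <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  degen <- compute_metrics(list(TP = 0, FP = 0, TN = 8, FN = 2))
  expect_equal(degen$precision, 0)
  expect_true(degen$degenerate)
  expect_error(compute_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)))
})

test_that("metric identities and positive-class relabelling behave", {
  withr::local_seed(5)
  for (i in 1:20) {
    cc <- list(TP = sample(0:20, 1), FP = sample(0:20, 1),
               TN = sample(0:20, 1), FN = sample(0:20, 1))
    if (sum(unlist(cc)) == 0) cc$TP <- 1
    m <- compute_metrics(cc)
    total <- cc$TP + cc$FP + cc$TN + cc$FN
    expect_equal(m$accuracy * total, cc$TP + cc$TN, tolerance = 1e-10)
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-10)
    }
    # swapping the positive class: accuracy invariant, P/R swap roles
    sw <- compute_metrics(list(TP = cc$TN, FP = cc$FN, TN = cc$TP, FN = cc$FP))
    expect_equal(sw$accuracy, m$accuracy)
    expect_equal(sw$recall, if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else 0)
  }
})

test_that("the ablation harness covers all four variants reproducibly", {
  fx <- tiny_synth()
  tcfg <- train_config(learning_rate = 1e-3, batch_size = 50, epochs = 2,
                       seed = 13)
  out <- withr::local_tempdir()
  tab <- run_ablation(fx$train, fx$test, branch_config("tiny"), tcfg,
                      loss_config(1), seed = 13, out_dir = out)
  expect_equal(tab$variant, c("none", "channel", "spatial", "both"))
  expect_true(all(!tab$failed))
  expect_true(all(is.finite(tab$accuracy)))
  expect_true(all(is.finite(tab$final_loss)))
  expect_true(file.exists(file.path(out, "ablation.csv")))
  expect_true(file.exists(file.path(out, "loss_both.csv")))
  expect_true(file.exists(file.path(out, "ablation_provenance.json")))

  # single-variant harness row equals the manual pipeline with the seed
  one <- run_ablation(fx$train, fx$test, branch_config("tiny"), tcfg,
                      loss_config(1), variants = "both", seed = 13)
  net <- build_branch(branch_config("tiny"), seed = 13)
  tr <- train_model(net, fx$train, tcfg, loss_config(1))
  gal <- build_gallery(tr$net, fx$train)
  m <- evaluate_model(tr$net, gal, fx$test, k = 2)
  expect_equal(one$accuracy, m$accuracy)
  expect_equal(one$f1, m$f1)
  expect_equal(one$final_loss, tr$history$mean_loss[nrow(tr$history)])
  both_row <- tab[tab$variant == "both", ]
  expect_equal(both_row$accuracy, one$accuracy)

  expect_error(run_ablation(fx$train, fx$test, branch_config("tiny"), tcfg,
                            variants = character(0)))
})

test_that("the k sweep reuses one gallery and rejects invalid k", {
  tt <- tiny_trained()
  fx <- tiny_synth()
  te <- embed_dataset(tt$net, fx$test)
  tab <- run_k_sweep(tt$gallery, te, ks = c(2, 4, 8, 10))
  expect_equal(tab$k, c(2, 4, 8, 10))
  expect_true(all(is.finite(tab$accuracy)))

  expect_warning(tab2 <- run_k_sweep(tt$gallery, te, ks = c(2, 2, 4)),
                 "deduplicated")
  expect_equal(tab2$k, c(2, 4))
  expect_error(run_k_sweep(tt$gallery, te, ks = 10000), "gallery size")

  # k = gallery size: every query gets the gallery-majority label
  n <- nrow(tt$gallery$embeddings)
  tabn <- run_k_sweep(tt$gallery, te, ks = n)
  preds <- knn_predict_all(tt$gallery, te$embeddings, k = n)$predicted
  maj <- names(which.max(table(tt$gallery$labels)))
  # balanced gallery -> whole-gallery vote always ties -> nearest wins;
  # with an unbalanced gallery all predictions equal the majority label
  if (length(unique(table(tt$gallery$labels))) > 1) {
    expect_true(all(preds == maj))
  }
  expect_true(all(preds %in% tt$gallery$labels))
})

test_that("classifier heads fit the gallery; knn head is self-consistent", {
  tt <- tiny_trained()
  fx <- tiny_synth()
  te <- embed_dataset(tt$net, fx$test)
  tab <- run_classifier_comparison(tt$gallery, te, heads = "knn", k = 2)
  base <- knn_predict_all(tt$gallery, te$embeddings, k = 2)$predicted
  m <- compute_metrics(confusion_counts(te$labels, base, "PVD"))
  expect_equal(tab$accuracy, m$accuracy)

  # linearly separable 2-D toy gallery: every head scores 1.0
  emb <- rbind(matrix(rnorm(40, -3, 0.3), 20, 2),
               matrix(rnorm(40, 3, 0.3), 20, 2))
  g <- structure(list(embeddings = emb,
                      labels = rep(c("VO", "PVD"), each = 20),
                      paths = rep(NA_character_, 40), provenance = list()),
                 class = "osm_gallery")
  q <- list(embeddings = rbind(matrix(rnorm(20, -3, 0.3), 10, 2),
                               matrix(rnorm(20, 3, 0.3), 10, 2)),
            labels = rep(c("VO", "PVD"), each = 10))
  tab2 <- run_classifier_comparison(g, q, k = 2)
  expect_equal(nrow(tab2), 4)
  expect_true(all(!tab2$failed))
  expect_true(all(tab2$accuracy == 1))

  expect_error(run_classifier_comparison(g, q, heads = "mystery"),
               "unknown classifier")
})
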
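test_that("the dual solver satisfies the KKT conditions on separable data", {
  set.seed(21)
  n <- 40
  x <- rbind(matrix(rnorm(n, 3), n / 2, 2), matrix(rnorm(n, -3), n / 2, 2))
  y <- rep(c(1, -1), each = n / 2)
  fit <- svm_fit(x, y, "linear", C = 10)
  expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= 10 + 1e-12))
  expect_lt(fit$max_violation, 1e-4)   # projected-gradient optimality
  pred <- sign(predict(fit, x))
  expect_equal(pred, y)
  # the weight vector points from the negative toward the positive class
  expect_true(all(fit$w > 0))

  rbf <- svm_fit(x, y, "rbf", C = 10, gamma = 0.5)
  expect_equal(sign(predict(rbf, x)), y)
})

test_that("XOR defeats a linear kernel under LOO", {
  df <- data.frame(image_id = letters[1:4],
                   label = c("malignant", "benign", "benign", "malignant"),
                   f1 = c(1, 1, -1, -1), f2 = c(1, -1, 1, -1),
                   check.names = FALSE)
  rep <- suppressWarnings(
    evaluate_classifier(df, classifier_config(kernel = "linear"), "loo"))
  expect_lte(rep$metrics[["accuracy"]], 0.5)
})

test_that("RFE ranks the separating feature last-removed (rank p)", {
  tab <- normalize_table(toy_table(n = 20, p = 8))
  rk <- svm_rfe_rank(tab)
  expect_setequal(as.integer(rk), 1:8)
  expect_equal(unname(rk["f1"]), 8L)

  # duplicated columns occupy adjacent ranks, earlier column ranked lower
  tab2 <- toy_table(n = 20, p = 4)
  tab2$f2 <- tab2$f1
  rk2 <- svm_rfe_rank(normalize_table(tab2))
  expect_equal(abs(rk2[["f1"]] - rk2[["f2"]]), 1L)
  expect_lt(rk2[["f1"]], rk2[["f2"]])

  # single feature gets rank 1
  one <- toy_table(n = 10, p = 1)
  expect_equal(unname(svm_rfe_rank(normalize_table(one))[["f1"]]), 1L)
})

test_that("channel scores sum ranks per channel (arithmetic identities)", {
  # handcrafted full ranking: channel blocks in canonical order
  nm <- feature_names()
  rk <- structure(seq_along(nm), names = nm, class = "ranked_features")
  # with ranks 1..240 in name order, the last channel block holds 217..240
  sc <- channel_scores(rk)
  expect_equal(sum(sc), 240 * 241 / 2)
  expect_equal(unname(sc["V"]), sum(217:240))  # V is the 10th channel block
  expect_equal(unname(sc["V"]), 5484)

  # two-channel toy: scores sum to p (p + 1) / 2 with p = 48
  nm2 <- feature_names(c("Blu", "Cr"))
  set.seed(1)
  rk2 <- structure(sample(48), names = nm2, class = "ranked_features")
  expect_equal(sum(channel_scores(rk2)), 48 * 49 / 2)

  bad <- structure(1:10, names = nm[1:10], class = "ranked_features")
  expect_error(channel_scores(bad), class = "abruptcut_data_error")
})

test_that("closed-form metrics match the published definitions", {
  perfect <- classification_metrics(TP = 31, TN = 69, FP = 0, FN = 0)
  expect_equal(unname(perfect[c("precision", "recall", "f_measure",
                                "accuracy")]),
               c(1, 1, 1, 1))
  # precision 0.5, recall 1 -> F = 2/3
  m <- classification_metrics(TP = 1, TN = 0, FP = 1, FN = 0)
  expect_equal(m[["precision"]], 0.5)
  expect_equal(m[["recall"]], 1)
  expect_equal(m[["f_measure"]], 2 / 3)
  expect_equal(m[["sensitivity"]], m[["recall"]])
  # zero-denominator rule (precision and F both warn here)
  w <- capture_warnings(z <- classification_metrics(0, 5, 0, 5))
  expect_true(any(grepl("undefined", w)))
  expect_equal(z[["f_measure"]], 0)
  expect_equal(z[["precision"]], 0)
})

test_that("evaluation schemes: separability, determinism, error paths", {
  tab <- toy_table(n = 20, p = 5)
  cfg <- classifier_config(kernel = "linear")
  expect_equal(evaluate_classifier(tab, cfg, "model")$metrics[["accuracy"]], 1)
  a <- evaluate_classifier(tab, cfg, "cv10")$metrics
  b <- evaluate_classifier(tab, cfg, "cv10")$metrics
  expect_identical(a, b)   # seeded folds are reproducible
  onecls <- tab; onecls$label <- "benign"
  expect_error(evaluate_classifier(onecls, cfg, "loo"),
               class = "abruptcut_data_error")
  expect_error(evaluate_classifier(tab[1:8, ], cfg, "cv10"),
               class = "abruptcut_data_error")
  expect_error(classifier_config(svm_type = "nu"),
               class = "abruptcut_param_error")
})

test_that("model accuracy is optimistic relative to LOO on average", {
  diffs <- vapply(1:20, function(seed) {
    tab <- toy_table(n = 16, p = 4, seed = seed, signal = 0.35)
    cfg <- classifier_config(kernel = "linear")
    evaluate_classifier(tab, cfg, "model")$metrics[["accuracy"]] -
      evaluate_classifier(tab, cfg, "loo")$metrics[["accuracy"]]
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("elimination curve spans p..1 and matches plain evaluation at p", {
  tab <- toy_table(n = 16, p = 6)
  cfg <- classifier_config(kernel = "linear")
  cur <- elimination_curve(tab, cfg, schemes = "model")
  expect_equal(nrow(cur), 6)
  expect_equal(cur$n_features, 6:1)
  expect_equal(cur$model[1],
               evaluate_classifier(tab, cfg, "model")$metrics[["accuracy"]])
  # every prefix containing the separating feature classifies perfectly
  rk <- svm_rfe_rank(normalize_table(tab), cfg)
  expect_equal(unname(rk["f1"]), 6L)
  expect_true(all(cur$model == 1))
})
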
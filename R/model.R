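## model: SVM-RFE ranking, channel scores, elimination curves, evaluation.

ft_xy <- function(t) {
  x <- as.matrix(t[, ft_feature_cols(t), drop = FALSE])
  y <- ifelse(t$label == "malignant", 1, -1)
  list(x = x, y = y)
}

# [-1, 1] normalization learned on training rows, applied to both splits
fold_normalize <- function(xtr, xte) {
  lo <- apply(xtr, 2, min)
  hi <- apply(xtr, 2, max)
  scl <- ifelse(hi > lo, 2 / (hi - lo), 0)
  nrm <- function(x) sweep(sweep(x, 2, lo), 2, scl, "*") - 1
  xtr2 <- nrm(xtr)
  xte2 <- nrm(xte)
  xtr2[, scl == 0] <- 0
  xte2[, scl == 0] <- 0
  list(train = xtr2, test = xte2)
}

#' SVM recursive feature elimination ranking
#'
#' Repeatedly trains a linear C-SVM, removes the feature with the smallest
#' squared weight, and assigns it the next-lowest rank; the last survivor
#' receives rank `p`. Higher rank = more significant. Ties in squared weight
#' (e.g. duplicated columns) are broken by column order: the earlier column
#' is removed first and gets the lower rank.
#'
#' @param t a normalized [feature_table()] (see [normalize_table()]).
#' @param cfg a [classifier_config()]; only `C` is used here (the
#'   elimination SVM is always linear).
#' @return object of class `ranked_features`: named integer vector mapping
#'   feature name to rank 1..p (a permutation).
#' @export
svm_rfe_rank <- function(t, cfg = classifier_config()) {
  d <- ft_xy(t)
  if (anyNA(d$x)) abort2("missing feature values", "abruptcut_data_error")
  p <- ncol(d$x)
  alive <- seq_len(p)
  rank <- integer(p)
  names(rank) <- colnames(d$x)
  next_rank <- 1L
  while (length(alive) > 1L) {
    fit <- svm_fit(d$x[, alive, drop = FALSE], d$y, kernel = "linear",
                   C = cfg$C)
    drop_local <- which.min(fit$w^2)  # first minimum: earlier column loses
    rank[alive[drop_local]] <- next_rank
    next_rank <- next_rank + 1L
    alive <- alive[-drop_local]
  }
  rank[alive] <- next_rank
  structure(rank, class = "ranked_features")
}

#' Per-channel total significance score
#'
#' Sums the ranks of each channel's 24 features (`T^C = sum of R_k`), so the
#' most informative color channel scores highest. The ranking must cover
#' whole channels (24 features each, one rank per feature, ranks a
#' permutation of 1..p); the full 240-feature ranking is the standard case.
#' Scores always sum to `p (p + 1) / 2`.
#'
#' @param r a [svm_rfe_rank()] result.
#' @return named numeric vector of per-channel scores, sorted decreasing.
#' @export
channel_scores <- function(r) {
  p <- length(r)
  if (!setequal(unclass(r), seq_len(p)))
    abort2("ranking is not a permutation of 1..p", "abruptcut_data_error")
  ch <- feature_channel(names(r))
  if (any(table(ch) != 24L))
    abort2("incomplete ranking: every channel needs its 24 features",
           "abruptcut_data_error")
  sc <- vapply(split(as.integer(r), ch), sum, numeric(1))
  sort(sc, decreasing = TRUE)
}

#' Confusion-count metrics
#'
#' Recall = TP/(TP+FN), precision = TP/(TP+FP), F = 2PR/(P+R),
#' sensitivity = recall, specificity = TN/(TN+FP). Any zero denominator
#' yields 0 with a warning. (The source text prints precision with an FN
#' denominator, identical to its recall — an evident typo; the standard form
#' is used.)
#'
#' @param TP,TN,FP,FN nonnegative confusion counts; malignant is positive.
#' @return named numeric vector of the six metrics plus the counts.
#' @export
classification_metrics <- function(TP, TN, FP, FN) {
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  accuracy <- safe(TP + TN, TP + TN + FP + FN, "accuracy")
  recall <- safe(TP, TP + FN, "recall")
  precision <- safe(TP, TP + FP, "precision")
  f_measure <- safe(2 * precision * recall, precision + recall, "F-measure")
  specificity <- safe(TN, TN + FP, "specificity")
  c(TP = TP, TN = TN, FP = FP, FN = FN,
    accuracy = accuracy, precision = precision, recall = recall,
    f_measure = f_measure, sensitivity = recall, specificity = specificity)
}

train_predict <- function(xtr, ytr, xte, cfg) {
  nm <- fold_normalize(xtr, xte)
  fit <- svm_fit(nm$train, ytr, kernel = cfg$kernel, C = cfg$C,
                 gamma = cfg$gamma, degree = cfg$degree, coef0 = cfg$coef0)
  dv <- predict(fit, nm$test)
  ifelse(dv >= 0, 1, -1)
}

#' Evaluate a classifier on a feature table
#'
#' Three assessment schemes: `"model"` trains and tests on all rows (a
#' separability check); `"loo"` leaves each image out in turn; `"cv10"` uses
#' 10 class-stratified random folds seeded by `cfg$seed`. Features are
#' normalized to `[-1, 1]` inside each training split and the learned map is
#' applied to the held-out rows. Confusion counts are pooled over held-out
#' predictions.
#'
#' @param t an (unnormalized) [feature_table()] with both classes present.
#' @param cfg a [classifier_config()].
#' @param scheme `"model"`, `"loo"` or `"cv10"`.
#' @return an `eval_report`: list with `scheme` and the
#'   [classification_metrics()] vector in `$metrics`.
#' @export
evaluate_classifier <- function(t, cfg = classifier_config(),
                                scheme = c("model", "loo", "cv10")) {
  scheme <- match.arg(scheme)
  d <- ft_xy(t)
  n <- nrow(d$x)
  if (length(unique(d$y)) < 2L)
    abort2("evaluation needs both classes", "abruptcut_data_error")
  pred <- numeric(n)
  if (scheme == "model") {
    pred <- train_predict(d$x, d$y, d$x, cfg)
  } else if (scheme == "loo") {
    for (i in seq_len(n))
      pred[i] <- train_predict(d$x[-i, , drop = FALSE], d$y[-i],
                               d$x[i, , drop = FALSE], cfg)
  } else {
    if (n < 10L) abort2("10-fold CV needs >= 10 rows", "abruptcut_data_error")
    folds <- integer(n)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(cfg$seed)
    for (cls in unique(d$y)) {
      idx <- sample(which(d$y == cls))
      folds[idx] <- rep_len(seq_len(10L), length(idx))
    }
    for (f in seq_len(10L)) {
      te <- which(folds == f)
      if (!length(te)) next
      pred[te] <- train_predict(d$x[-te, , drop = FALSE], d$y[-te],
                                d$x[te, , drop = FALSE], cfg)
    }
  }
  TP <- sum(pred == 1 & d$y == 1)
  TN <- sum(pred == -1 & d$y == -1)
  FP <- sum(pred == 1 & d$y == -1)
  FN <- sum(pred == -1 & d$y == 1)
  structure(list(scheme = scheme, n = n,
                 metrics = classification_metrics(TP, TN, FP, FN)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report scheme=%s n=%d accuracy=%.3f F=%.3f>\n",
              x$scheme, x$n, x$metrics[["accuracy"]],
              x$metrics[["f_measure"]]))
  invisible(x)
}

# save/restore global RNG state so seeded folds do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Backward-elimination accuracy curve
#'
#' Using one fixed initial RFE ranking, evaluates the classifier with the
#' top-n features for n = p down to 1 under each requested scheme.
#'
#' @param t an (unnormalized) [feature_table()].
#' @param cfg a [classifier_config()].
#' @param schemes subset of `c("model", "loo", "cv10")`.
#' @param ranking optional precomputed [svm_rfe_rank()] result (computed on
#'   the normalized table if omitted).
#' @return data.frame with column `n_features` and one accuracy column per
#'   scheme, ordered from p features down to 1.
#' @export
elimination_curve <- function(t, cfg = classifier_config(),
                              schemes = "model", ranking = NULL) {
  if (is.null(ranking)) ranking <- svm_rfe_rank(normalize_table(t), cfg)
  p <- length(ranking)
  ord <- names(sort(ranking, decreasing = TRUE))  # best first
  rows <- lapply(seq(p, 1L), function(nfeat) {
    sub <- t[, c("image_id", "label", ord[seq_len(nfeat)]), drop = FALSE]
    acc <- vapply(schemes, function(s)
      evaluate_classifier(sub, cfg, s)$metrics[["accuracy"]], numeric(1))
    c(n_features = nfeat, acc)
  })
  as.data.frame(do.call(rbind, rows))
}
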
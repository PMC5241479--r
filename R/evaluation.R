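#' Stratified train/test split
#'
#' Splits rows into disjoint, exhaustive train and test sets. Under
#' stratification (the default) each class contributes
#' `round(train_fraction * n_class)` training rows (R's round-half-to-even
#' rule), drawn by a seeded permutation.
#'
#' @param data Data.frame with a label column.
#' @param train_fraction Fraction of rows for training, in (0, 1);
#'   default 0.8 (an 80/20 split).
#' @param seed Integer seed.
#' @param stratified Stratify by label (default TRUE).
#' @param label_col Label column name.
#' @return List with `train` and `test` data.frames.
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 1,
                          stratified = TRUE, label_col = "label") {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  y <- data[[label_col]]
  idx_train <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        if (length(idx) < 2) {
          stop(sprintf("stratum '%s' has fewer than 2 rows", cl), call. = FALSE)
        }
        n_tr <- round(train_fraction * length(idx))
        idx[sample.int(length(idx))][seq_len(n_tr)]
      }))
    } else {
      sample.int(nrow(data))[seq_len(round(train_fraction * nrow(data)))]
    }
  })
  list(train = data[sort(idx_train), , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), idx_train), , drop = FALSE])
}

#' Confusion-matrix metrics for a binary classifier
#'
#' Positive class is label 1 (the diabetes-analog class). Accuracy is
#' `(TP + TN) / n`, sensitivity (true positive rate) `TP / (TP + FN)`,
#' specificity (true negative rate) `TN / (TN + FP)`. A metric whose class
#' is absent from `y_true` is NA.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return List: `accuracy`, `sensitivity`, `specificity`, and `counts`
#'   (named TP, FP, TN, FN).
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  stopifnot_binary_labels(y_true, "y_true")
  stopifnot_binary_labels(y_pred, "y_pred")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  list(accuracy = (tp + tn) / length(y_true),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' ROC curve and AUC
#'
#' Thresholds at every distinct score; tied scores step simultaneously. The
#' curve starts at (0, 0) and ends at (1, 1) and is monotone in both
#' coordinates; AUC is the trapezoid-rule area, which equals the normalized
#' Mann-Whitney statistic with ties counted one half.
#'
#' @param y_true 0/1 vector (both classes present).
#' @param scores Finite numeric scores, larger = more positive.
#' @return List: `points` (data.frame `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  stopifnot_binary_labels(y_true, "y_true")
  if (length(y_true) != length(scores)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y_true[o]; ss <- scores[o]
  last_of_tie <- c(ss[-length(ss)] != ss[-1], TRUE)
  tp <- cumsum(ys == 1)[last_of_tie]
  fp <- cumsum(ys == 0)[last_of_tie]
  pts <- data.frame(fpr = c(0, fp / n_neg),
                    tpr = c(0, tp / n_pos),
                    threshold = c(Inf, ss[last_of_tie]))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}

# Full per-classifier report, with ROC computed for each class as positive.
evaluate_classifier <- function(y_true, y_pred, scores) {
  m <- confusion_metrics(y_true, y_pred)
  roc_pos <- roc_auc(y_true, scores)
  roc_neg <- roc_auc(1 - y_true, -scores)
  structure(list(accuracy = m$accuracy, sensitivity = m$sensitivity,
                 specificity = m$specificity, counts = m$counts,
                 auc = roc_pos$auc,
                 roc = list(positive = roc_pos$points,
                            negative = roc_neg$points)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f, sensitivity %.4f, specificity %.4f, AUC %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Fit and evaluate the GA-SVM and the three reference classifiers
#'
#' Trains k-NN, Gaussian naive Bayes, a single-hidden-layer backpropagation
#' neural network, and the RBF SVM at the supplied parameters on identical
#' training data, and evaluates all four on identical test data. ROC scores
#' are the positive-neighbor fraction (k-NN), the posterior probability
#' (naive Bayes), the output activation (BP-NN) and the decision value
#' (GA-SVM). A classifier that fails is reported as NA without aborting the
#' rest.
#'
#' @param train,test Preprocessed feature tables with a 0/1 `label` column.
#' @param svm_params An [svm_params()] (typically from [ga_optimize()]).
#' @param knn_k Neighbors for k-NN (default 5).
#' @param nnet_size Hidden units for the BP-NN (default 10).
#' @param nnet_maxit Training iterations for the BP-NN.
#' @param seed Seed (k-NN tie-breaking, neural-net initialization).
#' @param label_col Label column name.
#' @return List with `reports` (named list of `eval_report`, order: kNN,
#'   NaiveBayes, BPNN, GASVM) and `summary` (data.frame with columns
#'   Algorithm, Accuracy, Specificity, Sensitivity, AUC).
#' @export
run_baselines <- function(train, test, svm_params, knn_k = 5,
                          nnet_size = 10, nnet_maxit = 200, seed = 1,
                          label_col = "label") {
  cols <- feature_cols(train, label_col)
  xtr <- as.matrix(train[, cols, drop = FALSE])
  xte <- as.matrix(test[, cols, drop = FALSE])
  ytr <- train[[label_col]]; yte <- test[[label_col]]
  yf <- factor(ytr, levels = c(0, 1))

  fitters <- list(
    kNN = function() {
      pr <- with_seed(seed, class::knn(xtr, xte, yf, k = knn_k, prob = TRUE))
      win <- attr(pr, "prob")
      score <- ifelse(pr == "1", win, 1 - win)
      list(labels = as.integer(as.character(pr)), scores = score)
    },
    NaiveBayes = function() {
      fit <- e1071::naiveBayes(xtr, yf)
      post <- predict(fit, xte, type = "raw")[, "1"]
      list(labels = as.integer(post > 0.5), scores = post)
    },
    BPNN = function() {
      fit <- with_seed(seed, nnet::nnet(xtr, ytr, size = nnet_size,
                                        entropy = TRUE, maxit = nnet_maxit,
                                        trace = FALSE))
      act <- as.numeric(predict(fit, xte))
      list(labels = as.integer(act > 0.5), scores = act)
    },
    GASVM = function() {
      model <- train_svm(train, svm_params, label_col)
      pr <- predict(model, test)
      list(labels = pr$labels, scores = pr$decision)
    })

  reports <- lapply(names(fitters), function(nm) {
    tryCatch(
      {
        out <- fitters[[nm]]()
        evaluate_classifier(yte, out$labels, out$scores)
      },
      error = function(e) {
        warning(sprintf("classifier %s failed: %s", nm, conditionMessage(e)),
                call. = FALSE)
        structure(list(accuracy = NA_real_, sensitivity = NA_real_,
                       specificity = NA_real_, counts = NULL, auc = NA_real_,
                       roc = NULL), class = "eval_report")
      })
  })
  names(reports) <- names(fitters)
  summary <- data.frame(
    Algorithm = c("k-NN", "Naive Bayes", "BP-NN", "GA-SVM"),
    Accuracy = vapply(reports, function(r) r$accuracy, 1),
    Specificity = vapply(reports, function(r) r$specificity, 1),
    Sensitivity = vapply(reports, function(r) r$sensitivity, 1),
    AUC = vapply(reports, function(r) r$auc, 1),
    row.names = NULL)
  list(reports = reports, summary = summary)
}
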
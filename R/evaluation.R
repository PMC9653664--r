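#' Binary confusion counts
#'
#' Class 1 is the positive class (carcinogen).
#'
#' @param y_true,y_pred equal-length vectors of 0/1 labels.
#' @return list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0 or 1")
  }
  list(TP = sum(y_true == 1 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FP = sum(y_true == 0 & y_pred == 1),
       FN = sum(y_true == 1 & y_pred == 0))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Percentages on the 0-100 scale:
#' accuracy = (TP+TN)/(TP+TN+FN+FP) x 100, sensitivity (TPR) =
#' TP/(TP+FN) x 100, specificity (TNR) = TN/(TN+FP) x 100. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param counts a list with TP, TN, FP, FN (see [confusion_counts()]).
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
binary_metrics <- function(counts) {
  with(counts, {
    pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    c(accuracy = pct(TP + TN, TP + TN + FN + FP),
      sensitivity = pct(TP, TP + FN),
      specificity = pct(TN, TN + FP))
  })
}

#' Micro-averaged multiclass accuracy, sensitivity and specificity
#'
#' Each class in turn is treated as positive against the rest
#' (one-vs-rest binarization); the per-class confusion counts are pooled
#' by summation and plugged into the binary formulas, giving equal weight
#' to every observation. Note that the micro accuracy keeps the pooled
#' true negatives in both numerator and denominator:
#' (sum TP + sum TN) / (sum TP + sum TN + sum FN + sum FP) x 100.
#'
#' @param y_true,y_pred equal-length vectors of labels in
#'   `0..(n_classes-1)`.
#' @param n_classes number of classes (default 3).
#' @return named numeric vector `micro_accuracy`, `micro_sensitivity`,
#'   `micro_specificity` (percent).
#' @export
micro_multiclass_metrics <- function(y_true, y_pred, n_classes = 3L) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  classes <- 0:(n_classes - 1L)
  if (!all(y_true %in% classes) || !all(y_pred %in% classes)) {
    stop("labels must lie in 0..", n_classes - 1L)
  }
  tp <- tn <- fp <- fn <- 0L
  for (k in classes) {
    c_k <- confusion_counts(as.integer(y_true == k), as.integer(y_pred == k))
    tp <- tp + c_k$TP; tn <- tn + c_k$TN
    fp <- fp + c_k$FP; fn <- fn + c_k$FN
  }
  c(micro_accuracy = 100 * (tp + tn) / (tp + tn + fn + fp),
    micro_sensitivity = 100 * tp / (tp + fn),
    micro_specificity = 100 * tn / (tn + fp))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' randomly chosen positive is scored above a randomly chosen negative,
#' with ties contributing 1/2.
#'
#' @param y_true 0/1 labels.
#' @param scores numeric scores (larger = more positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("y_true and scores must have equal length")
  }
  pos <- y_true == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC is undefined when only one class is present")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Micro-averaged multiclass AUC
#'
#' One-vs-rest indicators for every class are flattened together with the
#' corresponding class scores into one long binary problem before
#' ranking.
#'
#' @param y_true labels in `0..(n_classes-1)`.
#' @param scores K x n_classes matrix of class scores (column j+1 scores
#'   class j).
#' @return micro AUC in `[0, 1]`.
#' @export
micro_auc <- function(y_true, scores) {
  scores <- as.matrix(scores)
  n_classes <- ncol(scores)
  flat_y <- integer(0); flat_s <- numeric(0)
  for (k in 0:(n_classes - 1L)) {
    flat_y <- c(flat_y, as.integer(y_true == k))
    flat_s <- c(flat_s, scores[, k + 1L])
  }
  auc_score(flat_y, flat_s)
}

#' Coefficient of determination
#'
#' Default definition `1 - RSS/TSS` (residual over total sum of squares
#' about the observed mean). `method = "ess"` instead returns the
#' explained-over-total ratio `sum((yhat - ybar)^2) / sum((y - ybar)^2)`,
#' which coincides with the default only for fitted least-squares
#' predictions.
#'
#' @param y_true observed values (variance must be positive, n >= 2).
#' @param y_pred predicted values.
#' @param method "rss" (default) or "ess".
#' @return R squared.
#' @export
r_squared <- function(y_true, y_pred, method = c("rss", "ess")) {
  method <- match.arg(method)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (length(y_true) < 2L || stats::var(y_true) == 0) {
    stop("R squared is undefined for constant or length < 2 observations")
  }
  tss <- sum((y_true - mean(y_true))^2)
  if (method == "rss") 1 - sum((y_true - y_pred)^2) / tss
  else sum((y_pred - mean(y_true))^2) / tss
}

#' Pearson correlation between observations and predictions
#'
#' @inheritParams r_squared
#' @return sample correlation coefficient in `[-1, 1]`; `NA` when either
#'   vector is constant.
#' @export
pearson_r <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  suppressWarnings(stats::cor(y_true, y_pred))
}

#' Repeated random-split evaluation protocol
#'
#' In each repeat the data are shuffled with that repeat's seed,
#' split into training and held-out test parts (80:20 by default, plain
#' random, unstratified), the model is trained on the training part via
#' `factory` and evaluated on the test part. Reported metrics are the
#' per-repeat values and their arithmetic means over 10 repeats for the
#' binary and regression tasks and 30 repeats for the ternary task. If a
#' classification training split misses a class entirely, that repeat is
#' re-drawn with the next unused seed (recorded in the report).
#'
#' @param y full vector of labels (0/1 or 0/1/2) or numeric targets.
#' @param factory function(train_idx) that trains a model on those rows
#'   and returns a prediction function(test_idx) yielding, per task:
#'   binary, a probability vector; multiclass, a K x n_classes
#'   probability matrix; regression, a numeric vector.
#' @param task "binary", "multiclass" or "regression".
#' @param n_repeats number of repeats; defaults to 30 for multiclass and
#'   10 otherwise.
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed_base integer; repeat i uses seed `seed_base + i - 1`.
#' @param stratified stratify splits by class (off by default, matching
#'   plain random separation).
#' @return object of class `metric_report`: data.frame `per_repeat` (one
#'   row per repeat: seed and metrics), numeric `mean` (column means),
#'   `n_repeats`, `split_fraction`, and `redrawn` (seeds that were
#'   replaced).
#' @export
repeated_split_evaluate <- function(y, factory,
                                    task = c("binary", "multiclass",
                                             "regression"),
                                    n_repeats = NULL, test_fraction = 0.2,
                                    seed_base = 1000L, stratified = FALSE) {
  task <- match.arg(task)
  if (is.null(n_repeats)) {
    n_repeats <- if (task == "multiclass") 30L else 10L
  }
  n <- length(y)
  n_test <- max(1L, round(test_fraction * n))
  rows <- list(); redrawn <- integer(0)
  next_seed <- seed_base
  draw_split <- function(seed) {
    set.seed(seed)
    perm <- sample.int(n)   # shuffle, then cut: test first, rest train
    if (stratified && task != "regression") {
      test_idx <- unlist(lapply(split(perm, y[perm]), function(g) {
        g[seq_len(max(1L, round(test_fraction * length(g))))]
      }), use.names = FALSE)
    } else {
      test_idx <- perm[seq_len(n_test)]
    }
    list(test = test_idx, train = setdiff(perm, test_idx))
  }
  for (rep_i in seq_len(n_repeats)) {
    repeat {
      seed <- next_seed
      next_seed <- next_seed + 1L
      sp <- draw_split(seed)
      if (task == "regression") break
      want <- if (task == "binary") c(0, 1) else 0:2
      if (all(want %in% y[sp$train])) break
      redrawn <- c(redrawn, seed)
    }
    predict_fun <- factory(sp$train)
    out <- predict_fun(sp$test)
    y_test <- y[sp$test]
    metrics <- switch(task,
      binary = {
        scores <- as.numeric(out)
        cc <- confusion_counts(y_test, as.integer(scores >= 0.5))
        c(binary_metrics(cc),
          auc = if (length(unique(y_test)) == 2L)
            auc_score(y_test, scores) else NA_real_)
      },
      multiclass = {
        prob <- as.matrix(out)
        pred <- max.col(prob, ties.method = "first") - 1L
        acc <- 100 * mean(pred == y_test)
        c(overall_accuracy = acc,
          micro_multiclass_metrics(y_test, pred, ncol(prob)),
          micro_auc = micro_auc(y_test, prob))
      },
      regression = {
        pred <- as.numeric(out)
        c(r2 = r_squared(y_test, pred), r = pearson_r(y_test, pred),
          mse = mean((y_test - pred)^2))
      })
    rows[[rep_i]] <- c(seed = seed, metrics)
  }
  per_repeat <- as.data.frame(do.call(rbind, rows))
  means <- colMeans(per_repeat[, -1, drop = FALSE])
  structure(list(per_repeat = per_repeat, mean = means,
                 n_repeats = n_repeats, split_fraction = test_fraction,
                 redrawn = redrawn),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Repeated random-split evaluation: ", x$n_repeats, " repeats, ",
      sprintf("%.0f:%.0f", 100 * (1 - x$split_fraction),
              100 * x$split_fraction), " train:test\n", sep = "")
  cat("Mean metrics over repeats:\n")
  print(round(x$mean, 4))
  if (length(x$redrawn) > 0) {
    cat("Re-drawn seeds (class missing from a training split):",
        paste(x$redrawn, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a metric report to CSV and JSON
#'
#' The CSV carries one row per repeat plus a final `mean` row; the JSON
#' mirrors the report structure.
#'
#' @param report a `metric_report`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return the report, invisibly.
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    tab <- report$per_repeat
    tab$repeat_id <- as.character(seq_len(nrow(tab)))
    mean_row <- data.frame(seed = NA_real_, t(report$mean),
                           repeat_id = "mean", check.names = FALSE)
    tab <- rbind(tab, mean_row)
    tab <- tab[, c("repeat_id", setdiff(colnames(tab), "repeat_id"))]
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_repeats = report$n_repeats,
           split_fraction = report$split_fraction,
           mean = as.list(report$mean),
           per_repeat = report$per_repeat,
           redrawn_seeds = report$redrawn),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
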
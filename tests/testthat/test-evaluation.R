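test_that("confusion counts tally the four binary cells", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cc, list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_identical(perfect$FP + perfect$FN, 0L)
  allpos <- confusion_counts(c(0, 0, 0), c(1, 1, 1))
  expect_identical(allpos$TN, 0L)
  expect_identical(allpos$FP, 3L)
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")
})

test_that("percent metrics follow the printed formulas and report NA when undefined", {
  m <- binary_metrics(list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_equal(unname(m), c(50, 50, 50))
  m2 <- binary_metrics(list(TP = 3L, TN = 0L, FP = 0L, FN = 1L))
  expect_equal(unname(m2[["sensitivity"]]), 75)
  expect_true(is.na(m2[["specificity"]]))  # undefined, not 0
  m3 <- binary_metrics(list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  expect_equal(unname(m3), c(100, 100, 100))
})

test_that("micro metrics match hand-pooled one-vs-rest tables", {
  # y_true=(0,1,2), y_pred=(0,1,1): pooled TP=2 FN=1 FP=1 TN=5
  m <- micro_multiclass_metrics(c(0, 1, 2), c(0, 1, 1))
  expect_equal(unname(m[["micro_sensitivity"]]), 100 * 2 / 3)
  expect_equal(unname(m[["micro_specificity"]]), 100 * 5 / 6)
  expect_equal(unname(m[["micro_accuracy"]]), 100 * 7 / 9)
  perfect <- micro_multiclass_metrics(c(0, 1, 2, 2), c(0, 1, 2, 2))
  expect_equal(unname(perfect), c(100, 100, 100))
})

test_that("micro metrics agree with the brute-force oracle on random instances", {
  set.seed(123)
  for (i in 1:300) {
    n <- sample(2:30, 1)
    yt <- sample(0:2, n, replace = TRUE)
    yp <- sample(0:2, n, replace = TRUE)
    expect_equal(micro_multiclass_metrics(yt, yp), oracle_micro(yt, yp))
  }
})

test_that("AUC equals the pairwise Mann-Whitney statistic, ties at 1/2", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc_score(c(1, 0, 1, 0), c(0.5, 0.5, 0.5, 0.5)), 0.5)
  expect_equal(auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_error(auc_score(c(1, 1), c(0.2, 0.3)), "one class")

  set.seed(321)
  for (i in 1:60) {
    n <- sample(4:200, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)  # coarse scores force ties
    expect_equal(auc_score(y, s), oracle_auc_pairwise(y, s))
  }
})

test_that("micro AUC flattens one-vs-rest indicators with class scores", {
  y <- c(0, 1, 2, 1)
  s <- matrix(c(0.7, 0.1, 0.1, 0.2,
                0.2, 0.8, 0.2, 0.6,
                0.1, 0.1, 0.7, 0.2), ncol = 3)
  flat_y <- c(y == 0, y == 1, y == 2) * 1L
  flat_s <- c(s[, 1], s[, 2], s[, 3])
  expect_equal(micro_auc(y, s), oracle_auc_pairwise(flat_y, flat_s))
  perfect <- diag(3)[c(1, 2, 3, 2), ]
  expect_equal(micro_auc(y, perfect), 1)
})

test_that("R squared and Pearson R follow their definitions", {
  y <- c(0, 1, 2)
  expect_equal(r_squared(y, y), 1)
  expect_equal(pearson_r(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_true(is.na(pearson_r(y, rep(mean(y), 3))))

  # hand arithmetic: yhat=(0,1,4): RSS=4, TSS=2 -> R2=-1; r=6/sqrt(39)
  yp <- c(0, 1, 4)
  expect_equal(r_squared(y, yp), -1)
  expect_equal(pearson_r(y, yp), 6 / sqrt(39))
  # ESS/TSS variant: sum((yhat-1)^2)/2 = (1+0+9)/2
  expect_equal(r_squared(y, yp, method = "ess"), 5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "undefined")
})

test_that("metric ranges hold on random prediction vectors", {
  set.seed(555)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    yt <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    yp <- sample(0:1, n, replace = TRUE)
    m <- binary_metrics(confusion_counts(yt, yp))
    expect_true(all(m >= 0 & m <= 100, na.rm = TRUE))
    expect_true(auc_score(yt, runif(n)) >= 0 &&
                  auc_score(yt, runif(n)) <= 1)
    mm <- micro_multiclass_metrics(sample(0:2, n, TRUE), sample(0:2, n, TRUE))
    expect_true(all(mm >= 0 & mm <= 100))
  }
})

test_that("repeated splits hold out 20%, average exactly, and reproduce bit-for-bit", {
  set.seed(1)
  y <- sample(0:1, 100, replace = TRUE)
  # deterministic stump on a fake score: majority class of the training part
  factory <- function(train_idx) {
    p <- mean(y[train_idx])
    function(test_idx) rep(p, length(test_idx))
  }
  sizes <- integer(0)
  counting_factory <- function(train_idx) {
    sizes <<- c(sizes, 100L - length(train_idx))
    factory(train_idx)
  }
  rep1 <- repeated_split_evaluate(y, counting_factory, "binary",
                                  seed_base = 77L)
  expect_identical(sizes, rep(20L, 10L))
  expect_identical(rep1$n_repeats, 10L)
  expect_equal(unname(rep1$mean),
               unname(colMeans(rep1$per_repeat[, -1])))

  rep2 <- repeated_split_evaluate(y, factory, "binary", seed_base = 77L)
  expect_identical(rep1$per_repeat, rep2$per_repeat)

  # a constant predictor scores the majority-class base rate on average
  base_rate <- max(mean(y), 1 - mean(y))
  expect_lt(abs(mean(rep1$per_repeat$accuracy) / 100 - base_rate), 0.1)
})

test_that("multiclass protocol defaults to 30 repeats and re-draws class-starved splits", {
  y <- c(rep(0, 12), rep(1, 12), rep(2, 2))  # class 2 is rare
  seen <- list()
  factory <- function(train_idx) {
    seen[[length(seen) + 1L]] <<- sort(unique(y[train_idx]))
    function(test_idx) {
      matrix(rep(c(0.2, 0.5, 0.3), each = length(test_idx)),
             ncol = 3)
    }
  }
  rep3 <- repeated_split_evaluate(y, factory, "multiclass", seed_base = 5L)
  expect_identical(rep3$n_repeats, 30L)
  expect_identical(nrow(rep3$per_repeat), 30L)
  # every accepted training split contained all three classes
  for (cls in seen) expect_identical(cls, c(0, 1, 2))
})

test_that("metric reports serialize to CSV with a mean row and to JSON", {
  y <- rep(c(0, 1), 25)
  factory <- function(train_idx) {
    function(test_idx) runif(length(test_idx))
  }
  set.seed(2)
  rep4 <- repeated_split_evaluate(y, factory, "binary", n_repeats = 3L)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep4, csv, js)
  tab <- read.csv(csv)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$repeat_id[4], "mean")
  expect_equal(tab$accuracy[4], unname(rep4$mean[["accuracy"]]))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$n_repeats, 3)
  expect_equal(parsed$mean$auc, unname(rep4$mean[["auc"]]))
})
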
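test_that("a perfect diagonal confusion matrix scores 100 everywhere", {
  m <- confusion_metrics(confusion_matrix_2x2(40, 0, 0, 25))
  expect_equal(m$accuracy, 100)
  expect_equal(m$precision, 100)
  expect_equal(m$recall, 100)
  expect_equal(m$f1, 100)
  expect_equal(m$kappa, 100)
  expect_false(m$degenerate)
  expect_error(confusion_matrix_2x2(-1, 0, 0, 2), "non-negative")
  expect_error(confusion_matrix_2x2(0, 0, 0, 0), "at least one")
})

test_that("metrics match hand-computed values on a small matrix", {
  # bb=8 bm=2 mb=1 mm=9, positive = B:
  # acc 17/20, prec 8/9, rec 8/10, f1 16/19
  m <- confusion_metrics(confusion_matrix_2x2(8, 2, 1, 9))
  expect_equal(m$accuracy, 85)
  expect_equal(m$precision, round_half_up(100 * 8 / 9))
  expect_equal(m$recall, 80)
  expect_equal(m$f1, round_half_up(100 * 16 / 19))
  # pe = (10*9 + 10*11)/400 = 0.5 -> kappa = 0.35/0.5 = 0.7
  expect_equal(m$kappa, 70)
})

test_that("kappa equals the label-level oracle on random matrices", {
  set.seed(21)
  for (i in 1:25) {
    cnt <- rmultinom(1, sample(40:400, 1), prob = runif(4, 0.05, 1))[, 1]
    if (sum(cnt[1:2]) == 0 || sum(cnt[3:4]) == 0) next
    cm <- confusion_matrix_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    lab <- labels_from_cm(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(confusion_metrics(cm)$kappa,
                 round_half_up(100 * kappa_from_labels(lab$actual, lab$pred)))
  }
})

test_that("accuracy and kappa are invariant under the positive-class swap", {
  set.seed(22)
  for (i in 1:10) {
    cnt <- 1L + rpois(4, 30)
    cm <- confusion_matrix_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    b <- confusion_metrics(cm, positive = "B")
    m <- confusion_metrics(cm, positive = "M")
    expect_equal(b$accuracy, m$accuracy)
    expect_equal(b$kappa, m$kappa)
  }
  # precision/recall cross over under the swap
  cm <- confusion_matrix_2x2(8, 2, 1, 9)
  b <- confusion_metrics(cm, "B"); m <- confusion_metrics(cm, "M")
  expect_equal(b$precision, round_half_up(100 * 8 / 9))
  expect_equal(m$recall, 90)
})

test_that("degenerate denominators are reported as zero and flagged", {
  m <- confusion_metrics(confusion_matrix_2x2(0, 5, 0, 7))
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
  expect_true(m$degenerate)
})

test_that("stratified folds are balanced, exhaustive, and seeded", {
  y <- rep(c("B", "M"), c(10, 10))
  f <- stratified_kfold(y, 5L, seed = 3L)
  expect_identical(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_identical(sum(f == k & y == "B"), 2L)
    expect_identical(sum(f == k & y == "M"), 2L)
  }
  expect_identical(f, stratified_kfold(y, 5L, seed = 3L))
  expect_false(identical(f, stratified_kfold(y, 5L, seed = 4L)))

  # benchmark-sized cohort: 437 benign, 210 malignant, 5 folds
  y2 <- rep(c("B", "M"), c(437, 210))
  f2 <- stratified_kfold(y2, 5L, seed = 0L)
  bcounts <- tabulate(f2[y2 == "B"], 5L)
  mcounts <- tabulate(f2[y2 == "M"], 5L)
  expect_true(all(bcounts %in% c(87L, 88L)))
  expect_true(all(mcounts == 42L))
  expect_identical(length(f2), 647L)
  expect_error(stratified_kfold(rep(c("B", "M"), c(30, 3)), 5L),
               "class 'M'")
})

test_that("cross-validation pools a full-size confusion matrix", {
  set.seed(23)
  n <- 60L
  x <- matrix(rnorm(n * 4), n, 4)
  y <- rep(c("B", "M"), each = n / 2)
  x[, 1] <- x[, 1] + ifelse(y == "M", 6, -6)       # cleanly separable
  res <- cross_validate(x, y, classifier_spec("svm_cubic"), k = 5L, seed = 1L)
  cm <- res$cm
  expect_identical(cm$bb + cm$bm + cm$mb + cm$mm, n)
  expect_equal(res$metrics$accuracy, 100)
  expect_identical(sort(unique(res$folds)), 1:5)
  expect_error(cross_validate(x, rep("B", n), classifier_spec("svm_cubic")),
               "two classes")
})

test_that("every classifier kind trains and predicts a separable problem", {
  set.seed(24)
  n <- 80L
  x <- matrix(rnorm(n * 3), n, 3)
  y <- rep(c("B", "M"), c(50, 30))                  # imbalanced on purpose
  x[, 2] <- x[, 2] + ifelse(y == "M", 5, -5)
  for (kind in c("svm_cubic", "svm_quadratic", "tree_medium",
                 "rus_boost", "bag_boost", "lasso_binomial")) {
    res <- cross_validate(x, y, classifier_spec(kind, seed = 9L),
                          k = 5L, seed = 2L)
    expect_gte(res$metrics$accuracy, 95)
  }
})

test_that("confusion matrices round-trip through the CSV layout", {
  tmp <- withr::local_tempdir()
  cm <- confusion_matrix_2x2(436, 1, 8, 202)
  p <- file.path(tmp, "cm.csv")
  write_confusion_csv(cm, p)
  back <- read_confusion_csv(p)
  expect_identical(unclass(back), unclass(cm))
})
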
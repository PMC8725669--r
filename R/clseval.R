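# Classification evaluation: exact 2x2 confusion-matrix metrics
# (accuracy, precision, recall, F1, Cohen's kappa), stratified k-fold
# cross-validation, and a small family of pluggable classifiers.

#' 2x2 confusion matrix
#'
#' Rows are the actual class, columns the predicted class, in the fixed
#' order (B, M): benign then malignant.
#'
#' @param bb actual B predicted B
#' @param bm actual B predicted M
#' @param mb actual M predicted B
#' @param mm actual M predicted M
#' @return an object of class \code{confusion_matrix_2x2}
#' @export
confusion_matrix_2x2 <- function(bb, bm, mb, mm) {
  counts <- c(bb = bb, bm = bm, mb = mb, mm = mm)
  if (any(counts < 0)) sq_stop("confusion counts must be non-negative")
  if (any(counts %% 1 != 0)) sq_stop("confusion counts must be whole numbers")
  counts <- as.integer(counts)
  names(counts) <- c("bb", "bm", "mb", "mm")
  if (sum(counts) < 1) sq_stop("confusion matrix must contain at least one case")
  structure(as.list(counts), class = "confusion_matrix_2x2")
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall, F1 (for the positive class) and Cohen's
#' kappa, all as percentages rounded half-up to two decimals. Kappa is
#' (p_o - p_e) / (1 - p_e) with the expected agreement p_e computed from
#' the row/column marginals. Metrics whose denominator is zero are
#' reported as 0 and flagged degenerate.
#'
#' @param cm a \code{\link{confusion_matrix_2x2}}
#' @param positive which class counts as positive, "B" (default) or "M"
#' @return list with accuracy, precision, recall, f1, kappa,
#'   positive_class, degenerate
#' @export
confusion_metrics <- function(cm, positive = c("B", "M")) {
  positive <- match.arg(positive)
  if (!inherits(cm, "confusion_matrix_2x2"))
    cm <- do.call(confusion_matrix_2x2, as.list(cm))
  bb <- cm$bb; bm <- cm$bm; mb <- cm$mb; mm <- cm$mm
  tot <- bb + bm + mb + mm
  if (positive == "B") {
    tp <- bb; fp <- mb; fn <- bm; tn <- mm
  } else {
    tp <- mm; fp <- bm; fn <- mb; tn <- bb
  }
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; return(0) }
    num / den
  }
  acc <- (tp + tn) / tot
  prec <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  f1 <- if (prec + rec == 0) { degenerate <- TRUE; 0 }
        else 2 * prec * rec / (prec + rec)
  pe <- ((bb + bm) * (bb + mb) + (mb + mm) * (bm + mm)) / tot^2
  kappa <- if (pe == 1) { degenerate <- TRUE; 0 } else (acc - pe) / (1 - pe)
  list(accuracy = round_half_up(100 * acc),
       precision = round_half_up(100 * prec),
       recall = round_half_up(100 * rec),
       f1 = round_half_up(100 * f1),
       kappa = round_half_up(100 * kappa),
       positive_class = positive,
       degenerate = degenerate)
}

#' Seeded stratified k-fold assignment
#'
#' Partitions samples into k folds so per-fold class counts differ by at
#' most one from perfect stratification. Identical seed gives an
#' identical assignment.
#'
#' @param labels class label vector
#' @param k fold count
#' @param seed integer seed
#' @return integer vector of fold indices in 1..k
#' @export
stratified_kfold <- function(labels, k, seed = 0L) {
  y <- factor(labels)
  k <- as.integer(k)
  tab <- table(y)
  small <- names(tab)[tab < k]
  if (length(small))
    sq_stop("class '", small[1L], "' has fewer than k = ", k, " members")
  with_seed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      i <- which(y == lv)
      fold[i] <- sample(rep_len(sample.int(k), length(i)))
    }
    fold
  })
}

#' Classifier specification
#'
#' @param kind one of "svm_cubic", "svm_quadratic", "tree_medium",
#'   "rus_boost", "bag_boost", "lasso_binomial"
#' @param hyper named list of hyperparameter overrides
#' @param seed integer seed for any stochastic training step
#' @return an object of class \code{classifier_spec}
#' @export
classifier_spec <- function(kind = c("svm_cubic", "svm_quadratic",
                                     "tree_medium", "rus_boost",
                                     "bag_boost", "lasso_binomial"),
                            hyper = list(), seed = 0L) {
  structure(list(kind = match.arg(kind), hyper = hyper,
                 seed = as.integer(seed)), class = "classifier_spec")
}

hyper_get <- function(spec, name, default) {
  if (!is.null(spec$hyper[[name]])) spec$hyper[[name]] else default
}

train_classifier <- function(spec, x, y) {
  x <- as.matrix(x); y <- factor(y)
  kind <- spec$kind
  model <- with_seed(spec$seed, switch(kind,
    svm_cubic = e1071::svm(x, y, kernel = "polynomial",
                           degree = 3L, coef0 = hyper_get(spec, "coef0", 1),
                           cost = hyper_get(spec, "cost", 1),
                           scale = hyper_get(spec, "scale", FALSE)),
    svm_quadratic = e1071::svm(x, y, kernel = "polynomial",
                               degree = 2L, coef0 = hyper_get(spec, "coef0", 1),
                               cost = hyper_get(spec, "cost", 1),
                               scale = hyper_get(spec, "scale", FALSE)),
    tree_medium = {
      df <- data.frame(y = y, x)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = hyper_get(spec, "maxdepth", 20L),
                     cp = hyper_get(spec, "cp", 1e-3),
                     minsplit = hyper_get(spec, "minsplit", 10L)))
    },
    rus_boost = boost_fit(x, y, rounds = hyper_get(spec, "rounds", 30L),
                          maxdepth = hyper_get(spec, "maxdepth", 3L),
                          rus = TRUE),
    bag_boost = boost_fit(x, y, rounds = hyper_get(spec, "rounds", 30L),
                          maxdepth = hyper_get(spec, "maxdepth", 5L),
                          rus = FALSE),
    lasso_binomial = lasso_fit(x, y, folds = hyper_get(spec, "folds", 5L),
                               seed = spec$seed),
    sq_stop("unknown classifier kind: ", kind)))
  structure(list(kind = kind, model = model, levels = levels(y)),
            class = "sq_classifier")
}

predict_classifier <- function(fit, x) {
  x <- as.matrix(x)
  pred <- switch(fit$kind,
    svm_cubic = ,
    svm_quadratic = as.character(stats::predict(fit$model, x)),
    tree_medium = {
      cls <- stats::predict(fit$model, data.frame(x), type = "class")
      as.character(cls)
    },
    rus_boost = ,
    bag_boost = boost_predict(fit$model, x),
    lasso_binomial = as.character(stats::predict(fit$model, x)))
  factor(pred, levels = fit$levels)
}

# AdaBoost.M1 over shallow rpart learners; with rus = TRUE each round is
# trained on all minority cases plus a weight-proportional undersample of
# the majority class (RUS-Boost); with rus = FALSE rounds use
# weight-proportional bootstrap resamples (bagged boosting).
boost_fit <- function(x, y, rounds = 30L, maxdepth = 3L, rus = FALSE) {
  n <- length(y)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 5L,
                               xval = 0L)
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  for (t in seq_len(rounds)) {
    idx <- if (rus) {
      mi <- which(y == minority)
      ma <- which(y != minority)
      c(mi, sample(ma, size = min(length(ma), length(mi)),
                   prob = w[ma] / sum(w[ma])))
    } else {
      sample.int(n, n, replace = TRUE, prob = w)
    }
    df <- data.frame(y = y[idx], x[idx, , drop = FALSE])
    fit <- rpart::rpart(y ~ ., data = df, method = "class", control = ctrl)
    pred <- stats::predict(fit, data.frame(x), type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 0.5) next                      # unhelpful round, reweight only
    err <- max(err, 1e-10)
    a <- 0.5 * log((1 - err) / err)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(ifelse(miss, a, -a))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (length(learners) == 0L) {               # fall back to a single tree
    df <- data.frame(y = y, x)
    learners <- list(rpart::rpart(y ~ ., data = df, method = "class",
                                  control = ctrl))
    alphas <- 1
  }
  list(learners = learners, alphas = alphas, levels = levels(y))
}

boost_predict <- function(model, x) {
  score <- 0
  for (i in seq_along(model$learners)) {
    p <- stats::predict(model$learners[[i]], data.frame(x), type = "prob")
    # margin toward the second level
    score <- score + model$alphas[i] * (p[, model$levels[2L]] -
                                        p[, model$levels[1L]])
  }
  model$levels[(score > 0) + 1L]
}

#' Stratified k-fold cross-validation with a pooled confusion matrix
#'
#' Trains on k-1 folds, predicts the held-out fold, and accumulates all
#' out-of-fold predictions into one pooled 2x2 confusion matrix (so the
#' matrix total equals the dataset size), from which the metric set is
#' computed. Fully seeded.
#'
#' @param features numeric matrix (samples x features)
#' @param labels vector of class labels, levels ordered (B, M)
#' @param spec a \code{\link{classifier_spec}}
#' @param k fold count
#' @param seed integer seed for the fold assignment
#' @param positive positive class for the metrics
#' @return list with \code{cm} (confusion_matrix_2x2), \code{metrics}
#'   (see \code{\link{confusion_metrics}}) and \code{folds}
#' @export
cross_validate <- function(features, labels, spec, k = 5L, seed = 0L,
                           positive = "B") {
  features <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2L) sq_stop("labels must contain exactly two classes")
  fold <- stratified_kfold(y, k, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- tryCatch(
      train_classifier(spec, features[tr, , drop = FALSE], y[tr]),
      error = function(e) sq_stop("classifier '", spec$kind,
                                  "' failed on fold ", f, ": ",
                                  conditionMessage(e)))
    pred[!tr] <- predict_classifier(fit, features[!tr, , drop = FALSE])
  }
  lv <- levels(y)
  cm <- confusion_matrix_2x2(
    bb = sum(y == lv[1L] & pred == lv[1L]),
    bm = sum(y == lv[1L] & pred == lv[2L]),
    mb = sum(y == lv[2L] & pred == lv[1L]),
    mm = sum(y == lv[2L] & pred == lv[2L]))
  list(cm = cm, metrics = confusion_metrics(cm, positive), folds = fold)
}

#' Read / write a 2x2 confusion matrix as CSV
#'
#' The CSV layout mirrors the printed tables: header row/column labelled
#' B, M; rows are the actual class.
#'
#' @param path file path
#' @return a \code{\link{confusion_matrix_2x2}}
#' @export
read_confusion_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1L)
  confusion_matrix_2x2(bb = d["B", "B"], bm = d["B", "M"],
                       mb = d["M", "B"], mm = d["M", "M"])
}

#' @rdname read_confusion_csv
#' @param cm a \code{\link{confusion_matrix_2x2}}
#' @export
write_confusion_csv <- function(cm, path) {
  d <- data.frame(B = c(cm$bb, cm$mb), M = c(cm$bm, cm$mm),
                  row.names = c("B", "M"))
  utils::write.csv(d, path)
  invisible(path)
}
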
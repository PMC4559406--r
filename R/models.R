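CLASSIFIERS <- c("svm", "knn", "tree", "rf", "nb", "logistic", "mlp")

## Classifiers fit on standardized features; trees and naive Bayes take raw
## values.
STANDARDIZED <- c("svm", "knn", "logistic", "mlp")

SVM_COST_GRID <- 2^seq(-5, 5, by = 1)
SVM_GAMMA_GRID <- 2^seq(-7, 3, by = 1)

## Stratified fold assignment: within each class, shuffled round-robin.
make_folds <- function(labels, k, seed) {
  if (k < 2) stop("'k' must be at least 2", call. = FALSE)
  if (k > min(table(labels)))
    stop(sprintf("'k' (%d) exceeds the smallest class size (%d)", k,
                 min(table(labels))), call. = FALSE)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

standardize_fit <- function(xmat) {
  ctr <- colMeans(xmat)
  scl <- apply(xmat, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(xmat, std) {
  scale(xmat, center = std$center, scale = std$scale)[, , drop = FALSE]
}

## Fit one classifier on a numeric matrix. y is a factor with levels
## c("negative", "positive"). Returns an opaque fit plus a threshold on the
## score scale (SVM margin for svm, positive-class probability otherwise).
fit_classifier <- function(xmat, y, classifier, hyper = list(), seed = 42) {
  cls <- match.arg(classifier, CLASSIFIERS)
  fit <- with_seed(seed, switch(cls,
    svm = e1071::svm(xmat, y, kernel = "radial",
                     cost = hyper$cost %||% 1,
                     gamma = hyper$gamma %||% (1 / ncol(xmat)),
                     scale = FALSE),
    knn = list(train = xmat, y = y, k = hyper$k %||% 1L),
    tree = rpart::rpart(y ~ ., data = data.frame(y = y, xmat),
                        method = "class"),
    rf = randomForest::randomForest(xmat, y,
                                    ntree = hyper$ntree %||% 500),
    nb = e1071::naiveBayes(xmat, y),
    logistic = suppressWarnings(
      stats::glm(y ~ ., data = data.frame(y = y, xmat),
                 family = stats::binomial())),
    mlp = nnet::nnet(xmat, as.numeric(y == "positive"),
                     size = hyper$size %||% 5,
                     decay = hyper$decay %||% 0.1, maxit = 200,
                     trace = FALSE, entropy = TRUE)
  ))
  list(classifier = cls, fit = fit, hyper = hyper,
       threshold = if (cls == "svm") 0 else 0.5)
}

## Score new rows with a fitted classifier; scores above the threshold mean
## the positive class.
score_classifier <- function(model, xmat) {
  cls <- model$classifier
  fit <- model$fit
  score <- switch(cls,
    svm = {
      pred <- stats::predict(fit, xmat, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      if (grepl("^positive/", colnames(dv)[1])) as.numeric(dv)
      else -as.numeric(dv)
    },
    knn = {
      pr <- class::knn(fit$train, xmat, fit$y, k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "positive", p, 1 - p)
    },
    tree = stats::predict(fit, data.frame(xmat),
                          type = "prob")[, "positive"],
    rf = stats::predict(fit, xmat, type = "prob")[, "positive"],
    nb = stats::predict(fit, xmat, type = "raw")[, "positive"],
    logistic = suppressWarnings(
      as.numeric(stats::predict(fit, data.frame(xmat), type = "response"))),
    mlp = as.numeric(stats::predict(fit, xmat))
  )
  unname(score)
}

## 3-fold inner grid search over (cost, gamma) for the RBF SVM, selected by
## inner-CV MCC. All tuning happens inside the supplied training data.
tune_svm <- function(xmat, y, seed) {
  folds <- make_folds(as.character(y), 3, seed)
  best <- list(mcc = -Inf, cost = 1, gamma = 1 / ncol(xmat))
  for (cost in SVM_COST_GRID) {
    for (gamma in SVM_GAMMA_GRID) {
      counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
      for (f in 1:3) {
        tr <- folds != f
        m <- fit_classifier(xmat[tr, , drop = FALSE], y[tr], "svm",
                            list(cost = cost, gamma = gamma), seed)
        sc <- score_classifier(m, xmat[!tr, , drop = FALSE])
        pred <- ifelse(sc > m$threshold, "positive", "negative")
        truth <- as.character(y[!tr])
        counts <- counts + c(sum(truth == "positive" & pred == "positive"),
                             sum(truth == "negative" & pred == "negative"),
                             sum(truth == "negative" & pred == "positive"),
                             sum(truth == "positive" & pred == "negative"))
      }
      mcc <- compute_metrics(confusion_counts(counts[1], counts[2],
                                              counts[3], counts[4]))$mcc
      if (mcc > best$mcc) best <- list(mcc = mcc, cost = cost, gamma = gamma)
    }
  }
  best
}

#' Fit a peptide activity classifier
#'
#' The central fitting function of the package: encodes a labelled peptide
#' dataset under a terminus scheme and feature kind, then trains a binary
#' classifier of anti-angiogenic activity. The RBF-kernel SVM (the default)
#' tunes its cost and kernel width on an internal 3-fold grid search over
#' `C = 2^-5..2^5`, `gamma = 2^-7..2^3` (selected by inner
#' cross-validated MCC) unless fixed values are supplied.
#'
#' @param x A [peptide_set] containing both classes.
#' @param classifier One of `"svm"` (RBF support vector machine), `"knn"`
#'   (nearest neighbour), `"tree"` (decision tree), `"rf"` (random forest),
#'   `"nb"` (naive Bayes), `"logistic"`, `"mlp"` (single-hidden-layer
#'   perceptron).
#' @param feature Feature kind: `"aac"`, `"dpc"` or `"binary"`.
#' @param scheme Terminus scheme (see [terminus_schemes()]).
#' @param seed Integer seed governing tuning folds and any classifier
#'   randomness.
#' @param tune For `"svm"`: run the inner grid search (default `TRUE`).
#' @param hyper Optional named list of fixed hyperparameters (e.g.
#'   `list(cost = 2, gamma = 0.05)`), which disables tuning.
#' @return An object of class `peptide_model` with `print`, `summary` and
#'   [predict.peptide_model()] methods.
#' @examples
#' fx <- generate_fixture_data(30, 30, seed = 7)
#' ps <- bind_peptides(fx$positive, fx$negative)
#' m <- peptide_model(ps, "svm", "aac", "WHOLE", seed = 1, tune = FALSE)
#' predict(m, fx$positive[1:3, "sequence"])
#' @export
peptide_model <- function(x, classifier = "svm", feature = "aac",
                          scheme = "WHOLE", seed = 42, tune = TRUE,
                          hyper = NULL) {
  stopifnot(inherits(x, "peptide_set"))
  classifier <- match.arg(classifier, CLASSIFIERS)
  if (length(unique(x$label[x$label != "unlabeled"])) < 2)
    stop("training data must contain both classes", call. = FALSE)
  fm <- encode_dataset(x, scheme, feature)
  y <- factor(x$label, levels = c("negative", "positive"))
  std <- NULL
  xmat <- unclass(fm)
  attr(xmat, "schema") <- NULL
  attr(xmat, "labels") <- NULL
  if (classifier %in% STANDARDIZED) {
    std <- standardize_fit(xmat)
    xmat <- standardize_apply(xmat, std)
  }
  if (classifier == "svm" && is.null(hyper) && tune)
    hyper <- tune_svm(xmat, y, seed)
  core <- fit_classifier(xmat, y, classifier, hyper %||% list(), seed)
  structure(list(
    classifier = classifier,
    schema = attr(fm, "schema"),
    standardize = std,
    core = core,
    threshold = core$threshold,
    hyper = core$hyper,
    seed = seed,
    fingerprint = list(n = nrow(x),
                       checksum = sum(utf8ToInt(paste(x$id, x$sequence,
                                                      collapse = ""))))
  ), class = "peptide_model")
}

## Extract/validate a feature matrix for prediction.
model_features <- function(object, newdata) {
  if (inherits(newdata, "feature_matrix")) {
    sc <- attr(newdata, "schema")
    if (!identical(sc$kind, object$schema$kind) ||
        !identical(sc$scheme, object$schema$scheme))
      stop(sprintf(
        "feature schema mismatch: model expects %s/%s, got %s/%s",
        object$schema$kind, object$schema$scheme, sc$kind, sc$scheme),
        call. = FALSE)
    fm <- newdata
  } else {
    if (is.character(newdata))
      newdata <- peptide_set(sprintf("q%d", seq_along(newdata)), newdata)
    stopifnot(inherits(newdata, "peptide_set"))
    fm <- encode_dataset(newdata, object$schema$scheme, object$schema$kind)
  }
  xmat <- unclass(fm)
  attr(xmat, "schema") <- NULL
  attr(xmat, "labels") <- NULL
  if (!is.null(object$standardize))
    xmat <- standardize_apply(xmat, object$standardize)
  xmat
}

#' Predict anti-angiogenic activity
#'
#' @param object A [peptide_model()].
#' @param newdata A [peptide_set], a character vector of sequences, or a
#'   `feature_matrix` with a matching schema.
#' @param type `"class"`, `"score"` (SVM margin or positive-class
#'   probability) or `"both"` (data frame).
#' @param ... Unused.
#' @return Character vector of class labels, numeric scores, or a data
#'   frame with both.
#' @export
predict.peptide_model <- function(object, newdata,
                                  type = c("class", "score", "both"), ...) {
  type <- match.arg(type)
  xmat <- model_features(object, newdata)
  if (nrow(xmat) == 0) {
    sc <- numeric(0)
  } else {
    sc <- score_classifier(object$core, xmat)
  }
  cl <- ifelse(sc > object$threshold, "positive", "negative")
  switch(type, class = cl, score = sc,
         both = data.frame(id = rownames(xmat) %||%
                             sprintf("q%d", seq_along(sc)),
                           score = sc, class = cl))
}

#' @export
print.peptide_model <- function(x, ...) {
  cat(sprintf("<peptide_model> %s on %s/%s features (n = %d)\n",
              x$classifier, x$schema$scheme, x$schema$kind,
              x$fingerprint$n))
  if (x$classifier == "svm" && length(x$hyper) > 0)
    cat(sprintf("  RBF SVM: cost = %g, gamma = %g\n",
                x$hyper$cost %||% 1, x$hyper$gamma %||% NA))
  invisible(x)
}

#' @method summary peptide_model
#' @export
summary.peptide_model <- function(object, ...) {
  print(object)
  cat(sprintf("  decision threshold: %g (%s scale)\n", object$threshold,
              if (object$classifier == "svm") "margin" else "probability"))
  invisible(object)
}

#' Evaluate a fitted model on a labelled dataset
#'
#' Predicts every record (no refitting) and reduces predictions against the
#' stored labels to confusion counts and metrics.
#'
#' @param model A [peptide_model()].
#' @param x A non-empty [peptide_set] with class labels.
#' @return A [compute_metrics()] object.
#' @export
evaluate <- function(model, x) {
  stopifnot(inherits(model, "peptide_model"), inherits(x, "peptide_set"))
  if (nrow(x) == 0) stop("evaluation dataset is empty", call. = FALSE)
  pred <- predict(model, x, type = "class")
  compute_metrics(tabulate_confusion(x$label, pred))
}

#' Stratified k-fold cross-validation
#'
#' Partitions the dataset into k stratified folds, trains on k-1 and tests
#' on the held-out fold, each fold tested exactly once. SVM hyperparameter
#' tuning runs inside the training folds only. Aggregate metrics are
#' computed from the pooled fold confusion counts (the default) or as the
#' mean of per-fold metrics.
#'
#' @inheritParams peptide_model
#' @param k Number of folds (default 10).
#' @param aggregate `"pooled"` (counts summed over folds, then metrics) or
#'   `"fold_mean"` (mean of per-fold metrics).
#' @param folds Optional pre-computed integer fold assignment (overrides
#'   `k`/`seed` fold generation; used to compare classifiers on identical
#'   folds).
#' @return An object of class `peptide_cv`: list with `metrics` (aggregate),
#'   `fold_metrics` (per fold), `pooled_counts`, `folds`, `spec`, `seed`.
#' @export
cross_validate <- function(x, classifier = "svm", feature = "aac",
                           scheme = "WHOLE", k = 10, seed = 42, tune = TRUE,
                           hyper = NULL, aggregate = c("pooled", "fold_mean"),
                           folds = NULL) {
  stopifnot(inherits(x, "peptide_set"))
  aggregate <- match.arg(aggregate)
  if (is.null(folds)) folds <- make_folds(x$label, k, seed)
  k <- max(folds)
  fold_metrics <- vector("list", k)
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (f in seq_len(k)) {
    train <- subset_peptides(x, folds != f)
    test <- subset_peptides(x, folds == f)
    m <- peptide_model(train, classifier, feature, scheme,
                       seed = seed + f, tune = tune, hyper = hyper)
    pred <- predict(m, test, type = "class")
    cc <- tabulate_confusion(test$label, pred)
    fold_metrics[[f]] <- compute_metrics(cc)
    pooled <- pooled + unlist(cc)
  }
  pooled_counts <- confusion_counts(pooled["tp"], pooled["tn"],
                                    pooled["fp"], pooled["fn"])
  metrics <- if (aggregate == "pooled") compute_metrics(pooled_counts) else {
    agg <- compute_metrics(pooled_counts)
    agg$sn <- mean(vapply(fold_metrics, `[[`, numeric(1), "sn"))
    agg$sp <- mean(vapply(fold_metrics, `[[`, numeric(1), "sp"))
    agg$acc <- mean(vapply(fold_metrics, `[[`, numeric(1), "acc"))
    agg$mcc <- mean(vapply(fold_metrics, `[[`, numeric(1), "mcc"))
    agg
  }
  structure(list(metrics = metrics, fold_metrics = fold_metrics,
                 pooled_counts = pooled_counts, folds = folds,
                 spec = list(classifier = classifier, feature = feature,
                             scheme = toupper(scheme), k = k,
                             aggregate = aggregate),
                 seed = seed),
            class = "peptide_cv")
}

#' @export
print.peptide_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: %s on %s/%s\n", x$spec$k,
              x$spec$classifier, x$spec$scheme, x$spec$feature))
  print(x$metrics)
  invisible(x)
}

#' @method summary peptide_cv
#' @export
summary.peptide_cv <- function(object, ...) {
  print(object)
  cat("Per-fold accuracy:",
      paste(sprintf("%.0f", vapply(object$fold_metrics, `[[`, numeric(1),
                                   "acc")), collapse = " "), "\n")
  invisible(object)
}

#' Compare classifiers on identical cross-validation folds
#'
#' Runs [cross_validate()] for each classifier kind with one shared fold
#' assignment (same seed), so rows are directly comparable.
#'
#' @inheritParams cross_validate
#' @param classifiers Character vector of classifier kinds.
#' @return A data frame with one row per classifier: `classifier`, `sn`,
#'   `sp`, `acc`, `mcc` plus pooled counts. The shared fold assignment is
#'   attached as attribute `"folds"`.
#' @export
compare_classifiers <- function(x, classifiers = CLASSIFIERS,
                                feature = "aac", scheme = "WHOLE", k = 10,
                                seed = 42, tune = TRUE) {
  folds <- make_folds(x$label, k, seed)
  rows <- lapply(classifiers, function(cl) {
    cv <- cross_validate(x, cl, feature, scheme, seed = seed, tune = tune,
                         folds = folds)
    cbind(data.frame(classifier = cl), metrics_row(cv$metrics))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  out
}

#' Model stability under re-sampled negative datasets
#'
#' Repeats the whole experiment with fresh length-matched random negative
#' sets drawn from the background proteome: for each repeat a new negative
#' set is sampled, pooled with the positives, and cross-validated. Stable
#' models show similar metrics across repeats.
#'
#' @param positives A positive [peptide_set].
#' @param background Background proteins to sample negatives from.
#' @inheritParams cross_validate
#' @param n_repeats Number of re-sampled negative sets (default 5).
#' @return Data frame with one row per repeat (`repeat_id`, `sn`, `sp`,
#'   `acc`, `mcc`, counts).
#' @export
stability_experiment <- function(positives, background, n_repeats = 5,
                                 classifier = "svm", feature = "aac",
                                 scheme = "WHOLE", k = 10, seed = 42,
                                 tune = TRUE) {
  rows <- lapply(seq_len(n_repeats), function(r) {
    neg <- sample_negative_regions(background, positives,
                                   n = nrow(positives),
                                   seed = seed + 1000L * r,
                                   prefix = sprintf("rand%d", r))
    pooled <- bind_peptides(positives, neg,
                            name = sprintf("random%d", r))
    cv <- cross_validate(pooled, classifier, feature, scheme, k = k,
                         seed = seed + r, tune = tune)
    cbind(data.frame(repeat_id = r), metrics_row(cv$metrics))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
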
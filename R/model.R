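# Balanced one-vs-rest classification with 10-fold cross-validation.
#
# The multi-label task (a question may carry several topics) is decomposed
# into one binary classifier per topic. Class skew is handled by
# under-sampling the majority class to the minority's size before training
# and testing, so every binary task is exactly balanced.

#' Under-sample the majority class to balance a binary task
#'
#' The minority class is kept verbatim; a uniform random subset of equal
#' size is drawn from the majority class. "Majority" is whichever class is
#' larger — for a prevalent topic the positives may be the majority.
#'
#' @param ids vector of instance identifiers.
#' @param labels logical vector parallel to `ids` (`TRUE` = positive).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return vector of retained ids (minority ids first, in input order).
#' @export
under_sample <- function(ids, labels, seed = 1L) {
  stopifnot(length(ids) == length(labels))
  labels <- as.logical(labels)
  pos <- ids[labels]
  neg <- ids[!labels]
  if (length(pos) == 0L || length(neg) == 0L) {
    chq_stop("both classes must be non-empty", class = "chqclass_invalid_input")
  }
  if (length(pos) == length(neg)) return(c(pos, neg))
  minority <- if (length(pos) < length(neg)) pos else neg
  majority <- if (length(pos) < length(neg)) neg else pos
  keep <- with_seed(seed, sample(seq_along(majority), length(minority)))
  c(minority, majority[sort(keep)])
}

#' Assign instances to cross-validation folds
#'
#' Random permutation followed by round-robin assignment, so fold sizes
#' differ by at most one and every id sits in exactly one test fold. When
#' `strata` is supplied (the binary labels, typically), the round-robin runs
#' within each stratum with rotated starting folds, so every fold also
#' tests on a near-equal number of positives and negatives — keeping the
#' balanced-train-balanced-test property of the under-sampled task true
#' per fold, not just overall.
#'
#' @param ids instance identifiers, `length(ids) >= k`.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param strata optional vector parallel to `ids`; folds are balanced
#'   within each stratum level.
#' @return a `chq_fold_plan`: named integer vector, fold index (0-based,
#'   `0..k-1`) by id, with attributes `k` and `seed`.
#' @export
make_folds <- function(ids, k = 10L, seed = 1L, strata = NULL) {
  if (length(ids) < k) {
    chq_stop("need at least k instances for k folds",
             class = "chqclass_invalid_input")
  }
  fold <- integer(length(ids))
  if (is.null(strata)) {
    perm <- with_seed(seed, sample(seq_along(ids)))
    fold[perm] <- (seq_along(ids) - 1L) %% k
  } else {
    stopifnot(length(strata) == length(ids))
    levels <- unique(strata)
    with_seed(seed, {
      for (li in seq_along(levels)) {
        idx <- which(strata == levels[li])
        perm <- idx[sample(length(idx))]
        offset <- floor(k * (li - 1L) / length(levels))
        fold[perm] <- (seq_along(perm) - 1L + offset) %% k
      }
    })
  }
  structure(stats::setNames(fold, as.character(ids)), k = as.integer(k),
            seed = as.integer(seed), class = "chq_fold_plan")
}

# fit one binary classifier on a plain numeric matrix
fit_classifier <- function(x, y, classifier = c("svm", "naive_bayes", "logistic"),
                           cost = 1) {
  classifier <- match.arg(classifier)
  colnames(x) <- paste0("f", seq_len(ncol(x))) # neutral names for model fits
  y <- factor(as.logical(y), levels = c(FALSE, TRUE))
  if (nlevels(droplevels(y)) < 2L) {
    chq_stop("training data contains a single class",
             class = "chqclass_invalid_input")
  }
  fit <- switch(classifier,
    svm = e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE),
    naive_bayes = e1071::naiveBayes(x, y),
    logistic = {
      df <- as.data.frame(x)
      suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                  family = stats::binomial()))
    })
  list(classifier = classifier, fit = fit)
}

predict_classifier <- function(model, x) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  out <- switch(model$classifier,
    svm = stats::predict(model$fit, x),
    naive_bayes = stats::predict(model$fit, as.data.frame(x)),
    logistic = {
      df <- as.data.frame(x)
      p <- suppressWarnings(stats::predict(model$fit, newdata = df,
                                           type = "response"))
      factor(p > 0.5, levels = c(FALSE, TRUE))
    })
  as.logical(as.character(out))
}

#' Train one binary topic classifier on selected features
#'
#' Computes Phi scores on the training data (unless a precomputed report is
#' supplied), selects features with [select_features()], projects the matrix
#' onto the selected columns and fits the classifier. The default is a
#' linear-kernel margin classifier (C = 1); naive Bayes and logistic
#' regression are available as baselines.
#'
#' @param topic topic name (metadata only).
#' @param x feature matrix (rows = instances), column order matching `space`.
#' @param y logical labels.
#' @param space `chq_feature_space` describing the columns.
#' @param selection optional precomputed `chq_phi_report`; when `NULL`,
#'   computed from `x`/`y`.
#' @param classifier `"svm"` (default), `"naive_bayes"` or `"logistic"`.
#' @param select if `FALSE`, skip feature selection and use all columns.
#' @param seed stored as metadata.
#' @return a `chq_topic_model`.
#' @export
train_binary <- function(topic, x, y, space, selection = NULL,
                         classifier = "svm", select = TRUE, seed = NA_integer_) {
  stopifnot(ncol(x) == nrow(space))
  y <- as.logical(y)
  if (select) {
    if (is.null(selection)) {
      phi <- phi_scores(x, y)
      selection <- select_features(phi, space$type, space$key)
    }
    cols <- which(selection$phi$selected)
  } else {
    cols <- seq_len(ncol(x))
  }
  xd <- as.matrix(x[, cols, drop = FALSE])
  model <- fit_classifier(xd, y, classifier)
  structure(
    list(topic = topic, columns = cols,
         manifest = space[cols, , drop = FALSE],
         selection = selection, model = model,
         meta = list(seed = seed, n = nrow(x),
                     n_pos = sum(y), n_neg = sum(!y))),
    class = "chq_topic_model"
  )
}

#' @export
print.chq_topic_model <- function(x, ...) {
  cat(sprintf("<topic model> %s: %s on %d features (n = %d, %d+/%d-)\n",
              x$topic, x$model$classifier, length(x$columns),
              x$meta$n, x$meta$n_pos, x$meta$n_neg))
  invisible(x)
}

#' Predict with a trained topic model
#'
#' @param object a `chq_topic_model`.
#' @param x feature matrix over the same feature space the model was trained
#'   on (all columns; the model projects onto its selected columns).
#' @param ... unused.
#' @return logical vector of binary decisions.
#' @export
predict.chq_topic_model <- function(object, x, ...) {
  if (ncol(x) < max(object$columns)) {
    chq_stop("feature matrix does not match the model's feature space",
             class = "chqclass_invalid_input")
  }
  xd <- as.matrix(x[, object$columns, drop = FALSE])
  predict_classifier(object$model, xd)
}

#' Multi-label topic assignment from six binary models
#'
#' A question receives every topic whose binary classifier fires; a question
#' on which none fires falls into the residual `"Other"` topic.
#'
#' @param x feature matrix (rows = questions) over the shared feature space.
#' @param models named list of `chq_topic_model`, one per topic.
#' @return list of character vectors, one topic set per row of `x`.
#' @export
predict_topics <- function(x, models) {
  votes <- vapply(models, function(m) predict(m, x), logical(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L,
                                           dimnames = list(NULL, names(models)))
  lapply(seq_len(nrow(votes)), function(i) {
    hit <- names(models)[votes[i, ]]
    if (length(hit) == 0L) OTHER_TOPIC else hit
  })
}

#' Cross-validate one balanced binary topic task
#'
#' For each of the k folds: Phi-score feature selection is recomputed on the
#' nine training folds only (no leakage of held-out labels), the classifier
#' is trained on the selected projection, and precision/recall/F1 are
#' measured on the held-out fold. Reported are the per-fold metrics and
#' their mean and standard deviation.
#'
#' @param x feature matrix of the balanced task (rows = instances).
#' @param y logical labels.
#' @param space `chq_feature_space` for the columns of `x`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold plan.
#' @param classifier passed to [train_binary()].
#' @param select perform per-fold Phi selection (default `TRUE`).
#' @param stratify balance folds over the labels (default `TRUE`), so each
#'   held-out fold contains test positives whenever a class has at least k
#'   members.
#' @return a `chq_cv_result`: list with `folds` (data.frame fold, tp, fp,
#'   fn, tn, precision, recall, f1, n_selected), `mean`, `sd` (named numeric
#'   over precision/recall/f1) and `fold_plan`.
#' @export
cross_validate <- function(x, y, space, k = 10L, seed = 1L,
                           classifier = "svm", select = TRUE,
                           stratify = TRUE) {
  y <- as.logical(y)
  stopifnot(nrow(x) == length(y))
  plan <- make_folds(seq_len(nrow(x)), k = k, seed = seed,
                     strata = if (stratify) y)
  rows <- lapply(0:(k - 1L), function(f) {
    test <- which(unname(plan) == f)
    train <- setdiff(seq_len(nrow(x)), test)
    model <- train_binary("cv", x[train, , drop = FALSE], y[train], space,
                          classifier = classifier, select = select, seed = seed)
    pred <- predict(model, x[test, , drop = FALSE])
    cc <- confusion_counts(pred, y[test])
    m <- prf(cc)
    data.frame(fold = f, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
               precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]], n_selected = length(model$columns))
  })
  folds <- do.call(rbind, rows)
  metr <- c("precision", "recall", "f1")
  structure(
    list(folds = folds,
         mean = vapply(folds[metr], mean, numeric(1)),
         sd = vapply(folds[metr], stats::sd, numeric(1)),
         fold_plan = plan),
    class = "chq_cv_result"
  )
}

#' @export
print.chq_cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv result> %d folds: P = %.4f (sd %.4f), R = %.4f (sd %.4f), F1 = %.4f (sd %.4f)\n",
    nrow(x$folds), x$mean[["precision"]], x$sd[["precision"]],
    x$mean[["recall"]], x$sd[["recall"]], x$mean[["f1"]], x$sd[["f1"]]))
  invisible(x)
}
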
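# Evaluation metrics: precision / recall / F1, macro-averaging over the six
# topics, and feature-reduction reporting.

#' Confusion counts from predicted and gold binary labels
#'
#' @param predicted,gold logical vectors of equal length.
#' @return list with fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, gold) {
  predicted <- as.logical(predicted); gold <- as.logical(gold)
  stopifnot(length(predicted) == length(gold))
  list(tp = sum(predicted & gold), fp = sum(predicted & !gold),
       fn = sum(!predicted & gold), tn = sum(!predicted & !gold))
}

#' Precision, recall and F1 from confusion counts
#'
#' `p = tp/(tp+fp)`, `r = tp/(tp+fn)`, `F1 = 2pr/(p+r)`; each metric is 0
#' when its denominator is 0 (so a classifier that never fires scores 0, not
#' NaN).
#'
#' @param counts list with `tp`, `fp`, `fn` (from [confusion_counts()]).
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
prf <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Macro-average metrics over the six topics
#'
#' Unweighted arithmetic means of the per-topic precisions, recalls and F1s.
#' Note the macro F1 is the mean of the per-topic F1s, not the harmonic mean
#' of the macro precision and recall.
#'
#' @param per_topic data.frame with columns `topic`, `precision`, `recall`,
#'   `f1`, one row per topic in [PRIMARY_TOPICS].
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
macro_average <- function(per_topic) {
  missing <- setdiff(PRIMARY_TOPICS, per_topic$topic)
  if (length(missing)) {
    chq_stop("missing topic(s): ", paste(missing, collapse = ", "),
             class = "chqclass_invalid_input")
  }
  rows <- per_topic[match(PRIMARY_TOPICS, per_topic$topic), ]
  c(precision = mean(rows$precision), recall = mean(rows$recall),
    f1 = mean(rows$f1))
}

#' Feature-reduction proportion
#'
#' The fraction of the feature space dropped by selection:
#' `1 - n_selected / n_all`.
#'
#' @param n_all total number of features (>= 1).
#' @param n_selected number retained (0 <= n_selected <= n_all).
#' @return reduction proportion in `[0, 1]`.
#' @export
reduction_report <- function(n_all, n_selected) {
  if (n_all < 1 || n_selected < 0 || n_selected > n_all) {
    chq_stop("need 0 <= n_selected <= n_all and n_all >= 1",
             class = "chqclass_invalid_input")
  }
  1 - n_selected / n_all
}

#' Assemble an evaluation report over topics
#'
#' Combines per-topic cross-validation results into one table with fold
#' means and standard deviations, a macro-average row, and feature-reduction
#' columns.
#'
#' @param cv_by_topic named list of `chq_cv_result`, one per topic in
#'   [PRIMARY_TOPICS].
#' @return a `chq_evaluation_report`: list with `per_topic` (data.frame) and
#'   `macro` (named numeric).
#' @export
evaluation_report <- function(cv_by_topic) {
  per_topic <- do.call(rbind, lapply(names(cv_by_topic), function(tp) {
    cv <- cv_by_topic[[tp]]
    data.frame(
      topic = tp,
      precision = cv$mean[["precision"]], precision_sd = cv$sd[["precision"]],
      recall = cv$mean[["recall"]], recall_sd = cv$sd[["recall"]],
      f1 = cv$mean[["f1"]], f1_sd = cv$sd[["f1"]],
      n_selected_mean = mean(cv$folds$n_selected),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(per_topic = per_topic, macro = macro_average(per_topic)),
            class = "chq_evaluation_report")
}

#' @export
print.chq_evaluation_report <- function(x, ...) {
  cat("<evaluation report>\n")
  df <- x$per_topic
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4L)
  print(df, row.names = FALSE)
  cat(sprintf("macro: P = %.4f, R = %.4f, F1 = %.4f\n",
              x$macro[["precision"]], x$macro[["recall"]], x$macro[["f1"]]))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Per-topic rows plus a trailing `Macro` row; proportions at 4 decimals.
#'
#' @param report a `chq_evaluation_report`.
#' @param path output path.
#' @export
write_evaluation_report <- function(report, path) {
  df <- report$per_topic
  macro <- data.frame(topic = "Macro",
                      precision = report$macro[["precision"]], precision_sd = NA,
                      recall = report$macro[["recall"]], recall_sd = NA,
                      f1 = report$macro[["f1"]], f1_sd = NA,
                      n_selected_mean = NA)
  out <- rbind(df, macro)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 4L, format = "f"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
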
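# Phi-score feature selection.
#
# The Phi-score (the F-score of Chen & Lin) of one feature column, given a
# binary split of the rows into n+ positive and n- negative instances, is
#
#   Phi = [ (mean+ - mean)^2 + (mean- - mean)^2 ] /
#         [ var+ + var- ]
#
# where `mean` is the overall column mean and var+/var- are the *sample*
# variances (divisor n-1) within each class. Larger Phi means the feature
# separates the classes more strongly relative to its within-class spread.
#
# Selection keeps, within each feature type, the features whose Phi is at
# least the type's average Phi. Per-type thresholds stop high-Phi families
# (e.g. semantic types) from crowding out useful features of low-Phi
# families (e.g. bag-of-words).

#' Phi-score of one feature column
#'
#' @param positives numeric values of the feature on positive instances
#'   (length >= 2).
#' @param negatives numeric values on negative instances (length >= 2).
#' @param sentinel value returned when both within-class variances are zero
#'   but the class means differ (a perfect separator); default `Inf`, which
#'   sorts above every finite Phi so the feature is always selected. A column
#'   constant across *both* classes has no discriminative content and scores
#'   0.
#' @return non-negative Phi score.
#' @export
phi_score <- function(positives, negatives, sentinel = Inf) {
  if (length(positives) < 2L || length(negatives) < 2L) {
    chq_stop("phi_score needs >= 2 instances in each class",
             class = "chqclass_invalid_input")
  }
  m_all <- mean(c(positives, negatives))
  num <- (mean(positives) - m_all)^2 + (mean(negatives) - m_all)^2
  den <- stats::var(positives) + stats::var(negatives)
  if (den == 0) {
    if (num == 0) return(0)
    return(sentinel)
  }
  num / den
}

#' Phi-scores of every column of a feature matrix
#'
#' Vectorised version of [phi_score()] over matrix columns.
#'
#' @param x numeric matrix or `dgCMatrix`, rows = instances.
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive.
#' @param sentinel see [phi_score()].
#' @return numeric vector of Phi scores, one per column.
#' @export
phi_scores <- function(x, labels, sentinel = Inf) {
  labels <- as.logical(labels)
  stopifnot(nrow(x) == length(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np < 2L || nn < 2L) {
    chq_stop("phi_scores needs >= 2 instances in each class",
             class = "chqclass_invalid_input")
  }
  xp <- x[labels, , drop = FALSE]
  xn <- x[!labels, , drop = FALSE]
  mp <- Matrix::colMeans(xp)
  mn <- Matrix::colMeans(xn)
  ma <- Matrix::colMeans(x)
  # sample variance via E[x^2] with n/(n-1) correction
  vp <- (Matrix::colMeans(xp^2) - mp^2) * np / (np - 1)
  vn <- (Matrix::colMeans(xn^2) - mn^2) * nn / (nn - 1)
  vp <- pmax(vp, 0); vn <- pmax(vn, 0)
  num <- (mp - ma)^2 + (mn - ma)^2
  den <- vp + vn
  phi <- ifelse(den == 0, ifelse(num == 0, 0, sentinel), num / den)
  unname(phi)
}

#' Per-type average-Phi thresholds
#'
#' The threshold of each feature type is the arithmetic mean of its
#' features' Phi scores. Non-finite sentinel scores (perfect separators) are
#' excluded from the mean — they are selected regardless and would make the
#' mean undefined. Types with no features are omitted.
#'
#' @param phi numeric vector of Phi scores.
#' @param types character vector of feature types, parallel to `phi`.
#' @return named numeric vector: threshold by type.
#' @export
type_thresholds <- function(phi, types) {
  stopifnot(length(phi) == length(types))
  out <- vapply(split(phi, types), function(v) {
    fin <- v[is.finite(v)]
    if (length(fin) == 0L) 0 else mean(fin)
  }, numeric(1))
  out[match(intersect(FEATURE_TYPES, names(out)), names(out))]
}

#' Select features with Phi at or above their type's average
#'
#' @param phi numeric vector of Phi scores.
#' @param types character vector of types, parallel to `phi`.
#' @param keys optional feature keys for the report.
#' @param thresholds optional named thresholds; computed with
#'   [type_thresholds()] when missing.
#' @return a `chq_phi_report`: list with `phi` (data.frame type, key, phi,
#'   selected), `thresholds`, `n_all`, `n_selected`, `by_type` (data.frame
#'   with per-type counts, mean and sd of Phi), and `reduction_proportion =
#'   1 - n_selected / n_all`.
#' @export
select_features <- function(phi, types, keys = NULL, thresholds = NULL) {
  stopifnot(length(phi) == length(types))
  if (is.null(keys)) keys <- as.character(seq_along(phi))
  if (is.null(thresholds)) thresholds <- type_thresholds(phi, types)
  thr <- unname(thresholds[types])
  selected <- !is.finite(phi) | phi >= thr # sentinel always kept
  by_type <- do.call(rbind, lapply(intersect(FEATURE_TYPES, unique(types)),
    function(tp) {
      idx <- types == tp
      fin <- phi[idx][is.finite(phi[idx])]
      data.frame(type = tp,
                 avg_phi = if (length(fin)) mean(fin) else NA_real_,
                 sd_phi = if (length(fin) > 1L) stats::sd(fin) else NA_real_,
                 n_all = sum(idx), n_selected = sum(selected[idx]),
                 stringsAsFactors = FALSE)
    }))
  structure(
    list(phi = data.frame(type = types, key = keys, phi = phi,
                          selected = selected, stringsAsFactors = FALSE),
         thresholds = thresholds,
         n_all = length(phi),
         n_selected = sum(selected),
         by_type = by_type,
         reduction_proportion = 1 - sum(selected) / length(phi)),
    class = "chq_phi_report"
  )
}

#' @export
print.chq_phi_report <- function(x, ...) {
  cat(sprintf("<phi report> %d / %d features selected (reduction %.4f)\n",
              x$n_selected, x$n_all, x$reduction_proportion))
  print(x$by_type, row.names = FALSE)
  invisible(x)
}

#' Export a Phi report as TSV
#'
#' Columns mirror the per-type summary (type, avg Phi, sd Phi, n_all,
#' n_selected).
#'
#' @param report a `chq_phi_report`.
#' @param path output path.
#' @export
write_phi_report <- function(report, path) {
  utils::write.table(report$by_type, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
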
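# Feature extraction: seventeen feature families over tokenized questions.
#
# Families (in canonical order):
#   lexical      bow, pos
#   grammatical  interrogative, noun/verb head chunks, noun/verb rear chunks,
#                interrogative+head and rear+interrogative combinations
#   semantic     concept, semantic_type (from a medical lexicon)
#   lexical/statistical  keyword_tf, keyword_idf, keyword_tfidf
#   statistical  the 13 length/TF/IDF/TF-IDF summary statistics
#
# All families are binary indicators except `statistical`, whose values are
# non-negative reals.

#' Canonical feature-type names
#'
#' @format Character vector of the 17 family names, in canonical order.
#' @export
FEATURE_TYPES <- c(
  "bow", "pos", "interrogative",
  "noun_head_chunk", "verb_head_chunk", "noun_rear_chunk", "verb_rear_chunk",
  "int_plus_noun_head", "int_plus_verb_head",
  "noun_rear_plus_int", "verb_rear_plus_int",
  "concept", "semantic_type",
  "keyword_tf", "keyword_idf", "keyword_tfidf",
  "statistical"
)

fragment <- function(type = character(0), key = character(0),
                     value = numeric(0)) {
  data.frame(type = type, key = key, value = value, stringsAsFactors = FALSE)
}

#' Bag-of-words features
#'
#' Binary indicator per distinct token surface.
#'
#' @param tq a `chq_tokens` object.
#' @return data.frame fragment with columns `type`, `key`, `value`.
#' @export
bow_features <- function(tq) {
  surf <- unique(tq$surface)
  fragment(rep("bow", length(surf)), surf, rep(1, length(surf)))
}

#' Part-of-speech features
#'
#' Binary indicator per distinct (surface, tag) pair, keyed `surface/tag`.
#' Keying on the pair (not the tag alone) means an ambiguous surface tagged
#' differently in different questions yields distinct features.
#'
#' @inheritParams bow_features
#' @export
pos_features <- function(tq) {
  keys <- unique(paste0(tq$surface, "/", tq$pos))
  fragment(rep("pos", length(keys)), keys, rep(1, length(keys)))
}

#' Interrogative-anchored grammatical features
#'
#' Emits one binary `interrogative` feature per distinct interrogative word
#' present, and — anchored at the FIRST interrogative — up to four chunk
#' features and their four interrogative combinations:
#' \itemize{
#'   \item head chunks: first noun / first verb after the first interrogative;
#'   \item rear chunks: last noun / last verb before the first interrogative;
#'   \item combinations `int_plus_*` keyed `"q|chunk"` and `*_plus_int`
#'     keyed `"chunk|q"`, where `q` is the first interrogative's surface
#'     (key order mirrors Chinese word order).
#' }
#' Questions without an interrogative token emit nothing here.
#'
#' @inheritParams bow_features
#' @export
chunk_features <- function(tq) {
  out <- fragment()
  int_idx <- which(tq$pos == "int")
  if (length(int_idx) == 0L) return(out)

  ints <- unique(tq$surface[int_idx])
  out <- rbind(out, fragment(rep("interrogative", length(ints)), ints,
                             rep(1, length(ints))))

  first <- int_idx[1L]
  q <- tq$surface[first]
  after <- which(seq_len(nrow(tq)) > first)
  before <- which(seq_len(nrow(tq)) < first)
  pick <- function(idx, tag, last = FALSE) {
    hits <- idx[tq$pos[idx] == tag]
    if (length(hits) == 0L) return(NULL)
    tq$surface[if (last) hits[length(hits)] else hits[1L]]
  }

  noun_head <- pick(after, "n")
  verb_head <- pick(after, "v")
  noun_rear <- pick(before, "n", last = TRUE)
  verb_rear <- pick(before, "v", last = TRUE)

  add <- function(out, type, key) {
    if (is.null(key)) out else rbind(out, fragment(type, key, 1))
  }
  out <- add(out, "noun_head_chunk", noun_head)
  out <- add(out, "verb_head_chunk", verb_head)
  out <- add(out, "noun_rear_chunk", noun_rear)
  out <- add(out, "verb_rear_chunk", verb_rear)
  out <- add(out, "int_plus_noun_head",
             if (is.null(noun_head)) NULL else paste0(q, "|", noun_head))
  out <- add(out, "int_plus_verb_head",
             if (is.null(verb_head)) NULL else paste0(q, "|", verb_head))
  out <- add(out, "noun_rear_plus_int",
             if (is.null(noun_rear)) NULL else paste0(noun_rear, "|", q))
  out <- add(out, "verb_rear_plus_int",
             if (is.null(verb_rear)) NULL else paste0(verb_rear, "|", q))
  out
}

#' Load a medical-concept lexicon
#'
#' UTF-8 TSV with columns term, concept id, semantic type (Disease / Drug /
#' Symptom). Stands behind the same interface as any controlled vocabulary of
#' medical concepts.
#'
#' @param path file path.
#' @return data.frame with columns `term`, `concept_id`, `semantic_type`.
#' @export
load_lexicon <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  names(df) <- c("term", "concept_id", "semantic_type")[seq_len(ncol(df))]
  df
}

#' Medical concept and semantic-type features
#'
#' Matches lexicon terms against the raw question text (longest match wins,
#' so a term embedded in a longer matched term is not double-counted) and
#' emits a binary `concept` feature per matched concept id and a binary
#' `semantic_type` feature per matched type (presence, not count).
#'
#' @inheritParams bow_features
#' @param lexicon data.frame from [load_lexicon()].
#' @export
lexicon_features <- function(tq, lexicon) {
  if (is.null(lexicon) || nrow(lexicon) == 0L) return(fragment())
  text <- attr(tq, "text")
  # longest-match scan over the raw text
  ord <- order(-nchar(lexicon$term))
  lex <- lexicon[ord, , drop = FALSE]
  matched <- logical(nrow(lex))
  remaining <- text
  for (j in seq_len(nrow(lex))) {
    if (grepl(lex$term[j], remaining, fixed = TRUE)) {
      matched[j] <- TRUE
      remaining <- gsub(lex$term[j], "", remaining, fixed = TRUE)
    }
  }
  if (!any(matched)) return(fragment())
  concepts <- unique(lex$concept_id[matched])
  types <- unique(lex$semantic_type[matched])
  rbind(
    fragment(rep("concept", length(concepts)), concepts, rep(1, length(concepts))),
    fragment(rep("semantic_type", length(types)), types, rep(1, length(types)))
  )
}

#' Number of keywords for a question of a given length
#'
#' Heuristic: longer questions justify more keywords. The default rule is
#' `k = min(k_max, ceiling(L / c))` with `c = 10`, `k_max = 10`; both
#' constants are overridable so any monotone rule can be substituted.
#'
#' @param length question length (token count), >= 1.
#' @param c divisor; default 10.
#' @param k_max cap; default 10.
#' @return integer `k >= 1`, non-decreasing in `length`.
#' @export
keyword_count <- function(length, c = 10, k_max = 10) {
  if (!is.numeric(length) || length < 1) {
    chq_stop("question length must be >= 1", class = "chqclass_invalid_input")
  }
  max(1L, min(as.integer(k_max), as.integer(ceiling(length / c))))
}

#' Read a background document-frequency table
#'
#' UTF-8 TSV `term<TAB>df` with a header comment `#N=<document count>`.
#'
#' @param path file path.
#' @return a `chq_df_table`: data.frame (`term`, `df`) with attribute `N`.
#' @export
read_df_table <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!grepl("^#N=\\d+$", first)) {
    chq_stop("df table must start with a '#N=<count>' header",
             class = "chqclass_invalid_input")
  }
  N <- as.integer(sub("^#N=", "", first))
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          col.names = c("term", "df"))
  df_table(stats::setNames(df$df, df$term), N)
}

#' Construct a document-frequency table
#'
#' @param counts named integer vector: document frequency by term.
#' @param N total number of documents in the background corpus.
#' @return a `chq_df_table`.
#' @export
df_table <- function(counts, N) {
  stopifnot(N >= 1, all(counts >= 1), all(counts <= N))
  structure(list(df = counts, N = as.integer(N)), class = "chq_df_table")
}

#' Write a document-frequency table
#'
#' @param tab a `chq_df_table`.
#' @param path output path.
#' @export
write_df_table <- function(tab, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#N=", tab$N), con)
  writeLines(paste0(names(tab$df), "\t", tab$df), con)
  invisible(path)
}

#' Term frequency statistics for a question
#'
#' For each distinct term t in the question:
#' `tf(t) = count(t) / n_tokens`, `idf(t) = ln(N / df(t))` with `df`
#' floored at 1 for terms unseen in the background corpus, and
#' `tfidf(t) = tf(t) * idf(t)`.
#'
#' @inheritParams bow_features
#' @param background a `chq_df_table`.
#' @return data.frame with columns `term`, `count`, `tf`, `idf`, `tfidf` and
#'   attribute `first_pos` (first occurrence index per term, for tie-breaks).
#' @export
frequency_statistics <- function(tq, background) {
  stopifnot(inherits(background, "chq_df_table"))
  if (nrow(tq) == 0L) {
    chq_stop("cannot compute term statistics for an empty token list",
             class = "chqclass_invalid_input")
  }
  terms <- unique(tq$surface)
  counts <- vapply(terms, function(t) sum(tq$surface == t), numeric(1))
  tf <- counts / nrow(tq)
  dfv <- unname(background$df[terms])
  dfv[is.na(dfv)] <- 1
  idf <- log(background$N / dfv)
  first_pos <- vapply(terms, function(t) which(tq$surface == t)[1L], integer(1))
  out <- data.frame(term = terms, count = counts, tf = tf, idf = idf,
                    tfidf = tf * idf, stringsAsFactors = FALSE)
  attr(out, "first_pos") <- first_pos
  rownames(out) <- NULL
  out
}

# top-k terms of `stats` by column `by`; ties broken by earlier first
# occurrence in the question, then lexicographically.
top_k_terms <- function(stats, by, k) {
  fp <- attr(stats, "first_pos")
  ord <- order(-stats[[by]], fp, stats$term, method = "radix")
  stats$term[ord][seq_len(min(k, nrow(stats)))]
}

#' Keyword features (top-k by TF, IDF and TF-IDF)
#'
#' Three binary families: the k highest-TF terms (`keyword_tf`), highest-IDF
#' (`keyword_idf`) and highest-TF-IDF (`keyword_tfidf`). If the question has
#' fewer than k distinct terms, all its terms are keywords.
#'
#' @inheritParams bow_features
#' @param stats data.frame from [frequency_statistics()].
#' @param k number of keywords, from [keyword_count()].
#' @export
keyword_features <- function(tq, stats, k) {
  stopifnot(k >= 1)
  mk <- function(type, by) {
    terms <- top_k_terms(stats, by, k)
    fragment(rep(type, length(terms)), terms, rep(1, length(terms)))
  }
  rbind(mk("keyword_tf", "tf"), mk("keyword_idf", "idf"),
        mk("keyword_tfidf", "tfidf"))
}

#' The 13 statistical features
#'
#' question_length (token count) plus max/min/avg of word length, TF, IDF
#' and TF-IDF, computed over the question's tokens (length) and distinct
#' terms (TF/IDF/TF-IDF).
#'
#' @inheritParams keyword_features
#' @export
statistical_features <- function(tq, stats) {
  if (nrow(tq) == 0L) {
    chq_stop("cannot compute statistical features of an empty token list",
             class = "chqclass_invalid_input")
  }
  lens <- nchar(tq$surface)
  mma <- function(x) c(max = max(x), min = min(x), avg = mean(x))
  vals <- c(
    question_length = nrow(tq),
    stats::setNames(mma(lens), paste0(names(mma(lens)), "_word_length")),
    stats::setNames(mma(stats$tf), paste0(names(mma(stats$tf)), "_tf")),
    stats::setNames(mma(stats$idf), paste0(names(mma(stats$idf)), "_idf")),
    stats::setNames(mma(stats$tfidf), paste0(names(mma(stats$tfidf)), "_tfidf"))
  )
  fragment(rep("statistical", length(vals)), names(vals), unname(vals))
}

#' Extract the full feature vector of one question
#'
#' Runs every family and concatenates the fragments. A pure function of its
#' inputs: identical tokens and resources give an identical vector.
#'
#' @inheritParams bow_features
#' @param lexicon medical lexicon data.frame (or `NULL` to skip semantic
#'   features).
#' @param background `chq_df_table` (or `NULL` to skip keyword/statistical
#'   families).
#' @param k_rule function(length) -> k; defaults to [keyword_count()].
#' @return a feature-vector data.frame (`type`, `key`, `value`) with
#'   attribute `question_id`.
#' @export
extract_features <- function(tq, lexicon = NULL, background = NULL,
                             k_rule = keyword_count) {
  out <- rbind(bow_features(tq), pos_features(tq), chunk_features(tq),
               lexicon_features(tq, lexicon))
  if (!is.null(background) && nrow(tq) > 0L) {
    stats <- frequency_statistics(tq, background)
    k <- k_rule(nrow(tq))
    out <- rbind(out, keyword_features(tq, stats, k),
                 statistical_features(tq, stats))
  }
  bad <- setdiff(unique(out$type), FEATURE_TYPES)
  if (length(bad)) chq_stop("unknown feature type(s): ", paste(bad, collapse = ", "))
  attr(out, "question_id") <- attr(tq, "question_id")
  out
}

#' Build a feature space from feature vectors
#'
#' The space is the union of all (type, key) pairs, ordered by canonical
#' type order then key. Identical keys under different types (a bag-of-words
#' term that is also a keyword, say) remain distinct features.
#'
#' @param vectors list of feature-vector data.frames.
#' @return a `chq_feature_space`: data.frame `type`, `key`, `index`.
#' @export
build_feature_space <- function(vectors) {
  if (length(vectors) == 0L) {
    chq_stop("need at least one feature vector", class = "chqclass_invalid_input")
  }
  all <- do.call(rbind, c(vectors, list(fragment())))
  uni <- unique(all[, c("type", "key")])
  ord <- order(match(uni$type, FEATURE_TYPES), uni$key, method = "radix")
  uni <- uni[ord, , drop = FALSE]
  uni$index <- seq_len(nrow(uni))
  rownames(uni) <- NULL
  structure(uni, class = c("chq_feature_space", "data.frame"))
}

#' @export
print.chq_feature_space <- function(x, ...) {
  cat("<feature space>", nrow(x), "features over",
      length(unique(x$type)), "types\n")
  print(table(factor(x$type, levels = FEATURE_TYPES)))
  invisible(x)
}

#' Write / read a feature-space manifest
#'
#' TSV `type<TAB>key<TAB>index`.
#'
#' @param space a `chq_feature_space`.
#' @param path file path.
#' @export
write_feature_space <- function(space, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(space$type, space$key, space$index, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_feature_space
#' @export
read_feature_space <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          encoding = "UTF-8",
                          col.names = c("type", "key", "index"),
                          quote = "")
  structure(df, class = c("chq_feature_space", "data.frame"))
}

#' Assemble a sparse feature matrix
#'
#' Rows are questions, columns the features of `space`; features of a vector
#' absent from the space are dropped (they belong to other splits).
#'
#' @param vectors list of feature-vector data.frames.
#' @param space a `chq_feature_space`.
#' @return a `dgCMatrix` with question ids as rownames and `type:key`
#'   colnames.
#' @export
feature_matrix <- function(vectors, space) {
  key_of <- function(type, key) paste0(type, ":", key)
  col_ids <- key_of(space$type, space$key)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_along(vectors)) {
    v <- vectors[[r]]
    j <- match(key_of(v$type, v$key), col_ids)
    keep <- !is.na(j)
    ii <- c(ii, rep.int(r, sum(keep)))
    jj <- c(jj, j[keep])
    xx <- c(xx, v$value[keep])
  }
  rn <- vapply(seq_along(vectors), function(r) {
    id <- attr(vectors[[r]], "question_id")
    if (is.null(id)) paste0("q", r) else id
  }, character(1))
  if (anyDuplicated(rn)) rn <- make.unique(rn)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(vectors), nrow(space)),
                       dimnames = list(rn, col_ids))
}
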
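# Chinese word segmentation and POS tagging.
#
# Production pipelines can plug in any statistical segmenter/tagger that
# honours the same contract (text in, tokens out); the bundled fallback is a
# deterministic greedy forward-maximum-matching segmenter plus dictionary
# lookup tagging, which keeps every downstream stage testable offline.
#
# Tagset of the fallback tagger:
#   n    noun
#   v    verb
#   int  interrogative word (takes precedence over the POS dictionary)
#   m    numeral
#   x    unknown / punctuation / other

#' Load a term dictionary
#'
#' UTF-8 text, one term per line. Lines may carry a second TAB-separated
#' column (a POS tag or other payload); [load_dictionary()] keeps terms only,
#' [load_pos_dictionary()] returns the term-to-tag mapping.
#'
#' @param path file path.
#' @return character vector of terms.
#' @export
load_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' @rdname load_dictionary
#' @return for `load_pos_dictionary`, a named character vector tag by term.
#' @export
load_pos_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tags <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "x",
                 character(1))
  names(tags) <- vapply(parts, `[[`, character(1), 1L)
  tags
}

#' Segment text by greedy forward maximum matching
#'
#' At each position the longest dictionary term starting there is taken; when
#' no term matches, a single character is emitted. Whitespace separates
#' tokens and is never part of one. Deterministic: the same text and
#' dictionary always give the same segmentation.
#'
#' @param text non-empty string.
#' @param dictionary character vector of terms.
#' @return character vector of token surfaces.
#' @export
segment <- function(text, dictionary) {
  if (!is_string(text) || !nzchar(text)) {
    chq_stop("text must be a non-empty string", class = "chqclass_invalid_input")
  }
  dict <- unique(dictionary[nzchar(dictionary)])
  max_len <- if (length(dict)) max(nchar(dict)) else 1L
  dict_env <- new.env(hash = TRUE, parent = emptyenv())
  for (term in dict) assign(term, TRUE, envir = dict_env)

  cps <- chars(text)
  n <- length(cps)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (grepl("^\\s$", cps[i])) {
      i <- i + 1L
      next
    }
    hit <- cps[i]
    for (len in min(max_len, n - i + 1L):1L) {
      cand <- paste(cps[i:(i + len - 1L)], collapse = "")
      if (!is.null(dict_env[[cand]])) {
        hit <- cand
        break
      }
    }
    out <- c(out, hit)
    i <- i + nchar(hit)
  }
  out
}

#' Tokenize a question: segmentation, offsets and POS tags
#'
#' Runs the segmenter, records half-open character spans (0-based Unicode
#' code points), and assigns POS tags: interrogative-dictionary membership
#' wins (tag `int`), then the POS dictionary, then numerals (`m`), then the
#' unknown tag `x`.
#'
#' @param question a `chq_question` or plain string.
#' @param dictionary segmentation terms.
#' @param pos_dictionary named character vector tag-by-term (may be empty).
#' @param interrogatives character vector of interrogative words.
#' @param segmenter optional replacement segmentation function with the same
#'   contract as [segment()].
#' @return an object of class `chq_tokens`: data.frame with columns
#'   `surface`, `pos`, `start`, `end`, plus attributes `question_id`, `text`.
#' @export
tokenize_question <- function(question, dictionary,
                              pos_dictionary = character(0),
                              interrogatives = character(0),
                              segmenter = segment) {
  if (is.character(question)) {
    question <- structure(list(message_id = "<anon>", text = question,
                               source_rule = "whole_message"),
                          class = "chq_question")
  }
  stopifnot(inherits(question, "chq_question"))
  text <- question$text
  surfaces <- segmenter(text, dictionary)
  tags <- pos_tag(surfaces, pos_dictionary, interrogatives)

  # recover spans by walking the text, skipping whitespace
  cps <- chars(text)
  starts <- integer(length(surfaces))
  ends <- integer(length(surfaces))
  i <- 1L
  for (k in seq_along(surfaces)) {
    while (i <= length(cps) && grepl("^\\s$", cps[i])) i <- i + 1L
    starts[k] <- i - 1L
    ends[k] <- starts[k] + nchar(surfaces[k])
    i <- i + nchar(surfaces[k])
  }

  tk <- data.frame(surface = surfaces, pos = tags,
                   start = starts, end = ends,
                   stringsAsFactors = FALSE)
  structure(tk, class = c("chq_tokens", "data.frame"),
            question_id = question$message_id, text = text)
}

#' POS-tag token surfaces by dictionary lookup
#'
#' @param surfaces character vector from [segment()].
#' @param pos_dictionary named character vector tag-by-term.
#' @param interrogatives interrogative word list; members are tagged `int`
#'   regardless of the POS dictionary.
#' @return character vector of tags (`n`, `v`, `int`, `m`, `x`, ...).
#' @export
pos_tag <- function(surfaces, pos_dictionary = character(0),
                    interrogatives = character(0)) {
  vapply(surfaces, function(w) {
    if (w %in% interrogatives) return("int")
    tag <- unname(pos_dictionary[w])
    if (!is.na(tag) && length(tag) == 1L && !is.null(tag)) return(tag)
    if (grepl("^[0-9]+(\\.[0-9]+)?$", w)) return("m")
    "x"
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.chq_tokens <- function(x, ...) {
  cat("<tokenized question> ", attr(x, "question_id"), ": ",
      paste0(x$surface, "/", x$pos, collapse = " "), "\n", sep = "")
  invisible(x)
}
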
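# Corpus model: messages, extracted questions, hierarchical topic codes,
# annotations and inter-annotator agreement.

#' The six classified primary topics
#'
#' Order matches the topic numbering of the classification schema; the
#' residual "Other" topic is not classified and is returned by
#' [predict_topics()] only when no binary classifier fires.
#'
#' @format Character vector of length 6.
#' @export
PRIMARY_TOPICS <- c(
  "Diagnosis", "Treatment", "ConditionManagement",
  "Epidemiology", "HealthyLifestyle", "HealthProviderChoice"
)

#' @rdname PRIMARY_TOPICS
#' @format NULL
#' @export
OTHER_TOPIC <- "Other"

#' Default template marker phrase
#'
#' The health-website posting template ends with a "what kind of help do you
#' want" field; the text a consumer types after it is the actual question.
#'
#' @format A length-1 character string.
#' @export
DEFAULT_MARKER <- "想得到怎样的帮助" # 想得到怎样的帮助

#' Create a message record
#'
#' @param id opaque message identifier.
#' @param text message text (UTF-8); must be non-empty after trimming.
#' @param annotations optional list of [annotation()] objects.
#' @return an object of class `chq_message`.
#' @export
message_record <- function(id, text, annotations = list()) {
  if (!is_string(text) || !nzchar(trimws(text))) {
    chq_stop("message text must be a non-empty string", class = "chqclass_invalid_input")
  }
  structure(
    list(id = as.character(id), text = text, annotations = annotations),
    class = "chq_message"
  )
}

#' Extract the question from a templated message
#'
#' Messages posted through the website template often contain several fields;
#' the question proper is the text after the final "what kind of help do you
#' want" marker. If the marker is absent the whole message is the question.
#' One leading colon (ASCII or fullwidth) after the marker is stripped, as is
#' surrounding whitespace.
#'
#' @param message a [message_record()] or a plain string.
#' @param marker the template phrase; defaults to [DEFAULT_MARKER].
#' @return an object of class `chq_question` with fields `message_id`,
#'   `text` and `source_rule` (`"after_marker"` or `"whole_message"`).
#' @examples
#' q <- extract_question(message_record("m1", "血压高吗"))
#' q$source_rule
#' @export
extract_question <- function(message, marker = DEFAULT_MARKER) {
  if (is.character(message)) message <- message_record("<anon>", message)
  stopifnot(inherits(message, "chq_message"))
  txt <- message$text
  if (!nzchar(trimws(txt))) {
    chq_stop("message text must be non-empty", class = "chqclass_invalid_input")
  }
  pieces <- strsplit(txt, marker, fixed = TRUE)[[1L]]
  has_marker <- length(pieces) > 1L ||
    (length(pieces) == 1L && grepl(marker, txt, fixed = TRUE))
  if (has_marker) {
    # text after the LAST marker occurrence; a trailing marker yields ""
    after <- if (endsWith(txt, marker)) "" else pieces[length(pieces)]
    after <- sub("^[\\s]*[:：]?[\\s]*", "", after, perl = TRUE)
    after <- trimws(after)
    qtext <- if (nzchar(after)) after else trimws(txt)
    rule <- if (nzchar(after)) "after_marker" else "whole_message"
  } else {
    qtext <- trimws(txt)
    rule <- "whole_message"
  }
  structure(
    list(message_id = message$id, text = qtext, source_rule = rule),
    class = "chq_question"
  )
}

#' Filter messages by exclusion terms
#'
#' Messages mentioning look-alike but irrelevant compounds (hyperbaric oxygen,
#' pressure cooker, high voltage ...) can be dropped before analysis. Disabled
#' unless terms are supplied.
#'
#' @param messages list of `chq_message`.
#' @param terms character vector of exclusion substrings; `NULL` disables.
#' @return the messages whose text contains none of the terms.
#' @export
filter_exclusion_terms <- function(messages, terms = NULL) {
  if (is.null(terms) || length(terms) == 0L) return(messages)
  keep <- vapply(messages, function(m) {
    !any(vapply(terms, function(t) grepl(t, m$text, fixed = TRUE), logical(1)))
  }, logical(1))
  messages[keep]
}

#' Parse a hierarchical topic code
#'
#' Codes are dot-separated positive integers, e.g. `"1.1.4.1"`, with depth 1
#' (primary topic) to 4 (quaternary category).
#'
#' @param code_string code such as `"2.1.2.1"`.
#' @param label optional human-readable label.
#' @return an object of class `chq_topic_code` with integer `levels`.
#' @export
parse_topic_code <- function(code_string, label = "") {
  if (!is_string(code_string) || !grepl("^[0-9]+(\\.[0-9]+)*$", code_string)) {
    chq_stop("topic code must be dot-separated integers: ", code_string,
             class = "chqclass_parse_error")
  }
  levels <- as.integer(strsplit(code_string, ".", fixed = TRUE)[[1L]])
  if (length(levels) < 1L || length(levels) > 4L) {
    chq_stop("topic code depth must be 1-4: ", code_string,
             class = "chqclass_parse_error")
  }
  if (any(levels < 1L)) {
    chq_stop("topic code levels must be positive: ", code_string,
             class = "chqclass_parse_error")
  }
  if (levels[1L] > 7L) {
    chq_stop("primary level must be in 1..7: ", code_string,
             class = "chqclass_parse_error")
  }
  structure(list(levels = levels, label = label), class = "chq_topic_code")
}

#' @export
format.chq_topic_code <- function(x, ...) paste(x$levels, collapse = ".")

#' @export
print.chq_topic_code <- function(x, ...) {
  cat("<topic code>", format(x),
      if (nzchar(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  invisible(x)
}

#' Truncate a topic code to a comparison depth
#'
#' @param code a `chq_topic_code`.
#' @param depth keep at most this many levels.
#' @return a `chq_topic_code`.
#' @export
truncate_code <- function(code, depth) {
  stopifnot(inherits(code, "chq_topic_code"), depth >= 1L)
  structure(list(levels = code$levels[seq_len(min(depth, length(code$levels)))],
                 label = code$label),
            class = "chq_topic_code")
}

#' Create an annotation (one annotator's codes for one question)
#'
#' Each annotator assigns exactly one major code and any number of minor
#' codes.
#'
#' @param annotator_id identifier.
#' @param major major `chq_topic_code` or code string.
#' @param minors list of minor codes (objects or strings).
#' @return an object of class `chq_annotation`.
#' @export
annotation <- function(annotator_id, major, minors = list()) {
  as_code <- function(x) if (inherits(x, "chq_topic_code")) x else parse_topic_code(x)
  structure(
    list(annotator_id = as.character(annotator_id),
         major = as_code(major),
         minors = lapply(minors, as_code)),
    class = "chq_annotation"
  )
}

all_codes <- function(ann) c(list(ann$major), ann$minors)

#' Liberal match between two annotations
#'
#' Two annotations of the same question match if any code of one (major or
#' minor) equals any code of the other, after truncating every code to the
#' comparison depth. Users asking several things at once make it acceptable
#' to answer any of them, hence the liberal criterion.
#'
#' @param a,b `chq_annotation` objects.
#' @param depth comparison depth (1 = primary topics only, 4 = full codes).
#' @return logical.
#' @export
liberal_match <- function(a, b, depth = 4L) {
  stopifnot(inherits(a, "chq_annotation"), inherits(b, "chq_annotation"))
  fmt <- function(ann) vapply(all_codes(ann),
                              function(cd) format(truncate_code(cd, depth)),
                              character(1))
  length(intersect(fmt(a), fmt(b))) > 0L
}

#' Observed agreement over a set of multiply-annotated questions
#'
#' For each question the score is the fraction of annotator pairs whose
#' annotations liberally match at the given depth; the observed agreement is
#' the mean over questions. For two annotators per question this is simply
#' the fraction of questions on which they match.
#'
#' @param question_annotations list; each element is the list of
#'   `chq_annotation`s (>= 2) for one question.
#' @param depth comparison depth passed to [liberal_match()].
#' @return observed agreement in `[0, 1]`.
#' @export
observed_agreement <- function(question_annotations, depth = 4L) {
  if (length(question_annotations) == 0L) {
    chq_stop("no annotated questions supplied", class = "chqclass_invalid_input")
  }
  per_q <- vapply(question_annotations, function(anns) {
    n <- length(anns)
    if (n < 2L) {
      chq_stop("every question needs >= 2 annotations",
               class = "chqclass_invalid_input")
    }
    pairs <- utils::combn(n, 2L)
    mean(apply(pairs, 2L, function(ij) {
      liberal_match(anns[[ij[1L]]], anns[[ij[2L]]], depth = depth)
    }))
  }, numeric(1))
  mean(per_q)
}

#' Kappa agreement statistic
#'
#' `kappa = (p_o - p_e) / (1 - p_e)`. With many categories the chance
#' agreement `p_e` is close to zero, in which case `kappa` reduces to the
#' observed agreement `p_o` (the convention used when categories number in
#' the dozens).
#'
#' @param p_o observed agreement in `[0, 1]`.
#' @param p_e chance agreement in `[0, 1)`; defaults to 0.
#' @return an object of class `chq_agreement` with fields `p_o`, `p_e`,
#'   `kappa`.
#' @export
kappa_agreement <- function(p_o, p_e = 0) {
  stopifnot(is.numeric(p_o), is.numeric(p_e), length(p_o) == 1L, length(p_e) == 1L)
  if (p_o < 0 || p_o > 1 || p_e < 0 || p_e > 1) {
    chq_stop("p_o and p_e must lie in [0, 1]", class = "chqclass_invalid_input")
  }
  if (p_e >= 1) {
    chq_stop("kappa undefined when chance agreement is 1",
             class = "chqclass_undefined_kappa")
  }
  structure(list(p_o = p_o, p_e = p_e, kappa = (p_o - p_e) / (1 - p_e)),
            class = "chq_agreement")
}

#' @export
print.chq_agreement <- function(x, ...) {
  cat(sprintf("<agreement> Po = %.4f, Pe = %.4f, kappa = %.4f\n",
              x$p_o, x$p_e, x$kappa))
  invisible(x)
}

#' Annotation agreement for a corpus at a comparison depth
#'
#' Convenience wrapper: computes observed agreement with [observed_agreement()]
#' and converts it to kappa with [kappa_agreement()] under the many-category
#' approximation `p_e = 0`.
#'
#' @inheritParams observed_agreement
#' @param p_e chance agreement; defaults to 0.
#' @return a `chq_agreement`.
#' @export
corpus_kappa <- function(question_annotations, depth = 4L, p_e = 0) {
  kappa_agreement(observed_agreement(question_annotations, depth = depth), p_e)
}

# ---- corpus I/O ------------------------------------------------------------

annotation_from_record <- function(rec) {
  minors <- rec$minors
  if (is.null(minors)) minors <- list()
  if (is.character(minors)) minors <- as.list(minors)
  annotation(rec$annotator, rec$major, minors)
}

#' Read a message corpus from JSONL
#'
#' One JSON object per line: `{"id", "text", "annotations": [{"annotator",
#' "major", "minors": []}]}`; `annotations` is optional.
#'
#' @param path file path.
#' @return list of `chq_message`.
#' @export
read_messages_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    anns <- lapply(rec$annotations, annotation_from_record)
    message_record(rec$id, rec$text, anns)
  })
}

#' Write messages or questions to JSONL
#'
#' @param records list of `chq_message` or `chq_question`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records) {
    rec <- unclass(r)
    if (inherits(r, "chq_message")) {
      rec$annotations <- lapply(r$annotations, function(a) {
        list(annotator = a$annotator_id, major = format(a$major),
             minors = vapply(a$minors, format, character(1)))
      })
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a message corpus from CSV
#'
#' @param path file path.
#' @param id_col,text_col column names holding the id and text.
#' @return list of `chq_message`.
#' @export
read_messages_csv <- function(path, id_col = "id", text_col = "text") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c(id_col, text_col) %in% names(df))) {
    chq_stop("columns not found: ", id_col, ", ", text_col,
             class = "chqclass_invalid_input")
  }
  mapply(message_record, df[[id_col]], df[[text_col]],
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
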
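# Shared fixtures: a miniature dictionary set and tokenizer shortcuts used
# across the unit tests. All text is built in code; nothing is downloaded.

mini_resources <- function() {
  list(
    dictionary = c("血压", "高血压", "升高", "头晕", "为什么", "什么", "吃",
                   "药", "降压药", "检查", "医院"),
    pos_dictionary = c("血压" = "n", "高血压" = "n", "升高" = "v",
                       "头晕" = "n", "吃" = "v", "药" = "n",
                       "降压药" = "n", "检查" = "v", "医院" = "n"),
    interrogatives = c("为什么", "什么", "吗"),
    lexicon = data.frame(
      term = c("高血压", "降压药", "头晕"),
      concept_id = c("C001", "C101", "C201"),
      semantic_type = c("Disease", "Drug", "Symptom"),
      stringsAsFactors = FALSE
    )
  )
}

# tokenize a plain string with the mini resources
mini_tokens <- function(text, res = mini_resources()) {
  tokenize_question(text, res$dictionary, res$pos_dictionary,
                    res$interrogatives)
}

# build a chq_tokens object directly from surface/pos vectors (offsets
# synthesized); lets feature tests state token sequences exactly
tokens_from <- function(surfaces, pos, text = paste(surfaces, collapse = "")) {
  ends <- cumsum(nchar(surfaces))
  tk <- data.frame(surface = surfaces, pos = pos,
                   start = ends - nchar(surfaces), end = ends,
                   stringsAsFactors = FALSE)
  structure(tk, class = c("chq_tokens", "data.frame"),
            question_id = "t1", text = text)
}

# brute-force segmentation oracle: exhaustive search for the segmentation a
# greedy longest-match-first scanner must produce
oracle_segment <- function(text, dict) {
  cps <- strsplit(text, "", fixed = TRUE)[[1L]]
  out <- character(0)
  i <- 1L
  while (i <= length(cps)) {
    best <- cps[i]
    for (j in length(cps):i) { # longest candidate first
      cand <- paste(cps[i:j], collapse = "")
      if (cand %in% dict) {
        best <- cand
        break
      }
    }
    out <- c(out, best)
    i <- i + nchar(best)
  }
  out
}

# brute-force Phi-score oracle: direct transcription of the formula
oracle_phi <- function(pos, neg) {
  xbar <- mean(c(pos, neg))
  num <- (mean(pos) - xbar)^2 + (mean(neg) - xbar)^2
  den <- sum((pos - mean(pos))^2) / (length(pos) - 1) +
    sum((neg - mean(neg))^2) / (length(neg) - 1)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}
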
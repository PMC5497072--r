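# The seventeen feature families.

frag_keys <- function(frag, type) frag$key[frag$type == type]

test_that("bag-of-words features are presence indicators over surfaces", {
  tk <- tokens_from(c("血压", "高", "血压"), c("n", "x", "n"))
  bw <- bow_features(tk)
  expect_setequal(frag_keys(bw, "bow"), c("血压", "高"))
  expect_true(all(bw$value == 1))
  expect_equal(nrow(bow_features(tokens_from(character(0), character(0)))), 0)
})

test_that("POS features key on (surface, tag) pairs", {
  tk <- tokens_from(c("血压", "升高"), c("n", "v"))
  expect_setequal(frag_keys(pos_features(tk), "pos"), c("血压/n", "升高/v"))
  # same surface under two tags gives two features
  tk2 <- tokens_from(c("检查", "检查"), c("n", "v"))
  expect_setequal(frag_keys(pos_features(tk2), "pos"), c("检查/n", "检查/v"))
  tk3 <- tokens_from("w", "x")
  expect_equal(frag_keys(pos_features(tk3), "pos"), "w/x")
})

test_that("chunk features anchor at the first interrogative", {
  tk <- tokens_from(c("血压", "为什么", "升高"), c("n", "int", "v"))
  fr <- chunk_features(tk)
  expect_equal(frag_keys(fr, "noun_rear_chunk"), "血压")
  expect_equal(frag_keys(fr, "verb_head_chunk"), "升高")
  expect_equal(frag_keys(fr, "noun_rear_plus_int"), "血压|为什么")
  expect_equal(frag_keys(fr, "int_plus_verb_head"), "为什么|升高")
  expect_equal(frag_keys(fr, "interrogative"), "为什么")
  # nothing on the other side of the interrogative
  expect_length(frag_keys(fr, "noun_head_chunk"), 0)
  expect_length(frag_keys(fr, "verb_rear_chunk"), 0)
})

test_that("chunks are head-first / rear-last and unique per question", {
  tk <- tokens_from(c("吃", "药", "为什么", "头晕", "医院", "检查"),
                    c("v", "n", "int", "n", "n", "v"))
  fr <- chunk_features(tk)
  expect_equal(frag_keys(fr, "noun_head_chunk"), "头晕")  # first noun after
  expect_equal(frag_keys(fr, "noun_rear_chunk"), "药")    # last noun before
  expect_equal(frag_keys(fr, "verb_rear_chunk"), "吃")
  expect_equal(frag_keys(fr, "verb_head_chunk"), "检查")
  # at most one chunk per kind
  for (tp in c("noun_head_chunk", "verb_head_chunk",
               "noun_rear_chunk", "verb_rear_chunk")) {
    expect_lte(length(frag_keys(fr, tp)), 1)
  }
})

test_that("several interrogatives: the first anchors, all are features", {
  tk <- tokens_from(c("为什么", "头晕", "吗"), c("int", "n", "int"))
  fr <- chunk_features(tk)
  expect_setequal(frag_keys(fr, "interrogative"), c("为什么", "吗"))
  expect_equal(frag_keys(fr, "noun_head_chunk"), "头晕")
  expect_equal(frag_keys(fr, "int_plus_noun_head"), "为什么|头晕")
})

test_that("questions without interrogatives emit no chunk features", {
  tk <- tokens_from(c("血压", "升高"), c("n", "v"))
  expect_equal(nrow(chunk_features(tk)), 0)
})

test_that("lexicon features emit concepts and semantic types as sets", {
  res <- mini_resources()
  tk <- mini_tokens("高血压吃降压药头晕")
  fr <- lexicon_features(tk, res$lexicon)
  expect_setequal(frag_keys(fr, "concept"), c("C001", "C101", "C201"))
  expect_setequal(frag_keys(fr, "semantic_type"),
                  c("Disease", "Drug", "Symptom"))
  # two drugs still give ONE Drug semantic-type feature
  lex2 <- rbind(res$lexicon,
                data.frame(term = "利尿剂", concept_id = "C102",
                           semantic_type = "Drug"))
  tk2 <- mini_tokens("降压药和利尿剂")
  fr2 <- lexicon_features(tk2, lex2)
  expect_setequal(frag_keys(fr2, "concept"), c("C101", "C102"))
  expect_equal(frag_keys(fr2, "semantic_type"), "Drug")
  expect_equal(nrow(lexicon_features(mini_tokens("咳嗽"), res$lexicon)), 0)
})

test_that("keyword count is monotone with documented defaults", {
  expect_equal(keyword_count(1), 1)
  expect_equal(keyword_count(48), 5)   # average-length question
  expect_equal(keyword_count(500), 10) # cap
  ks <- vapply(1:200, keyword_count, numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_error(keyword_count(0), class = "chqclass_invalid_input")
  expect_equal(keyword_count(48, c = 5, k_max = 20), 10) # overridable rule
})

test_that("tf, idf and tf-idf follow the stated formulas", {
  bg <- df_table(c("血压" = 50, "头晕" = 1), N = 100)
  tk <- tokens_from(c("血压", "血压", "头晕", "新词"),
                    c("n", "n", "n", "x"))
  st <- frequency_statistics(tk, bg)
  expect_equal(st$tf[st$term == "血压"], 0.5)
  expect_equal(st$idf[st$term == "血压"], log(100 / 50))
  expect_equal(st$idf[st$term == "头晕"], log(100))
  expect_equal(st$tfidf[st$term == "头晕"], 0.25 * log(100))
  # unseen terms have df floored at 1
  expect_equal(st$idf[st$term == "新词"], log(100))
  # ubiquitous term scores zero
  bg2 <- df_table(c("吗" = 100), N = 100)
  st2 <- frequency_statistics(tokens_from("吗", "int"), bg2)
  expect_equal(st2$idf, 0)
  expect_equal(st2$tfidf, 0)
  # df = 1, tf = 0.5 worked example
  bg3 <- df_table(c("a" = 1), N = 100)
  st3 <- frequency_statistics(tokens_from(c("a", "a", "b", "c"),
                                          rep("x", 4)), bg3)
  expect_equal(st3$tfidf[st3$term == "a"], 0.5 * log(100), tolerance = 1e-12)
  expect_error(frequency_statistics(tokens_from(character(0), character(0)),
                                    bg),
               class = "chqclass_invalid_input")
})

test_that("tfidf = tf * idf for every term (conservation)", {
  set.seed(53)
  vocab <- paste0("w", 1:30)
  bg <- df_table(setNames(sample(1:80, 30, replace = TRUE), vocab), N = 80)
  for (i in 1:25) {
    tk_surf <- sample(vocab, sample(3:15, 1), replace = TRUE)
    st <- frequency_statistics(tokens_from(tk_surf, rep("x", length(tk_surf))),
                               bg)
    expect_equal(st$tfidf, st$tf * st$idf, tolerance = 1e-14)
    expect_equal(sum(st$count), length(tk_surf))
  }
})

test_that("keyword families take the top-k with the documented tie-breaks", {
  bg <- df_table(c(a = 10, b = 10, c = 1), N = 100)
  # tf ranks: a 0.5, b 0.25, c 0.25
  tk <- tokens_from(c("a", "a", "b", "c"), rep("x", 4))
  st <- frequency_statistics(tk, bg)
  kf <- keyword_features(tk, st, 1)
  expect_equal(frag_keys(kf, "keyword_tf"), "a")
  # idf tie between a and b broken by earlier occurrence (a)
  expect_equal(frag_keys(kf, "keyword_idf"), "c") # c has df 1 -> max idf
  kf2 <- keyword_features(tk, st, 2)
  expect_setequal(frag_keys(kf2, "keyword_idf"), c("c", "a"))
  # fewer distinct terms than k: all are keywords
  kf5 <- keyword_features(tk, st, 5)
  expect_setequal(frag_keys(kf5, "keyword_tf"), c("a", "b", "c"))
  # equal tfidf: the earlier-occurring term wins at k = 1
  bg2 <- df_table(c(x = 5, y = 5), N = 50)
  tk2 <- tokens_from(c("y", "x"), c("x", "x"))
  st2 <- frequency_statistics(tk2, bg2)
  expect_equal(frag_keys(keyword_features(tk2, st2, 1), "keyword_tfidf"),
               "y")
})

test_that("keyword_tf keys are a subset of the question's own tokens", {
  set.seed(59)
  vocab <- paste0("w", 1:20)
  bg <- df_table(setNames(sample(1:40, 20, replace = TRUE), vocab), N = 40)
  for (i in 1:20) {
    surf <- sample(vocab, sample(2:12, 1), replace = TRUE)
    tk <- tokens_from(surf, rep("x", length(surf)))
    st <- frequency_statistics(tk, bg)
    kf <- keyword_features(tk, st, keyword_count(nrow(tk)))
    expect_true(all(frag_keys(kf, "keyword_tf") %in% surf))
    expect_true(all(frag_keys(kf, "keyword_tfidf") %in% surf))
  }
})

test_that("exactly 13 statistical features with correct arithmetic", {
  bg <- df_table(c("血压" = 2, "升高" = 1, "了" = 3), N = 4)
  tk <- tokens_from(c("血压", "升高", "了"), c("n", "v", "x"))
  st <- frequency_statistics(tk, bg)
  sf <- statistical_features(tk, st)
  expect_equal(nrow(sf), 13)
  expect_true(all(sf$type == "statistical"))
  v <- setNames(sf$value, sf$key)
  expect_equal(v[["question_length"]], 3)
  expect_equal(v[["max_word_length"]], 2)
  expect_equal(v[["min_word_length"]], 1)
  expect_equal(v[["avg_word_length"]], 5 / 3)
  expect_equal(v[["max_idf"]], log(4))
  expect_equal(v[["avg_tf"]], mean(st$tf))
  # degenerate single-token question: max = min = avg
  tk1 <- tokens_from("血压", "n")
  sf1 <- statistical_features(tk1, frequency_statistics(tk1, bg))
  v1 <- setNames(sf1$value, sf1$key)
  expect_equal(v1[["max_tf"]], v1[["min_tf"]])
  expect_equal(v1[["max_tf"]], v1[["avg_tf"]])
  expect_equal(nrow(sf1), 13)
})

test_that("extraction emits only declared feature types and is pure", {
  res <- mini_resources()
  bg <- df_table(c("血压" = 2, "升高" = 1), N = 10)
  tk <- mini_tokens("血压为什么升高要吃降压药吗")
  fv1 <- extract_features(tk, res$lexicon, bg)
  fv2 <- extract_features(tk, res$lexicon, bg)
  expect_identical(fv1, fv2)
  expect_true(all(fv1$type %in% FEATURE_TYPES))
  # binary families take value 1; statistical features are non-negative
  expect_true(all(fv1$value[fv1$type != "statistical"] == 1))
  expect_true(all(fv1$value[fv1$type == "statistical"] >= 0))
})

test_that("feature space deduplicates (type, key) pairs but not across types", {
  v1 <- data.frame(type = c("bow", "keyword_tf"), key = c("血压", "血压"),
                   value = 1)
  v2 <- data.frame(type = "bow", key = "血压", value = 1)
  sp <- build_feature_space(list(v1, v2))
  expect_equal(nrow(sp), 2) # bow:血压 shared; keyword_tf:血压 distinct
  expect_setequal(paste(sp$type, sp$key), c("bow 血压", "keyword_tf 血压"))
  # empty vector contributes nothing
  sp2 <- build_feature_space(list(v1, data.frame(type = character(0),
                                                 key = character(0),
                                                 value = numeric(0))))
  expect_equal(nrow(sp2), 2)
  # canonical ordering: bow before keyword_tf, stable indices
  expect_equal(sp$index, seq_len(nrow(sp)))
  expect_equal(sp$type, c("bow", "keyword_tf"))
})

test_that("feature matrices place values at the manifest positions", {
  v1 <- data.frame(type = c("bow", "statistical"), key = c("a", "question_length"),
                   value = c(1, 7))
  attr(v1, "question_id") <- "q1"
  v2 <- data.frame(type = "bow", key = "b", value = 1)
  attr(v2, "question_id") <- "q2"
  sp <- build_feature_space(list(v1, v2))
  m <- feature_matrix(list(v1, v2), sp)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m["q1", "bow:a"], 1)
  expect_equal(m["q1", "statistical:question_length"], 7)
  expect_equal(m["q2", "bow:a"], 0)
  expect_equal(m["q2", "bow:b"], 1)
})

test_that("feature-space manifests round-trip through TSV", {
  res <- mini_resources()
  bg <- df_table(c("血压" = 2), N = 10)
  vs <- lapply(c("血压为什么升高", "吃降压药吗"), function(tx) {
    extract_features(mini_tokens(tx), res$lexicon, bg)
  })
  sp <- build_feature_space(vs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_space(sp, path)
  back <- read_feature_space(path)
  expect_equal(back$type, sp$type)
  expect_equal(back$key, sp$key)
  expect_equal(back$index, sp$index)
})
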
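# Synthetic Chinese consumer-health-question generator.
#
# Emulates hypertension-style consumer questions: topic-conditioned question
# templates with slot fillers (symptoms, diseases, drugs, foods, activities,
# departments), skewed topic priors, multi-label co-occurrence, and the
# website posting template whose final field ("what kind of help do you
# want") carries the actual question. The topic signal lives in the
# template's fixed wording and its topic keyword pool, as it does in the
# pattern-based classification schema the classifier targets; slot fillers
# are shared across topics.
#
# `vocabulary_separation` interpolates between fully topic-determined text
# (1: template and keyword always drawn from the gold topic) and text
# carrying no topic signal at all (0: template and keyword drawn uniformly
# across topics, independent of the gold label).

# ---- bundled vocabulary ----------------------------------------------------

SLOT_POOLS <- list(
  symptom  = c("头晕", "头痛", "心慌", "胸闷", "耳鸣", "乏力", "恶心", "心悸",
               "失眠", "出冷汗"),
  disease  = c("高血压", "低血压", "糖尿病", "冠心病", "高血脂", "肾病",
               "心脏病", "脑梗塞"),
  drug     = c("降压药", "硝苯地平", "卡托普利", "氨氯地平", "缬沙坦",
               "倍他乐克", "利尿剂", "阿司匹林"),
  food     = c("盐", "肉", "鸡蛋", "水果", "蔬菜", "咖啡", "浓茶", "海鲜"),
  activity = c("跑步", "游泳", "爬山", "健身", "打球"),
  dept     = c("心内科", "内科", "急诊", "神经内科")
)

TOPIC_KEYWORDS <- list(
  Diagnosis            = c("诊断", "判断", "确诊", "查明"),
  Treatment            = c("副作用", "禁忌", "疗效"),
  ConditionManagement  = c("调理", "保养", "管理"),
  Epidemiology         = c("遗传", "发病率", "概率", "风险"),
  HealthyLifestyle     = c("饮酒", "熬夜", "应酬"),
  HealthProviderChoice = c("挂号", "专家", "就诊"),
  Other                = c("医保", "报销")
)

TEMPLATE_BANK <- list(
  Diagnosis = c(
    "最近总是{symptom}，这是啥病？",
    "{symptom}还伴有{symptom}，血压比以往高，是什么原因？",
    "血压高加上{symptom}，是不是{disease}？",
    "体检查体发现血压偏高，需要做哪些检查才能{kw}？",
    "{symptom}去医院能{kw}出是{disease}吗？"
  ),
  Treatment = c(
    "得了{disease}，吃哪种药最好？",
    "{disease}应该服用{drug}吗？",
    "吃{drug}有什么{kw}吗？",
    "{drug}的剂量怎么调整治疗效果好？",
    "血压一直高，怎么用药治疗？"
  ),
  ConditionManagement = c(
    "怎样才能把血压控制稳定？",
    "血压忽高忽低，平时监测要注意什么？",
    "服药期间多久测量一次血压合适？",
    "血压控制不好，日常怎么{kw}？",
    "{disease}病人怎么{kw}病情？"
  ),
  Epidemiology = c(
    "{disease}会遗传给孩子吗？",
    "哪些人群容易得{disease}？",
    "年轻人得{disease}的{kw}有多大？",
    "{disease}的发病率是多少？",
    "{disease}会不会引起{disease}？"
  ),
  HealthyLifestyle = c(
    "高血压平时吃{food}好不好？",
    "血压高能不能{activity}？",
    "饮食上多吃{food}可以降血压吗？",
    "经常{kw}对血压有影响吗？",
    "每天{activity}多长时间比较合适？"
  ),
  HealthProviderChoice = c(
    "看血压高应该挂哪个科室？",
    "哪家医院治{disease}比较好？",
    "这种情况需要去{dept}{kw}吗？",
    "要不要去医院看医生？",
    "找哪个{kw}看{disease}靠谱？"
  ),
  Other = c(
    "{kw}能报销{drug}的费用吗？",
    "网上买的血压计准不准？"
  )
)

INTERROGATIVES <- c(
  "什么", "怎么", "怎样", "如何", "为什么", "为啥", "哪", "哪些", "哪个",
  "哪种", "哪家", "哪里", "哪儿", "几", "多少", "多久", "多长时间", "多大",
  "多高", "多重", "吗", "呢", "吧", "啥", "咋", "何时", "什么时候",
  "怎么办", "怎么回事", "是否", "能否", "可否", "会不会", "能不能",
  "可不可以", "要不要", "该不该", "好不好", "行不行", "有没有", "是不是",
  "对不对"
)

# term -> (concept id, semantic type): a small synthetic stand-in for a
# controlled medical vocabulary, covering the generator's content words.
SYNTH_LEXICON <- data.frame(
  term = c(SLOT_POOLS$disease, SLOT_POOLS$drug, SLOT_POOLS$symptom),
  concept_id = c(sprintf("C%03d", 1:8), sprintf("C1%02d", 1:8),
                 sprintf("C2%02d", 1:10)),
  semantic_type = c(rep("Disease", 8), rep("Drug", 8), rep("Symptom", 10)),
  stringsAsFactors = FALSE
)

SYNTH_POS <- local({
  nouns <- c(SLOT_POOLS$symptom, SLOT_POOLS$disease, SLOT_POOLS$drug,
             SLOT_POOLS$food, SLOT_POOLS$dept,
             "血压", "高压", "医院", "医生", "科室", "专家", "病", "原因",
             "症状", "检查", "剂量", "药", "效果", "费用", "孩子", "人群",
             "年轻人", "概率", "发病率", "风险", "病人", "病情", "饮食",
             "体检", "血压计", "副作用", "禁忌", "疗效", "早餐", "体重",
             "医保", "挂号", "病情描述", "帮助")
  verbs <- c(SLOT_POOLS$activity,
             "吃", "服用", "得", "得了", "做", "治", "治疗", "控制", "监测",
             "测量", "注意", "调整", "调理", "保养", "管理", "遗传", "引起",
             "增加", "挂", "就诊", "看", "买", "报销", "诊断", "判断",
             "确诊", "查明", "饮酒", "熬夜", "应酬", "锻炼", "伴有", "发现",
             "去", "降血压")
  other <- c("最近", "总是", "以往", "最好", "比较", "合适", "平时", "日常",
             "长期", "经常", "每天", "网上", "这种", "情况", "需要", "应该",
             "才能", "可以", "一直", "一次", "稳定", "偏高", "忽高忽低",
             "服药", "期间", "容易", "靠谱", "准不准", "有点")
  stats::setNames(
    c(rep("n", length(nouns)), rep("v", length(verbs)),
      rep("x", length(other))),
    c(nouns, verbs, other)
  )
})

#' Bundled dictionary resources for the synthetic domain
#'
#' Returns the segmentation dictionary, POS dictionary, interrogative list
#' and medical lexicon that cover the generator's vocabulary. These are the
#' same data shipped as TSV fixtures under `inst/extdata/`.
#'
#' @return list with `dictionary`, `pos_dictionary`, `interrogatives`,
#'   `lexicon`.
#' @export
synth_resources <- function() {
  list(
    dictionary = unique(c(names(SYNTH_POS), INTERROGATIVES,
                          SYNTH_LEXICON$term)),
    pos_dictionary = SYNTH_POS,
    interrogatives = INTERROGATIVES,
    lexicon = SYNTH_LEXICON
  )
}

#' Write the bundled dictionaries as TSV files
#'
#' Emits `interrogatives.tsv`, `segdict.tsv`, `posdict.tsv` and
#' `lexicon.tsv` (the plain-text fixture formats the loaders read) into a
#' directory.
#'
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundled_dictionaries <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- synth_resources()
  wl <- function(lines, file) {
    con <- file(file.path(dir, file), open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con)
  }
  wl(res$interrogatives, "interrogatives.tsv")
  wl(sort(res$dictionary, method = "radix"), "segdict.tsv")
  wl(paste0(names(res$pos_dictionary), "\t", unname(res$pos_dictionary)),
     "posdict.tsv")
  wl(paste(res$lexicon$term, res$lexicon$concept_id,
           res$lexicon$semantic_type, sep = "\t"), "lexicon.tsv")
  invisible(dir)
}

# ---- generator -------------------------------------------------------------

default_topic_priors <- function() {
  counts <- c(Diagnosis = 600, Treatment = 1167, ConditionManagement = 136,
              Epidemiology = 233, HealthyLifestyle = 278,
              HealthProviderChoice = 45)
  # scale so the six topics plus the residual Other (5 / 2000) sum to one
  counts / sum(counts) * (1 - 5 / 2000)
}

#' Configuration of the synthetic corpus generator
#'
#' Defaults emulate the corpus the classifier targets: topic priors
#' proportional to the observed topic distribution of hypertension consumer
#' questions (with a 0.25% residual "Other" mass), a 26.35% multi-label
#' rate, and full vocabulary separation.
#'
#' @param n_questions number of questions to generate.
#' @param topic_priors named non-negative vector over the six topics,
#'   summing to at most 1; the remainder is the residual Other mass.
#' @param multi_label_rate probability that a (non-Other) question carries a
#'   second topic.
#' @param vocabulary_separation in `[0, 1]`: probability that a clause's
#'   template and keyword are drawn from its gold topic rather than from the
#'   pooled banks. 1 = fully topic-determined text, 0 = text independent of
#'   the gold label.
#' @param marker_rate probability that a question is wrapped in the
#'   three-field website template (so extraction has to find the marker).
#' @param seed integer seed; generation is deterministic given the config.
#' @return a `chq_synth_config` list.
#' @export
synth_config <- function(n_questions = 2000L,
                         topic_priors = default_topic_priors(),
                         multi_label_rate = 0.2635,
                         vocabulary_separation = 1,
                         marker_rate = 0.7,
                         seed = 1L) {
  if (is.null(names(topic_priors)) ||
      !setequal(names(topic_priors), PRIMARY_TOPICS)) {
    chq_stop("topic_priors must be named by the six primary topics",
             class = "chqclass_invalid_input")
  }
  topic_priors <- topic_priors[PRIMARY_TOPICS]
  if (any(topic_priors < 0) || sum(topic_priors) > 1 + 1e-12) {
    chq_stop("topic_priors must be non-negative and sum to <= 1",
             class = "chqclass_invalid_input")
  }
  stopifnot(n_questions >= 1, multi_label_rate >= 0, multi_label_rate <= 1,
            vocabulary_separation >= 0, vocabulary_separation <= 1,
            marker_rate >= 0, marker_rate <= 1)
  structure(list(n_questions = as.integer(n_questions),
                 topic_priors = topic_priors,
                 multi_label_rate = multi_label_rate,
                 vocabulary_separation = vocabulary_separation,
                 marker_rate = marker_rate,
                 seed = as.integer(seed)),
            class = "chq_synth_config")
}

fill_template <- function(template, kw_pool) {
  out <- template
  repeat {
    m <- regmatches(out, regexpr("\\{[a-z_]+\\}", out))
    if (length(m) == 0L) break
    slot <- sub("^\\{(.*)\\}$", "\\1", m)
    filler <- if (slot == "kw") {
      sample(kw_pool, 1L)
    } else {
      sample(SLOT_POOLS[[slot]], 1L)
    }
    out <- sub("\\{[a-z_]+\\}", filler, out)
  }
  out
}

make_clause <- function(topic, separation) {
  use_own <- stats::runif(1) < separation
  src <- if (use_own) topic else sample(names(TEMPLATE_BANK), 1L)
  template <- sample(TEMPLATE_BANK[[src]], 1L)
  kw_pool <- if (use_own) TOPIC_KEYWORDS[[topic]] else
    unlist(TOPIC_KEYWORDS, use.names = FALSE)
  fill_template(template, kw_pool)
}

#' Generate a synthetic consumer-health-question corpus
#'
#' Each question samples a topic set (primary topic from the priors, an
#' optional second topic with probability `multi_label_rate`), one clause
#' per gold topic, and — with probability `marker_rate` — a wrapping in the
#' website's three-field posting template.
#'
#' @param config a [synth_config()].
#' @return a `chq_synth_corpus`: list with `messages` (list of
#'   `chq_message`), `gold` (list of character topic sets), `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "chq_synth_config"))
  p6 <- config$topic_priors
  p_other <- max(0, 1 - sum(p6))
  with_seed(config$seed, {
    messages <- vector("list", config$n_questions)
    gold <- vector("list", config$n_questions)
    for (i in seq_len(config$n_questions)) {
      primary <- sample(c(PRIMARY_TOPICS, OTHER_TOPIC), 1L,
                        prob = c(p6, p_other))
      topics <- primary
      if (primary != OTHER_TOPIC &&
          stats::runif(1) < config$multi_label_rate) {
        rest <- setdiff(PRIMARY_TOPICS, primary)
        topics <- c(primary, sample(rest, 1L, prob = p6[rest]))
      }
      clauses <- vapply(topics, make_clause, character(1),
                        separation = config$vocabulary_separation)
      qtext <- paste(clauses, collapse = "")
      text <- if (stats::runif(1) < config$marker_rate) {
        paste0("病情描述：最近血压有点高。", DEFAULT_MARKER, "：", qtext)
      } else {
        qtext
      }
      messages[[i]] <- message_record(sprintf("s%05d", i), text)
      gold[[i]] <- topics
    }
    structure(list(messages = messages, gold = gold, config = config),
              class = "chq_synth_corpus")
  })
}

#' @export
print.chq_synth_corpus <- function(x, ...) {
  multi <- mean(vapply(x$gold, length, integer(1)) > 1L)
  cat(sprintf(
    "<synthetic corpus> %d questions, %.1f%% multi-label, separation %.2f, seed %d\n",
    length(x$messages), 100 * multi, x$config$vocabulary_separation,
    x$config$seed))
  invisible(x)
}

#' Background document-frequency table from a corpus
#'
#' Tokenizes every question and counts, for each term, the number of
#' questions containing it; `N` is the corpus size. The result feeds
#' [frequency_statistics()]. Deterministic given the corpus.
#'
#' @param corpus a `chq_synth_corpus`, or a list of `chq_tokens`.
#' @param resources dictionary resources (defaults to [synth_resources()]);
#'   ignored when `corpus` is already tokenized.
#' @return a `chq_df_table`.
#' @export
generate_df_table <- function(corpus, resources = synth_resources()) {
  toks <- if (inherits(corpus, "chq_synth_corpus")) {
    lapply(corpus$messages, function(m) {
      q <- extract_question(m)
      tokenize_question(q, resources$dictionary, resources$pos_dictionary,
                        resources$interrogatives)
    })
  } else {
    corpus
  }
  counts <- table(unlist(lapply(toks, function(tk) unique(tk$surface))))
  df_table(stats::setNames(as.integer(counts), names(counts)), length(toks))
}

#' Vocabulary of a topic's question patterns
#'
#' The token surfaces that can occur in questions generated from one topic's
#' templates: fixed template wording, its keyword pool, and the fillers of
#' the slots its templates use. With `distinct = TRUE` (the default) only
#' surfaces obtainable from no other topic are returned — an oracle for
#' which bag-of-words features should discriminate the topic.
#'
#' @param topic topic name (a template-bank entry).
#' @param resources dictionary resources for segmentation.
#' @param distinct drop surfaces also obtainable from other topics.
#' @return character vector of surfaces.
#' @export
topic_vocabulary <- function(topic, resources = synth_resources(),
                             distinct = TRUE) {
  stopifnot(topic %in% names(TEMPLATE_BANK))
  surfaces_of <- function(tp) {
    templates <- TEMPLATE_BANK[[tp]]
    fixed <- unlist(lapply(templates, function(t) {
      pieces <- strsplit(t, "\\{[a-z_]+\\}")[[1L]] # literal text between slots
      pieces <- pieces[nzchar(pieces)]
      unlist(lapply(pieces, segment, dictionary = resources$dictionary))
    }))
    slots <- unique(unlist(regmatches(templates,
                                      gregexpr("\\{[a-z_]+\\}", templates))))
    slots <- sub("^\\{(.*)\\}$", "\\1", slots)
    fillers <- unlist(lapply(setdiff(slots, "kw"),
                             function(s) SLOT_POOLS[[s]]))
    if ("kw" %in% slots) fillers <- c(fillers, TOPIC_KEYWORDS[[tp]])
    unique(c(fixed, fillers))
  }
  own <- surfaces_of(topic)
  if (!distinct) return(own)
  others <- unique(unlist(lapply(setdiff(names(TEMPLATE_BANK), topic),
                                 surfaces_of)))
  setdiff(own, others)
}
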